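test_that("human-gap stripping drops exactly the human-gap columns", {
  out <- strip_human_gaps(c(human = "AC-GT", chimp = "ACAGT"))
  expect_equal(unname(out["human"]), "ACGT")
  expect_equal(unname(out["chimp"]), "ACGT")

  aln <- c(human = "ACGT", chimp = "A-GT")
  expect_equal(strip_human_gaps(aln), aln)  # non-human gaps retained

  empty <- strip_human_gaps(c(human = "---", chimp = "ACG"))
  expect_true(attr(empty, "empty"))
  expect_equal(nchar(empty[["human"]]), 0)

  expect_error(strip_human_gaps(c(chimp = "ACGT")), "human")
})

test_that("F81 transition probabilities match closed-form limits", {
  m <- f81_model(c(0.1, 0.2, 0.3, 0.4))
  # zero time: identity
  for (b in c("A", "C", "G", "T")) {
    expect_equal(f81_transition_prob(m, b, b, 0), 1)
    expect_equal(f81_transition_prob(m, b, "A", 0), as.numeric(b == "A"))
  }
  # long time: stationarity
  expect_equal(f81_transition_prob(m, "A", "T", 500), 0.4, tolerance = 1e-12)
  expect_equal(f81_transition_prob(m, "G", "C", 500), 0.2, tolerance = 1e-12)
  expect_error(f81_transition_prob(m, "A", "C", -1), ">= 0")
})

test_that("F81 transition matrix equals the matrix exponential oracle", {
  skip_if_not_installed("Matrix")
  for (freq in list(rep(0.25, 4), c(0.1, 0.2, 0.3, 0.4))) {
    m <- f81_model(freq)
    for (t in c(0.01, 0.3, 1)) {
      p_impl <- vapply(BASES, function(a) {
        vapply(BASES, function(b) f81_transition_prob(m, a, b, t),
               numeric(1))
      }, numeric(4))
      expect_equal(max(abs(t(p_impl) - oracle_f81_expm(freq, t))), 0,
                   tolerance = 1e-10)
      expect_equal(rowSums(t(p_impl)), rep(1, 4), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("marginal posteriors equal exhaustive enumeration", {
  for (spec in list(
    list(tree = tiny_tree_4(), seed = 1, missing = FALSE),
    list(tree = tiny_tree_4(), seed = 2, missing = TRUE),
    list(tree = tiny_tree_5(), seed = 3, missing = TRUE)
  )) {
    freq <- c(0.3, 0.2, 0.2, 0.3)
    aln <- random_aln(spec$tree, 12, spec$seed, with_missing = spec$missing)
    post <- marginal_ancestral_posteriors(spec$tree, f81_model(freq), aln)
    oracle <- oracle_posteriors_enum(spec$tree, freq, aln)
    labs <- c(spec$tree$tip.label, spec$tree$node.label)
    ntip <- length(spec$tree$tip.label)
    for (n in seq_len(spec$tree$Nnode)) {
      got <- post$post[[labs[ntip + n]]]
      expect_equal(max(abs(got - oracle[, , n])), 0, tolerance = 1e-10)
      expect_equal(colSums(got), rep(1, ncol(got)), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("unanimous tips give near-certain posteriors on short branches", {
  tr <- tiny_tree_4()
  tr$edge.length <- rep(0.01, nrow(tr$edge))
  aln <- setNames(rep("AAAA", 4), tr$tip.label)
  post <- marginal_ancestral_posteriors(tr, f81_model(), aln)
  for (p in post$post) expect_true(all(p["A", ] > 0.999))
})

test_that("site log-likelihood matches phangorn and survives rerooting", {
  skip_if_not_installed("phangorn")
  tr <- tiny_tree_5()
  freq <- c(0.28, 0.22, 0.24, 0.26)
  aln <- random_aln(tr, 40, 5)
  model <- f81_model(freq)
  post <- marginal_ancestral_posteriors(tr, model, aln)

  dat <- phangorn::phyDat(t(vapply(aln, function(s) strsplit(s, "")[[1]],
                                   character(40))))
  fit <- phangorn::pml(tr, dat, bf = freq, model = "F81")
  expect_equal(post$loglik, as.numeric(stats::logLik(fit)), tolerance = 1e-6)

  # pulley principle: rerooting along a branch leaves the likelihood
  # unchanged under a reversible model
  skip_if_not_installed("phytools")
  tr2 <- phytools::reroot(tr, node.number = ape::getMRCA(tr, c("t1", "t2")))
  post2 <- marginal_ancestral_posteriors(tr2, model, aln)
  expect_equal(post2$loglik, post$loglik, tolerance = 1e-8)
})

test_that("branch-length optimisation recovers a simulated length", {
  # simulate 2000 sites on a 6-taxon (guide) tree, then refit
  cfg <- sim_config(seed = 42, n_gres = 1L,
                    gre_length_range = c(2000L, 2000L),
                    background_sub_rate = 0.001)
  tr <- build_guide_tree(cfg)
  sim <- simulate_alignments(tr, cfg)
  aln <- sim$alignments[[1]]

  start <- tr
  start$edge.length <- rep(0.02, nrow(start$edge))
  fit <- fit_f81(start, aln)
  expect_true(fit$optimised)
  expect_true(is.finite(fit$loglik))
  # the catarrhine->ape branch is 13 MY x 0.001 = 0.013 truth; recovery is
  # noisy at 2000 sites but must land in a sane window
  labs <- c(fit$tree$tip.label, fit$tree$node.label)
  got <- fit$tree$edge.length[fit$tree$edge[, 2] == match("Ape", labs)]
  expect_gt(got, 0.004)
  expect_lt(got, 0.04)
  # ascent: the fit never ends below its starting log-likelihood
  x <- epilineage:::aln_to_matrix(aln)
  cp <- epilineage:::compress_patterns(x)
  ll0 <- epilineage:::sum_loglik_weighted(start, fit$model, cp)
  expect_gte(fit$loglik, ll0)
})

test_that("invariant alignments fall back to the input branch lengths", {
  tr <- tiny_tree_4()
  aln <- setNames(rep("ACGTACGT", 4), tr$tip.label)
  fit <- fit_f81(tr, aln)
  expect_false(fit$optimised)
  expect_identical(fit$tree$edge.length, tr$edge.length)
  expect_true(is.finite(fit$loglik))
})

test_that("ancestral calls respect the strict 0.75 confidence rule", {
  # hand-built posterior object covering the five internal chain nodes
  nodes6 <- lineage_chain()$node
  mk_post <- function(vecs) {
    post <- lapply(nodes6[1:5], function(nd) {
      m <- do.call(cbind, vecs)
      rownames(m) <- BASES
      m
    })
    names(post) <- nodes6[1:5]
    structure(list(post = post, loglik = 0, all_missing = rep(FALSE, 3),
                   tree = NULL), class = "ancestral_posterior")
  }
  post <- mk_post(list(c(0.97, 0.01, 0.01, 0.01),
                       c(0.74, 0.26, 0, 0),
                       c(0.75, 0.25, 0, 0)))
  aln <- c(human = "GGG")
  seqs <- call_ancestral_sequences(post, aln)
  expect_equal(unname(seqs["Hominin"]), "ANN")  # 0.97 -> A; 0.74, 0.75 -> N
  expect_equal(unname(seqs["Human"]), "GGG")    # copied verbatim
})

test_that("reconstruction recovers simulated chain states at >99%", {
  cfg <- sim_config(seed = 9, n_gres = 60L, gre_length_range = c(400L, 600L))
  tr <- build_guide_tree(cfg)
  sim <- simulate_alignments(tr, cfg)
  rec <- reconstruct_gres(sim$alignments, tr)
  truth <- sim$truth$chain_states
  cmp <- dplyr::inner_join(rec, truth, by = c("gre_id", "node"),
                           suffix = c("_rec", "_true"))
  tot_nonN <- 0; agree <- 0
  for (i in seq_len(nrow(cmp))) {
    r <- strsplit(cmp$sequence_rec[i], "")[[1]]
    t <- strsplit(cmp$sequence_true[i], "")[[1]]
    keep <- r != "N"
    tot_nonN <- tot_nonN + sum(keep)
    agree <- agree + sum(r[keep] == t[keep])
  }
  expect_gt(agree / tot_nonN, 0.99)
})

test_that("gap injection is handled as missing data end to end", {
  cfg <- sim_config(seed = 13, n_gres = 10L,
                    gre_length_range = c(300L, 400L), gap_rate = 0.05)
  tr <- build_guide_tree(cfg)
  sim <- simulate_alignments(tr, cfg)
  expect_true(any(grepl("-", unlist(sim$alignments))))
  # the human record never carries gaps
  expect_false(any(grepl("-", vapply(sim$alignments, `[[`, "", "human"))))
  rec <- reconstruct_gres(sim$alignments, tr)
  expect_equal(nrow(rec), 60)
})
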