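test_that("zero substitution rate yields identical sequences across taxa", {
  cfg <- sim_config(seed = 3, n_gres = 5L, gre_length_range = c(100L, 150L),
                    background_sub_rate = 0)
  tr <- build_guide_tree(cfg)
  tr$edge.length <- tr$edge.length + 1e-9  # keep the tree usable downstream
  sim <- simulate_alignments(tr, cfg)
  for (aln in sim$alignments) {
    expect_equal(length(unique(unname(aln))), 1L)
  }
})

test_that("planted events are forced onto the named branch", {
  cfg <- sim_config(
    seed = 5, n_gres = 8L, gre_length_range = c(200L, 200L),
    planted_events = tibble::tibble(
      gre_id = c("gre_7", "gre_2"), branch = c("Human", "Ape"),
      position = c(42L, 10L), ancestral_base = c("A", "C"),
      derived_base = c("T", "G")))
  tr <- build_guide_tree(cfg)
  sim <- simulate_alignments(tr, cfg)
  a7 <- sim$alignments[["gre_7"]]
  expect_equal(substr(a7[["human"]], 43, 43), "T")
  for (t in setdiff(names(a7), "human")) {
    expect_equal(substr(a7[[t]], 43, 43), "A")
  }
  # Ape-branch event: all apes derived, monkeys ancestral
  a2 <- sim$alignments[["gre_2"]]
  for (t in cfg$taxa$ape) expect_equal(substr(a2[[t]], 11, 11), "G")
  for (t in c(cfg$taxa$owm, cfg$taxa$nwm)) {
    expect_equal(substr(a2[[t]], 11, 11), "C")
  }
  # homoplasy-free along the chain: exactly one transition at the site
  ch <- sim$truth$chain_states
  st <- vapply(lineage_chain()$node, function(nd) {
    substr(ch$sequence[ch$gre_id == "gre_7" & ch$node == nd], 43, 43)
  }, character(1))
  expect_equal(sum(st[-1] != st[-6]), 1L)

  bad <- sim_config(seed = 5, n_gres = 2L, gre_length_range = c(50L, 50L),
                    planted_events = tibble::tibble(
                      gre_id = "gre_1", branch = "Human", position = 60L,
                      ancestral_base = "A", derived_base = "T"))
  expect_error(simulate_alignments(build_guide_tree(bad), bad),
               "out of range")
})

test_that("same seed reproduces identical alignments and matrices", {
  cfg <- sim_config(seed = 21, n_gres = 6L, gre_length_range = c(150L, 250L),
                    n_genes = 20L, n_pseudobulk = 40L)
  tr <- build_guide_tree(cfg)
  s1 <- simulate_alignments(tr, cfg)
  s2 <- simulate_alignments(tr, cfg)
  expect_identical(s1$alignments, s2$alignments)
  m1 <- simulate_multiome(cfg)
  m2 <- simulate_multiome(cfg)
  expect_identical(m1$acc, m2$acc)
  expect_identical(m1$expr, m2$expr)
  # different seed differs
  cfg2 <- sim_config(seed = 22, n_gres = 6L,
                     gre_length_range = c(150L, 250L),
                     n_genes = 20L, n_pseudobulk = 40L)
  expect_false(identical(simulate_alignments(tr, cfg2)$alignments,
                         s1$alignments))
})

test_that("BED intervals are half-open, non-overlapping and truth-consistent", {
  cfg <- sim_config(seed = 8, n_gres = 12L, gre_length_range = c(100L, 300L))
  tr <- build_guide_tree(cfg)
  sim <- simulate_alignments(tr, cfg)
  bed <- sim$bed
  expect_true(all(bed$end - bed$start ==
                    nchar(vapply(sim$alignments, `[[`, "", "human"))))
  expect_true(all(bed$start[-1] >= bed$end[-nrow(bed)]))
  expect_setequal(sim$truth$chain_states$gre_id, bed$gre_id)
})

test_that("planted correlations land near their targets; nulls near zero", {
  cfg <- sim_config(
    seed = 17, n_gres = 40L, n_genes = 40L, n_pseudobulk = 200L,
    planted_links = tibble::tibble(
      gre_id = paste0("gre_", 1:5), gene_id = paste0("gene_", 1:5),
      correlation_target = c(0.8, 0.8, 0.6, -0.7, 0.8)))
  mo <- simulate_multiome(cfg)
  for (i in 1:5) {
    r <- cor(mo$acc[paste0("gre_", i), ], mo$expr[paste0("gene_", i), ])
    tgt <- cfg$planted_links$correlation_target[i]
    expect_gt(abs(r), abs(tgt) - 0.1)
    expect_lt(abs(r), abs(tgt) + 0.1)
    expect_equal(sign(r), sign(tgt))
  }
  # unplanted pairs: mean |r| small at n = 200
  r_all <- abs(cor(t(mo$acc[6:40, ]), t(mo$expr[6:40, ])))
  expect_lt(mean(r_all), 0.1)
  # linked genes placed within 500 kb of their GRE
  for (i in 1:5) {
    gs <- mo$gene_coords$start[mo$gene_coords$gene_id == paste0("gene_", i)]
    ps <- mo$gre_coords$start[mo$gre_coords$gre_id == paste0("gre_", i)]
    expect_lt(abs(gs - ps), 5e5)
  }
})

test_that("markers, motifs and detection tables honour the config", {
  cfg <- sim_config(seed = 30, n_gres = 50L, n_motifs = 6L,
                    marker_fractions = c(Microglia = 0.10, Neuron = 0.20))
  mm <- generate_motifs_and_markers(cfg)
  expect_equal(sum(mm$markers$cell_type == "Microglia"), 5L)  # floor(0.1*50)
  expect_equal(sum(mm$markers$cell_type == "Neuron"), 10L)
  # marker sets are disjoint
  expect_false(anyDuplicated(mm$markers$gre_id) > 0)
  # informative PFMs: per-column max frequency >= 0.8
  for (pfm in mm$pfms) {
    freq <- sweep(pfm, 2, colSums(pfm), "/")
    expect_true(all(apply(freq, 2, max) >= 0.8))
  }
  expect_equal(nrow(mm$detection), 6L * 2L)
  # uniform PFM rejected
  unif <- matrix(25, 4, 8)
  expect_error(generate_motifs_and_markers(cfg, pfms = list(BAD = unif)),
               "informative")
})

test_that("Poisson-count generator plants divergence and marker multipliers", {
  cfg <- sim_config(
    seed = 2, n_gres = 400L, gre_length_range = c(1000L, 1000L),
    divergent_gre_spec = tibble::tibble(lineage = "Human", n_planted = 20L,
                                        rate_multiplier = 5),
    marker_rate_multiplier = c(Microglia = 3),
    marker_fractions = c(Microglia = 0.1, Neuron = 0.2))
  mm <- generate_motifs_and_markers(cfg)
  out <- simulate_substitution_counts(cfg, markers = mm$markers)
  rt <- out$rate_table
  planted <- out$truth$divergent$Human
  expect_length(planted, 20L)
  mh <- function(ids) {
    mean(rt$count[rt$lineage == "Human" & rt$gre_id %in% ids])
  }
  others <- setdiff(unique(rt$gre_id),
                    c(planted, mm$markers$gre_id))
  expect_gt(mh(planted) / mh(others), 3)
  mg <- mm$markers$gre_id[mm$markers$cell_type == "Microglia"]
  mg <- setdiff(mg, planted)
  expect_gt(mh(mg) / mh(others), 2)
  expect_identical(simulate_substitution_counts(cfg, markers = mm$markers)$rate_table,
                   rt)
})
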