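consensus_seq <- function(pw) {
  paste(BASES[apply(pw$pfm, 2, which.max)], collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("scanning finds planted consensus on both strands, never across N", {
  cfg <- sim_config(seed = 44, n_motifs = 3L, motif_length = 10L,
                    n_gres = 10L)
  mm <- generate_motifs_and_markers(cfg)
  pw <- mm$pwms[[1]]
  cons <- consensus_seq(pw)
  pad <- strrep("A", 15)
  seqs <- tibble::tibble(
    gre_id = "g1",
    node = c("fwd", "rev", "none", "withN"),
    sequence = c(paste0(pad, cons, pad),
                 paste0(pad, revcomp(cons), pad),
                 strrep("AC", 20),
                 paste0(pad, sub("^.", "N", cons), pad)))
  pres <- scan_motifs(seqs, mm$pwms[1])
  expect_true(pres$present[pres$node == "fwd"])
  expect_true(pres$present[pres$node == "rev"])
  expect_false(pres$present[pres$node == "none"])
  expect_false(pres$present[pres$node == "withN"])
  # motif longer than sequence: absent
  short <- tibble::tibble(gre_id = "g", node = "x", sequence = "ACGT")
  expect_false(scan_motifs(short, mm$pwms[1])$present)
})

test_that("threshold DP matches exhaustive window enumeration (L <= 8)", {
  withr::with_seed(50, {
    for (len in c(6L, 7L, 8L)) {
      cons <- sample.int(4, len, TRUE)
      pfm <- matrix(5, 4, len)
      pfm[cbind(cons, seq_len(len))] <- 85
      for (p in c(5e-5, 1e-3, 0.05)) {
        pw <- build_pwm(pfm, "m", match_p = p)
        thr_oracle <- oracle_pwm_threshold(pw$score_int, pw$bg, p)
        expect_equal(pw$threshold_int, thr_oracle)
      }
    }
  })
  # a match probability below the most extreme window: no threshold
  pfm <- matrix(5, 4, 6); pfm[cbind(rep(1, 6), 1:6)] <- 85
  pw_imp <- build_pwm(pfm, "m", match_p = 1e-9)
  expect_true(is.infinite(pw_imp$threshold_int))
})

test_that("event caller keeps exactly single-transition patterns", {
  mk_presence <- function(v) {
    tibble::tibble(gre_id = "g", motif_id = "m",
                   node = lineage_chain()$node, present = as.logical(v))
  }
  ev <- call_tfbs_events(mk_presence(c(0, 0, 0, 0, 1, 1)))
  expect_equal(ev$lineage, "Hominin")
  expect_equal(ev$direction, "gain")
  expect_equal(nrow(call_tfbs_events(mk_presence(rep(1, 6)))), 0)
  expect_equal(nrow(call_tfbs_events(mk_presence(rep(0, 6)))), 0)
  expect_equal(nrow(call_tfbs_events(mk_presence(c(0, 1, 0, 1, 1, 1)))), 0)
  ev2 <- call_tfbs_events(mk_presence(c(1, 1, 1, 1, 1, 0)))
  expect_equal(ev2$lineage, "Human")
  expect_equal(ev2$direction, "loss")

  # exhaustive: all 64 presence vectors against a transition-count oracle
  for (code in 0:63) {
    v <- as.integer(intToBits(code))[1:6]
    got <- call_tfbs_events(mk_presence(v))
    ntrans <- sum(v[-1] != v[-6])
    if (ntrans == 1) {
      k <- which(v[-1] != v[-6])
      expect_equal(got$lineage, lineage_names()[k])
      expect_equal(got$direction, if (v[k + 1] == 1) "gain" else "loss")
    } else {
      expect_equal(nrow(got), 0)
    }
  }
})

test_that("gain/loss ratios conserve counts and handle zero losses", {
  ev <- tibble::tibble(
    gre_id = paste0("g", 1:30),
    motif_id = rep(c("m1", "m2"), 15),
    lineage = rep(c("Human", "Ape", "Hominin"), each = 10),
    direction = c(rep("gain", 20), rep("loss", 10)))
  gl <- gain_loss_ratios(ev)
  expect_equal(sum(gl$gains), 20)
  expect_equal(sum(gl$losses), 10)
  glob <- attr(gl, "global")
  expect_equal(sum(glob$gains), sum(gl$gains))
  r <- gl[gl$motif_id == "m1" & gl$lineage == "Human", ]
  expect_true(is.na(r$ratio) || r$ratio >= 0)
  zero_loss <- gl[gl$losses == 0 & gl$gains > 0, ]
  expect_true(all(is.na(zero_loss$ratio)))
})

test_that("a planted expansion passes the double chi-square rule", {
  rows <- list()
  withr::with_seed(60, {
    for (m in paste0("m", 1:10)) {
      for (l in lineage_names()) {
        g <- rpois(1, 20); lo <- rpois(1, 10)  # global ratio ~2
        rows[[length(rows) + 1]] <- tibble::tibble(
          motif_id = m, lineage = l, gains = g, losses = lo)
      }
    }
  })
  summ <- dplyr::bind_rows(rows) |>
    dplyr::mutate(ratio = gains / losses)
  summ$gains[summ$motif_id == "m1" & summ$lineage == "Human"] <- 80
  summ$losses[summ$motif_id == "m1" & summ$lineage == "Human"] <- 4
  res <- test_expansion_depletion(summ)
  hit <- res[res$motif_id == "m1" & res$lineage == "Human", ]
  expect_equal(hit$status, "expanded")
  expect_lt(hit$fdr_global, 0.01)
  expect_lt(hit$fdr_lineage, 0.01)

  # a motif at the global ratio everywhere stays ns
  flat <- res[res$motif_id == "m2", ]
  expect_true(all(flat$status %in% c("ns", "untested")))

  # detection filter drops motifs undetected everywhere
  det <- tidyr::expand_grid(motif_id = paste0("m", 1:10),
                            cell_type = c("A", "B")) |>
    dplyr::mutate(fraction = ifelse(motif_id == "m1", 0.1, 0.9))
  res2 <- test_expansion_depletion(summ, detection = det)
  expect_true(all(res2$status[res2$motif_id == "m1"] == "untested"))

  # chi-square matches the closed form on one hand-computed table
  st <- epilineage:::chisq_gof2(40, 45 * (2 / 3), 45)
  o <- 40; e <- 30; tot <- 45
  expect_equal(st$stat, (o - e)^2 / e + (5 - 15)^2 / 15)
})

test_that("family aggregation deduplicates member events", {
  fam <- tibble::tibble(motif_id = c("m1", "m2", "m3"),
                        family = c("F1", "F1", "F2"))
  ev <- tibble::tibble(gre_id = c("g1", "g1", "g2", "g3"),
                       motif_id = c("m1", "m2", "m3", "zz"),
                       lineage = "Human", direction = "gain")
  agg <- aggregate_family(ev, fam)
  expect_equal(nrow(agg[agg$family == "F1", ]), 1)  # dedup within family
  expect_true("zz" %in% agg$family)                  # passthrough unmapped
  expect_gte(nrow(agg), length(unique(fam$family)))
})

test_that("cell-type enrichment of events flags planted concentration", {
  universe <- paste0("g", 1:300)
  markers <- tibble::tibble(
    cell_type = rep(c("Microglia", "Neuron"), each = 50),
    gre_id = c(paste0("g", 1:50), paste0("g", 51:100)))
  ev <- tibble::tibble(gre_id = paste0("g", c(1:30, 250:254)),
                       motif_id = "m1", lineage = "Human",
                       direction = "gain")
  res <- tfbs_celltype_enrichment(ev, markers, universe)
  mg <- res[res$cell_type == "Microglia", ]
  expect_equal(mg$label, "enriched")
  expect_gt(mg$odds_ratio, 1.3)
  nn <- res[res$cell_type == "Neuron", ]
  expect_equal(nn$label, "ns")
  # p matches the one-sided hypergeometric tail
  p_or <- stats::phyper(mg$overlap - 1, 50, 250, 35, lower.tail = FALSE)
  expect_equal(mg$p, p_or, tolerance = 1e-9)
})

test_that("planted motif gains and losses are recovered from truth states", {
  pme <- tibble::tibble(
    gre_id = paste0("gre_", 1:20),
    motif_id = rep(paste0("MOTIF_", 1:4), 5),
    branch = rep(lineage_names(), 4),
    direction = rep(c("gain", "loss"), 10))
  cfg <- sim_config(seed = 71, n_gres = 25L,
                    gre_length_range = c(250L, 350L),
                    n_motifs = 4L, planted_motif_events = pme)
  mm <- generate_motifs_and_markers(cfg)
  tr <- build_guide_tree(cfg)
  sim <- simulate_alignments(tr, cfg, motifs = mm)
  pres <- scan_motifs(sim$truth$chain_states, mm$pwms)
  ev <- call_tfbs_events(pres)
  hits <- dplyr::inner_join(pme, ev,
                            by = c("gre_id", "motif_id",
                                   branch = "lineage", "direction"))
  expect_gte(nrow(hits), 19)  # >= 95% recovery
})
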