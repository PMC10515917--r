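# small helper: a rate table from a count matrix
rate_table_from_counts <- function(counts, len = 1000L) {
  n <- nrow(counts)
  tibble::tibble(
    gre_id = rep(paste0("gre_", seq_len(n)), 5),
    lineage = rep(lineage_names(), each = n),
    count = as.integer(counts[, lineage_names()]),
    length = len,
    branch_my = rep(unname(default_branch_my()[lineage_names()]), each = n)
  ) |>
    dplyr::mutate(rate_per_my = count / branch_my,
                  rate_per_my_per_kb = count / branch_my / length * 1000)
}

test_that("resampling null is deterministic and degenerates correctly", {
  counts <- matrix(2L, 50, 5, dimnames = list(NULL, lineage_names()))
  rt <- rate_table_from_counts(counts)
  expect_message(n1 <- build_resampling_null(rt, n_draw = 10000,
                                             n_iter = 100, seed = 4),
                 "lowered")
  # identical per-GRE counts -> every draw gives the same pooled proportion
  expect_true(all(abs(n1$props - 0.2) < 1e-12))
  n2 <- suppressMessages(build_resampling_null(rt, n_draw = 30,
                                               n_iter = 100, seed = 4))
  n3 <- suppressMessages(build_resampling_null(rt, n_draw = 30,
                                               n_iter = 100, seed = 4))
  n4 <- suppressMessages(build_resampling_null(rt, n_draw = 30,
                                               n_iter = 100, seed = 5))
  expect_identical(n2$props, n3$props)
  expect_identical(n2$props, n1$props)  # degenerate regardless of seed
  expect_identical(n4$props, n2$props)
})

test_that("null medians approximate the pooled full-dataset proportions", {
  cfg <- sim_config(seed = 6, n_gres = 800L)
  rt <- simulate_substitution_counts(cfg)$rate_table
  null <- suppressMessages(build_resampling_null(rt, n_draw = 400,
                                                 n_iter = 300, seed = 1))
  pooled <- rt |>
    dplyr::group_by(lineage) |>
    dplyr::summarise(n = sum(count)) |>
    dplyr::mutate(p = n / sum(n))
  expect_equal(unname(null$medians[pooled$lineage]), pooled$p,
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("divergence cutoffs behave at the edges", {
  withr::with_seed(10, {
    counts <- matrix(rpois(200 * 5, 4), 200, 5,
                     dimnames = list(NULL, lineage_names()))
  })
  counts[1, ] <- 0L                      # no substitutions -> unclassified
  counts[2, ] <- c(0L, 0L, 0L, 0L, 40L)  # hugely human-skewed
  rt <- rate_table_from_counts(counts)
  null <- suppressMessages(build_resampling_null(rt, n_draw = 200,
                                                 n_iter = 200, seed = 2))
  fit <- classify_divergent(rt, null)
  tbl <- tidy(fit)
  expect_s3_class(tbl, "tbl_df")
  g1 <- tbl[tbl$gre_id == "gre_1", ]
  expect_true(all(!g1$divergent))
  expect_true(all(is.na(g1$p)))
  expect_true(tbl$divergent[tbl$gre_id == "gre_2" &
                              tbl$lineage == "Human"])
  # below-median observation can never pass the fold-change cutoff
  low <- tbl[!is.na(tbl$fold_change) & tbl$fold_change < 1, ]
  expect_true(all(!low$divergent))
  # empirical p on the 1/n grid
  pp <- tbl$p[!is.na(tbl$p)]
  expect_true(all(abs(pp * 200 - round(pp * 200)) < 1e-9))
  # glance gives one row
  expect_equal(nrow(glance(fit)), 1)
})

test_that("conserved set excludes divergent GREs and respects the median rule", {
  withr::with_seed(11, {
    counts <- matrix(rpois(300 * 5, 3), 300, 5,
                     dimnames = list(NULL, lineage_names()))
  })
  counts[5, ] <- 0L  # all-zero GRE: strictly below every lineage median
  rt <- rate_table_from_counts(counts)
  null <- suppressMessages(build_resampling_null(rt, n_draw = 300,
                                                 n_iter = 200, seed = 3))
  fit <- classify_divergent(rt, null)
  cons <- classify_conserved(rt, fit)
  dsets <- divergent_sets(fit)
  expect_true("gre_5" %in% cons)
  expect_length(intersect(cons, unlist(dsets)), 0)
  expect_lte(length(cons), 150)  # below-median bound per lineage
  # every conserved GRE is below the median in every lineage
  meds <- rt |>
    dplyr::group_by(lineage) |>
    dplyr::summarise(med = median(rate_per_my_per_kb))
  for (l in meds$lineage) {
    r <- rt[rt$lineage == l & rt$gre_id %in% cons, ]
    expect_true(all(r$rate_per_my_per_kb < meds$med[meds$lineage == l]))
  }
})

test_that("jaccard and conservation score follow their definitions", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(c(1, 2, 3), c(3, 4)), 0.25)
  expect_equal(jaccard(character(), character()), 0)

  tbl <- tibble::tibble(gre_id = rep(c("g1", "g2"), each = 5),
                        fold_change = c(rep(1, 5), rep(2, 5)))
  cs <- conservation_score(tbl)
  expect_equal(cs$conservation_score[cs$gre_id == "g1"], 1)
  expect_equal(cs$conservation_score[cs$gre_id == "g2"], 0.5)
})

test_that("LDSC preparation clips flanks and emits 41 sliding windows", {
  gres <- tibble::tibble(chrom = "chrS1",
                         start = c(1000L, 60000L, 120000L),
                         end = c(1400L, 60500L, 120600L),
                         gre_id = c("g1", "g2", "g3"),
                         score = c(3, 2, 1))
  dir <- withr::local_tempdir()
  man <- ldsc_annotation_prep(gres, top_n = 2, out_dir = dir, mode = "flank")
  bed <- read_bed(man$file)
  expect_equal(bed$start, c(0L, 35000L))  # clipped at zero
  expect_equal(bed$end, c(26400L, 85500L))
  expect_equal(bed$gre_id, c("g1", "g2"))  # ranked by score

  man2 <- ldsc_annotation_prep(gres, top_n = 3, out_dir = dir,
                               mode = "sliding")
  expect_equal(nrow(man2), 41L)
  expect_equal(man2$shift, seq(-100000L, 100000L, by = 5000L))
  # zero-shift window is centred on the GRE centre
  b0 <- read_bed(man2$file[man2$shift == 0])
  centre <- floor((gres$start + gres$end) / 2)
  expect_equal(b0$start + 25000L, pmax(centre, 25000L))
  expect_message(
    ldsc_annotation_prep(gres, top_n = 10, out_dir = dir, mode = "flank"),
    "clamped")
})
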