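# Motif, marker and detection-table generation, plus the rate-table-level
# Poisson count generator used for classifier-scale experiments.

# every column's max frequency must reach min_max (informative PFM)
check_informative_pfm <- function(pfm, min_max = 0.8) {
  freq <- sweep(pfm, 2L, colSums(pfm), "/")
  if (any(apply(freq, 2L, max) < min_max)) {
    abort(sprintf("PFM is not informative (per-column max frequency < %.2f)",
                  min_max))
  }
  invisible(TRUE)
}

#' Generate motifs, marker sets and a TF detection table
#'
#' Builds `n_motifs` informative position frequency matrices (per-column
#' dominant base at frequency 0.85, so planted consensus matches are robust),
#' a motif-to-family map (pairs of motifs per family), cell-type marker GRE
#' sets of the configured fractions (disjoint across cell types), and a
#' per-motif, per-cell-type detection-fraction table.
#'
#' @param config A [sim_config()].
#' @param pfms Optional named list of custom 4 x L count PFMs; each must be
#'   informative (per-column max frequency >= 0.8) or generation aborts.
#' @return List with `pwms` (named list of [build_pwm()] objects), `pfms`,
#'   `family_map`, `markers` (tibble `cell_type`, `gre_id`), `detection`
#'   (tibble `motif_id`, `tf`, `cell_type`, `fraction`).
#' @export
generate_motifs_and_markers <- function(config, pfms = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$motif_length > config$gre_length_range[1]) {
    abort("motif longer than the shortest GRE")
  }
  withr::with_seed(stage_seed(config$seed, "motifs"), {
    if (is.null(pfms)) {
      pfms <- lapply(seq_len(config$n_motifs), function(i) {
        cons <- sample.int(4L, config$motif_length, replace = TRUE)
        pfm <- matrix(5, 4L, config$motif_length)
        pfm[cbind(cons, seq_len(config$motif_length))] <- 85
        rownames(pfm) <- .BASES
        pfm
      })
      names(pfms) <- paste0("MOTIF_", seq_along(pfms))
    } else {
      if (is.null(names(pfms))) abort("custom pfms must be named")
    }
    lapply(pfms, check_informative_pfm)
    if (any(vapply(pfms, ncol, integer(1)) < 6L)) {
      abort("motif lengths must be >= 6")
    }

    family_map <- tibble::tibble(
      motif_id = names(pfms),
      family = paste0("FAM_", ceiling(seq_along(pfms) / 2)))
    pwms <- purrr::imap(pfms, function(pfm, id) {
      build_pwm(pfm, motif_id = id, tf = sub("MOTIF", "TF", id),
                family = family_map$family[match(id, family_map$motif_id)])
    })

    gre_ids <- paste0("gre_", seq_len(config$n_gres))
    pool <- gre_ids
    markers <- purrr::imap(config$marker_fractions, function(frac, ct) {
      k <- floor(frac * config$n_gres)
      pick <- sort(sample(pool, k))
      pool <<- setdiff(pool, pick)
      tibble::tibble(cell_type = ct, gre_id = pick)
    }) |>
      dplyr::bind_rows()

    detection <- tidyr::expand_grid(
      motif_id = names(pfms),
      cell_type = names(config$marker_fractions)) |>
      dplyr::mutate(tf = sub("MOTIF", "TF", .data$motif_id),
                    fraction = round(stats::runif(dplyr::n()), 3)) |>
      dplyr::select("motif_id", "tf", "cell_type", "fraction")

    list(pwms = pwms, pfms = pfms, family_map = family_map,
         markers = markers, detection = detection)
  })
}

#' Simulate a substitution rate table directly (Poisson counts)
#'
#' Generates per-GRE, per-lineage substitution counts at the rate-table
#' level: counts are Poisson with mean
#' `background_sub_rate x length x branch_MY`, times the configured
#' rate multiplier on planted divergent GREs' lineages and any cell-type
#' marker multiplier. This is the generator used for classifier- and
#' enrichment-scale experiments where per-site sequence evolution adds only
#' runtime; the planted truth is identical in structure to
#' [simulate_alignments()].
#'
#' @param config A [sim_config()] (`divergent_gre_spec`,
#'   `marker_rate_multiplier` honoured).
#' @param markers Optional marker tibble (`cell_type`, `gre_id`) required
#'   when `config$marker_rate_multiplier` is set.
#' @return List with `rate_table` (as [substitution_rate_table()]),
#'   `gre_info` and `truth$divergent` (named list lineage -> GRE ids).
#' @export
simulate_substitution_counts <- function(config, markers = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_gres
  gre_ids <- paste0("gre_", seq_len(n))
  bmy <- config$branch_lengths_my
  withr::with_seed(stage_seed(config$seed, "counts"), {
    rng_len <- config$gre_length_range
    lens <- rng_len[1] + sample.int(rng_len[2] - rng_len[1] + 1L, n,
                                    replace = TRUE) - 1L
    mult <- matrix(1, n, 5L, dimnames = list(gre_ids, lineage_names()))
    divergent <- list()
    pool <- seq_len(n)
    if (!is.null(config$divergent_gre_spec)) {
      for (i in seq_len(nrow(config$divergent_gre_spec))) {
        sp <- config$divergent_gre_spec[i, ]
        pick <- sort(sample(pool, sp$n_planted))
        divergent[[sp$lineage]] <- gre_ids[pick]
        pool <- setdiff(pool, pick)
        mult[pick, sp$lineage] <- sp$rate_multiplier
      }
    }
    if (!is.null(config$marker_rate_multiplier)) {
      if (is.null(markers)) {
        abort("marker_rate_multiplier requires `markers`")
      }
      for (ct in names(config$marker_rate_multiplier)) {
        ids <- markers$gre_id[markers$cell_type == ct]
        mult[ids, ] <- mult[ids, ] * config$marker_rate_multiplier[[ct]]
      }
    }
    lambda <- config$background_sub_rate * lens *
      matrix(bmy[lineage_names()], n, 5L, byrow = TRUE) * mult
    counts <- matrix(stats::rpois(length(lambda), lambda), n, 5L)
    rate_table <- tibble::tibble(
      gre_id = rep(gre_ids, 5L),
      lineage = rep(lineage_names(), each = n),
      count = as.integer(counts),
      length = rep(lens, 5L),
      branch_my = rep(unname(bmy[lineage_names()]), each = n)
    ) |>
      dplyr::mutate(rate_per_my = .data$count / .data$branch_my,
                    rate_per_my_per_kb =
                      .data$count / .data$branch_my / .data$length * 1000)
    starts <- cumsum(c(0L, lens[-n] + 1000L))
    gre_info <- tibble::tibble(chrom = "chrS1", start = starts,
                               end = starts + lens, gre_id = gre_ids,
                               length = lens)
    list(rate_table = rate_table, gre_info = gre_info,
         truth = list(divergent = divergent))
  })
}
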