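# Count-based enrichment statistics: cell-type substitution deviation,
# Fisher marker enrichment, length-adjusted logistic enrichment, interval
# overlaps.

# 2x2 Fisher machinery shared by the marker and TFBS enrichments.
# Returns a, b, c, d, sample odds ratio (0.5 continuity only when a cell is
# zero) and the exact conditional p.
fisher_2x2 <- function(setA, setB, universe, alternative = "two.sided") {
  setA <- intersect(unique(setA), universe)
  setB <- intersect(unique(setB), universe)
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  cc <- length(setB) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), 2L, 2L)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  or <- if (min(a, b, cc, d) == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  list(a = a, b = b, c = cc, d = d, or = or, p = p)
}

#' Substitution-rate deviation across cell-type marker GREs
#'
#' For every lineage and cell type, sums the evolutionary-time-normalised
#' substitution counts (count / branch MY) over the cell type's marker GREs,
#' divides by the total marker length, and expresses the value relative to
#' the mean across cell types (values around 1; above 1 means
#' substitution-enriched relative to other cell types). Significance of an
#' excess is assessed with a one-sided 1-df chi-square of the cell type's
#' observed substitution count against its expectation under a uniform
#' per-bp rate (lineage total x cell-type length share); deviations are only
#' claimed where observed exceeds expected.
#'
#' @param rate_table Tibble from [substitution_rate_table()].
#' @param markers Tibble `cell_type`, `gre_id`.
#' @param fdr_max FDR cutoff for a significant deviation, default 1e-5.
#' @return Tibble `lineage`, `cell_type`, `deviation_ratio`, `observed`,
#'   `expected`, `p`, `fdr`, `label`.
#' @export
marker_substitution_deviation <- function(rate_table, markers,
                                          fdr_max = 1e-5) {
  cts <- unique(markers$cell_type)
  if (length(cts) < 2L) abort("need at least 2 cell types")
  lens <- rate_table |> dplyr::distinct(.data$gre_id, .data$length)
  ct_len <- markers |>
    dplyr::distinct(.data$cell_type, .data$gre_id) |>
    dplyr::left_join(lens, by = "gre_id") |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(total_len = sum(as.numeric(.data$length)),
                     .groups = "drop")
  if (any(is.na(ct_len$total_len)) || any(ct_len$total_len == 0)) {
    abort("every marker cell type needs marker GREs with nonzero length")
  }
  joined <- markers |>
    dplyr::distinct(.data$cell_type, .data$gre_id) |>
    dplyr::inner_join(rate_table, by = "gre_id",
                      relationship = "many-to-many")
  per <- joined |>
    dplyr::group_by(.data$lineage, .data$cell_type) |>
    dplyr::summarise(observed = sum(.data$count),
                     value = sum(.data$count / .data$branch_my),
                     .groups = "drop") |>
    tidyr::complete(lineage = unique(rate_table$lineage), cell_type = cts,
                    fill = list(observed = 0, value = 0)) |>
    dplyr::left_join(ct_len, by = "cell_type") |>
    dplyr::mutate(norm_value = .data$value / .data$total_len)
  out <- per |>
    dplyr::group_by(.data$lineage) |>
    dplyr::mutate(deviation_ratio = .data$norm_value / mean(.data$norm_value),
                  lineage_total = sum(as.numeric(.data$observed)),
                  expected = .data$lineage_total *
                    .data$total_len / sum(.data$total_len)) |>
    dplyr::ungroup()
  stat <- purrr::pmap(list(out$observed, out$expected, out$lineage_total),
                      function(o, e, tot) {
                        if (tot == 0 || e <= 0 || e >= tot) {
                          return(list(stat = NA_real_, p = NA_real_))
                        }
                        chisq_gof2(o, e, tot)
                      })
  out$p <- purrr::map_dbl(stat, "p")
  out$fdr <- bh_adjust(out$p)
  out$label <- dplyr::if_else(
    !is.na(out$fdr) & out$fdr < fdr_max & out$observed > out$expected,
    "enriched", "ns")
  dplyr::select(out, "lineage", "cell_type", "deviation_ratio", "observed",
                "expected", "p", "fdr", "label")
}

#' Fisher enrichment of marker GREs in a GRE class
#'
#' Two-tailed Fisher exact test of the overlap between each cell type's
#' marker GREs and a GRE class (e.g. a lineage-divergent or the conserved
#' set) over the full GRE universe, BH-adjusted across cell types. Labels
#' follow the FDR < `fdr_max` with odds ratio above/below 1 convention.
#'
#' @param markers Tibble `cell_type`, `gre_id`.
#' @param class_set Character vector of GRE ids in the class.
#' @param universe All GRE ids.
#' @param fdr_max FDR cutoff, default 0.05.
#' @param alternative Fisher tail, default two-sided.
#' @return Tibble `cell_type`, `overlap`, `odds_ratio`, `p`, `fdr`, `label`.
#' @export
fisher_marker_enrichment <- function(markers, class_set, universe,
                                     fdr_max = 0.05,
                                     alternative = "two.sided") {
  if (!length(universe)) abort("empty GRE universe")
  if (!all(class_set %in% universe)) {
    abort("class_set must be a subset of the universe")
  }
  degenerate <- setequal(class_set, universe) || !length(class_set)
  out <- markers |>
    dplyr::distinct(.data$cell_type) |>
    dplyr::pull(.data$cell_type) |>
    purrr::map(function(ct) {
      mset <- markers$gre_id[markers$cell_type == ct]
      ft <- fisher_2x2(mset, class_set, universe, alternative = alternative)
      tibble::tibble(cell_type = ct, overlap = ft$a, odds_ratio = ft$or,
                     p = ft$p)
    }) |>
    dplyr::bind_rows()
  out$fdr <- bh_adjust(out$p)
  out$label <- dplyr::case_when(
    degenerate ~ "ns",
    out$fdr < fdr_max & out$odds_ratio > 1 ~ "enriched",
    out$fdr < fdr_max & out$odds_ratio < 1 ~ "depleted",
    TRUE ~ "ns"
  )
  out
}

#' Length-adjusted logistic enrichment
#'
#' Models a binary GRE label (e.g. a species-specific accessibility class)
#' as a function of GRE length and one or more binary predictor labels
#' (e.g. lineage-divergence classes) with logistic regression, reporting the
#' Wald test on each predictor's coefficient. This controls the
#' length confound that a naive overlap test ignores. Perfect separation is
#' flagged and left unlabelled.
#'
#' @param data Tibble with one row per GRE.
#' @param response Name of the binary (logical or 0/1) response column.
#' @param predictors Character vector of binary predictor column names; one
#'   model is fitted per predictor.
#' @param length_col Name of the GRE length column, default `"length"`.
#' @param fdr_max FDR cutoff, default 0.05.
#' @return Tibble `predictor`, `beta`, `se`, `z`, `p`, `fdr`, `separated`,
#'   `label`.
#' @export
logistic_enrichment <- function(data, response, predictors,
                                length_col = "length", fdr_max = 0.05) {
  y <- as.integer(as.logical(data[[response]]))
  if (length(unique(y)) < 2L) abort("response is degenerate")
  len <- as.numeric(data[[length_col]])
  rows <- purrr::map(predictors, function(pr) {
    x <- as.integer(as.logical(data[[pr]]))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ len + x, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    beta <- unname(coef(fit)["x"])
    se <- sqrt(diag(vcov(fit))["x"])
    sep <- sep || is.na(beta) || abs(beta) > 15
    z <- beta / se
    tibble::tibble(predictor = pr, beta = beta, se = unname(se),
                   z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))),
                   separated = sep)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_adjust(out$p)
  out$label <- dplyr::case_when(
    out$separated ~ NA_character_,
    out$fdr < fdr_max & out$beta > 0 ~ "enriched",
    out$fdr < fdr_max & out$beta < 0 ~ "depleted",
    TRUE ~ "ns"
  )
  out
}

#' Any-overlap pairs between two interval sets
#'
#' BED-convention (0-based, half-open) interval intersection: a pair is
#' reported when the intervals share at least one base. Adjacent half-open
#' intervals (`[0,10)` vs `[10,20)`) do not overlap.
#'
#' @param a,b Tibbles with columns `chrom`, `start`, `end` and optionally an
#'   id column (`gre_id`, `name` or `id`; row number otherwise).
#' @return Tibble of overlapping pairs `a_id`, `b_id`, `overlap_bp`, with an
#'   attribute `"counts"` (tibble `a_id`, `n`, including zero counts).
#' @export
interval_overlap <- function(a, b) {
  get_id <- function(x) {
    for (cand in c("gre_id", "name", "id")) {
      if (cand %in% names(x)) return(as.character(x[[cand]]))
    }
    as.character(seq_len(nrow(x)))
  }
  chk <- function(x) {
    if (any(x$start >= x$end)) abort("intervals must satisfy start < end")
  }
  chk(a); chk(b)
  # half-open BED -> 1-based closed IRanges
  gr_a <- GenomicRanges::GRanges(a$chrom,
                                 IRanges::IRanges(a$start + 1L, a$end))
  gr_b <- GenomicRanges::GRanges(b$chrom,
                                 IRanges::IRanges(b$start + 1L, b$end))
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b)
  qa <- S4Vectors::queryHits(hits)
  sb <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(gr_a[qa], gr_b[sb])
  ids_a <- get_id(a); ids_b <- get_id(b)
  pairs <- tibble::tibble(a_id = ids_a[qa], b_id = ids_b[sb],
                          overlap_bp = BiocGenerics::width(ov))
  counts <- tibble::tibble(a_id = ids_a,
                           n = tabulate(qa, nbins = nrow(a)))
  attr(pairs, "counts") <- counts
  pairs
}
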