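# Motif scanning across lineage sequences and TFBS gain/loss evolution.

.PWM_SCALE <- 1000L  # log-odds are scaled to integers for the exact-DP threshold

#' Build a scannable PWM from a position frequency matrix
#'
#' Adds a pseudocount of `pseudocount / 4` to every cell of the PFM, converts
#' to probabilities per column, takes log2 odds against the background, and
#' computes the match score threshold by exact dynamic programming over the
#' integer-scaled null score distribution: the threshold is the smallest score
#' whose exceedance probability under the background model is at most
#' `match_p`.
#'
#' @param pfm 4 x L numeric matrix of counts (rows A, C, G, T).
#' @param motif_id Motif identifier.
#' @param tf Transcription factor name (defaults to `motif_id`).
#' @param family Optional TF family label.
#' @param bg Background base frequencies.
#' @param match_p Match p-value defining the threshold; default 5e-5.
#' @param pseudocount Total pseudocount added per column (0.8, i.e. 0.2 per
#'   cell).
#' @return Object of class `pwm` with the score matrices and threshold.
#' @export
build_pwm <- function(pfm, motif_id, tf = motif_id, family = NA_character_,
                      bg = rep(0.25, 4), match_p = 5e-5, pseudocount = 0.8) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L) abort("PFM must have 4 rows (A, C, G, T)")
  if (ncol(pfm) < 1L) abort("PFM must have at least one column")
  if (any(pfm < 0)) abort("PFM entries must be non-negative")
  prob <- sweep(pfm + pseudocount / 4, 2L, colSums(pfm) + pseudocount, "/")
  lo <- log2(prob / bg)
  s_int <- round(lo * .PWM_SCALE)
  thr <- pwm_threshold_int(s_int, bg, match_p)
  structure(list(motif_id = motif_id, tf = tf, family = family,
                 pfm = pfm, prob = prob, logodds = lo, bg = bg,
                 score_int = s_int, threshold_int = thr, match_p = match_p),
            class = "pwm")
}

# Exact null distribution of the integer window score by DP (convolution
# across columns); returns the minimal integer score s with
# P(S >= s) <= match_p, or Inf when even the maximal score is too likely.
pwm_threshold_int <- function(s_int, bg, match_p) {
  d <- 1
  off <- 0L  # d[k] = P(S = off + k - 1) over the columns processed so far
  for (j in seq_len(ncol(s_int))) {
    mn <- min(s_int[, j])
    mx <- max(s_int[, j])
    nd <- numeric(length(d) + (mx - mn))
    for (b in 1:4) {
      idx <- seq_along(d) + (s_int[b, j] - mn)
      nd[idx] <- nd[idx] + d * bg[b]
    }
    d <- nd
    off <- off + mn
  }
  tail_p <- rev(cumsum(rev(d)))
  # smallest achievable score whose exceedance probability is <= match_p
  ok <- which(tail_p <= match_p & d > 0)
  if (!length(ok)) return(Inf)
  off + ok[1L] - 1L
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$motif_id, " (", ncol(x$pfm), " bp, TF ", x$tf,
      ", threshold ", x$threshold_int / .PWM_SCALE, " bits at p=",
      x$match_p, ")\n", sep = "")
  invisible(x)
}

# integer scores of all windows of int-coded sequence `xi` (1..6);
# windows containing N/gap score -Inf. Returns numeric vector (possibly empty).
pwm_window_scores <- function(xi, pwm) {
  l <- ncol(pwm$score_int)
  n <- length(xi)
  if (n < l) return(numeric(0))
  e <- embed(xi, l)[, l:1, drop = FALSE]  # windows x L
  bad <- rowSums(e > 4L) > 0L
  e[e > 4L] <- 1L
  sc <- matrix(pwm$score_int[cbind(as.vector(e), rep(seq_len(l), each = nrow(e)))],
               nrow(e), l)
  out <- rowSums(sc)
  out[bad] <- -Inf
  out
}

.COMPLEMENT <- c(4L, 3L, 2L, 1L, 5L, 6L)

# does the motif match anywhere on either strand?
pwm_matches_int <- function(xi, pwm) {
  if (is.infinite(pwm$threshold_int) && pwm$threshold_int > 0) return(FALSE)
  s <- pwm_window_scores(xi, pwm)
  if (length(s) && any(s >= pwm$threshold_int)) return(TRUE)
  rc <- rev(.COMPLEMENT[xi])
  s <- pwm_window_scores(rc, pwm)
  length(s) > 0L && any(s >= pwm$threshold_int)
}

#' Scan motifs across lineage sequences
#'
#' Log-odds scan of every PWM against every sequence, both strands, at every
#' offset; a sequence is scored present for a motif when any window reaches
#' the motif's threshold (see [build_pwm()]). Windows containing N or gaps
#' never match; motifs longer than the sequence are absent.
#'
#' @param lineage_seqs Tibble with columns `gre_id`, `node`, `sequence`
#'   (e.g. from [reconstruct_gres()] or the simulator truth).
#' @param pwms List of [build_pwm()] objects (a `pwm_set` from
#'   [generate_motifs_and_markers()] works as is).
#' @return Tibble `gre_id`, `motif_id`, `node`, `present` (logical).
#' @export
scan_motifs <- function(lineage_seqs, pwms) {
  stopifnot(all(c("gre_id", "node", "sequence") %in% names(lineage_seqs)))
  ints <- lapply(lineage_seqs$sequence, seq_to_int)
  rows <- lapply(pwms, function(pw) {
    tibble::tibble(
      gre_id = lineage_seqs$gre_id,
      motif_id = pw$motif_id,
      node = lineage_seqs$node,
      present = vapply(ints, pwm_matches_int, logical(1), pwm = pw)
    )
  })
  dplyr::bind_rows(rows)
}

#' Call TFBS gain and loss events along the lineage chain
#'
#' For each (GRE, motif) pair, orders the presence states along the six-node
#' chain (deepest first) and keeps only single-transition patterns: exactly
#' one 0 to 1 transition is a gain, exactly one 1 to 0 a loss, assigned to
#' the lineage in which the change occurred. Zero or two-plus transitions
#' yield no event (unstable patterns are discarded).
#'
#' @param presence Tibble from [scan_motifs()] covering all six chain nodes.
#' @param human Node id used for the human tip in `presence` (default
#'   `"Human"`).
#' @return Tibble `gre_id`, `motif_id`, `lineage`, `direction`.
#' @export
call_tfbs_events <- function(presence, human = "Human") {
  nodes <- chain_nodes()
  pres <- presence
  pres$node[pres$node == human] <- "Human"
  pres <- pres[pres$node %in% nodes, , drop = FALSE]
  wide <- tidyr::pivot_wider(pres, id_cols = c("gre_id", "motif_id"),
                             names_from = "node", values_from = "present")
  if (!all(nodes %in% names(wide))) {
    abort("presence must cover all six chain nodes")
  }
  m <- as.matrix(wide[, nodes])
  storage.mode(m) <- "integer"
  keep <- stats::complete.cases(m)
  wide <- wide[keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]
  d <- m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  ntrans <- rowSums(d != 0L)
  ev <- which(ntrans == 1L)
  if (!length(ev)) {
    return(tibble::tibble(gre_id = character(), motif_id = character(),
                          lineage = character(), direction = character()))
  }
  j <- max.col(abs(d[ev, , drop = FALSE]), ties.method = "first")
  tibble::tibble(
    gre_id = wide$gre_id[ev],
    motif_id = wide$motif_id[ev],
    lineage = lineage_names()[j],
    direction = ifelse(d[cbind(ev, j)] > 0L, "gain", "loss")
  )
}

#' Gain/loss counts and ratios per motif and lineage
#'
#' Counts gains and losses per motif across all GREs and forms the gain/loss
#' ratio per motif and lineage; the ratio is missing (`NA`) when there are no
#' losses (counts are still reported). The per-lineage totals over all motifs
#' are attached as attribute `"global"`.
#'
#' @param events Tibble from [call_tfbs_events()] (or family-aggregated
#'   events; the motif column may be named `motif_id` or `family`).
#' @return Tibble `motif_id`, `lineage`, `gains`, `losses`, `ratio`.
#' @export
gain_loss_ratios <- function(events) {
  key <- if ("motif_id" %in% names(events)) "motif_id" else "family"
  ev <- dplyr::rename(events, motif_id = dplyr::all_of(key))
  grid <- tidyr::expand_grid(motif_id = unique(ev$motif_id),
                             lineage = lineage_names())
  counts <- ev |>
    dplyr::count(.data$motif_id, .data$lineage, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  for (col in c("gain", "loss")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- grid |>
    dplyr::left_join(counts, by = c("motif_id", "lineage")) |>
    dplyr::mutate(gains = dplyr::coalesce(.data$gain, 0L),
                  losses = dplyr::coalesce(.data$loss, 0L),
                  ratio = dplyr::if_else(.data$losses > 0,
                                         .data$gains / .data$losses,
                                         NA_real_)) |>
    dplyr::select("motif_id", "lineage", "gains", "losses", "ratio")
  global <- out |>
    dplyr::group_by(.data$lineage) |>
    dplyr::summarise(gains = sum(.data$gains), losses = sum(.data$losses),
                     ratio = dplyr::if_else(sum(.data$losses) > 0,
                                            sum(.data$gains) / sum(.data$losses),
                                            NA_real_),
                     .groups = "drop")
  attr(out, "global") <- global
  out
}

#' Flag significant TFBS expansions and depletions
#'
#' Tests each motif-lineage gain/loss ratio against (i) the overall gain/loss
#' ratio pooled over all motifs and lineages (one-df goodness of fit of the
#' gain/loss split) and (ii) the same motif's pooled other-lineage counts
#' (2x2 chi-square; 0.5 continuity when a cell is zero). P-values are BH
#' adjusted separately per test family. A motif-lineage is `expanded` when
#' both FDRs are below `fdr_max` and its continuity-corrected ratio exceeds
#' both reference ratios, `depleted` symmetrically below. Motifs with fewer
#' than `min_events` total events, and motifs whose TF is detected in fewer
#' than `min_detect` of cells in every cell type, are not tested.
#'
#' @param summary Tibble from [gain_loss_ratios()].
#' @param detection Optional tibble `motif_id` (or `tf`), `cell_type`,
#'   `fraction` of cells in which the TF is detected.
#' @param min_detect Detection-fraction filter, default 0.25.
#' @param min_events Minimum gains+losses per motif-lineage to test.
#' @param fdr_max Significance cutoff on both FDRs, default 0.01.
#' @return `summary` with columns `p_global`, `fdr_global`, `p_lineage`,
#'   `fdr_lineage`, `status` in `{expanded, depleted, ns, untested}`.
#' @export
test_expansion_depletion <- function(summary, detection = NULL,
                                     min_detect = 0.25, min_events = 5L,
                                     fdr_max = 0.01) {
  global <- attr(summary, "global")
  if (is.null(global)) {
    global <- summary |>
      dplyr::group_by(.data$lineage) |>
      dplyr::summarise(gains = sum(.data$gains), losses = sum(.data$losses),
                       .groups = "drop")
  }
  g_tot <- sum(global$gains); l_tot <- sum(global$losses)
  p0 <- g_tot / (g_tot + l_tot)
  ratio0 <- g_tot / l_tot

  detected <- unique(summary$motif_id)
  if (!is.null(detection)) {
    key <- if ("motif_id" %in% names(detection)) "motif_id" else "tf"
    det <- detection |>
      dplyr::group_by(id = .data[[key]]) |>
      dplyr::summarise(max_frac = max(.data$fraction), .groups = "drop")
    detected <- det$id[det$max_frac >= min_detect]
  }

  out <- summary |>
    dplyr::group_by(.data$motif_id) |>
    dplyr::mutate(oth_gains = sum(.data$gains) - .data$gains,
                  oth_losses = sum(.data$losses) - .data$losses) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      tested = .data$motif_id %in% detected &
        (.data$gains + .data$losses) >= min_events
    )
  n <- nrow(out)
  p_g <- p_l <- rep(NA_real_, n)
  cr <- function(g, l) (g + 0.5) / (l + 0.5)
  for (i in seq_len(n)) {
    if (!out$tested[i]) next
    g <- out$gains[i]; l <- out$losses[i]; tot <- g + l
    p_g[i] <- chisq_gof2(g, tot * p0, tot)$p
    p_l[i] <- chisq_2x2(matrix(c(g, l, out$oth_gains[i], out$oth_losses[i]),
                               2L, 2L))$p
  }
  fdr_g <- fdr_l <- rep(NA_real_, n)
  fdr_g[out$tested] <- bh_adjust(p_g[out$tested])
  fdr_l[out$tested] <- bh_adjust(p_l[out$tested])
  ratio_c <- cr(out$gains, out$losses)
  ratio_oth <- cr(out$oth_gains, out$oth_losses)
  status <- dplyr::case_when(
    !out$tested ~ "untested",
    fdr_g < fdr_max & fdr_l < fdr_max &
      ratio_c > ratio0 & ratio_c > ratio_oth ~ "expanded",
    fdr_g < fdr_max & fdr_l < fdr_max &
      ratio_c < ratio0 & ratio_c < ratio_oth ~ "depleted",
    TRUE ~ "ns"
  )
  out |>
    dplyr::mutate(p_global = p_g, fdr_global = fdr_g,
                  p_lineage = p_l, fdr_lineage = fdr_l, status = status) |>
    dplyr::select(-"oth_gains", -"oth_losses", -"tested")
}

#' Aggregate motif events into TF-family events
#'
#' Unions member-motif events per family, deduplicated per GRE, lineage and
#' direction (two members gained in the same GRE and lineage count once).
#' Motifs absent from `family_map` pass through with their own id as family.
#'
#' @param events Tibble from [call_tfbs_events()].
#' @param family_map Tibble `motif_id`, `family`.
#' @return Tibble `gre_id`, `family`, `lineage`, `direction`.
#' @export
aggregate_family <- function(events, family_map) {
  events |>
    dplyr::left_join(family_map, by = "motif_id") |>
    dplyr::mutate(family = dplyr::coalesce(.data$family, .data$motif_id)) |>
    dplyr::distinct(.data$gre_id, .data$family, .data$lineage,
                    .data$direction)
}

#' Cell-type marker enrichment of TFBS events
#'
#' For each motif (or family), direction and cell type, tests whether GREs
#' carrying the event are enriched among the cell type's marker GREs with a
#' Fisher exact test over the full GRE universe. Default one-tailed
#' (`greater`); two-tailed is available for class-style contrasts.
#'
#' @param events Event tibble (`motif_id` or `family` column).
#' @param markers Tibble `cell_type`, `gre_id`.
#' @param universe Character vector of all GRE ids.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param or_min Odds-ratio cutoff for the enriched label, default 1.3.
#' @param fdr_max FDR cutoff, default 0.05.
#' @return Tibble with one row per motif x direction x cell type:
#'   overlap counts, odds ratio, p, FDR and label.
#' @export
tfbs_celltype_enrichment <- function(events, markers, universe,
                                     alternative = c("greater", "two.sided"),
                                     or_min = 1.3, fdr_max = 0.05) {
  alternative <- match.arg(alternative)
  key <- if ("motif_id" %in% names(events)) "motif_id" else "family"
  combos <- events |> dplyr::distinct(.data[[key]], .data$direction)
  cell_types <- unique(markers$cell_type)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    mset <- events$gre_id[events[[key]] == combos[[key]][i] &
                            events$direction == combos$direction[i]]
    mset <- unique(mset)
    for (ct in cell_types) {
      cset <- unique(markers$gre_id[markers$cell_type == ct])
      ft <- fisher_2x2(mset, cset, universe, alternative = alternative)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        motif_id = combos[[key]][i], direction = combos$direction[i],
        cell_type = ct, overlap = ft$a, odds_ratio = ft$or, p = ft$p
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(motif_id = character(), direction = character(),
                          cell_type = character(), overlap = integer(),
                          odds_ratio = numeric(), p = numeric(),
                          fdr = numeric(), label = character()))
  }
  out$fdr <- bh_adjust(out$p)
  out$label <- dplyr::case_when(
    out$fdr < fdr_max & out$odds_ratio > or_min ~ "enriched",
    alternative == "two.sided" & out$fdr < fdr_max &
      out$odds_ratio < 1 / or_min ~ "depleted",
    TRUE ~ "ns"
  )
  out
}
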