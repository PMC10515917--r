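# Resampling-based divergence/conservation classification of GREs and
# LD-score-regression annotation preparation.

#' Build the resampling background of lineage substitution proportions
#'
#' Draws `n_draw` GREs without replacement `n_iter` times; each draw yields
#' one pooled per-lineage proportion of substitutions (lineage count sum /
#' total sum over the drawn GREs). When the dataset holds fewer than
#' `n_draw` GREs, `n_draw` is lowered to the dataset size (with a message).
#'
#' @param rate_table Tibble from [substitution_rate_table()].
#' @param n_draw GREs per draw, default 10000.
#' @param n_iter Number of draws, default 1000.
#' @param seed Integer seed.
#' @return Object of class `resampling_null`: list with `props` (n_iter x 5
#'   matrix), `medians` (named), `n_draw`, `n_iter`.
#' @export
build_resampling_null <- function(rate_table, n_draw = 10000L,
                                  n_iter = 1000L, seed = 1L) {
  counts <- rate_table |>
    tidyr::pivot_wider(id_cols = "gre_id", names_from = "lineage",
                       values_from = "count")
  m <- as.matrix(counts[, lineage_names()])
  if (!nrow(m)) abort("empty rate table")
  if (nrow(m) < n_draw) {
    inform(sprintf("n_draw lowered from %d to dataset size %d",
                   n_draw, nrow(m)))
    n_draw <- nrow(m)
  }
  props <- matrix(NA_real_, n_iter, 5L,
                  dimnames = list(NULL, lineage_names()))
  withr::with_seed(seed, {
    for (i in seq_len(n_iter)) {
      idx <- sample.int(nrow(m), n_draw)
      cs <- colSums(m[idx, , drop = FALSE])
      props[i, ] <- cs / sum(cs)
    }
  })
  structure(list(props = props, medians = apply(props, 2L, stats::median),
                 n_draw = n_draw, n_iter = n_iter),
            class = "resampling_null")
}

#' Classify lineage-divergent GREs
#'
#' Implements the three-cutoff classification. Per GRE, the per-lineage
#' substitution proportion (lineage count / total count in the GRE) is
#' compared against the resampling background: the empirical p-value is the
#' number of background proportions exceeding the observation divided by the
#' number of draws, BH-adjusted per lineage; the fold change divides the
#' observed proportion by the background median. A GRE is divergent in
#' lineage L when FDR < `fdr_max`, fold change > `fc_min`, its z-scored
#' proportion (standardised across all GREs with substitutions, per lineage)
#' exceeds `z_min`, and it carries at least `min_subs` substitutions in L.
#' A GRE may qualify in more than one lineage.
#'
#' @param rate_table Tibble from [substitution_rate_table()].
#' @param null A [build_resampling_null()] on the same GRE universe.
#' @param fc_min,fdr_max,z_min,min_subs The three cutoffs plus the minimum
#'   substitution count (defaults 1.5, 0.05, 1, 2).
#' @return Object of class `divergence_fit`; see [tidy.divergence_fit()].
#'   The per-GRE, per-lineage table is in `$table`; `divergent_sets()`
#'   extracts the id sets.
#' @export
classify_divergent <- function(rate_table, null, fc_min = 1.5,
                               fdr_max = 0.05, z_min = 1, min_subs = 2L) {
  stopifnot(inherits(null, "resampling_null"))
  wide <- rate_table |>
    tidyr::pivot_wider(id_cols = "gre_id", names_from = "lineage",
                       values_from = "count")
  m <- as.matrix(wide[, lineage_names()])
  tot <- rowSums(m)
  prop <- m / ifelse(tot > 0, tot, NA_real_)

  p <- fc <- z <- matrix(NA_real_, nrow(m), 5L,
                         dimnames = list(NULL, lineage_names()))
  for (l in seq_len(5L)) {
    nl <- sort(null$props[, l])
    obs <- prop[, l]
    # #{null > obs} = n_iter - #{null <= obs}, via the sorted null values
    n_le <- findInterval(obs, nl)
    p[, l] <- (null$n_iter - n_le) / null$n_iter
    fc[, l] <- obs / null$medians[l]
    ok <- !is.na(obs)
    z[ok, l] <- (obs[ok] - mean(obs[ok])) / stats::sd(obs[ok])
  }
  fdr <- apply(p, 2L, bh_adjust)

  tbl <- tibble::tibble(
    gre_id = rep(wide$gre_id, 5L),
    lineage = rep(lineage_names(), each = nrow(m)),
    count = as.integer(m),
    total = rep(as.integer(tot), 5L),
    proportion = as.numeric(prop),
    p = as.numeric(p),
    fdr = as.numeric(fdr),
    fold_change = as.numeric(fc),
    z = as.numeric(z)
  ) |>
    dplyr::mutate(divergent = !is.na(.data$fdr) & .data$fdr < fdr_max &
                    !is.na(.data$fold_change) & .data$fold_change > fc_min &
                    !is.na(.data$z) & .data$z > z_min &
                    .data$count >= min_subs)
  structure(list(table = tbl, null_medians = null$medians,
                 params = list(fc_min = fc_min, fdr_max = fdr_max,
                               z_min = z_min, min_subs = min_subs,
                               n_iter = null$n_iter, n_draw = null$n_draw)),
            class = "divergence_fit")
}

#' @export
print.divergence_fit <- function(x, ...) {
  nd <- x$table |> dplyr::filter(.data$divergent) |> dplyr::count(.data$lineage)
  cat("<divergence_fit> ", dplyr::n_distinct(x$table$gre_id), " GREs\n",
      sep = "")
  if (nrow(nd)) {
    cat("  divergent:",
        paste(sprintf("%s=%d", nd$lineage, nd$n), collapse = ", "), "\n")
  } else cat("  divergent: none\n")
  invisible(x)
}

#' Extract the lineage-divergent GRE sets
#'
#' @param fit A [classify_divergent()] result.
#' @return Named list lineage -> character vector of divergent GRE ids.
#' @export
divergent_sets <- function(fit) {
  stopifnot(inherits(fit, "divergence_fit"))
  tbl <- dplyr::filter(fit$table, .data$divergent)
  sets <- split(tbl$gre_id, factor(tbl$lineage, levels = lineage_names()))
  lapply(sets, unique)
}

#' Identify conserved GREs
#'
#' Per lineage, GREs whose normalised substitution rate (per MY per kb) lies
#' strictly below the lineage median; the conserved set is the intersection
#' across all five lineages minus every lineage-divergent GRE.
#'
#' @param rate_table Tibble from [substitution_rate_table()].
#' @param divergent A [classify_divergent()] fit or a list of divergent id
#'   sets.
#' @return Character vector of conserved GRE ids.
#' @export
classify_conserved <- function(rate_table, divergent) {
  dsets <- if (inherits(divergent, "divergence_fit")) {
    divergent_sets(divergent)
  } else divergent
  below <- rate_table |>
    dplyr::group_by(.data$lineage) |>
    dplyr::mutate(below = .data$rate_per_my_per_kb <
                    stats::median(.data$rate_per_my_per_kb)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$gre_id) |>
    dplyr::summarise(all_below = all(.data$below), .groups = "drop")
  setdiff(below$gre_id[below$all_below], unlist(dsets))
}

#' Jaccard similarity between two id sets
#'
#' @param a,b Character vectors.
#' @return `|A intersect B| / |A union B|`; 0 for an empty union.
#' @examples
#' jaccard(c("a", "b", "c"), c("c", "d"))
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Per-GRE conservation score
#'
#' `1 / mean(fold change across the five lineages)`; higher means more
#' conserved. Missing where the mean fold change is undefined or zero
#' (e.g. GREs without substitutions).
#'
#' @param fit A [classify_divergent()] result (or its `$table`).
#' @return Tibble `gre_id`, `conservation_score`.
#' @export
conservation_score <- function(fit) {
  tbl <- if (inherits(fit, "divergence_fit")) fit$table else fit
  tbl |>
    dplyr::group_by(.data$gre_id) |>
    dplyr::summarise(mean_fc = mean(.data$fold_change), .groups = "drop") |>
    dplyr::mutate(conservation_score =
                    dplyr::if_else(!is.na(.data$mean_fc) & .data$mean_fc > 0,
                                   1 / .data$mean_fc, NA_real_)) |>
    dplyr::select("gre_id", "conservation_score")
}

#' Prepare LD-score-regression annotation BED files
#'
#' Two modes. `"flank"`: takes the `top_n` highest-scoring GREs, expands each
#' by `flank` bp on both sides (clipped at 0) and writes one BED file.
#' `"sliding"`: writes one BED per window shift in `shift_grid` (default
#' -100 kb to +100 kb in 5 kb steps, 41 files), each a `window`-wide interval
#' centred at the GRE centre plus the shift, for the same `top_n` GREs.
#'
#' @param gres Tibble `chrom`, `start`, `end`, `gre_id`, `score` (ranking
#'   score: e.g. a lineage's divergence fold change, or the conservation
#'   score).
#' @param top_n Number of top-ranked GREs (20000, 10000 or 5000 in typical
#'   use); clamped to the dataset size with a message.
#' @param out_dir Output directory (created if needed).
#' @param mode `"flank"` or `"sliding"`.
#' @param flank Expansion in bp for flank mode, default 25000.
#' @param window Window width for sliding mode, default 50000.
#' @param shift_grid Shifts in bp for sliding mode.
#' @param prefix File-name prefix.
#' @return Tibble manifest (`file`, `shift` where applicable, `n_intervals`),
#'   invisibly; files are written as 4-column BED (0-based half-open).
#' @export
ldsc_annotation_prep <- function(gres, top_n, out_dir,
                                 mode = c("flank", "sliding"),
                                 flank = 25000L, window = 50000L,
                                 shift_grid = seq(-100000L, 100000L,
                                                  by = 5000L),
                                 prefix = "ldsc") {
  mode <- match.arg(mode)
  stopifnot(all(c("chrom", "start", "end", "gre_id", "score") %in%
                  names(gres)))
  if (top_n > nrow(gres)) {
    inform(sprintf("top_n clamped from %d to dataset size %d",
                   top_n, nrow(gres)))
    top_n <- nrow(gres)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  top <- gres |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gre_id) |>
    dplyr::slice_head(n = top_n)
  write_bed <- function(tbl, path) {
    readr::write_tsv(tbl[, c("chrom", "start", "end", "gre_id")], path,
                     col_names = FALSE, progress = FALSE)
  }
  if (mode == "flank") {
    out <- top |>
      dplyr::mutate(start = pmax(0L, .data$start - as.integer(flank)),
                    end = .data$end + as.integer(flank))
    f <- file.path(out_dir, sprintf("%s_top%d_flank%d.bed", prefix, top_n,
                                    flank))
    write_bed(out, f)
    return(invisible(tibble::tibble(file = f, n_intervals = nrow(out))))
  }
  centre <- floor((top$start + top$end) / 2)
  half <- floor(window / 2)
  manifest <- purrr::map(shift_grid, function(sh) {
    st <- pmax(0, centre + sh - half)
    en <- centre + sh + half
    keep <- en > 0
    out <- tibble::tibble(chrom = top$chrom[keep],
                          start = as.integer(st[keep]),
                          end = as.integer(en[keep]),
                          gre_id = top$gre_id[keep])
    f <- file.path(out_dir, sprintf("%s_window%d_shift%+dkb.bed", prefix,
                                    window, as.integer(sh / 1000)))
    write_bed(out, f)
    tibble::tibble(file = f, shift = sh, n_intervals = nrow(out))
  }) |>
    dplyr::bind_rows()
  invisible(manifest)
}
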