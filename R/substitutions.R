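# Lineage-specific single-event substitution calling from the six chain
# sequences, rate normalisation and the GC conversion ratio.

#' Call a substitution at one site of the lineage chain
#'
#' Given the six chain states ordered deepest (Catarrhine ancestor) to
#' shallowest (Human), applies the retention criteria: every state must be
#' confidently reconstructed (no `N`), and exactly one state transition may
#' exist between consecutive chain nodes. Sites with two or more transitions
#' (changes that occurred more than once, or were reversed in a daughter
#' lineage) are discarded; a single transition is returned as a substitution
#' on the lineage in which it occurred, with the deeper state as ancestral
#' and the shallower as derived.
#'
#' @param states Character vector of 6 states over A/C/G/T/N, deepest first.
#' @return One-row tibble (`lineage`, `ancestral_base`, `derived_base`) or
#'   `NULL` when no single-event substitution is retained.
#' @examples
#' # retained: one change on the African Great Ape branch (A -> T)
#' call_site(c("A", "A", "A", "T", "T", "T"))
#' # discarded: two changes along the chain
#' call_site(c("G", "G", "C", "C", "C", "A"))
#' @export
call_site <- function(states) {
  if (length(states) != 6L) abort("need exactly 6 chain states")
  if (any(states == "N")) return(NULL)
  if (!all(states %in% .BASES)) abort("states must be A/C/G/T/N")
  chg <- which(states[-1L] != states[-6L])
  if (length(chg) != 1L) return(NULL)
  tibble::tibble(lineage = lineage_names()[chg],
                 ancestral_base = states[chg],
                 derived_base = states[chg + 1L])
}

#' Call all substitutions within one GRE
#'
#' Applies the single-transition criteria of [call_site()] to every position
#' of the six chain sequences (vectorised), returning records sorted by
#' position. Genome positions are 0-based offsets from the GRE's BED start.
#'
#' @param chain_seqs Named character vector of the six chain sequences
#'   (names `Catarrhine`..`Human`), equal lengths.
#' @param gre_id GRE identifier.
#' @param chrom,start GRE interval (0-based BED start); used to compute
#'   `position` on the pseudo-genome.
#' @return Tibble `lineage`, `chrom`, `position`, `gre_id`, `offset`,
#'   `ancestral_base`, `derived_base`.
#' @export
call_gre <- function(chain_seqs, gre_id, chrom = NA_character_, start = 0L) {
  nodes <- chain_nodes()
  if (!all(nodes %in% names(chain_seqs))) {
    abort("chain_seqs must be named with the six chain nodes")
  }
  m <- aln_to_matrix(chain_seqs[nodes])  # 6 x S, codes 1..5
  if (any(m == 6L)) abort("chain sequences must not contain gaps")
  ok <- colSums(m == 5L) == 0L
  d <- m[-1L, , drop = FALSE] != m[-6L, , drop = FALSE]
  sel <- which(ok & colSums(d) == 1L)
  if (!length(sel)) {
    return(tibble::tibble(lineage = character(), chrom = character(),
                          position = integer(), gre_id = character(),
                          offset = integer(), ancestral_base = character(),
                          derived_base = character()))
  }
  j <- max.col(t(d[, sel, drop = FALSE]), ties.method = "first")
  tibble::tibble(
    lineage = lineage_names()[j],
    chrom = chrom,
    position = as.integer(start) + sel - 1L,
    gre_id = gre_id,
    offset = sel - 1L,
    ancestral_base = .BASES[m[cbind(j, sel)]],
    derived_base = .BASES[m[cbind(j + 1L, sel)]]
  )
}

#' Call substitutions across all GREs
#'
#' @param chain_tbl Tibble `gre_id`, `node`, `sequence` (six rows per GRE),
#'   e.g. from [reconstruct_gres()].
#' @param bed Tibble `chrom`, `start`, `end`, `gre_id` with the GRE
#'   intervals (0-based half-open).
#' @return Tibble of substitution records, as in [call_gre()].
#' @export
call_substitutions <- function(chain_tbl, bed) {
  split_tbl <- split(chain_tbl, chain_tbl$gre_id)
  hit <- match(names(split_tbl), bed$gre_id)
  if (anyNA(hit)) abort("bed is missing intervals for some GREs")
  bed_idx <- bed[hit, ]
  out <- purrr::map2(split_tbl, seq_along(split_tbl), function(g, i) {
    seqs <- stats::setNames(g$sequence, g$node)
    call_gre(seqs, gre_id = g$gre_id[1],
             chrom = bed_idx$chrom[i], start = bed_idx$start[i])
  })
  dplyr::bind_rows(out)
}

#' Per-GRE, per-lineage substitution counts and normalised rates
#'
#' Sums substitutions per lineage and GRE, divides by the lineage branch time
#' in million years, then by the GRE length in bp, and multiplies by 1000 to
#' obtain the normalised substitution rate per MY per kb. All GRE x lineage
#' combinations are present (zero counts included).
#'
#' @param subs Substitution records from [call_substitutions()].
#' @param gre_info Tibble `gre_id`, `length` (bp). A `bed` tibble works:
#'   lengths are derived from `end - start` when no `length` column exists.
#' @param branch_my Named lineage branch times in MY; see
#'   [default_branch_my()].
#' @return Tibble `gre_id`, `lineage`, `count`, `length`, `branch_my`,
#'   `rate_per_my`, `rate_per_my_per_kb`.
#' @examples
#' subs <- tibble::tibble(gre_id = "g1", lineage = "Human")
#' substitution_rate_table(subs, tibble::tibble(gre_id = "g1", length = 1000))
#' @export
substitution_rate_table <- function(subs, gre_info,
                                    branch_my = default_branch_my()) {
  if (any(branch_my <= 0)) abort("branch times must be positive")
  if (!"length" %in% names(gre_info)) {
    gre_info <- dplyr::mutate(gre_info, length = .data$end - .data$start)
  }
  if (any(gre_info$length <= 0)) abort("GRE lengths must be positive")
  grid <- tidyr::expand_grid(gre_id = gre_info$gre_id,
                             lineage = lineage_names())
  counts <- subs |> dplyr::count(.data$gre_id, .data$lineage, name = "count")
  grid |>
    dplyr::left_join(counts, by = c("gre_id", "lineage")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::left_join(dplyr::select(gre_info, "gre_id", "length"),
                     by = "gre_id") |>
    dplyr::mutate(branch_my = unname(branch_my[.data$lineage]),
                  rate_per_my = .data$count / .data$branch_my,
                  rate_per_my_per_kb =
                    .data$count / .data$branch_my / .data$length * 1000)
}

#' Weak-to-strong (GC) conversion ratio
#'
#' Fraction of substitutions converting A/T (weak) to G/C (strong), a
#' signature of GC-biased gene conversion typical of accelerated regions.
#' Empty record sets yield `NA` (0/0 is reported as missing, not 0, to avoid
#' biasing comparisons among sparse record sets).
#'
#' @param subs Substitution records with `ancestral_base`, `derived_base`.
#' @return A single ratio in `[0, 1]`, or `NA_real_`.
#' @examples
#' gc_conversion_ratio(tibble::tibble(ancestral_base = c("A", "T"),
#'                                    derived_base = c("G", "C")))
#' @export
gc_conversion_ratio <- function(subs) {
  n <- nrow(subs)
  if (is.null(n) || n == 0L) return(NA_real_)
  ws <- subs$ancestral_base %in% c("A", "T") &
    subs$derived_base %in% c("G", "C")
  sum(ws) / n
}
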