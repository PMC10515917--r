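#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study generator. The defaults are the
#' study-like conditions the package is tested under: a catarrhine phylogeny
#' with the five ape-lineage branch times (MY) used for rate normalisation, a
#' neutral background substitution rate of 0.001 substitutions/site/MY
#' (roughly the catarrhine phylogenetic rate of ~1e-9 per site per year),
#' open-chromatin elements of 600-1400 bp and 200 pseudobulk units.
#'
#' @param seed Integer seed; together with the config it fully determines every
#'   generated byte. Per-stage streams are derived from it by stage name so
#'   stages can be rerun independently.
#' @param n_gres Number of gene regulatory elements (GREs) to simulate.
#' @param gre_length_range Length-2 integer vector; GRE lengths are drawn
#'   uniformly from this range (inclusive).
#' @param taxa Named list with character vectors `ape` (exactly 5 tips ordered
#'   human, chimp-like, gorilla-like, orangutan-like, gibbon-like), `owm`
#'   (>= 2 Old World monkey tips) and `nwm` (>= 2 New World monkey outgroup
#'   tips).
#' @param branch_lengths_my Named numeric vector of lineage branch times in
#'   million years; see [default_branch_my()].
#' @param background_sub_rate Background substitution rate in substitutions
#'   per site per million years; scales MY into expected substitutions/site.
#' @param equilibrium_freq Equilibrium base frequencies (A,C,G,T) of the F81
#'   process used for simulation; default uniform.
#' @param planted_events Tibble of forced single substitutions with columns
#'   `gre_id`, `branch` (a lineage name), `position` (0-based offset within
#'   the GRE), `ancestral_base`, `derived_base`. `NULL` for none.
#' @param divergent_gre_spec Tibble with columns `lineage`, `n_planted`,
#'   `rate_multiplier`: that many GREs receive `rate_multiplier`-fold
#'   substitution rate on the named lineage branch. `NULL` for none.
#' @param n_pseudobulk Number of pseudobulk units (columns of the multiome
#'   matrices); must be >= 30.
#' @param n_genes Number of genes in the synthetic multiome.
#' @param planted_links Tibble with columns `gre_id`, `gene_id`,
#'   `correlation_target` in (-1, 1). `NULL` for none.
#' @param n_motifs,motif_length Number and length (>= 6 bp) of generated
#'   position frequency matrices.
#' @param planted_motif_events Tibble with columns `gre_id`, `motif_id`,
#'   `branch` (lineage name), `direction` (`"gain"` or `"loss"`). `NULL` for
#'   none.
#' @param marker_fractions Named numeric vector mapping cell types to the
#'   fraction of GREs labelled as that cell type's markers.
#' @param marker_rate_multiplier Optional named numeric vector mapping cell
#'   types to a substitution-rate multiplier applied to their marker GREs by
#'   [simulate_substitution_counts()] (planted cell-type deviation).
#' @param gap_rate Per-site probability of injecting an alignment gap into a
#'   non-human tip sequence (exercises missing-data handling); default 0.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_study()], [build_guide_tree()]
#' @export
sim_config <- function(seed = 1L,
                       n_gres = 100L,
                       gre_length_range = c(600L, 1400L),
                       taxa = list(
                         ape = c("human", "chimp", "gorilla", "orangutan",
                                 "gibbon"),
                         owm = c("macaque", "baboon"),
                         nwm = c("marmoset", "squirrel_monkey")
                       ),
                       branch_lengths_my = default_branch_my(),
                       background_sub_rate = 0.001,
                       equilibrium_freq = rep(0.25, 4),
                       planted_events = NULL,
                       divergent_gre_spec = NULL,
                       n_pseudobulk = 200L,
                       n_genes = 100L,
                       planted_links = NULL,
                       n_motifs = 8L,
                       motif_length = 10L,
                       planted_motif_events = NULL,
                       marker_fractions = c(Neuron = 0.2, Astrocyte = 0.1,
                                            Oligodendrocyte = 0.1,
                                            Microglia = 0.1),
                       marker_rate_multiplier = NULL,
                       gap_rate = 0) {
  if (!is.list(taxa) || !all(c("ape", "owm", "nwm") %in% names(taxa))) {
    abort("`taxa` must be a list with elements ape, owm and nwm")
  }
  if (length(taxa$ape) != 5L) {
    abort("`taxa$ape` must contain exactly 5 tips (human first)")
  }
  if (length(taxa$owm) < 2L || length(taxa$nwm) < 2L) {
    abort("`taxa$owm` and `taxa$nwm` each need at least 2 tips")
  }
  if (anyDuplicated(unlist(taxa))) abort("taxon names must be unique")
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_gres >= 1L,
    length(gre_length_range) == 2L,
    gre_length_range[1] >= 1L, diff(gre_length_range) >= 0,
    background_sub_rate >= 0,
    length(equilibrium_freq) == 4L,
    all(equilibrium_freq > 0),
    abs(sum(equilibrium_freq) - 1) < 1e-9,
    n_pseudobulk >= 30L,
    n_genes >= 1L,
    n_motifs >= 1L, motif_length >= 6L,
    gap_rate >= 0, gap_rate < 1
  )
  if (!setequal(names(branch_lengths_my), lineage_names())) {
    abort("`branch_lengths_my` must name exactly the five lineages")
  }
  if (any(branch_lengths_my <= 0)) abort("branch times must be positive")

  chk_tbl <- function(x, cols, what) {
    if (is.null(x)) return(NULL)
    x <- tibble::as_tibble(x)
    if (!all(cols %in% names(x))) {
      abort(sprintf("`%s` needs columns %s", what, paste(cols, collapse = ", ")))
    }
    x
  }
  planted_events <- chk_tbl(planted_events,
                            c("gre_id", "branch", "position",
                              "ancestral_base", "derived_base"),
                            "planted_events")
  if (!is.null(planted_events)) {
    if (!all(planted_events$branch %in% lineage_names())) {
      abort("planted_events$branch must be one of the five lineages")
    }
    if (!all(planted_events$ancestral_base %in% .BASES) ||
        !all(planted_events$derived_base %in% .BASES)) {
      abort("planted bases must be A/C/G/T")
    }
    if (any(planted_events$ancestral_base == planted_events$derived_base)) {
      abort("planted ancestral and derived bases must differ")
    }
    if (any(planted_events$position < 0)) abort("planted positions are 0-based and must be >= 0")
  }
  divergent_gre_spec <- chk_tbl(divergent_gre_spec,
                                c("lineage", "n_planted", "rate_multiplier"),
                                "divergent_gre_spec")
  if (!is.null(divergent_gre_spec)) {
    if (!all(divergent_gre_spec$lineage %in% lineage_names())) {
      abort("divergent_gre_spec$lineage must be one of the five lineages")
    }
    if (any(divergent_gre_spec$rate_multiplier < 0)) abort("rate multipliers must be >= 0")
    if (anyDuplicated(divergent_gre_spec$lineage)) {
      abort("one divergent_gre_spec row per lineage")
    }
  }
  planted_links <- chk_tbl(planted_links,
                           c("gre_id", "gene_id", "correlation_target"),
                           "planted_links")
  if (!is.null(planted_links) &&
      any(abs(planted_links$correlation_target) >= 1)) {
    abort("correlation_target must lie in (-1, 1)")
  }
  planted_motif_events <- chk_tbl(planted_motif_events,
                                  c("gre_id", "motif_id", "branch", "direction"),
                                  "planted_motif_events")
  if (!is.null(planted_motif_events)) {
    if (!all(planted_motif_events$branch %in% lineage_names())) {
      abort("planted_motif_events$branch must be one of the five lineages")
    }
    if (!all(planted_motif_events$direction %in% c("gain", "loss"))) {
      abort("planted_motif_events$direction must be 'gain' or 'loss'")
    }
  }
  if (motif_length > gre_length_range[1]) {
    abort("motif_length exceeds the shortest configured GRE length")
  }
  if (is.null(names(marker_fractions)) || any(marker_fractions < 0) ||
      sum(marker_fractions) > 1 + 1e-9) {
    abort("`marker_fractions` must be a named non-negative vector summing to <= 1")
  }

  structure(
    list(seed = as.integer(seed), n_gres = as.integer(n_gres),
         gre_length_range = as.integer(gre_length_range), taxa = taxa,
         branch_lengths_my = branch_lengths_my[lineage_names()],
         background_sub_rate = background_sub_rate,
         equilibrium_freq = equilibrium_freq,
         planted_events = planted_events,
         divergent_gre_spec = divergent_gre_spec,
         n_pseudobulk = as.integer(n_pseudobulk),
         n_genes = as.integer(n_genes),
         planted_links = planted_links,
         n_motifs = as.integer(n_motifs),
         motif_length = as.integer(motif_length),
         planted_motif_events = planted_motif_events,
         marker_fractions = marker_fractions,
         marker_rate_multiplier = marker_rate_multiplier,
         gap_rate = gap_rate),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " n_gres:", x$n_gres,
      " lengths:", paste(x$gre_length_range, collapse = "-"), "bp\n")
  cat("  taxa:", length(x$taxa$ape), "apes,", length(x$taxa$owm), "OWM,",
      length(x$taxa$nwm), "NWM\n")
  cat("  background rate:", x$background_sub_rate, "subs/site/MY\n")
  np <- function(t) if (is.null(t)) 0L else nrow(t)
  cat("  planted: ", np(x$planted_events), " substitutions, ",
      np(x$divergent_gre_spec), " divergence specs, ",
      np(x$planted_links), " links, ",
      np(x$planted_motif_events), " motif events\n", sep = "")
  invisible(x)
}
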