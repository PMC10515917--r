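# Top-level orchestration of the synthetic study.

#' Simulate a complete synthetic study
#'
#' Runs every generator stage off one config: guide tree, motifs/markers,
#' per-GRE alignments (with planted substitutions, divergent GREs and motif
#' events) and the pseudo-multiome (with planted GRE-gene links). All stages
#' draw from per-stage streams derived from `config$seed`, so the result is
#' byte-reproducible and stages can be regenerated independently.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, all inputs and truth
#'   tables are written as plain-text files (multi-FASTA alignments, newick
#'   tree, BED intervals, JASPAR PFMs, TSV matrices and tables).
#' @return Object of class `epilineage_sim`: list with `config`, `tree`,
#'   `motifs`, `alignments`, `bed`, `gre_info`, `acc`, `expr`,
#'   `gene_coords` and `truth` (substitutions, divergent, chain_states,
#'   motif_events, branch_diffs, links).
#' @export
simulate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tree <- build_guide_tree(config)
  motifs <- generate_motifs_and_markers(config)
  aln <- simulate_alignments(tree, config, motifs = motifs)
  mo <- simulate_multiome(config, gre_info = aln$gre_info)
  sim <- structure(list(
    config = config, tree = tree, motifs = motifs,
    alignments = aln$alignments, bed = aln$bed, gre_info = aln$gre_info,
    acc = mo$acc, expr = mo$expr, gene_coords = mo$gene_coords,
    truth = c(aln$truth, mo$truth)
  ), class = "epilineage_sim")
  if (!is.null(out_dir)) write_study(sim, out_dir)
  sim
}

#' @export
print.epilineage_sim <- function(x, ...) {
  cat("<epilineage_sim> ", length(x$alignments), " GREs, ",
      nrow(x$expr), " genes, ", ncol(x$acc), " pseudobulk units, ",
      length(x$motifs$pwms), " motifs\n", sep = "")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' @param sim An [simulate_study()] result.
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_study <- function(sim, out_dir) {
  stopifnot(inherits(sim, "epilineage_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_alignments_fasta(sim$alignments, file.path(out_dir, "alignments"))
  ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
  write_bed(sim$bed, file.path(out_dir, "gres.bed"))
  write_jaspar(sim$motifs$pfms, file.path(out_dir, "motifs.jaspar"),
               tf_names = vapply(sim$motifs$pwms, `[[`, character(1), "tf"))
  w <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(out_dir, name), progress = FALSE)
  }
  w(sim$motifs$markers, "markers.tsv")
  w(sim$motifs$detection, "detection.tsv")
  w(sim$motifs$family_map, "family_map.tsv")
  w(sim$gre_info, "gre_coords.tsv")
  w(sim$gene_coords, "gene_coords.tsv")
  write_matrix_tsv(sim$acc, file.path(out_dir, "accessibility.tsv"))
  write_matrix_tsv(sim$expr, file.path(out_dir, "expression.tsv"))
  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  wt <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(tdir, name), progress = FALSE)
  }
  wt(sim$truth$substitutions, "substitutions.tsv")
  wt(sim$truth$chain_states, "chain_states.tsv")
  wt(sim$truth$motif_events, "motif_events.tsv")
  wt(sim$truth$branch_diffs, "branch_diffs.tsv")
  wt(sim$truth$links, "links.tsv")
  div <- sim$truth$divergent
  wt(tibble::tibble(
    lineage = rep(names(div), lengths(div)),
    gre_id = unlist(div, use.names = FALSE) %||% character(0)
  ), "divergent.tsv")
  invisible(out_dir)
}
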