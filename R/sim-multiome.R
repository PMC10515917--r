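# Pseudo-multiome generation: pseudobulk accessibility and expression
# matrices with planted GRE-gene correlations.

#' Simulate pseudobulk multiome matrices with planted GRE-gene links
#'
#' Generates Gaussian pseudobulk accessibility (GREs x units) and expression
#' (genes x units) matrices. Each planted link shares a latent factor between
#' the GRE and gene rows so their Pearson correlation is centred on
#' `correlation_target`; all other pairs are independent (expected
#' correlation zero). Linked genes are placed within 500 kb of their GRE on
#' the pseudo-chromosome; unlinked genes are placed uniformly.
#'
#' @param config A [sim_config()] (`n_pseudobulk >= 30`).
#' @param gre_info Optional GRE coordinate tibble from
#'   [simulate_alignments()]; synthesised deterministically from the config
#'   when absent.
#' @return List with `acc`, `expr` (matrices with dimnames), `gre_coords`,
#'   `gene_coords`, `truth` (`links` tibble).
#' @export
simulate_multiome <- function(config, gre_info = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_units <- config$n_pseudobulk
  n_genes <- config$n_genes
  withr::with_seed(stage_seed(config$seed, "multiome"), {
    if (is.null(gre_info)) {
      lens <- rep(round(mean(config$gre_length_range)), config$n_gres)
      starts <- cumsum(c(0L, lens[-config$n_gres] + 1000L))
      gre_info <- tibble::tibble(
        chrom = "chrS1", start = starts, end = starts + lens,
        gre_id = paste0("gre_", seq_len(config$n_gres)),
        length = lens,
        gc = stats::runif(config$n_gres, 0.35, 0.65))
    }
    gre_ids <- gre_info$gre_id
    gene_ids <- paste0("gene_", seq_len(n_genes))
    units <- paste0("pb_", seq_len(n_units))

    acc <- matrix(stats::rnorm(length(gre_ids) * n_units),
                  length(gre_ids), n_units,
                  dimnames = list(gre_ids, units))
    expr <- matrix(stats::rnorm(n_genes * n_units), n_genes, n_units,
                   dimnames = list(gene_ids, units))

    span <- max(gre_info$end)
    gene_start <- round(stats::runif(n_genes, 0, span))
    gene_len <- round(stats::runif(n_genes, 1000, 10000))

    links <- config$planted_links
    if (!is.null(links)) {
      if (!all(links$gre_id %in% gre_ids)) {
        abort("planted link references unknown GRE")
      }
      if (!all(links$gene_id %in% gene_ids)) {
        abort("planted link references unknown gene")
      }
      if (anyDuplicated(links$gre_id) || anyDuplicated(links$gene_id)) {
        warn("planted links share a GRE or gene; later rows overwrite earlier")
      }
      for (i in seq_len(nrow(links))) {
        rho <- links$correlation_target[i]
        z <- stats::rnorm(n_units)
        a <- sqrt(abs(rho)) * z +
          sqrt(1 - abs(rho)) * stats::rnorm(n_units)
        e <- sign(rho) * sqrt(abs(rho)) * z +
          sqrt(1 - abs(rho)) * stats::rnorm(n_units)
        acc[links$gre_id[i], ] <- a
        expr[links$gene_id[i], ] <- e
        # place the gene near its GRE (within 200 kb of the peak start)
        gi <- match(links$gene_id[i], gene_ids)
        anchor <- gre_info$start[match(links$gre_id[i], gre_ids)]
        gene_start[gi] <- max(0, anchor +
                                round(stats::runif(1, -2e5, 2e5)))
      }
    }
    gene_coords <- tibble::tibble(
      gene_id = gene_ids, chrom = "chrS1",
      start = as.integer(gene_start),
      end = as.integer(gene_start + gene_len))

    truth_links <- if (is.null(links)) {
      tibble::tibble(gre_id = character(), gene_id = character(),
                     correlation_target = numeric())
    } else links

    list(acc = acc, expr = expr,
         gre_coords = gre_info,
         gene_coords = gene_coords,
         truth = list(links = truth_links))
  })
}
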