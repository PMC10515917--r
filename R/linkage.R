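# GRE-gene linkage with a matched background null, the
# regulation-divergent-gene (RDG) permutation test, and the HS-DEG overlap
# test.

#' Link GREs to genes by accessibility-expression correlation
#'
#' For every GRE-gene pair whose GRE lies within `max_dist` of the gene body,
#' computes the Pearson correlation between the GRE's pseudobulk
#' accessibility and the gene's pseudobulk expression and standardises it
#' against a matched background: the correlations of `n_bg` background GREs
#' (nearest neighbours of the focal GRE in standardised mean-accessibility /
#' GC space) with the same gene. The z-score yields a two-sided normal
#' p-value, BH-adjusted over all tested pairs; a link is significant at
#' FDR < 0.05 with correlation score > 0.01 (negative links are never
#' significant).
#'
#' @param acc Accessibility matrix, GREs x pseudobulk units (rownames =
#'   gre ids).
#' @param expr Expression matrix, genes x pseudobulk units (rownames =
#'   gene ids); columns must match `acc`.
#' @param gre_coords Tibble `gre_id`, `chrom`, `start`, `end`, optionally
#'   `gc`.
#' @param gene_coords Tibble `gene_id`, `chrom`, `start`, `end`.
#' @param max_dist Candidate window around the gene body in bp, default
#'   500 kb.
#' @param n_bg Background GREs per focal GRE, default 200 (capped at the
#'   number of other GREs).
#' @param seed Integer seed (reserved; the matched background is
#'   deterministic nearest-neighbour selection).
#' @param fdr_max,score_min Significance cutoffs (0.05, 0.01).
#' @return Tibble `gre_id`, `gene_id`, `score` (Pearson r), `null_mean`,
#'   `null_sd`, `z`, `p`, `fdr`, `significant`. Pairs skipped for zero
#'   variance are counted in attribute `"skipped"`.
#' @export
link_gres_to_genes <- function(acc, expr, gre_coords, gene_coords,
                               max_dist = 5e5, n_bg = 200L, seed = 1L,
                               fdr_max = 0.05, score_min = 0.01) {
  stopifnot(ncol(acc) == ncol(expr))
  n_units <- ncol(acc)
  gre_ids <- rownames(acc)
  gene_ids <- rownames(expr)
  stopifnot(!is.null(gre_ids), !is.null(gene_ids))

  # variance screen
  v_acc <- apply(acc, 1L, stats::sd)
  v_expr <- apply(expr, 1L, stats::sd)
  skip_gre <- gre_ids[v_acc == 0]
  skip_gene <- gene_ids[v_expr == 0]
  if (length(skip_gre) || length(skip_gene)) {
    inform(sprintf("skipping %d zero-variance GRE(s) and %d gene(s)",
                   length(skip_gre), length(skip_gene)))
  }

  # candidate pairs within max_dist of the gene body
  gg <- gene_coords[gene_coords$gene_id %in% setdiff(gene_ids, skip_gene), ]
  pg <- gre_coords[gre_coords$gre_id %in% setdiff(gre_ids, skip_gre), ]
  gr_gene <- GenomicRanges::GRanges(
    gg$chrom, IRanges::IRanges(pmax(0L, gg$start - max_dist) + 1L,
                               gg$end + max_dist))
  gr_gre <- GenomicRanges::GRanges(pg$chrom,
                                   IRanges::IRanges(pg$start + 1L, pg$end))
  hits <- GenomicRanges::findOverlaps(gr_gre, gr_gene)
  if (!length(hits)) {
    out <- tibble::tibble(gre_id = character(), gene_id = character(),
                          score = numeric(), null_mean = numeric(),
                          null_sd = numeric(), z = numeric(), p = numeric(),
                          fdr = numeric(), significant = logical())
    attr(out, "skipped") <- c(gres = length(skip_gre),
                              genes = length(skip_gene))
    return(out)
  }
  pair_gre <- pg$gre_id[S4Vectors::queryHits(hits)]
  pair_gene <- gg$gene_id[S4Vectors::subjectHits(hits)]

  # all correlations at once on row-standardised matrices
  az <- t(scale(t(acc)))  # rows: mean 0, sd 1
  ez <- t(scale(t(expr)))
  r_all <- tcrossprod(az, ez) / (n_units - 1)  # gres x genes

  # matched background: nearest neighbours in (mean accessibility, GC) space
  feat <- cbind(rowMeans(acc), NA_real_)
  gc <- gre_coords$gc[match(gre_ids, gre_coords$gre_id)]
  feat[, 2] <- if (!is.null(gre_coords$gc)) gc else rowMeans(acc)
  feat <- scale(feat)
  feat[is.na(feat)] <- 0
  usable <- which(!(gre_ids %in% skip_gre))
  n_bg_eff <- min(n_bg, length(usable) - 1L)
  if (n_bg_eff < 2L) abort("too few GREs for a matched background")

  focal_ids <- unique(pair_gre)
  bg_idx <- lapply(focal_ids, function(g) {
    i <- match(g, gre_ids)
    d2 <- (feat[usable, 1] - feat[i, 1])^2 + (feat[usable, 2] - feat[i, 2])^2
    cand <- usable[order(d2, usable)]
    utils::head(setdiff(cand, i), n_bg_eff)
  })
  names(bg_idx) <- focal_ids

  r <- r_all[cbind(match(pair_gre, gre_ids), match(pair_gene, gene_ids))]
  nm <- nsd <- numeric(length(r))
  for (k in seq_along(r)) {
    nullr <- r_all[bg_idx[[pair_gre[k]]], match(pair_gene[k], gene_ids)]
    nm[k] <- mean(nullr)
    nsd[k] <- stats::sd(nullr)
  }
  z <- (r - nm) / nsd
  p <- 2 * stats::pnorm(-abs(z))
  fdr <- bh_adjust(p)
  out <- tibble::tibble(gre_id = pair_gre, gene_id = pair_gene, score = r,
                        null_mean = nm, null_sd = nsd, z = z, p = p,
                        fdr = fdr,
                        significant = !is.na(fdr) & fdr < fdr_max &
                          r > score_min)
  attr(out, "skipped") <- c(gres = length(skip_gre),
                            genes = length(skip_gene))
  out
}

#' Identify regulation-divergent genes (RDGs)
#'
#' Per lineage, counts each gene's significant links to lineage-divergent
#' GREs and compares the count against a permutation background built by
#' drawing the same number of GREs from the full universe `n_perm` times and
#' recounting links per gene. The empirical p-value is the fraction of
#' permutations reaching at least the observed count (ties count against
#' significance), BH-adjusted over genes per lineage. A gene is an RDG when
#' FDR < `fdr_max` and it has at least `min_divergent` divergent links and
#' `min_total` total significant links.
#'
#' @param links Link table from [link_gres_to_genes()]; only rows with
#'   `significant == TRUE` are used.
#' @param divergent A [classify_divergent()] fit or named list of divergent
#'   GRE id sets per lineage.
#' @param universe Character vector of all GRE ids to draw permutations
#'   from.
#' @param n_perm Permutations, default 1000.
#' @param seed Integer seed.
#' @param fdr_max,min_divergent,min_total Filters (0.05, 2, 5).
#' @return Object of class `rdg_fit` with `$table`: `gene_id`, `lineage`,
#'   `divergent_links`, `total_links`, `p`, `fdr`, `is_rdg`.
#' @export
identify_rdgs <- function(links, divergent, universe, n_perm = 1000L,
                          seed = 1L, fdr_max = 0.05, min_divergent = 2L,
                          min_total = 5L) {
  dsets <- if (inherits(divergent, "divergence_fit")) {
    divergent_sets(divergent)
  } else divergent
  sig <- links[links$significant, , drop = FALSE]
  genes <- unique(sig$gene_id)
  total <- sig |> dplyr::count(.data$gene_id, name = "total_links")
  gre_pos <- match(sig$gre_id, universe)
  if (anyNA(gre_pos)) abort("links reference GREs outside the universe")
  by_gene <- split(gre_pos, factor(sig$gene_id, levels = genes))

  rows <- vector("list", length(dsets))
  for (li in seq_along(dsets)) {
    lin <- names(dsets)[li]
    dset <- dsets[[li]]
    if (!length(dset)) {
      inform(sprintf("no divergent GREs for lineage %s; no RDGs", lin))
      next
    }
    member <- universe %in% dset
    obs <- vapply(by_gene, function(ix) sum(member[ix]), integer(1))
    exceed <- integer(length(genes))
    withr::with_seed(stage_seed(seed, paste0("rdg_", lin)), {
      for (b in seq_len(n_perm)) {
        mask <- logical(length(universe))
        mask[sample.int(length(universe), length(dset))] <- TRUE
        nullc <- vapply(by_gene, function(ix) sum(mask[ix]), integer(1))
        exceed <- exceed + (nullc >= obs)
      }
    })
    p <- exceed / n_perm
    rows[[li]] <- tibble::tibble(gene_id = genes, lineage = lin,
                                 divergent_links = unname(obs), p = p)
  }
  tbl <- dplyr::bind_rows(rows)
  if (!nrow(tbl)) {
    tbl <- tibble::tibble(gene_id = character(), lineage = character(),
                          divergent_links = integer(),
                          total_links = integer(), p = numeric(),
                          fdr = numeric(), is_rdg = logical())
    return(structure(list(table = tbl), class = "rdg_fit"))
  }
  tbl <- tbl |>
    dplyr::left_join(total, by = "gene_id") |>
    dplyr::group_by(.data$lineage) |>
    dplyr::mutate(fdr = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(is_rdg = .data$fdr < fdr_max &
                    .data$divergent_links >= min_divergent &
                    .data$total_links >= min_total) |>
    dplyr::select("gene_id", "lineage", "divergent_links", "total_links",
                  "p", "fdr", "is_rdg")
  structure(list(table = tbl,
                 params = list(n_perm = n_perm, fdr_max = fdr_max,
                               min_divergent = min_divergent,
                               min_total = min_total)),
            class = "rdg_fit")
}

#' @export
print.rdg_fit <- function(x, ...) {
  nr <- x$table |> dplyr::filter(.data$is_rdg) |> dplyr::count(.data$lineage)
  cat("<rdg_fit> ", dplyr::n_distinct(x$table$gene_id), " genes tested\n",
      sep = "")
  if (nrow(nr)) {
    cat("  RDGs:", paste(sprintf("%s=%d", nr$lineage, nr$n), collapse = ", "),
        "\n")
  } else cat("  RDGs: none\n")
  invisible(x)
}

#' Permutation overlap test between RDGs and a gene list
#'
#' Tests whether the observed overlap between an RDG set and a list of
#' human-specific differentially expressed genes (HS-DEGs) exceeds the
#' overlap with `n_perm` random same-size gene draws from the universe.
#'
#' @param rdg_genes Character vector (e.g. one lineage's RDGs).
#' @param hsdeg Character vector, subset of `universe`.
#' @param universe All candidate gene ids.
#' @param n_perm Permutations, default 1000.
#' @param seed Integer seed.
#' @return Tibble with `observed`, `expected` (mean null), `p` (fraction of
#'   null overlaps >= observed) and `overlap_ratio` (share of HS-DEGs that
#'   are RDGs).
#' @export
hsdeg_overlap_test <- function(rdg_genes, hsdeg, universe, n_perm = 1000L,
                               seed = 1L) {
  if (!length(hsdeg) || !length(universe)) abort("empty inputs")
  if (!all(hsdeg %in% universe)) abort("hsdeg must be a subset of universe")
  rdg_genes <- unique(rdg_genes)
  obs <- length(intersect(rdg_genes, hsdeg))
  inr <- universe %in% rdg_genes
  nullv <- integer(n_perm)
  withr::with_seed(stage_seed(seed, "hsdeg"), {
    for (b in seq_len(n_perm)) {
      nullv[b] <- sum(inr[sample.int(length(universe), length(hsdeg))])
    }
  })
  tibble::tibble(observed = obs, expected = mean(nullv),
                 p = sum(nullv >= obs) / n_perm,
                 overlap_ratio = obs / length(unique(hsdeg)))
}
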