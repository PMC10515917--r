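# Sequence-level simulation: F81 evolution down the guide tree with planted
# single-event substitutions, lineage-divergent rate multipliers and planted
# motif gains/losses.

# sample child states from parent states across one branch (vectorised)
evolve_branch <- function(parent, pmat) {
  cum <- t(apply(pmat, 1L, cumsum))
  u <- stats::runif(length(parent))
  cu <- cum[parent, , drop = FALSE]
  1L + (u > cu[, 1L]) + (u > cu[, 2L]) + (u > cu[, 3L])
}

#' Simulate per-GRE multi-species alignments with planted ground truth
#'
#' Evolves each GRE root sequence tip-ward under F81 along the guide tree,
#' then forces the configured ground truth onto the realised states:
#'
#' * planted substitutions: the whole alignment column is reset to the
#'   ancestral base and the derived base written into the named branch's
#'   child node and all its descendants, so exactly one state transition
#'   exists along the chain at that site (homoplasy-free by construction);
#' * lineage-divergent GREs: the named lineage branch length is multiplied
#'   by the configured rate multiplier;
#' * planted motif gains/losses (when `motifs` is supplied): the motif
#'   consensus is embedded at a free offset in the gaining clade and a
#'   non-matching shuffle everywhere else (losses inverted).
#'
#' Alignments are generated gapless; with `gap_rate > 0`, gaps are injected
#' into non-human tips at unplanted sites (missing data for reconstruction).
#'
#' @param tree Guide tree from [build_guide_tree()].
#' @param config A [sim_config()].
#' @param motifs Optional result of [generate_motifs_and_markers()] (needed
#'   only when `config$planted_motif_events` is set).
#' @return List with `alignments` (named list of tip alignments), `bed`
#'   (0-based half-open intervals on `chrS1`), `gre_info` (adds `length` and
#'   `gc`), `truth` (list: `substitutions`, `divergent`, `chain_states`,
#'   `motif_events`, `branch_diffs`) and `tree`.
#' @export
simulate_alignments <- function(tree, config, motifs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  taxa <- unlist(config$taxa, use.names = FALSE)
  if (!setequal(tree$tip.label, taxa)) {
    abort("tree tips do not cover the configured taxa")
  }
  human <- config$taxa$ape[1]
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length
  ne <- nrow(edge)
  ntip <- length(tr$tip.label)
  ntot <- ntip + tr$Nnode
  root <- edge[ne, 1L]
  labs <- node_labels(tr)
  pi0 <- config$equilibrium_freq
  pmats <- lapply(elen, function(t) f81_pmat(f81_model(pi0), t))
  chain_ids <- chain_node_ids(tr, human = human)
  lin_child <- vapply(lineage_names(), function(l) {
    lineage_child_node(tr, l, human = human)
  }, integer(1))
  clades <- lapply(lin_child, function(nd) clade_nodes(tr, nd))

  if (!is.null(config$planted_motif_events) && is.null(motifs)) {
    abort("planted_motif_events require `motifs` (generate_motifs_and_markers)")
  }

  n <- config$n_gres
  gre_ids <- paste0("gre_", seq_len(n))
  out <- withr::with_seed(stage_seed(config$seed, "alignments"), {
    rng_len <- config$gre_length_range
    lens <- rng_len[1] + sample.int(rng_len[2] - rng_len[1] + 1L, n,
                                    replace = TRUE) - 1L

    # assign lineage-divergent GREs (disjoint across lineages)
    divergent <- list()
    pool <- seq_len(n)
    if (!is.null(config$divergent_gre_spec)) {
      for (i in seq_len(nrow(config$divergent_gre_spec))) {
        sp <- config$divergent_gre_spec[i, ]
        if (sp$n_planted > length(pool)) {
          abort("not enough GREs to plant the divergent specification")
        }
        pick <- sort(sample(pool, sp$n_planted))
        divergent[[sp$lineage]] <- gre_ids[pick]
        pool <- setdiff(pool, pick)
      }
    }
    div_gre_mult <- stats::setNames(rep(1, n), gre_ids)
    div_gre_lin <- stats::setNames(rep(NA_character_, n), gre_ids)
    if (length(divergent)) {
      for (lin in names(divergent)) {
        mult <- config$divergent_gre_spec$rate_multiplier[
          config$divergent_gre_spec$lineage == lin]
        div_gre_mult[divergent[[lin]]] <- mult
        div_gre_lin[divergent[[lin]]] <- lin
      }
    }

    pe <- config$planted_events
    pe_by_gre <- if (is.null(pe)) list() else split(pe, pe$gre_id)
    pme <- config$planted_motif_events
    pme_by_gre <- if (is.null(pme)) list() else split(pme, pme$gre_id)

    ndiff <- nsite <- numeric(ne)
    alignments <- vector("list", n)
    chain_rows <- vector("list", n)
    motif_truth <- list()
    sub_truth <- list()

    for (g in seq_len(n)) {
      l <- lens[g]
      gid <- gre_ids[g]
      states <- matrix(0L, ntot, l)
      states[root, ] <- sample.int(4L, l, replace = TRUE, prob = pi0)
      for (e in rev(seq_len(ne))) {
        p <- edge[e, 1L]; ch <- edge[e, 2L]
        pm <- pmats[[e]]
        if (!is.na(div_gre_lin[gid]) &&
            ch == lin_child[[div_gre_lin[gid]]]) {
          pm <- f81_pmat(f81_model(pi0), elen[e] * div_gre_mult[gid])
        }
        states[ch, ] <- evolve_branch(states[p, ], pm)
        ndiff[e] <- ndiff[e] + sum(states[ch, ] != states[p, ])
        nsite[e] <- nsite[e] + l
      }

      occupied <- integer(0)
      ev <- pe_by_gre[[gid]]
      if (!is.null(ev)) {
        if (any(ev$position >= l)) {
          abort(sprintf("planted event position out of range in %s", gid))
        }
        if (anyDuplicated(ev$position)) {
          abort(sprintf("duplicate planted positions in %s", gid))
        }
        for (i in seq_len(nrow(ev))) {
          col <- ev$position[i] + 1L
          anc <- match(ev$ancestral_base[i], .BASES)
          der <- match(ev$derived_base[i], .BASES)
          states[, col] <- anc
          states[clades[[ev$branch[i]]], col] <- der
          occupied <- c(occupied, col)
          sub_truth[[length(sub_truth) + 1L]] <- tibble::tibble(
            lineage = ev$branch[i], gre_id = gid, offset = ev$position[i],
            ancestral_base = ev$ancestral_base[i],
            derived_base = ev$derived_base[i])
        }
      }

      mev <- pme_by_gre[[gid]]
      if (!is.null(mev)) {
        for (i in seq_len(nrow(mev))) {
          pw <- motifs$pwms[[mev$motif_id[i]]]
          if (is.null(pw)) abort(sprintf("unknown motif %s", mev$motif_id[i]))
          ml <- ncol(pw$pfm)
          if (ml > l) abort("motif longer than GRE")
          cons <- apply(pw$pfm, 2L, which.max)
          shuf <- shuffle_nonmatching(cons, pw)
          off <- NULL
          for (try in 1:200) {
            cand <- sample.int(l - ml + 1L, 1L)
            if (!any(seq(cand, cand + ml - 1L) %in% occupied)) {
              off <- cand
              break
            }
          }
          if (is.null(off)) abort("could not place planted motif event")
          cols <- seq(off, off + ml - 1L)
          occupied <- c(occupied, cols)
          clade <- clades[[mev$branch[i]]]
          if (mev$direction[i] == "gain") {
            states[, cols] <- matrix(shuf, ntot, ml, byrow = TRUE)
            states[clade, cols] <- matrix(cons, length(clade), ml,
                                          byrow = TRUE)
          } else {
            states[, cols] <- matrix(cons, ntot, ml, byrow = TRUE)
            states[clade, cols] <- matrix(shuf, length(clade), ml,
                                          byrow = TRUE)
          }
          motif_truth[[length(motif_truth) + 1L]] <- tibble::tibble(
            gre_id = gid, motif_id = mev$motif_id[i],
            lineage = mev$branch[i], direction = mev$direction[i],
            offset = off - 1L)
        }
      }

      tip_states <- states[seq_len(ntip), , drop = FALSE]
      rownames(tip_states) <- tr$tip.label
      if (config$gap_rate > 0) {
        for (ti in which(tr$tip.label != human)) {
          mask <- stats::runif(l) < config$gap_rate
          mask[occupied] <- FALSE
          tip_states[ti, mask] <- 6L
        }
      }
      alignments[[g]] <- matrix_to_aln(tip_states)
      chain_rows[[g]] <- tibble::tibble(
        gre_id = gid, node = chain_nodes(),
        sequence = apply(states[chain_ids, , drop = FALSE], 1L, int_to_seq))
    }

    starts <- cumsum(c(0L, lens[-n] + 1000L))
    bed <- tibble::tibble(chrom = "chrS1", start = starts,
                          end = starts + lens, gre_id = gre_ids)
    gc <- vapply(seq_len(n), function(g) {
      hx <- seq_to_int(alignments[[g]][[human]])
      mean(hx %in% c(2L, 3L))
    }, numeric(1))
    gre_info <- dplyr::mutate(bed, length = lens, gc = gc)

    subs <- dplyr::bind_rows(sub_truth)
    if (nrow(subs)) {
      subs <- subs |>
        dplyr::left_join(dplyr::select(bed, "gre_id", "chrom", "start"),
                         by = "gre_id") |>
        dplyr::mutate(position = .data$start + .data$offset) |>
        dplyr::select("lineage", "chrom", "position", "gre_id", "offset",
                      "ancestral_base", "derived_base")
    }
    list(
      alignments = stats::setNames(alignments, gre_ids),
      bed = bed,
      gre_info = gre_info,
      truth = list(
        substitutions = subs,
        divergent = divergent,
        chain_states = dplyr::bind_rows(chain_rows),
        motif_events = dplyr::bind_rows(motif_truth),
        branch_diffs = {
          child_lab <- labs[edge[, 2L]]
          child_lab[is.na(child_lab)] <-
            as.character(edge[is.na(child_lab), 2L])
          tibble::tibble(child = child_lab, branch_length = elen,
                         sites = nsite, diffs = ndiff)
        }
      ),
      tree = tree
    )
  })
  out
}

# permute the consensus until it no longer matches the motif on either
# strand (checked in isolation); bounded retries
shuffle_nonmatching <- function(cons, pw, max_try = 100L) {
  for (i in seq_len(max_try)) {
    sh <- sample(cons)
    if (!pwm_matches_int(sh, pw)) return(sh)
  }
  abort(sprintf("could not shuffle a non-matching variant of %s",
                pw$motif_id))
}
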