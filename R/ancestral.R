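# Maximum-likelihood ancestral reconstruction under F81.
#
# The machinery is deliberately small and self-contained: F81 transition
# probabilities in closed form, Felsenstein pruning for the site likelihood,
# and an up-down pass for marginal posteriors at internal nodes. Gaps and N in
# tip sequences are treated as missing data (all-ones partials).

#' F81 substitution model
#'
#' @param freq Equilibrium base frequencies (A, C, G, T); must be positive and
#'   sum to 1 within 1e-9.
#' @return Object of class `f81_model` with fields `freq` and the rate
#'   normalisation `beta = 1 / (1 - sum(freq^2))` so branch lengths are in
#'   expected substitutions per site.
#' @examples
#' f81_model(c(0.3, 0.2, 0.2, 0.3))
#' @export
f81_model <- function(freq = rep(0.25, 4)) {
  stopifnot(length(freq) == 4L)
  if (any(freq <= 0) || any(freq >= 1) || abs(sum(freq) - 1) > 1e-9) {
    abort("F81 frequencies must lie in (0,1) and sum to 1")
  }
  freq <- as.numeric(freq)
  names(freq) <- .BASES
  structure(list(freq = freq, beta = 1 / (1 - sum(freq^2))),
            class = "f81_model")
}

# 4x4 transition matrix P(to | from, t), rows = from.
f81_pmat <- function(model, t) {
  e <- exp(-model$beta * t)
  p <- matrix(rep((1 - e) * model$freq, each = 4L), 4L, 4L)
  diag(p) <- diag(p) + e
  p
}

#' F81 transition probability
#'
#' Closed-form `P(to | from, t) = exp(-beta t) [from == to] +
#' (1 - exp(-beta t)) pi_to`.
#'
#' @param model An [f81_model()].
#' @param from,to Bases among A, C, G, T.
#' @param branch_length Branch length `t >= 0` in expected substitutions per
#'   site.
#' @return Probability.
#' @examples
#' m <- f81_model()
#' f81_transition_prob(m, "A", "G", 0.1)
#' @export
f81_transition_prob <- function(model, from, to, branch_length) {
  stopifnot(inherits(model, "f81_model"))
  if (branch_length < 0) abort("branch length must be >= 0")
  i <- match(from, .BASES); j <- match(to, .BASES)
  if (anyNA(c(i, j))) abort("bases must be A, C, G or T")
  f81_pmat(model, branch_length)[i, j]
}

# ---------------------------------------------------------------------------

#' Remove columns where the human sequence has a gap
#'
#' Projects a GRE alignment onto human genome coordinates: every alignment
#' column in which the human record carries `-` (a putative human-specific
#' deletion) is dropped from all taxa; column order is otherwise preserved.
#' Non-human gaps are retained (they become missing states in reconstruction).
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   over A/C/G/T/N/-; one element per taxon.
#' @param human Name of the human record.
#' @return The stripped alignment. If the human record is entirely gaps the
#'   result has zero-length sequences and attribute `empty = TRUE` so callers
#'   can skip the GRE.
#' @examples
#' strip_human_gaps(c(human = "AC-GT", chimp = "ACAGT"))
#' @export
strip_human_gaps <- function(alignment, human = "human") {
  if (!human %in% names(alignment)) {
    abort(sprintf("alignment has no '%s' record", human))
  }
  m <- aln_to_matrix(alignment)
  keep <- m[human, ] != 6L
  m <- m[, keep, drop = FALSE]
  out <- matrix_to_aln(m)
  if (!any(keep)) attr(out, "empty") <- TRUE
  out
}

# ---------------------------------------------------------------------------
# Pruning engine. `x` is an integer state matrix (taxa x sites, codes 1..6)
# whose rownames cover tree$tip.label.

# tip partial likelihoods: 4 x S x Ntip slice values
tip_partials <- function(xrow) {
  s <- length(xrow)
  p <- matrix(0, 4L, s)
  obs <- xrow <= 4L
  p[cbind(xrow[obs], which(obs))] <- 1
  p[, !obs] <- 1  # N or gap: missing data
  p
}

# Full up-down pass. Returns list(loglik, post, lik_root, tips_all_missing).
# `post` is a 4 x S x Nnode array of marginal posteriors for internal nodes
# (index = node id - Ntip) when `posteriors = TRUE`.
f81_pruning <- function(tree, model, x, posteriors = FALSE) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  s <- ncol(x)
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length
  ne <- nrow(edge)
  root <- edge[ne, 1L]

  pmats <- lapply(elen, function(t) f81_pmat(model, t))
  lik <- array(1, dim = c(4L, s, ntot))
  for (i in seq_len(ntip)) {
    lik[, , i] <- tip_partials(x[tr$tip.label[i], ])
  }
  msgs <- vector("list", ne)
  for (e in seq_len(ne)) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    msgs[[e]] <- pmats[[e]] %*% lik[, , ch]
    lik[, , p] <- lik[, , p] * msgs[[e]]
  }
  site_lik <- colSums(model$freq * matrix(lik[, , root], nrow = 4L))
  loglik <- sum(log(site_lik))

  out <- list(loglik = loglik, tree = tr)
  if (!posteriors) return(out)

  # upward ("above") partials, preorder = reverse postorder
  up <- array(0, dim = c(4L, s, ntot))
  up[, , root] <- model$freq
  child_edges <- split(seq_len(ne), edge[, 1L])
  for (e in rev(seq_len(ne))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    sib <- matrix(up[, , p], nrow = 4L)
    for (e2 in child_edges[[as.character(p)]]) {
      if (e2 != e) sib <- sib * msgs[[e2]]
    }
    up[, , ch] <- crossprod(pmats[[e]], sib)
  }

  post <- array(NA_real_, dim = c(4L, s, nnode))
  all_missing <- colSums(matrix(lik[, , root], nrow = 4L)) == 4
  for (n in seq_len(nnode)) {
    un <- matrix(up[, , ntip + n] * lik[, , ntip + n], nrow = 4L)
    cs <- colSums(un)
    bad <- cs <= 0
    un <- sweep(un, 2L, pmax(cs, .Machine$double.xmin), "/")
    un[, bad] <- 0.25
    post[, , n] <- un
  }
  out$post <- post
  out$ntip <- ntip
  out$all_missing <- all_missing
  out
}

# collapse identical site patterns; returns list(x = unique columns,
# weight, index map back to original columns)
compress_patterns <- function(x) {
  key <- apply(x, 2L, paste, collapse = "\r")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(x = x[, u, drop = FALSE],
       weight = tabulate(idx, sum(u)),
       map = idx)
}

# ---------------------------------------------------------------------------

#' Fit an F81 model and branch lengths to a GRE alignment
#'
#' Sets the equilibrium frequencies to the empirical tip base frequencies
#' (with a one-count smoothing so none is zero), then maximises the pruning
#' log-likelihood over branch lengths by cyclic bounded univariate
#' optimisation, stopping when a full cycle improves the log-likelihood by
#' less than `tol` or after `max_cycles` cycles. If the alignment carries no
#' variable usable site, the input branch lengths are returned unchanged.
#'
#' @param tree Rooted `phylo` with branch lengths (starting values).
#' @param alignment Named character vector of aligned sequences.
#' @param max_cycles,tol Convergence controls.
#' @param bounds Search interval for each branch length.
#' @return List with elements `tree` (fitted branch lengths), `model`
#'   ([f81_model()]), `loglik`, `cycles`, and `optimised` (FALSE when the
#'   invariant-alignment fallback was taken).
#' @export
fit_f81 <- function(tree, alignment, max_cycles = 20L, tol = 1e-6,
                    bounds = c(1e-8, 5)) {
  if (!length(alignment) || !nchar(alignment[[1]])) abort("empty alignment")
  x <- aln_to_matrix(alignment)
  obs <- x[x <= 4L]
  cnt <- tabulate(obs, 4L) + 1  # smoothed empirical frequencies
  model <- f81_model(cnt / sum(cnt))

  cp <- compress_patterns(x)
  variable <- apply(cp$x, 2L, function(col) {
    b <- unique(col[col <= 4L]); length(b) > 1L
  })
  if (!any(variable)) {
    ll <- sum_loglik_weighted(tree, model, cp)
    return(list(tree = tree, model = model, loglik = ll, cycles = 0L,
                optimised = FALSE))
  }

  tr <- tree
  ll <- sum_loglik_weighted(tr, model, cp)
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    ll_prev <- ll
    for (e in seq_len(nrow(tr$edge))) {
      opt <- stats::optimize(function(t) {
        tr$edge.length[e] <- t
        sum_loglik_weighted(tr, model, cp)
      }, interval = bounds, maximum = TRUE, tol = 1e-8)
      if (opt$objective >= ll) {
        tr$edge.length[e] <- opt$maximum
        ll <- opt$objective
      }
    }
    if (ll - ll_prev < tol || cycles >= max_cycles) break
  }
  list(tree = tr, model = model, loglik = ll, cycles = cycles,
       optimised = TRUE)
}

# weighted loglik without building posteriors
sum_loglik_weighted <- function(tree, model, cp) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge; elen <- tr$edge.length; ne <- nrow(edge)
  root <- edge[ne, 1L]
  s <- ncol(cp$x)
  lik <- array(1, dim = c(4L, s, ntip + tree$Nnode))
  for (i in seq_len(ntip)) lik[, , i] <- tip_partials(cp$x[tr$tip.label[i], ])
  for (e in seq_len(ne)) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    lik[, , p] <- lik[, , p] * (f81_pmat(model, elen[e]) %*% lik[, , ch])
  }
  sum(cp$weight * log(colSums(model$freq * matrix(lik[, , root], nrow = 4L))))
}

#' Marginal ancestral posteriors at every internal node
#'
#' Per site and internal node, the posterior distribution over A/C/G/T given
#' all tip states, computed by combining downward (pruning) and upward
#' partials under the supplied F81 model; tips with N or `-` contribute
#' all-ones partials (missing data). Sites at which every tip is missing get
#' a uniform posterior and are flagged.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param model An [f81_model()].
#' @param alignment Named character vector of aligned sequences covering the
#'   tree tips.
#' @return Object of class `ancestral_posterior`: list with `post` (named
#'   list, internal node label -> 4 x S posterior matrix), `loglik`,
#'   `all_missing` (logical per site) and `tree`.
#' @export
marginal_ancestral_posteriors <- function(tree, model, alignment) {
  x <- aln_to_matrix(alignment)
  if (!all(tree$tip.label %in% rownames(x))) {
    abort("alignment does not cover all tree tips")
  }
  cp <- compress_patterns(x)
  res <- f81_pruning(tree, model, cp$x, posteriors = TRUE)
  ntip <- res$ntip
  labs <- node_labels(res$tree)
  post <- vector("list", dim(res$post)[3])
  for (n in seq_along(post)) {
    m <- res$post[, cp$map, n, drop = FALSE]
    dim(m) <- c(4L, length(cp$map))
    rownames(m) <- .BASES
    post[[n]] <- m
  }
  lab_int <- labs[ntip + seq_along(post)]
  lab_int[is.na(lab_int) | lab_int == ""] <-
    paste0("node", which(is.na(lab_int) | lab_int == ""))
  names(post) <- lab_int
  all_missing <- colSums(x <= 4L) == 0L
  structure(list(post = post,
                 loglik = sum_loglik_weighted(tree, model, cp),
                 all_missing = all_missing,
                 tree = res$tree),
            class = "ancestral_posterior")
}

#' Call ancestral chain sequences from posteriors
#'
#' For each internal chain node and site, emits the argmax base when its
#' posterior strictly exceeds `threshold`, otherwise `N` (including exact
#' ties at the threshold). The human chain state is copied verbatim from the
#' alignment.
#'
#' @param posterior An [marginal_ancestral_posteriors()] result.
#' @param alignment The (human-gap-stripped) alignment the posteriors were
#'   computed from.
#' @param threshold Confidence cutoff; strictly greater-than. Default 0.75.
#' @param human Human record name.
#' @return Named character vector of six sequences, names
#'   `Catarrhine, Ape, GreatApe, AfricanGreatApe, Hominin, Human`.
#' @export
call_ancestral_sequences <- function(posterior, alignment, threshold = 0.75,
                                     human = "human") {
  stopifnot(inherits(posterior, "ancestral_posterior"))
  internal <- chain_nodes()[1:5]
  missing_nodes <- setdiff(internal, names(posterior$post))
  if (length(missing_nodes)) {
    abort(sprintf("posteriors missing chain nodes: %s",
                  paste(missing_nodes, collapse = ", ")))
  }
  seqs <- vapply(internal, function(nd) {
    p <- posterior$post[[nd]]
    best <- max.col(t(p), ties.method = "first")
    conf <- p[cbind(best, seq_len(ncol(p)))] > threshold
    paste(ifelse(conf, .BASES[best], "N"), collapse = "")
  }, character(1))
  c(seqs, Human = unname(toupper(alignment[[human]])))
}

#' Reconstruct chain sequences for a set of GRE alignments
#'
#' Runs the full per-GRE reconstruction: human-gap stripping, empirical F81
#' frequencies (optionally per-GRE branch-length optimisation), marginal
#' posteriors, and confidence-thresholded ancestral calls at the six chain
#' nodes.
#'
#' @param alignments Named list of alignments (named character vectors), one
#'   per GRE.
#' @param tree Guide tree from [build_guide_tree()] (or compatible, with
#'   labelled chain nodes).
#' @param threshold Posterior confidence cutoff (strict), default 0.75.
#' @param optimise Re-optimise branch lengths per GRE ([fit_f81()]); default
#'   FALSE reuses the guide-tree lengths, appropriate for short elements with
#'   little length signal.
#' @param human Human tip name.
#' @return Tibble with columns `gre_id`, `node`, `sequence` (six rows per
#'   usable GRE, deepest node first). GREs whose human record is all gaps are
#'   skipped; their ids are kept in attribute `"skipped"`.
#' @export
reconstruct_gres <- function(alignments, tree, threshold = 0.75,
                             optimise = FALSE, human = "human") {
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  skipped <- character()
  rows <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    gid <- names(alignments)[i]
    aln <- strip_human_gaps(alignments[[i]], human = human)
    if (isTRUE(attr(aln, "empty"))) {
      skipped <- c(skipped, gid)
      next
    }
    if (optimise) {
      fit <- fit_f81(tree, aln)
      tr <- fit$tree; model <- fit$model
    } else {
      tr <- tree
      x <- aln_to_matrix(aln)
      cnt <- tabulate(x[x <= 4L], 4L) + 1
      model <- f81_model(cnt / sum(cnt))
    }
    post <- marginal_ancestral_posteriors(tr, model, aln)
    seqs <- call_ancestral_sequences(post, aln, threshold = threshold,
                                     human = human)
    rows[[i]] <- tibble::tibble(gre_id = gid, node = names(seqs),
                                sequence = unname(seqs))
  }
  out <- dplyr::bind_rows(rows)
  if (length(skipped)) {
    inform(sprintf("skipped %d GRE(s) with all-gap human sequence",
                   length(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}
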