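# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (enumeration, closed form, or a reference
# package) and must stay independent of the package code paths it verifies.

BASES <- c("A", "C", "G", "T")

# --- substitution-site oracle ----------------------------------------------
# A site is a retained single-event substitution iff the state vector equals
# one of the 5 x 4 x 3 "step" patterns: ancestral base a repeated down to the
# transition, derived base d thereafter. Enumerating patterns is a different
# route than counting transitions.
oracle_call_site <- function(states) {
  if (any(states == "N")) return(NULL)
  lineages <- c("Ape", "GreatApe", "AfricanGreatApe", "Hominin", "Human")
  hit <- NULL
  for (k in 1:5) {
    for (a in BASES) {
      for (d in setdiff(BASES, a)) {
        patt <- c(rep(a, k), rep(d, 6 - k))
        if (identical(states, patt)) {
          hit <- list(lineage = lineages[k], ancestral = a, derived = d)
        }
      }
    }
  }
  hit
}

# --- F81 matrix-exponential oracle -----------------------------------------
oracle_f81_expm <- function(freq, t) {
  beta <- 1 / (1 - sum(freq^2))
  q <- beta * matrix(freq, 4, 4, byrow = TRUE)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  as.matrix(Matrix::expm(q * t))
}

# --- exhaustive marginal-posterior oracle ----------------------------------
# Enumerates every assignment of internal-node states, accumulating the
# joint probability prior(root) * prod(edge transitions) * tip indicators.
oracle_posteriors_enum <- function(tree, freq, aln) {
  beta <- 1 / (1 - sum(freq^2))
  pmat <- function(t) {
    e <- exp(-beta * t)
    p <- matrix((1 - e) * freq, 4, 4, byrow = TRUE)
    diag(p) <- diag(p) + e
    p
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  pm <- lapply(tree$edge.length, pmat)
  root <- setdiff(edge[, 1], edge[, 2])
  x <- lapply(aln, function(s) strsplit(s, "")[[1]])
  s_len <- length(x[[1]])
  post <- array(0, c(4, s_len, nnode))
  grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  for (site in seq_len(s_len)) {
    for (g in seq_len(nrow(grid))) {
      assign_int <- grid[g, ]
      state_of <- function(node) {
        if (node <= ntip) {
          b <- x[[tree$tip.label[node]]][site]
          match(b, BASES)  # NA for N or gap
        } else assign_int[node - ntip]
      }
      pr <- freq[assign_int[root - ntip]]
      ok <- TRUE
      for (e in seq_len(nrow(edge))) {
        p <- edge[e, 1]; ch <- edge[e, 2]
        sc <- state_of(ch)
        if (is.na(sc)) next  # missing tip: marginalised, contributes 1
        pr <- pr * pm[[e]][assign_int[p - ntip], if (ch <= ntip) sc else sc]
        if (pr == 0) { ok <- FALSE; break }
      }
      if (!ok) next
      for (n in seq_len(nnode)) {
        post[assign_int[n], site, n] <- post[assign_int[n], site, n] + pr
      }
    }
    for (n in seq_len(nnode)) {
      tot <- sum(post[, site, n])
      if (tot > 0) post[, site, n] <- post[, site, n] / tot
    }
  }
  post
}

# --- two-tailed Fisher oracle (point-probability method) --------------------
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b          # row 1 margin (set A)
  n_ <- c + d         # row 2 margin
  k <- a + c          # column margin
  xs <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(xs, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- BH oracle from the definition -----------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# --- exhaustive PWM threshold oracle (all 4^L windows) ----------------------
oracle_pwm_threshold <- function(s_int, bg, match_p) {
  l <- ncol(s_int)
  grid <- as.matrix(expand.grid(rep(list(1:4), l)))
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    sum(s_int[cbind(grid[i, ], seq_len(l))])
  }, numeric(1))
  probs <- vapply(seq_len(nrow(grid)), function(i) {
    prod(bg[grid[i, ]])
  }, numeric(1))
  for (s in sort(unique(scores))) {
    if (sum(probs[scores >= s]) <= match_p) return(s)
  }
  Inf
}

# --- independent IRLS logistic oracle --------------------------------------
oracle_irls_logistic <- function(xmat, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(xmat))
  for (i in seq_len(max_iter)) {
    eta <- drop(xmat %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    zv <- eta + (y - mu) / w
    wx <- xmat * w
    beta_new <- solve(crossprod(xmat, wx), crossprod(wx, zv))
    if (max(abs(beta_new - beta)) < tol) {
      return(drop(beta_new))
    }
    beta <- drop(beta_new)
  }
  beta
}

# --- misc fixtures ----------------------------------------------------------
tiny_tree_4 <- function() {
  ape::read.tree(text = "((t1:0.1,t2:0.2)n1:0.15,(t3:0.05,t4:0.3)n2:0.1)r;")
}
tiny_tree_5 <- function() {
  ape::read.tree(
    text = "(((t1:0.1,t2:0.2)n1:0.1,t3:0.25)n2:0.15,(t4:0.05,t5:0.3)n3:0.1)r;")
}

random_aln <- function(tree, s, seed, with_missing = FALSE) {
  withr::with_seed(seed, {
    chars <- if (with_missing) c(BASES, "N", "-") else BASES
    prob <- if (with_missing) c(rep(0.22, 4), 0.06, 0.06) else rep(0.25, 4)
    stats::setNames(
      vapply(tree$tip.label, function(t) {
        paste(sample(chars, s, TRUE, prob = prob), collapse = "")
      }, character(1)),
      tree$tip.label)
  })
}
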