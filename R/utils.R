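# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

# Integer encoding used throughout: A=1, C=2, G=3, T=4, N=5, '-'=6.
.STATE_CHARS <- c("A", "C", "G", "T", "N", "-")

seq_to_int <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  out <- match(chars, .STATE_CHARS)
  if (anyNA(out)) {
    abort(sprintf("sequence contains characters outside {A,C,G,T,N,-}: '%s'",
                  paste(unique(chars[is.na(out)]), collapse = "")))
  }
  out
}

int_to_seq <- function(x) paste(.STATE_CHARS[x], collapse = "")

# Alignment (named character vector of equal-length strings) -> integer matrix
# with one row per taxon.
aln_to_matrix <- function(aln) {
  stopifnot(is.character(aln), !is.null(names(aln)))
  lens <- nchar(aln)
  if (length(unique(lens)) > 1L) {
    abort("alignment sequences have unequal lengths")
  }
  t(vapply(aln, seq_to_int, integer(lens[[1]])))
}

matrix_to_aln <- function(m) {
  apply(m, 1L, int_to_seq)
}

# Deterministic per-stage seed derived from the run seed, kept < 2^31.
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% 2147483629)
}

# Benjamini-Hochberg wrapper; NA-safe.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Strict two-cell 1-df chi-square goodness of fit of observed count o (out of
# total tot) against expected e. Returns list(stat, p).
chisq_gof2 <- function(o, e, tot) {
  stopifnot(e > 0, tot >= o, tot > e)
  stat <- (o - e)^2 / e + ((tot - o) - (tot - e))^2 / (tot - e)
  list(stat = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

# 2x2 chi-square (no Yates by default; optional 0.5 continuity on zero cells).
chisq_2x2 <- function(tab, continuity_on_zero = TRUE) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  if (continuity_on_zero && any(tab == 0)) tab <- tab + 0.5
  rs <- rowSums(tab); cs <- colSums(tab); tot <- sum(tab)
  e <- outer(rs, cs) / tot
  stat <- sum((tab - e)^2 / e)
  list(stat = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}
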