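# Internal helpers shared across modules.

# Pseudocount added to every grid point of a density profile before
# normalization, so that log(P/Q) is always defined.
.profile_eps <- function(n_grid) 1e-9 / n_grid

# Squared Euclidean distances between rows of a and rows of b.
.dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Per-row medians for a dense matrix or a dgCMatrix, exploiting stored
# zeros in the sparse case (values are assumed non-negative).
.row_medians <- function(x) {
  if (inherits(x, "sparseMatrix")) {
    x <- methods::as(x, "CsparseMatrix")
    n <- ncol(x)
    tx <- Matrix::t(x)  # column-oriented access per gene
    p <- tx@p
    vals <- tx@x
    vapply(seq_len(nrow(x)), function(g) {
      v <- vals[(p[g] + 1L):p[g + 1L]]
      if (p[g + 1L] == p[g]) v <- numeric(0)
      nz <- length(v)
      z <- n - nz
      # median positions in the full sorted vector of z zeros then sorted v
      lo <- (n + 1L) %/% 2L
      hi <- (n + 2L) %/% 2L
      v <- sort(v)
      pick <- function(k) if (k <= z) 0 else v[k - z]
      (pick(lo) + pick(hi)) / 2
    }, numeric(1))
  } else {
    apply(x, 1L, stats::median)
  }
}

# Per-gene detection counts from a detection matrix (genes x cells).
.n_detected <- function(det) {
  if (inherits(det, "Matrix")) as.numeric(Matrix::rowSums(det)) else rowSums(det)
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)

# Standardize embedding columns to unit variance (zero-variance columns are
# left unscaled); centering does not change distances but keeps values tame.
.scale_coords <- function(coords) {
  s <- apply(coords, 2L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  scale(coords, center = TRUE, scale = s)
}
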