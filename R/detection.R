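#' Binarize an expression matrix into a detection matrix
#'
#' Converts expression values (raw counts or normalized values) into the
#' binary gene-by-cell detection matrix the divergence statistic operates on.
#' A gene is "detected" in a cell when its value strictly exceeds a cutoff:
#' either the per-gene median across cells (`method = "median"`, the default
#' for scRNA-seq) or a global fixed value (`method = "threshold"`, e.g. 1
#' read for spatial transcriptomics spots).
#'
#' Strict inequality is used deliberately: with a per-gene median cutoff, a
#' non-strict comparison would mark at least half of all cells as detecting
#' every gene, including all-zero genes. For integer counts whose median is
#' zero, the median rule therefore reduces to "count > 0" detection.
#'
#' @param x numeric matrix or `Matrix::dgCMatrix`, genes in rows, cells in
#'   columns, non-negative values; dimnames are carried through.
#' @param method `"median"` (per-gene median cutoff) or `"threshold"`
#'   (global cutoff).
#' @param threshold non-negative global cutoff used when
#'   `method = "threshold"`. Default 1.
#' @return A sparse logical `Matrix` (genes x cells) with the same dimnames
#'   as `x`. Per-gene detection counts are available via `Matrix::rowSums()`.
#' @examples
#' x <- rbind(g1 = c(0, 0, 1, 3), g2 = c(5, 5, 5, 5))
#' colnames(x) <- paste0("c", 1:4)
#' det <- binarize(x)                     # g1 detected in 2 cells, g2 in none
#' Matrix::rowSums(det)
#' @export
binarize <- function(x, method = c("median", "threshold"), threshold = 1) {
  method <- match.arg(method)
  if (is.null(dim(x)) || nrow(x) < 1L)
    stop("'x' must be a gene x cell matrix")
  cutoff <- switch(method,
    median = .row_medians(x),
    threshold = {
      if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
        stop("'threshold' must be a single non-negative number")
      rep(threshold, nrow(x))
    })
  if (inherits(x, "sparseMatrix")) {
    tr <- Matrix::mat2triplet(x)
    if (length(tr$x) && min(tr$x) < 0) stop("expression values must be non-negative")
    keep <- tr$x > cutoff[tr$i]
    det <- Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep], x = TRUE,
                                dims = dim(x), dimnames = dimnames(x))
  } else {
    if (min(x) < 0) stop("expression values must be non-negative")
    det <- Matrix::Matrix(x > cutoff, sparse = TRUE)  # cutoff recycles by row
    dimnames(det) <- dimnames(x)
  }
  det
}

#' Filter uninformative genes from a detection matrix
#'
#' Removes genes detected in fewer than `min_detected` cells (too few
#' detections make the randomization null unstable) and genes detected in
#' every cell (their detection density equals the reference by construction,
#' so the divergence is identically ~0).
#'
#' @param det sparse logical detection matrix (genes x cells), as returned
#'   by [binarize()].
#' @param min_detected minimum number of detecting cells required to keep a
#'   gene. Default 10, matching the fixed prefilter used for spatial data.
#' @return The filtered detection matrix. The number of genes removed by
#'   each rule is reported via `message()` and attached as attribute
#'   `"removed"` (named integer vector).
#' @export
filter_genes <- function(det, min_detected = 10) {
  if (min_detected < 0) stop("'min_detected' must be >= 0")
  nd <- .n_detected(det)
  n_cells <- ncol(det)
  low <- nd < max(min_detected, 1)
  full <- nd >= n_cells
  keep <- !low & !full
  if (!any(keep))
    stop("no genes left after detection filtering (min_detected = ",
         min_detected, ")")
  if (any(full))
    warning(sum(full), " gene(s) detected in all cells removed (no signal)")
  if (any(low))
    message(sum(low), " gene(s) below min_detected = ", min_detected, " removed")
  out <- det[keep, , drop = FALSE]
  attr(out, "removed") <- c(below_min = sum(low), all_cells = sum(full))
  out
}

#' Per-cell weights from detected-gene totals
#'
#' Weights for the "advanced" mode: each cell is weighted by the total
#' number of genes it detects, normalized to sum to 1. Cells detecting no
#' gene receive the minimum positive total before normalization so that all
#' weights are strictly positive.
#'
#' @param det detection matrix (genes x cells).
#' @return Numeric vector of positive weights over cells, summing to 1.
#' @export
compute_cell_weights <- function(det) {
  tot <- if (inherits(det, "Matrix")) as.numeric(Matrix::colSums(det)) else colSums(det)
  if (all(tot == 0)) stop("no gene is detected in any cell")
  tot[tot == 0] <- min(tot[tot > 0])
  w <- tot / sum(tot)
  names(w) <- colnames(det)
  w
}

#' Export / import a detection matrix as Matrix Market triplets
#'
#' Writes `<prefix>.mtx` (0/1 pattern), `<prefix>.genes.txt` and
#' `<prefix>.cells.txt`; `read_detection()` reads them back.
#'
#' @param det detection matrix (genes x cells) with dimnames.
#' @param prefix file path prefix.
#' @return `write_detection()` returns `prefix` invisibly; `read_detection()`
#'   returns a sparse logical matrix with dimnames.
#' @export
write_detection <- function(det, prefix) {
  m <- methods::as(Matrix::drop0(det * 1), "CsparseMatrix")
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  writeLines(rownames(det), paste0(prefix, ".genes.txt"))
  writeLines(colnames(det), paste0(prefix, ".cells.txt"))
  invisible(prefix)
}

#' @rdname write_detection
#' @export
read_detection <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  genes <- readLines(paste0(prefix, ".genes.txt"))
  cells <- readLines(paste0(prefix, ".cells.txt"))
  if (length(genes) != nrow(m) || length(cells) != ncol(m))
    stop("label files do not match matrix dimensions for prefix ", prefix)
  out <- methods::as(methods::as(m, "lMatrix"), "CsparseMatrix")
  dimnames(out) <- list(genes, cells)
  out
}
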