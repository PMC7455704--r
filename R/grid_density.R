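#' Lattice grid points for a 2D input space
#'
#' Divides a 2D space (t-SNE/UMAP plot or physical spatial coordinates) into
#' a regular grid along both axes; the intersection points are the grid
#' points at which cell densities are evaluated. `k = ceiling(sqrt(n_grid))`
#' equally spaced levels per axis span the observed range inclusively, so
#' the actual number of points, `k^2`, may exceed the request. Lattice
#' points falling in empty regions are kept; they just carry near-zero
#' density mass.
#'
#' @param coords numeric matrix of cell coordinates, exactly 2 columns.
#' @param n_grid requested number of grid points (>= 4). Default 100
#'   (a 10 x 10 lattice).
#' @return Object of class `divergescan_grid`: list with `points`
#'   (n_grid x 2 matrix), `bandwidth` (`NULL` until set) and `space_label`.
#' @export
select_grid_2d <- function(coords, n_grid = 100) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("2D grids require exactly 2 coordinate columns")
  if (n_grid < 4) stop("'n_grid' must be >= 4")
  k <- ceiling(sqrt(n_grid))
  axes <- lapply(1:2, function(j) {
    r <- range(coords[, j])
    if (r[1] == r[2])
      stop("all cells share the same value on axis ", j, "; cannot build a 2D grid")
    seq(r[1], r[2], length.out = k)
  })
  pts <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], KEEP.OUT.ATTRS = FALSE))
  colnames(pts) <- colnames(coords)
  structure(list(points = pts, bandwidth = NULL, space_label = "2d"),
            class = "divergescan_grid")
}

#' Grid points covering the occupied region of a multidimensional space
#'
#' For input spaces with more than two dimensions (typically the first tens
#' of principal components) a bounding-box lattice would place almost all
#' points in empty space, so grid points are instead placed as k-means
#' centroids of the cell coordinates: they cover exactly the subspace the
#' cells occupy. Deterministic for a fixed seed.
#'
#' @param coords numeric matrix of cell coordinates (n_cells x n_dims,
#'   n_dims >= 2).
#' @param n_grid number of grid points (2 <= n_grid <= n_cells). Default 100.
#' @param seed integer seed for centroid initialization.
#' @return Object of class `divergescan_grid` (see [select_grid_2d()]).
#' @export
select_grid_highd <- function(coords, n_grid = 100, seed = 42) {
  coords <- as.matrix(coords)
  n_cells <- nrow(coords)
  if (ncol(coords) < 2L) stop("at least 2 dimensions required")
  if (n_grid < 2) stop("'n_grid' must be >= 2")
  if (n_grid > n_cells) stop("'n_grid' (", n_grid, ") exceeds the number of cells (",
                             n_cells, ")")
  if (n_grid == n_cells) {
    pts <- coords
  } else {
    set.seed(seed)
    km <- suppressWarnings(
      stats::kmeans(coords, centers = n_grid, iter.max = 50, nstart = 1))
    pts <- km$centers
  }
  dimnames(pts) <- list(NULL, colnames(coords))
  structure(list(points = pts, bandwidth = NULL, space_label = "highd"),
            class = "divergescan_grid")
}

#' Default Gaussian kernel bandwidth
#'
#' The bandwidth h is the mean nearest-neighbor distance among the grid
#' points — the typical grid spacing. The kernel then smooths each cell's
#' mass across neighboring grid points instead of effectively assigning it
#' to the nearest one, which keeps density profiles (and hence divergence
#' scores and rankings) stable under moderate changes of grid size and
#' bandwidth. Because the grid itself is built from the cell coordinates,
#' the rule adapts to the scale and dimensionality of the input space. For
#' degenerate grids (a single point, or coincident points) the median
#' cell-to-nearest-grid-point distance is used instead.
#'
#' @param coords numeric matrix of cell coordinates.
#' @param grid `divergescan_grid` object.
#' @return A single positive bandwidth.
#' @export
default_bandwidth <- function(coords, grid) {
  coords <- as.matrix(coords)
  pts <- grid$points
  if (nrow(pts) < 1L) stop("empty grid")
  h <- 0
  if (nrow(pts) >= 2L) {
    dg <- sqrt(.dist2(pts, pts))
    diag(dg) <- Inf
    h <- mean(apply(dg, 1L, min))
  }
  if (h == 0) {
    nearest <- sqrt(apply(.dist2(coords, pts), 1L, min))
    h <- stats::median(nearest)
  }
  if (!is.finite(h) || h <= 0)
    stop("cannot derive a positive bandwidth: grid and cells are coincident")
  h
}

#' Gaussian kernel weights of cells at grid points
#'
#' Computes the untruncated Gaussian kernel weight
#' `exp(-d(c, x)^2 / (2 h^2))` of every cell `c` at every grid point `x`,
#' with `d` the Euclidean distance. This cells-by-grid matrix is the shared
#' ingredient of the reference distribution Q and of every per-gene density
#' profile.
#'
#' @param coords numeric matrix of cell coordinates.
#' @param grid `divergescan_grid` with its `bandwidth` set (see
#'   [default_bandwidth()]).
#' @return Numeric matrix (n_cells x n_grid) with entries in (0, 1]; an
#'   entry is 1 iff the cell coincides with the grid point. Bandwidth is
#'   attached as attribute `"bandwidth"`.
#' @export
kernel_weights <- function(coords, grid) {
  h <- grid$bandwidth
  if (is.null(h) || !is.finite(h) || h <= 0) stop("grid bandwidth must be positive")
  dm <- exp(-.dist2(as.matrix(coords), grid$points) / (2 * h^2))
  attr(dm, "bandwidth") <- h
  dm
}

.normalize_profile <- function(raw) {
  p <- raw + .profile_eps(length(raw))
  p / sum(p)
}

#' Reference distribution Q over grid points
#'
#' The reference distribution Q is the (optionally cell-weighted) kernel
#' density mass of all cells at each grid point, normalized to sum to 1. A
#' pseudocount of `1e-9 / n_grid` is added at every grid point before
#' normalization so Q is strictly positive everywhere, keeping `log(P/Q)`
#' defined even at grid points far from all cells.
#'
#' @param dm kernel weight matrix from [kernel_weights()].
#' @param weights optional positive per-cell weights (advanced mode, see
#'   [compute_cell_weights()]); `NULL` means uniform.
#' @return Numeric probability vector over grid points (sums to 1).
#' @export
reference_distribution <- function(dm, weights = NULL) {
  if (is.null(weights)) {
    raw <- colSums(dm)
  } else {
    if (length(weights) != nrow(dm)) stop("'weights' must have one entry per cell")
    if (any(weights <= 0)) stop("'weights' must be strictly positive")
    raw <- as.numeric(crossprod(dm, weights))
  }
  .normalize_profile(raw)
}

#' Detection-class distributions P(G = T) and P(G = F)
#'
#' Density profiles over grid points of the cells in which a gene is
#' detected (P(G = T)) and not detected (P(G = F)), each normalized to sum
#' to 1 with the same pseudocount as Q.
#'
#' @param dm kernel weight matrix (cells x grid points).
#' @param detected logical vector over cells; must contain at least one
#'   `TRUE` and one `FALSE` (all-detected / never-detected genes are removed
#'   by [filter_genes()]).
#' @return List with probability vectors `p_t` and `p_f`.
#' @export
class_distributions <- function(dm, detected) {
  detected <- as.logical(detected)
  if (length(detected) != nrow(dm))
    stop("'detected' must have one entry per cell")
  if (all(detected) || !any(detected))
    stop("gene is detected in all or in no cells; filter such genes first")
  tot <- colSums(dm)
  p_t_raw <- colSums(dm[detected, , drop = FALSE])
  list(p_t = .normalize_profile(p_t_raw),
       p_f = .normalize_profile(tot - p_t_raw))
}
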