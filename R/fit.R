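#' Clustering-free differential expression scan
#'
#' Scores every gene by how non-randomly the cells detecting it are placed
#' in an input space, without clustering the cells first. The scan (i)
#' binarizes expression into detection, (ii) places grid points in the input
#' space and computes Gaussian-kernel density profiles of all cells (the
#' reference Q) and of each gene's detecting / non-detecting cells, (iii)
#' sums the Kullback-Leibler divergences of the two class profiles from Q,
#' and (iv) calibrates p-values against a randomization null whose log-scale
#' mean and sd are B-spline functions of the detection count.
#'
#' In the advanced mode (`mode = "advanced"`) both the reference Q and the
#' randomizations weight cells by their total number of detected genes, so
#' genes whose detection merely tracks overall detection depth lose
#' significance and genes running against that pattern gain it.
#'
#' @param x genes x cells expression matrix (dense or `dgCMatrix`), raw
#'   counts or normalized values; ignored when `detection` is supplied.
#' @param coords cells x dims numeric matrix of cell coordinates in the
#'   input space (>= 2 dims). If both `x`/`detection` and `coords` carry
#'   cell ids they are reconciled with [align_cells()].
#' @param detection optional precomputed logical detection matrix
#'   (genes x cells) replacing the binarization step.
#' @param method `"highd"` (k-means grid covering the occupied subspace;
#'   any dimensionality) or `"2d"` (axis lattice; exactly 2 dims, meant for
#'   t-SNE/UMAP plots and spatial coordinates).
#' @param mode `"default"` or `"advanced"` (detection-depth weighting).
#' @param grid_points requested number of grid points (default 100).
#' @param bandwidth Gaussian kernel bandwidth; `NULL` (default) uses
#'   [default_bandwidth()]. Interpreted in the (scaled) coordinate units.
#' @param detection_method,detection_threshold passed to [binarize()].
#' @param min_detected gene prefilter, passed to [filter_genes()].
#' @param randomizations shuffles per count level (default 100).
#' @param count_levels number of detection-count levels for the null
#'   (default 20).
#' @param spline_df degrees of freedom of the null spline fits (default 6).
#' @param seed integer seed controlling grid placement and randomizations.
#' @param scale_coords standardize each coordinate dimension to unit
#'   variance before distances are computed. Default `FALSE`: PCA scores and
#'   t-SNE/UMAP or spatial coordinates already carry meaningful relative
#'   scale, and standardizing inflates noise dimensions to the size of
#'   signal dimensions, diluting the density signal. Set `TRUE` for input
#'   spaces whose axes have incomparable units.
#' @param verbose print one line per stage with timing.
#' @return Object of class `divergescan`: list with `results` (the per-gene
#'   table: `gene`, `d_kl`, `n_detected`, `log10_pval`, `log10_pval_adj`,
#'   `rank`), `grid`, `null` (the fitted null model), `dm` (cell x grid
#'   kernel weights), `q`, `detection` (the filtered detection matrix),
#'   `weights` (advanced mode), `params` and `call`.
#' @examples
#' set.seed(1)
#' sim <- simulate_dataset(n_cells = 300, n_clusters = 2, n_genes = 400,
#'                         n_deg = 20, seed = 1)
#' emb <- embed_for_test(sim, n_dims = 5)
#' fit <- divergescan(sim$counts, emb, grid_points = 40, seed = 1)
#' head(fit$results[order(fit$results$rank), ])
#' @export
divergescan <- function(x = NULL, coords, detection = NULL,
                        method = c("highd", "2d"),
                        mode = c("default", "advanced"),
                        grid_points = 100, bandwidth = NULL,
                        detection_method = c("median", "threshold"),
                        detection_threshold = 1, min_detected = 10,
                        randomizations = 100, count_levels = 20,
                        spline_df = 6, seed = 42, scale_coords = FALSE,
                        verbose = FALSE) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  cl <- match.call()
  t0 <- proc.time()[3]
  stage <- function(what) .msg(verbose, sprintf("[%6.1fs] %s",
                                                proc.time()[3] - t0, what))

  coords <- as.matrix(coords)
  if (ncol(coords) < 2L) stop("'coords' needs at least 2 dimensions")
  if (any(!is.finite(coords))) stop("'coords' contains non-finite values")
  if (method == "2d" && ncol(coords) != 2L)
    stop("method '2d' requires exactly 2 coordinate dimensions")

  if (is.null(detection)) {
    if (is.null(x)) stop("supply either 'x' or 'detection'")
    if (!is.null(colnames(x)) && !is.null(rownames(coords))) {
      al <- align_cells(x, coords)
      x <- al$expr; coords <- al$coords
    } else if (ncol(x) != nrow(coords)) {
      stop("'x' has ", ncol(x), " cells but 'coords' has ", nrow(coords))
    }
    stage(sprintf("binarizing %d genes x %d cells (%s)", nrow(x), ncol(x),
                  detection_method[1]))
    det_full <- binarize(x, method = detection_method,
                         threshold = detection_threshold)
  } else {
    if (!is.null(colnames(detection)) && !is.null(rownames(coords))) {
      al <- align_cells(detection, coords)
      detection <- al$expr; coords <- al$coords
    } else if (ncol(detection) != nrow(coords)) {
      stop("'detection' has ", ncol(detection), " cells but 'coords' has ",
           nrow(coords))
    }
    det_full <- detection
    if (!inherits(det_full, "Matrix"))
      det_full <- Matrix::Matrix(det_full != 0, sparse = TRUE)
  }
  det <- filter_genes(det_full, min_detected = min_detected)
  stage(sprintf("%d of %d genes retained", nrow(det), nrow(det_full)))

  if (isTRUE(scale_coords)) coords_use <- .scale_coords(coords)
  else coords_use <- coords

  set.seed(seed)
  grid <- if (method == "2d") select_grid_2d(coords_use, grid_points)
          else select_grid_highd(coords_use, grid_points, seed = seed)
  h_default <- default_bandwidth(coords_use, grid)
  grid$bandwidth <- if (is.null(bandwidth)) h_default else bandwidth
  if (grid$bandwidth <= 0) stop("'bandwidth' must be positive")
  stage(sprintf("%d grid points (%s), bandwidth %.4g", nrow(grid$points),
                method, grid$bandwidth))

  dm <- kernel_weights(coords_use, grid)
  weights <- if (mode == "advanced") compute_cell_weights(det_full) else NULL
  q <- reference_distribution(dm, weights)

  stage("scoring genes")
  scores <- score_all_genes(det, dm, q)

  stage("building randomization null")
  levels <- choose_count_levels(ncol(det), scores$n_detected, count_levels)
  null_pts <- vapply(levels, function(lv)
    randomized_divergences(lv, dm, q, n_randomizations = randomizations,
                           seed = seed + lv, weights = weights),
    numeric(2))
  model <- fit_null_model(levels, null_pts["mean", ], null_pts["sd", ],
                          spline_df = spline_df, n_cells = ncol(det))

  res <- p_values(scores, model)
  stage("done")

  structure(list(results = res, grid = grid, null = model, dm = dm, q = q,
                 detection = det, weights = weights,
                 params = list(method = method, mode = mode,
                               grid_points = grid_points,
                               bandwidth = grid$bandwidth,
                               default_bandwidth = h_default,
                               detection_method = if (is.null(detection))
                                 match.arg(detection_method) else "precomputed",
                               detection_threshold = detection_threshold,
                               min_detected = min_detected,
                               randomizations = randomizations,
                               count_levels = count_levels,
                               spline_df = spline_df, seed = seed,
                               scale_coords = scale_coords),
                 n_cells = ncol(det), call = cl),
            class = "divergescan")
}

#' @export
print.divergescan <- function(x, ...) {
  cat("Divergence scan (", x$params$method, " grid, ", x$params$mode,
      " mode)\n", sep = "")
  cat("  ", nrow(x$results), " genes x ", x$n_cells, " cells; ",
      nrow(x$grid$points), " grid points; bandwidth ",
      format(x$params$bandwidth, digits = 4), "\n", sep = "")
  top <- x$results[order(x$results$rank), ][seq_len(min(5L, nrow(x$results))), ]
  cat("  top genes:\n")
  print(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.divergescan <- function(object, alpha = 0.05, ...) {
  res <- object$results
  n_sig <- sum(res$log10_pval_adj < log10(alpha))
  out <- list(n_genes = nrow(res), n_cells = object$n_cells,
              n_grid = nrow(object$grid$points),
              bandwidth = object$params$bandwidth,
              mode = object$params$mode, alpha = alpha, n_significant = n_sig,
              top = utils::head(res[order(res$rank), ], 10L))
  class(out) <- "summary.divergescan"
  out
}

#' @export
print.summary.divergescan <- function(x, ...) {
  cat("Divergence scan of", x$n_genes, "genes across", x$n_cells, "cells\n")
  cat(x$n_grid, "grid points, bandwidth", format(x$bandwidth, digits = 4),
      ",", x$mode, "mode\n")
  cat(x$n_significant, "genes with BH-adjusted p <", x$alpha, "\n\n")
  cat("Top 10 genes by rank:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Diagnostic plot of a divergence scan
#'
#' Plots per-gene log divergence against log detection count, with the
#' fitted null mean curve and a +/- 2 sd band; genes far above the band are
#' the candidate DEGs. This is the standard diagnostic for judging whether
#' the spline null tracks the randomized pattern.
#'
#' @param x `divergescan` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.divergescan <- function(x, ...) {
  res <- x$results
  lx <- log(res$n_detected)
  ly <- log(pmax(res$d_kl, 1e-300))
  graphics::plot(lx, ly, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.4, 0.5),
                 xlab = "log n_detected", ylab = "log D_KL", ...)
  gx <- seq(min(lx), max(lx), length.out = 200)
  m <- x$null$mean_fun(exp(gx)); s <- x$null$sd_fun(exp(gx))
  graphics::lines(gx, m, col = "red3", lwd = 2)
  graphics::lines(gx, m + 2 * s, col = "red3", lty = 2)
  graphics::lines(gx, m - 2 * s, col = "red3", lty = 2)
  invisible(x)
}
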