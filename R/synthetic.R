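#' Simulate a benchmark scRNA-seq dataset with ground-truth DEGs
#'
#' Generates an artificial count matrix in the style of Splatter's
#' cluster/path simulations: gamma-distributed baseline gene means,
#' lognormal per-cell size factors, negative-binomial counts, and
#' multiplicative per-cluster differential-expression factors for a chosen
#' set of genes. With `paths = TRUE`, cluster means are connected by
#' randomly wired paths and each cell sits at a uniform pseudotime along its
#' cluster's incoming path, emulating differentiation trajectories.
#'
#' For each of `n_deg` candidate genes, every cluster independently receives
#' a DE factor with probability 1/2 (at least one cluster always does); the
#' factor is `exp(s * |N(0,1)|)` with random sign of the exponent, where `s`
#' is `de_strength`. Each gene's DE score is the sum over clusters of
#' `|log2(factor)|`, and the `n_deg` genes with the highest score (ties
#' broken by gene index) are labeled the true DEGs — so with
#' `de_strength = 0` the truth labels carry no signal at all, giving a
#' random-classifier baseline.
#'
#' @param n_cells,n_clusters,n_genes dataset dimensions (`n_clusters >= 2`).
#' @param n_deg number of true DEGs (`<= n_genes`). Default 100.
#' @param de_strength scale of the log DE factors (default 1; 0 disables DE).
#' @param paths simulate paths between clusters instead of discrete clusters.
#' @param seed integer seed; the full dataset is reproducible from it.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`).
#' @param libsize_sdlog sd of the lognormal per-cell size factors.
#' @param mean_shape,mean_rate gamma parameters of baseline gene means.
#' @param de_prob probability that a given cluster of a DE gene is affected.
#' @return Object of class `divergescan_sim`: list with `counts` (integer
#'   genes x cells matrix with dimnames), `cluster_of_cell`, `de_factor`
#'   (genes x clusters), `de_score`, `truth` (logical, exactly `n_deg`
#'   `TRUE`), and for path simulations `path_from` and `pseudotime`.
#' @export
simulate_dataset <- function(n_cells, n_clusters, n_genes, n_deg = 100,
                             de_strength = 1, paths = FALSE, seed = 42,
                             dispersion = 0.1, libsize_sdlog = 0.2,
                             mean_shape = 0.6, mean_rate = 0.3,
                             de_prob = 0.5) {
  if (n_clusters < 2) stop("'n_clusters' must be >= 2")
  if (n_deg > n_genes) stop("'n_deg' cannot exceed 'n_genes'")
  if (n_cells < n_clusters) stop("need at least one cell per cluster")
  if (de_strength < 0) stop("'de_strength' must be >= 0")
  set.seed(seed)

  base_mean <- stats::rgamma(n_genes, shape = mean_shape, rate = mean_rate)
  base_mean <- pmax(base_mean, 1e-4)

  de_factor <- matrix(1, n_genes, n_clusters)
  if (n_deg > 0 && de_strength > 0) {
    deg_idx <- sample.int(n_genes, n_deg)
    for (g in deg_idx) {
      hit <- stats::runif(n_clusters) < de_prob
      if (!any(hit)) hit[sample.int(n_clusters, 1L)] <- TRUE
      k <- sum(hit)
      de_factor[g, hit] <- exp(sample(c(-1, 1), k, replace = TRUE) *
                                 de_strength * abs(stats::rnorm(k)))
    }
  }
  de_score <- rowSums(abs(log2(de_factor)))
  truth <- logical(n_genes)
  truth[order(-de_score, seq_len(n_genes))[seq_len(n_deg)]] <- TRUE

  cluster_of_cell <- sample(rep_len(seq_len(n_clusters), n_cells))
  sf <- stats::rlnorm(n_cells, 0, libsize_sdlog)
  cluster_mean <- base_mean * de_factor  # genes x clusters

  path_from <- NULL
  pseudotime <- NULL
  mu <- matrix(0, n_genes, n_cells)
  if (paths) {
    # cluster k's cells interpolate from its source's mean to its own;
    # cluster 1 starts from the unperturbed baseline
    path_from <- c(0L, vapply(2:n_clusters,
                              function(k) sample.int(k - 1L, 1L), integer(1)))
    pseudotime <- stats::runif(n_cells)
    for (c in seq_len(n_cells)) {
      k <- cluster_of_cell[c]
      from_mean <- if (path_from[k] == 0L) base_mean
                   else cluster_mean[, path_from[k]]
      t <- pseudotime[c]
      mu[, c] <- ((1 - t) * from_mean + t * cluster_mean[, k]) * sf[c]
    }
  } else {
    mu <- cluster_mean[, cluster_of_cell, drop = FALSE] *
      rep(sf, each = n_genes)
  }

  counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                  size = 1 / dispersion),
                   n_genes, n_cells,
                   dimnames = list(sprintf("gene%d", seq_len(n_genes)),
                                   sprintf("cell%d", seq_len(n_cells))))

  structure(list(counts = counts, cluster_of_cell = cluster_of_cell,
                 de_factor = de_factor, de_score = de_score, truth = truth,
                 path_from = path_from, pseudotime = pseudotime,
                 params = list(n_cells = n_cells, n_clusters = n_clusters,
                               n_genes = n_genes, n_deg = n_deg,
                               de_strength = de_strength, paths = paths,
                               seed = seed)),
            class = "divergescan_sim")
}

#' @export
print.divergescan_sim <- function(x, ...) {
  p <- x$params
  cat("Simulated dataset:", p$n_genes, "genes x", p$n_cells, "cells,",
      p$n_clusters, if (isTRUE(p$paths)) "path-connected clusters,"
      else "clusters,", sum(x$truth), "true DEGs\n")
  invisible(x)
}

#' Low-dimensional embedding of a simulated dataset
#'
#' Standard scRNA-seq preprocessing used to feed the scan in benchmarks:
#' counts are library-size normalized (to 10,000 per cell) and
#' log1p-transformed, the `n_hvg` most variable genes are kept, genes are
#' centered, and cells are projected onto the top right-singular directions
#' of the centered matrix (i.e. unscaled PCA scores). Library-size
#' normalization matters: without it the leading component tracks
#' sequencing depth, which every gene's detection correlates with, and the
#' null calibration degrades. Signs follow a fixed convention — the
#' largest-magnitude gene loading of each component is positive — so the
#' embedding is fully deterministic.
#'
#' @param x `divergescan_sim` object or a genes x cells count matrix.
#' @param n_dims number of dimensions to keep.
#' @param n_hvg number of most-variable genes used for the decomposition
#'   (default 1000; `Inf` keeps all genes).
#' @param normalize library-size normalize before the log transform
#'   (default `TRUE`).
#' @param seed unused (the decomposition is deterministic); accepted so
#'   callers can treat all generators uniformly.
#' @return Numeric matrix (cells x n_dims) with cell ids as rownames.
#' @export
embed_for_test <- function(x, n_dims = 10, n_hvg = 1000, normalize = TRUE,
                           seed = NULL) {
  counts <- if (inherits(x, "divergescan_sim")) x$counts else x
  if (n_dims > min(dim(counts)))
    stop("'n_dims' cannot exceed min(n_genes, n_cells)")
  vals <- as.matrix(counts)
  if (isTRUE(normalize)) {
    libsize <- pmax(colSums(vals), 1)
    vals <- t(t(vals) / libsize) * 1e4
  }
  vals <- log1p(vals)
  if (is.finite(n_hvg) && n_hvg < nrow(vals)) {
    v <- apply(vals, 1L, stats::var)
    vals <- vals[order(-v)[seq_len(n_hvg)], , drop = FALSE]
  }
  xc <- t(vals)                               # cells x genes
  xc <- sweep(xc, 2L, colMeans(xc))
  n_cells <- nrow(xc)
  if (n_cells <= ncol(xc)) {
    eg <- eigen(tcrossprod(xc), symmetric = TRUE)
    d <- sqrt(pmax(eg$values[seq_len(n_dims)], 0))
    scores <- eg$vectors[, seq_len(n_dims), drop = FALSE] *
      rep(d, each = n_cells)
    for (j in seq_len(n_dims)) {
      if (d[j] == 0) next
      v <- crossprod(xc, eg$vectors[, j]) / d[j]
      if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
    }
  } else {
    sv <- svd(xc, nu = n_dims, nv = n_dims)
    scores <- sv$u * rep(sv$d[seq_len(n_dims)], each = n_cells)
    for (j in seq_len(n_dims)) {
      v <- sv$v[, j]
      if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- colnames(counts)
  colnames(scores) <- sprintf("dim%d", seq_len(n_dims))
  scores
}

#' ROC AUC of a gene ranking against ground truth
#'
#' Area under the ROC curve in its Mann-Whitney form: the probability that a
#' uniformly drawn true DEG outranks a uniformly drawn non-DEG, counting
#' ties as 1/2. Genes present in the truth vector but absent from the result
#' table (e.g. removed by the detection filter) are assigned the shared
#' worst rank `length(truth) + 1`: a method is penalized, not excused, for
#' discarding true DEGs.
#'
#' @param result result `data.frame` with columns `gene` and `rank`
#'   (rank 1 = most significant).
#' @param truth named logical vector over the full gene universe
#'   (`TRUE` = true DEG), or an unnamed vector aligned with `result$gene`.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(result, truth) {
  if (is.null(names(truth))) {
    if (length(truth) != nrow(result))
      stop("unnamed 'truth' must align with the result rows")
    names(truth) <- result$gene
  }
  if (all(truth) || !any(truth))
    stop("'truth' must contain both true DEGs and non-DEGs")
  worst <- length(truth) + 1
  r <- rep(worst, length(truth))
  names(r) <- names(truth)
  hit <- intersect(result$gene, names(truth))
  r[hit] <- result$rank[match(hit, result$gene)]
  score <- -r                       # higher = more significant
  rk <- rank(score)                 # midranks handle ties as 1/2
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  (sum(rk[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
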