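#' Detection-count levels for the randomization null
#'
#' The null distribution of the log divergence depends on how many cells a
#' gene is detected in, and on essentially nothing else, so randomizations
#' are performed at a modest set of representative detection counts and the
#' null mean/sd are interpolated between them. Levels are approximately
#' log-spaced between the smallest and largest observed detection count
#' (endpoints always included), deduplicated, and clamped to
#' `[1, n_cells - 1]`.
#'
#' @param n_cells number of cells.
#' @param n_detected integer vector of observed per-gene detection counts.
#' @param n_levels number of levels requested (default 20).
#' @return Sorted integer vector of distinct levels.
#' @export
choose_count_levels <- function(n_cells, n_detected, n_levels = 20) {
  if (n_levels < 1) stop("'n_levels' must be >= 1")
  lo <- as.integer(max(1, min(n_detected)))
  hi <- as.integer(min(n_cells - 1, max(n_detected)))
  if (lo >= hi) return(lo)
  lv <- exp(seq(log(lo), log(hi), length.out = n_levels))
  lv <- as.integer(round(lv))
  lv[1] <- lo
  lv[length(lv)] <- hi
  sort(unique(pmin(pmax(lv, 1L), as.integer(n_cells) - 1L)))
}

#' Null mean and sd of the log divergence at one detection count
#'
#' Randomly shuffles detection over all cells: each randomization draws
#' `level` cells without replacement — uniformly, or with probability
#' proportional to `weights` in the advanced mode — marks them detected,
#' and computes the divergence statistic of that pattern against `q`. The
#' sample mean and standard deviation of the natural-log divergences form
#' one point of the null model.
#'
#' @param level detection count to randomize at (`1 <= level <= n_cells - 1`).
#' @param dm kernel weight matrix (cells x grid points).
#' @param q reference distribution over grid points.
#' @param n_randomizations number of shuffles (default 100).
#' @param seed integer seed; the same seed reproduces the draws exactly.
#' @param weights optional positive per-cell weights for weighted sampling.
#' @return Named numeric vector `c(mean = ..., sd = ...)` of log divergences.
#' @export
randomized_divergences <- function(level, dm, q, n_randomizations = 100,
                                   seed = 42, weights = NULL) {
  n_cells <- nrow(dm)
  if (level < 1 || level > n_cells - 1)
    stop("'level' must be in [1, n_cells - 1]")
  if (n_randomizations < 2) stop("'n_randomizations' must be >= 2")
  set.seed(seed)
  idx <- if (is.null(weights)) {
    replicate(n_randomizations, sample.int(n_cells, level), simplify = FALSE)
  } else {
    if (length(weights) != n_cells) stop("'weights' must have one entry per cell")
    replicate(n_randomizations, sample.int(n_cells, level, prob = weights),
              simplify = FALSE)
  }
  sel <- Matrix::sparseMatrix(i = rep(seq_len(n_randomizations), each = level),
                              j = unlist(idx), x = 1,
                              dims = c(n_randomizations, n_cells))
  pt_raw <- as.matrix(sel %*% dm)
  tot <- colSums(dm)
  pf_raw <- matrix(tot, n_randomizations, length(tot), byrow = TRUE) - pt_raw
  pf_raw[pf_raw < 0] <- 0
  ld <- log(pmax(.kl_rows(pt_raw, pf_raw, q), 1e-300))
  s <- stats::sd(ld)
  if (!is.finite(s) || s <= 0) {
    warning("zero spread among randomized divergences at level ", level,
            "; sd floored at 1e-6")
    s <- 1e-6
  }
  c(mean = mean(ld), sd = s)
}

#' Fit the spline null model of log divergence vs detection count
#'
#' Least-squares cubic B-spline fits of the randomized null mean, and of the
#' log of the null standard deviation, as functions of the log detection
#' count. Because complementing a detection pattern swaps the two classes
#' and leaves the statistic unchanged, the null at count k is (for uniform
#' shuffles, exactly) the null at `n_cells - k`; when `n_cells` is supplied
#' the curves are therefore fit against the log *effective* count
#' `k (n_cells - k) / n_cells`, which is symmetric in k and `n_cells - k`,
#' reduces to k for small counts, and removes the sharp curvature the raw
#' log count shows as k approaches `n_cells`. Fitting the sd on the log
#' scale guarantees a positive fitted sd. Outside the fitted range both
#' curves are clamped to their boundary values (polynomial spline tails are
#' not trusted for extrapolation). With fewer than 4 distinct levels a
#' constant model (global mean and sd) is used instead.
#'
#' @param levels integer vector of detection counts randomized at.
#' @param means,sds null means and sds of the log divergence at each level.
#' @param spline_df degrees of freedom of each spline fit (default 6; capped
#'   at `length(levels) - 1` and floored at 3).
#' @param n_cells total number of cells; enables the symmetric effective
#'   count (recommended; `NULL` fits against the raw log count).
#' @return Object of class `divergescan_null`: list with functions
#'   `mean_fun(count)` and `sd_fun(count)` taking raw detection counts, the
#'   fitted `table`, and the clamping `domain` on the internal scale.
#' @export
fit_null_model <- function(levels, means, sds, spline_df = 6, n_cells = NULL) {
  if (length(levels) != length(means) || length(levels) != length(sds))
    stop("'levels', 'means' and 'sds' must have equal length")
  if (any(!is.finite(means)) || any(!is.finite(sds)) || any(sds <= 0))
    stop("null means must be finite and sds finite and positive")
  ord <- order(levels)
  levels <- levels[ord]; means <- means[ord]; sds <- sds[ord]
  to_x <- if (is.null(n_cells)) function(k) log(k)
          else function(k) log(k * (n_cells - k) / n_cells)
  x <- to_x(levels)
  domain <- range(x)
  if (length(unique(levels)) < 4) {
    m0 <- mean(means); s0 <- mean(sds)
    mean_fun <- function(k) rep(m0, length(k))
    sd_fun <- function(k) rep(s0, length(k))
  } else {
    df <- max(3L, min(spline_df, length(unique(levels)) - 1L))
    fit_m <- stats::lm(y ~ splines::bs(x, df = df),
                       data = data.frame(x = x, y = means))
    fit_s <- stats::lm(y ~ splines::bs(x, df = df),
                       data = data.frame(x = x, y = log(sds)))
    clamp <- function(v) pmin(pmax(v, domain[1]), domain[2])
    mean_fun <- function(k)
      as.numeric(stats::predict(fit_m, data.frame(x = clamp(to_x(k)))))
    sd_fun <- function(k)
      exp(as.numeric(stats::predict(fit_s, data.frame(x = clamp(to_x(k))))))
  }
  structure(list(mean_fun = mean_fun, sd_fun = sd_fun,
                 table = data.frame(level = levels, mean = means, sd = sds),
                 domain = domain, n_cells = n_cells),
            class = "divergescan_null")
}

#' Benjamini-Hochberg adjustment in log10 space
#'
#' Step-up false-discovery-rate adjustment applied directly to log10
#' p-values, avoiding underflow for extremely significant genes. Adjusted
#' values are monotone along the ranking and capped at 0 (p = 1).
#'
#' @param log10_pvals numeric vector of log10 p-values (all <= 0).
#' @return Vector of adjusted log10 p-values, in the input order.
#' @export
adjust_bh <- function(log10_pvals) {
  m <- length(log10_pvals)
  if (m == 0L) return(numeric(0))
  o <- order(log10_pvals)
  lp <- log10_pvals[o] + log10(m / seq_len(m))
  lp <- rev(cummin(rev(lp)))
  lp <- pmin(lp, 0)
  out <- numeric(m)
  out[o] <- lp
  out
}

#' Calibrated p-values and gene ranking
#'
#' Converts divergence scores to one-sided p-values against the fitted null:
#' `z = (log D_KL - mean_curve(n)) / sd_curve(n)` and the upper-tail
#' standard-normal survival probability, computed in log space so extreme
#' genes do not underflow. Only excess divergence — detection patterns less
#' random than shuffles — is of interest, hence the one-sided test. Genes
#' are ranked by ascending log10 p-value with ties broken by descending
#' divergence.
#'
#' @param scores `data.frame` from [score_all_genes()] (columns `gene`,
#'   `d_kl`, `n_detected`).
#' @param model `divergescan_null` from [fit_null_model()].
#' @return `data.frame` with columns `gene`, `d_kl`, `n_detected`,
#'   `log10_pval`, `log10_pval_adj`, `rank` (rows in input gene order).
#' @export
p_values <- function(scores, model) {
  stopifnot(inherits(model, "divergescan_null"))
  k <- scores$n_detected
  z <- (log(pmax(scores$d_kl, 1e-300)) - model$mean_fun(k)) / model$sd_fun(k)
  log10p <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
  res <- data.frame(gene = scores$gene,
                    d_kl = scores$d_kl,
                    n_detected = scores$n_detected,
                    log10_pval = log10p,
                    log10_pval_adj = adjust_bh(log10p),
                    stringsAsFactors = FALSE)
  ord <- order(res$log10_pval, -res$d_kl)
  res$rank[ord] <- seq_len(nrow(res))
  res
}
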