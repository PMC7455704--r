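# Shared fixture builders; everything is generated in code.

# Cells drawn from isotropic Gaussian blobs.
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2L,
          centers[k, ], "+")))
  rownames(coords) <- paste0("c", seq_len(nrow(coords)))
  attr(coords, "blob") <- rep(seq_len(nrow(centers)), each = n_per)
  coords
}

# Random sparse detection matrix with given per-gene counts.
make_detection <- function(n_genes, n_cells, n_detected, seed = 1) {
  set.seed(seed)
  n_detected <- rep_len(n_detected, n_genes)
  Matrix::sparseMatrix(
    i = rep(seq_len(n_genes), n_detected),
    j = unlist(lapply(n_detected, function(k) sample.int(n_cells, k))),
    x = TRUE, dims = c(n_genes, n_cells),
    dimnames = list(paste0("g", seq_len(n_genes)),
                    paste0("c", seq_len(n_cells))))
}

# Independent brute-force evaluation of the divergence statistic, written
# directly from the double-sum formula (loops, no shared code paths).
oracle_kl <- function(p_t, p_f, q) {
  total <- 0
  for (p in list(p_t, p_f)) {
    for (x in seq_along(q)) {
      if (p[x] > 0) total <- total + p[x] * log(p[x] / q[x])
    }
  }
  total
}

# Brute-force all-pairs AUC with half-credit for ties.
oracle_auc <- function(rank_vec, truth) {
  pos <- rank_vec[truth]
  neg <- rank_vec[!truth]
  conc <- 0
  for (p in pos) for (n in neg)
    conc <- conc + if (p < n) 1 else if (p == n) 0.5 else 0
  conc / (length(pos) * length(neg))
}
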