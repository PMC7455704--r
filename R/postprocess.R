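#' Expression-distribution profiles of genes over grid points
#'
#' For each requested gene, the normalized density profile of its detecting
#' cells over the grid points (the P(G = T) distribution). The ratio
#' P(G = T) / Q — how enriched each grid region is for the gene relative to
#' all cells — is attached as attribute `"ratio"` when `q` is supplied, for
#' visualization of where in the space a gene is expressed.
#'
#' @param det filtered detection matrix (genes x cells).
#' @param dm kernel weight matrix (cells x grid points).
#' @param genes character vector of gene ids (default: all rows of `det`).
#' @param q optional reference distribution for the ratio profiles.
#' @return Numeric matrix (genes x grid points), each row summing to 1.
#' @export
gene_profiles <- function(det, dm, genes = NULL, q = NULL) {
  if (is.null(genes)) genes <- rownames(det)
  missing <- setdiff(genes, rownames(det))
  if (length(missing))
    stop("unknown gene id(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  sub <- det[genes, , drop = FALSE]
  raw <- as.matrix(sub %*% dm)
  eps <- .profile_eps(ncol(raw))
  prof <- raw + eps
  prof <- prof / rowSums(prof)
  rownames(prof) <- genes
  if (!is.null(q))
    attr(prof, "ratio") <- sweep(prof, 2L, q, "/")
  prof
}

#' Cluster genes by their expression-distribution profile
#'
#' Groups genes whose detecting cells occupy similar regions of the input
#' space — e.g. the significant genes of a scan — so that one representative
#' gene per group can be inspected. Hierarchical clustering (default) uses
#' average linkage on correlation distance (1 - Pearson across grid points),
#' which is invariant to the overall magnitude of a profile; k-means runs on
#' the raw profiles with a fixed seed. Cluster labels are renumbered by
#' decreasing cluster size.
#'
#' @param profiles genes x grid-points matrix from [gene_profiles()].
#' @param k number of clusters (`k <= nrow(profiles)`).
#' @param method `"hierarchical"` or `"kmeans"`.
#' @param seed seed for the k-means initialization.
#' @return `data.frame` with columns `gene` and `cluster` (integer in 1..k).
#' @export
cluster_genes <- function(profiles, k, method = c("hierarchical", "kmeans"),
                          seed = 42) {
  method <- match.arg(method)
  profiles <- as.matrix(profiles)
  if (k < 1 || k > nrow(profiles))
    stop("'k' must be between 1 and the number of genes (", nrow(profiles), ")")
  if (k == 1L) {
    cl <- rep(1L, nrow(profiles))
  } else if (method == "hierarchical") {
    vars <- apply(profiles, 1L, stats::var)
    if (any(vars == 0)) {
      warning("constant profile row(s); falling back to Euclidean distance")
      d <- stats::dist(profiles)
    } else {
      d <- stats::as.dist(1 - stats::cor(t(profiles)))
    }
    cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  } else {
    set.seed(seed)
    cl <- suppressWarnings(
      stats::kmeans(profiles, centers = k, iter.max = 50, nstart = 5))$cluster
  }
  # relabel by decreasing size, ties by first appearance
  sizes <- table(cl)
  new_id <- seq_along(sizes)
  names(new_id) <- names(sort(sizes, decreasing = TRUE))
  cl <- as.integer(new_id[as.character(cl)])
  data.frame(gene = rownames(profiles), cluster = cl, stringsAsFactors = FALSE)
}
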