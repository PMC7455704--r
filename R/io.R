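# Reading and writing of external formats: expression matrices (Matrix
# Market triplets or dense delimited), coordinate tables, result tables.

.detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a gene x cell expression matrix
#'
#' Two formats are supported. `"mtx"`: a Matrix Market triplet file with
#' companion plain-text label files (one gene id per line, one cell id per
#' line); by convention genes are rows and cells are columns, with
#' `transpose = TRUE` for matrices stored the other way around. `"dense"`:
#' a delimited table (tab or comma, auto-detected) with a header row of cell
#' ids and a first column of gene ids. `"auto"` picks by file extension.
#'
#' @param path path to the matrix file.
#' @param format `"auto"`, `"mtx"` or `"dense"`.
#' @param genes_path,cells_path label files for `"mtx"`; default
#'   `<path minus .mtx>.genes.txt` / `.cells.txt`, falling back to
#'   `genes.tsv` / `barcodes.tsv` next to the matrix.
#' @param transpose set `TRUE` when the mtx file stores cells as rows.
#' @return Sparse `dgCMatrix` (genes x cells) with gene/cell ids as dimnames.
#' @export
read_expression <- function(path, format = c("auto", "mtx", "dense"),
                            genes_path = NULL, cells_path = NULL,
                            transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "dense"
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed Matrix Market file ", path,
                                           ": ", conditionMessage(e)))
    if (isTRUE(transpose)) m <- Matrix::t(m)
    stem <- sub("\\.mtx(\\.gz)?$", "", path)
    pick <- function(explicit, candidates, what) {
      if (!is.null(explicit)) return(explicit)
      for (p in candidates) if (file.exists(p)) return(p)
      stop("no ", what, " label file found next to ", path)
    }
    gp <- pick(genes_path, c(paste0(stem, ".genes.txt"),
                             file.path(dirname(path), "genes.tsv")), "gene")
    cp <- pick(cells_path, c(paste0(stem, ".cells.txt"),
                             file.path(dirname(path), "barcodes.tsv")), "cell")
    genes <- read.delim(gp, header = FALSE, stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(cp, header = FALSE, stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m))
      stop("gene label file ", gp, " has ", length(genes),
           " entries but matrix declares ", nrow(m), " genes")
    if (length(cells) != ncol(m))
      stop("cell label file ", cp, " has ", length(cells),
           " entries but matrix declares ", ncol(m), " cells")
    if (anyDuplicated(genes)) stop("duplicate gene ids in ", gp)
    if (anyDuplicated(cells)) stop("duplicate cell ids in ", cp)
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(genes, cells)
  } else {
    sep <- .detect_sep(path)
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(rownames(tab))) stop("duplicate gene ids in ", path)
    if (anyDuplicated(colnames(tab))) stop("duplicate cell ids in ", path)
    vals <- as.matrix(tab)
    if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
    m <- methods::as(methods::as(vals, "generalMatrix"), "CsparseMatrix")
  }
  if (length(m@x) && min(m@x) < 0) stop("negative expression values in ", path)
  m
}

#' Read cell coordinates in an input space
#'
#' Delimited file (tab or comma, auto-detected) whose first column holds the
#' cell id and whose remaining columns are numeric coordinates: principal
#' components, t-SNE/UMAP coordinates, or physical 2D/3D positions. At least
#' two dimensions are required.
#'
#' @param path path to the coordinate table. A header line is used when the
#'   coordinate fields of the first line are non-numeric.
#' @return Numeric matrix (cells x dims) with cell ids as rownames.
#' @export
read_coordinates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- length(first) > 1L &&
    any(is.na(suppressWarnings(as.numeric(first[-1]))))
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 3L) stop("at least 2 dimensions required (found ",
                           ncol(tab) - 1L, " in ", path, ")")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate cell ids in ", path)
  coords <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(coords) || any(!is.finite(coords)))
    stop("non-numeric or non-finite coordinate values in ", path)
  rownames(coords) <- ids
  coords
}

#' Reconcile cells between an expression matrix and an embedding
#'
#' Restricts both objects to the intersection of their cell ids, in the
#' expression matrix's order. Embeddings are routinely computed on filtered
#' cells, so cells present on only one side are dropped with a warning
#' rather than an error; an empty intersection is fatal.
#'
#' @param expr genes x cells matrix with cell ids as colnames.
#' @param coords cells x dims matrix with cell ids as rownames.
#' @return List with elements `expr` and `coords`, cells aligned 1:1.
#' @export
align_cells <- function(expr, coords) {
  ce <- colnames(expr)
  cc <- rownames(coords)
  if (is.null(ce) || is.null(cc))
    stop("both inputs need cell ids (colnames / rownames)")
  common <- ce[ce %in% cc]
  if (length(common) == 0L)
    stop("expression matrix and coordinates share no cell ids")
  dropped <- c(setdiff(ce, cc), setdiff(cc, ce))
  if (length(dropped))
    warning(length(dropped), " cell(s) present on only one side dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  list(expr = expr[, common, drop = FALSE],
       coords = coords[common, , drop = FALSE])
}

#' Write / read a result table
#'
#' Serializes a result table as TSV with columns
#' `gene d_kl n_detected log10_pval log10_pval_adj rank`, one row per gene
#' sorted by rank, numbers at 9 significant digits (log10 p-values rather
#' than raw p-values, which underflow for extreme genes).
#'
#' @param res result `data.frame` as produced by [p_values()] or found in
#'   `fit$results`.
#' @param path output (input) file path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the table sorted by rank.
#' @export
write_results <- function(res, path) {
  cols <- c("gene", "d_kl", "n_detected", "log10_pval", "log10_pval_adj", "rank")
  if (!all(cols %in% names(res))) stop("result table lacks required columns")
  res <- res[order(res$rank), cols, drop = FALSE]
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(res)) sprintf("%s\t%.9g\t%d\t%.9g\t%.9g\t%d",
                                    res$gene, res$d_kl,
                                    as.integer(res$n_detected),
                                    res$log10_pval, res$log10_pval_adj,
                                    as.integer(res$rank)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab[order(tab$rank), , drop = FALSE]
}
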