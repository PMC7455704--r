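test_that("dense and mtx expression readers agree and attach labels", {
  m <- matrix(c(0, 2, 0, 5, 1, 0), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("c1", "c2")))
  dense <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2",
               sprintf("%s\t%g\t%g", rownames(m), m[, 1], m[, 2])), dense)
  got <- read_expression(dense)
  expect_identical(dim(got), c(3L, 2L))
  expect_equal(as.matrix(got), m)

  prefix <- tempfile()
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), mtx)
  writeLines(rownames(m), paste0(prefix, ".genes.txt"))
  writeLines(colnames(m), paste0(prefix, ".cells.txt"))
  got2 <- read_expression(mtx)
  expect_equal(as.matrix(got2), m)
  expect_identical(Matrix::nnzero(got2), 3L)  # nonzeros conserved
})

test_that("expression reader rejects malformed inputs", {
  prefix <- tempfile()
  mtx <- paste0(prefix, ".mtx")
  m <- Matrix::sparseMatrix(i = c(1, 5), j = c(1, 4), x = c(1, 2),
                            dims = c(5, 4))
  Matrix::writeMM(m, mtx)
  writeLines(paste0("g", 1:4), paste0(prefix, ".genes.txt"))  # 4 labels, 5 rows
  writeLines(paste0("c", 1:4), paste0(prefix, ".cells.txt"))
  expect_error(read_expression(mtx), "4 entries but matrix declares 5")

  writeLines(c("g1", "g1", "g3", "g4", "g5"), paste0(prefix, ".genes.txt"))
  expect_error(read_expression(mtx), "duplicate gene ids")

  dense <- tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2", "gA,-1,2"), dense)
  expect_error(read_expression(dense), "negative")
})

test_that("coordinate reader enforces >= 2 numeric dimensions", {
  f <- tempfile()
  writeLines(c("cell\tx\ty", sprintf("c%d\t%g\t%g", 1:4, 1:4, (1:4)^2)), f)
  got <- read_coordinates(f)
  expect_identical(dim(got), c(4L, 2L))
  expect_identical(rownames(got), paste0("c", 1:4))

  f1 <- tempfile()
  writeLines(c("cell\tx", sprintf("c%d\t%g", 1:4, 1:4)), f1)
  expect_error(read_coordinates(f1), "at least 2 dimensions")

  f50 <- tempfile()
  coords <- matrix(rnorm(150), 3)
  writeLines(sprintf("c%d,%s", 1:3,
                     apply(coords, 1, paste, collapse = ",")), f50)
  expect_identical(ncol(read_coordinates(f50)), 50L)

  fbad <- tempfile()
  writeLines(c("cell\tx\ty", "c1\t1\toops", "c2\t2\t3"), fbad)
  expect_error(read_coordinates(fbad), "non-numeric")
})

test_that("align_cells intersects, preserves order, and is idempotent", {
  expr <- matrix(1:10, 2, dimnames = list(c("g1", "g2"), paste0("c", 1:5)))
  coords <- matrix(rnorm(8), 4, dimnames = list(paste0("c", c(3, 1, 4, 2)), NULL))
  expect_warning(al <- align_cells(expr, coords), "dropped")
  expect_identical(colnames(al$expr), paste0("c", 1:4))
  expect_identical(rownames(al$coords), colnames(al$expr))
  al2 <- align_cells(al$expr, al$coords)   # no further change
  expect_identical(al2$expr, al$expr)
  expect_identical(al2$coords, al$coords)

  disjoint <- matrix(0, 2, 2, dimnames = list(c("x1", "x2"), NULL))
  expect_error(align_cells(expr, disjoint), "share no cell ids")
})

test_that("result tables round-trip through TSV at full precision", {
  res <- data.frame(gene = c("a", "b", "c"),
                    d_kl = c(0.123456789, 2e-7, 1.5),
                    n_detected = c(10L, 99L, 500L),
                    log10_pval = c(-12.3456789, -0.5, -3),
                    log10_pval_adj = c(-11.8, -0.5, -2.7),
                    rank = c(1L, 3L, 2L))
  f <- tempfile()
  write_results(res, f)
  lines <- readLines(f)
  expect_length(lines, 4L)
  expect_identical(lines[1],
    "gene\td_kl\tn_detected\tlog10_pval\tlog10_pval_adj\trank")
  back <- read_results(f)
  expect_identical(back$gene, c("a", "c", "b"))  # sorted by rank
  expect_identical(back$rank, 1:3)
  expect_equal(back$d_kl, res$d_kl[match(back$gene, res$gene)], tolerance = 1e-7)

  empty <- res[0, ]
  write_results(empty, f)
  expect_length(readLines(f), 1L)
})
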