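#' Read a single-cell gene x cell count matrix
#'
#' Accepts either a TSV (first column = gene ids, remaining columns = cells)
#' or a MatrixMarket triplet file plus row/column name files (one name per
#' line).
#'
#' @param path Matrix file (`.mtx` for MatrixMarket, otherwise TSV).
#' @param genes_path,cells_path Name files, required for MatrixMarket input.
#' @return Integer matrix (genes x cells); sparse input is densified.
#' @export
read_sc_matrix <- function(path, genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path)) {
      abort_ipqms("MatrixMarket input needs genes_path and cells_path")
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_path, warn = FALSE)
    colnames(m) <- readLines(cells_path, warn = FALSE)
  } else {
    df <- read_table_auto(path)
    m <- as.matrix(df[-1])
    rownames(m) <- as.character(df[[1]])
  }
  if (any(m < 0)) abort_ipqms("negative counts in single-cell matrix")
  storage.mode(m) <- "integer"
  m
}

#' Write a single-cell matrix as a MatrixMarket triplet
#' @param matrix Genes x cells count matrix.
#' @param dir Output directory; writes `matrix.mtx`, `genes.txt`, `cells.txt`.
#' @export
write_sc_matrix <- function(matrix, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(matrix, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(matrix), file.path(dir, "genes.txt"))
  writeLines(colnames(matrix), file.path(dir, "cells.txt"))
  invisible(dir)
}

binarize_sc <- function(matrix, min_count = 1L) {
  matrix >= min_count
}

#' Fraction of positive cells per gene
#'
#' A cell is positive for a gene when its count reaches `min_count` (default
#' 1: presence/absence, the natural reading in dropout-dominated single-cell
#' data).
#'
#' @param matrix Genes x cells count matrix.
#' @param genes Genes to evaluate; absent genes are reported, not an error.
#' @param min_count Positivity threshold.
#' @return List with `fractions` (named numeric over found genes) and
#'   `not_found` (character).
#' @export
positive_fraction <- function(matrix, genes = rownames(matrix),
                              min_count = 1L) {
  if (ncol(matrix) == 0L) abort_ipqms("matrix has zero cells")
  found <- intersect(genes, rownames(matrix))
  nf <- setdiff(genes, rownames(matrix))
  pos <- binarize_sc(matrix[found, , drop = FALSE], min_count)
  list(fractions = rowMeans(pos), not_found = nf)
}

#' Per-cell SWI/SNF subtype calls
#'
#' A cell is positive for a subtype when at least one subtype-specific
#' component is detected. With `require_core = TRUE` (default) subtype calls
#' are evaluated only on cells positive for at least one core component;
#' other cells are excluded from the summary denominators.
#'
#' @param matrix Genes x cells count matrix (gene names matched to the
#'   catalog through aliases).
#' @param catalog A `swisnf_catalog`.
#' @param require_core Restrict to core-positive cells.
#' @param min_count Positivity threshold.
#' @return List with `calls` (data frame: cell, core_positive, cbaf, pbaf,
#'   gbaf, n_subtypes, evaluated) and `summary` (list: `n_cells_evaluated`,
#'   `subtype_fractions`, `n_subtype_distribution` over 0..3 detected
#'   subtypes).
#' @export
call_subtypes <- function(matrix, catalog, require_core = TRUE,
                          min_count = 1L) {
  mapped <- match_catalog_symbols(catalog, rownames(matrix))
  pos <- binarize_sc(matrix, min_count)
  member_rows <- function(genes) which(!is.na(mapped) & mapped %in% genes)
  any_pos <- function(rows) {
    if (!length(rows)) rep(FALSE, ncol(matrix))
    else colSums(pos[rows, , drop = FALSE]) > 0
  }
  sub_rows <- lapply(c(cbaf = "cbaf", pbaf = "pbaf", gbaf = "gbaf"),
                     function(s) member_rows(subtype_members(catalog, s)))
  if (!any(lengths(sub_rows) > 0)) {
    abort_ipqms("no subtype-specific genes present in the matrix")
  }
  core_positive <- any_pos(member_rows(core_members(catalog)))
  calls <- data.frame(cell = colnames(matrix),
                      core_positive = core_positive,
                      cbaf = any_pos(sub_rows$cbaf),
                      pbaf = any_pos(sub_rows$pbaf),
                      gbaf = any_pos(sub_rows$gbaf),
                      stringsAsFactors = FALSE)
  calls$n_subtypes <- calls$cbaf + calls$pbaf + calls$gbaf
  calls$evaluated <- if (require_core) calls$core_positive
                     else rep(TRUE, nrow(calls))
  ev <- calls[calls$evaluated, , drop = FALSE]
  summary <- list(
    n_cells_evaluated = nrow(ev),
    subtype_fractions = c(cbaf = mean(ev$cbaf), pbaf = mean(ev$pbaf),
                          gbaf = mean(ev$gbaf)),
    n_subtype_distribution = stats::setNames(
      as.numeric(table(factor(ev$n_subtypes, levels = 0:3)) / nrow(ev)),
      0:3)
  )
  list(calls = calls, summary = summary)
}

#' Co-expression independence test for a gene pair
#'
#' Compares the observed frequency of joint detection of two genes with the
#' frequency expected if they were detected independently (the product of
#' their marginal positive fractions). The dependency ratio is
#' observed/expected; the p-value comes from Fisher's exact test on the 2x2
#' detection table (default) or from a label-permutation null.
#'
#' @param matrix Genes x cells count matrix.
#' @param gene_i,gene_j Gene ids (must be present).
#' @param method `"fisher"` (exact, default) or `"permutation"`.
#' @param n_perm Number of permutations for `method = "permutation"`.
#' @param seed Seed for the permutation null.
#' @param min_count Positivity threshold.
#' @return List: `observed` (joint positive fraction), `expected`
#'   (product of marginals), `ratio` (`NA` when expected is 0), `p_value`,
#'   `table` (the 2x2 detection table), `method`.
#' @export
coexpression_independence <- function(matrix, gene_i, gene_j,
                                      method = c("fisher", "permutation"),
                                      n_perm = 1000L, seed = NULL,
                                      min_count = 1L) {
  method <- match.arg(method)
  for (g in c(gene_i, gene_j)) {
    if (!g %in% rownames(matrix)) {
      abort_ipqms(sprintf("gene '%s' absent from the matrix", g))
    }
  }
  if (ncol(matrix) < 1L) abort_ipqms("matrix has zero cells")
  xi <- binarize_sc(matrix[gene_i, , drop = TRUE], min_count)
  xj <- binarize_sc(matrix[gene_j, , drop = TRUE], min_count)
  n <- length(xi)
  tab <- table(factor(xi, levels = c(TRUE, FALSE)),
               factor(xj, levels = c(TRUE, FALSE)),
               dnn = c(gene_i, gene_j))
  observed <- mean(xi & xj)
  expected <- mean(xi) * mean(xj)
  ratio <- if (expected > 0) observed / expected else NA_real_
  p <- if (method == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    obs_dev <- abs(sum(xi & xj) - expected * n)
    with_seed(seed, {
      dev <- replicate(n_perm, {
        abs(sum(xi & sample(xj)) - expected * n)
      })
      (1 + sum(dev >= obs_dev)) / (1 + n_perm)
    })
  }
  list(observed = observed, expected = expected, ratio = ratio,
       p_value = p, table = tab, method = method)
}

#' Number of detected complex components per cell
#'
#' @param matrix Genes x cells count matrix.
#' @param catalog A `swisnf_catalog`.
#' @param band Optional integer band `c(lo, hi)`: the fraction of cells whose
#'   component count lies in `[lo, hi]` is reported.
#' @param min_count Positivity threshold.
#' @return List: `counts` (named per-cell integer), `histogram` (table over
#'   observed counts), `band_fraction` (`NA` if no band requested),
#'   `genes_used`.
#' @export
components_per_cell <- function(matrix, catalog, band = NULL,
                                min_count = 1L) {
  mapped <- match_catalog_symbols(catalog, rownames(matrix))
  rows <- which(!is.na(mapped))
  pos <- binarize_sc(matrix[rows, , drop = FALSE], min_count)
  counts <- colSums(pos)
  band_fraction <- NA_real_
  if (!is.null(band)) {
    band_fraction <- mean(counts >= band[1] & counts <= band[2])
  }
  list(counts = counts,
       histogram = table(counts),
       band_fraction = band_fraction,
       genes_used = rownames(matrix)[rows])
}
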