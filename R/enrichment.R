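#' Significance thresholds for differential IP enrichment
#'
#' Defaults mirror a sensitive AP-MS workflow: proteins below 1.5-fold over
#' the IgG control are treated as background and removed; between two IPs a
#' 20% enrichment (fold change > 1.2) on either side with Welch p < 0.05 is
#' called significant, with BH false-discovery rates reported alongside.
#'
#' @param igg_fc_min IgG filter: remove proteins with fold change strictly
#'   below this ratio (boundary values are kept).
#' @param comparison_fc_min Comparison significance requires fold change
#'   strictly above this ratio on the enriched side.
#' @param alpha Raw p-value cutoff used for the significance call.
#' @param fdr_report_level FDR level reported in summaries (not used for the
#'   primary call).
#' @return List of class `ip_thresholds`.
#' @export
ip_thresholds <- function(igg_fc_min = 1.5, comparison_fc_min = 1.2,
                          alpha = 0.05, fdr_report_level = 0.05) {
  stopifnot_scalar_number(igg_fc_min, "igg_fc_min", positive = TRUE)
  stopifnot_scalar_number(comparison_fc_min, "comparison_fc_min",
                          positive = TRUE)
  stopifnot_scalar_number(alpha, "alpha", positive = TRUE)
  if (alpha >= 1) abort_ipqms("`alpha` must be in (0, 1)")
  structure(list(igg_fc_min = igg_fc_min,
                 comparison_fc_min = comparison_fc_min,
                 alpha = alpha,
                 fdr_report_level = fdr_report_level),
            class = "ip_thresholds")
}

#' IgG background filter
#'
#' For one bait IP, computes each protein's fold change versus the matched
#' IgG control (mean over IP replicates / mean over IgG replicates in the same
#' cell context) and retains proteins at or above `igg_fc_min`. Proteins
#' strictly below the threshold are background binders and are removed from
#' further analysis.
#'
#' @param matrix Imputed abundance matrix.
#' @param design Matching `ip_design`.
#' @param ip Length-2 character `c(target, context)`.
#' @param igg_fc_min Retention threshold (default 1.5; `fc == 1.5` is kept).
#' @return List with `retained` (character vector) and `fold_change`
#'   (named numeric over all proteins).
#' @export
igg_filter <- function(matrix, design, ip, igg_fc_min = 1.5) {
  target <- ip[1]; context <- ip[2]
  ip_cols <- design_samples(design, target, context)
  igg_cols <- design_samples(design, target, context, control = TRUE)
  if (!length(igg_cols)) {
    abort_ipqms(sprintf("no IgG control group in context %s", context))
  }
  if (!length(ip_cols)) {
    abort_ipqms(sprintf("no samples for IP %s:%s", target, context))
  }
  fc <- rowMeans(matrix[, ip_cols, drop = FALSE]) /
    rowMeans(matrix[, igg_cols, drop = FALSE])
  list(retained = rownames(matrix)[!is.na(fc) & fc >= igg_fc_min],
       fold_change = fc)
}

#' Intersect the retained sets of two IPs for a comparison
#'
#' Only proteins passing the IgG filter in both IPs enter a comparison.
#'
#' @param retained_a,retained_b Character vectors from [igg_filter()].
#' @return Character vector (order of `retained_a`).
#' @export
intersect_for_comparison <- function(retained_a, retained_b) {
  out <- intersect(retained_a, retained_b)
  if (!length(out)) {
    abort_ipqms("empty intersection of retained protein sets")
  }
  out
}

#' Bait normalization
#'
#' Divides every protein's abundance in each IP replicate by the bait
#' protein's abundance in that same replicate, so that downstream comparisons
#' measure composition per pulled-down complex rather than pull-down yield.
#' The bait row becomes exactly 1 in every normalized column. Control (IgG)
#' columns are left untouched: they have already served their purpose in the
#' background filter.
#'
#' @param matrix Imputed abundance matrix.
#' @param design Matching `ip_design`.
#' @param bait Gene symbol of the normalization bait (e.g. BRG1); matched
#'   case-insensitively, with alias expansion when `catalog` is given.
#' @param catalog Optional `swisnf_catalog` for alias-aware bait matching.
#' @return Matrix with non-control columns normalized, provenance
#'   `"normalized"`.
#' @export
bait_normalize <- function(matrix, design, bait, catalog = NULL) {
  bait_row <- find_protein_row(matrix, bait, catalog)
  if (is.na(bait_row)) {
    abort_ipqms(sprintf("bait '%s' not found in the matrix", bait))
  }
  norm_cols <- design$sample_id[!design$is_control]
  norm_cols <- intersect(norm_cols, colnames(matrix))
  bv <- matrix[bait_row, norm_cols]
  bad <- norm_cols[is.na(bv) | bv <= 0]
  if (length(bad)) {
    abort_ipqms(paste0("bait abundance missing or non-positive in replicate(s): ",
                       paste(bad, collapse = ", ")))
  }
  out <- matrix
  out[, norm_cols] <- sweep(matrix[, norm_cols, drop = FALSE], 2, bv, `/`)
  attr(out, "provenance") <- "normalized"
  out
}

# row index of a protein, by case-insensitive symbol or catalog alias
find_protein_row <- function(matrix, gene, catalog = NULL) {
  rn <- toupper(rownames(matrix))
  i <- match(toupper(gene), rn)
  if (!is.na(i) || is.null(catalog)) return(i)
  primary <- match_catalog_symbols(catalog, gene)
  if (is.na(primary)) return(NA_integer_)
  mapped <- match_catalog_symbols(catalog, rownames(matrix))
  idx <- which(!is.na(mapped) & mapped == primary)
  if (length(idx) == 1L) idx else NA_integer_
}

# Vectorized two-sided Welch t-test on the rows of two matrices.
# Returns p-values, t statistics, Welch-Satterthwaite dfs and a degeneracy
# flag (both groups constant). Kept separate from stats::t.test, which serves
# as the independent oracle in the tests.
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) abort_ipqms("need >= 2 replicates per side")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se2 == 0
  # zero variance on both sides: equal means -> no evidence, p = 1;
  # different means -> t is infinite, p -> 0. Both are flagged.
  p[degenerate & ma == mb] <- 1
  p[degenerate & ma != mb] <- 0
  list(p = p, t = tt, df = df, mean_a = ma, mean_b = mb,
       degenerate = degenerate)
}

#' Differential enrichment between two IPs
#'
#' For each protein, fold change is the ratio of bait-normalized group means
#' (side A over side B), the p-value comes from a two-sided Welch t-test on
#' the normalized replicate values, and BH-adjusted FDRs are computed across
#' all proteins of the comparison. A protein is significant on side A when
#' `fold_change > comparison_fc_min` and `p < alpha`; on side B when the
#' reciprocal fold change exceeds the same threshold.
#'
#' @param norm_a,norm_b Numeric matrices (proteins x replicates) of
#'   bait-normalized abundances, with identical row names.
#' @param thresholds An [ip_thresholds()] object.
#' @param log_scale Run the t-test on log2-transformed values (fold change is
#'   still reported as the linear ratio of linear-scale means). Off by
#'   default, matching a linear-scale analysis workflow.
#' @param label Comparison label stored on the result.
#' @return Data frame of class `enrichment_table`: `protein`, `mean_a`,
#'   `mean_b`, `fold_change`, `p_value`, `fdr`, `significant_in`
#'   (factor a/b/none), `degenerate`.
#' @export
differential_enrichment <- function(norm_a, norm_b,
                                    thresholds = ip_thresholds(),
                                    log_scale = FALSE,
                                    label = NULL) {
  if (is.null(rownames(norm_a)) || is.null(rownames(norm_b)) ||
      !identical(rownames(norm_a), rownames(norm_b))) {
    abort_ipqms("norm_a and norm_b must share identical row names")
  }
  w <- if (log_scale) welch_rows(log2(norm_a), log2(norm_b))
       else welch_rows(norm_a, norm_b)
  mean_a <- rowMeans(norm_a); mean_b <- rowMeans(norm_b)
  fc <- ifelse(mean_b > 0, mean_a / mean_b, NA_real_)
  fdr <- stats::p.adjust(w$p, method = "BH")
  sig <- rep("none", nrow(norm_a))
  ok <- !is.na(fc) & w$p < thresholds$alpha
  sig[ok & fc > thresholds$comparison_fc_min] <- "a"
  sig[ok & (1 / fc) > thresholds$comparison_fc_min] <- "b"
  out <- data.frame(protein = rownames(norm_a),
                    mean_a = mean_a, mean_b = mean_b,
                    fold_change = fc,
                    p_value = w$p, fdr = fdr,
                    significant_in = factor(sig, levels = c("a", "b", "none")),
                    degenerate = w$degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  attr(out, "label") <- label
  attr(out, "log_scale") <- log_scale
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Count significantly enriched proteins per side
#'
#' The normalization bait is excluded (its fold change is 1 by construction).
#'
#' @param table An `enrichment_table`.
#' @param bait Optional bait symbol to exclude from the counts.
#' @return Named integer vector `c(a = ..., b = ...)`.
#' @export
significant_counts <- function(table, bait = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(bait)) keep <- toupper(table$protein) != toupper(bait)
  c(a = sum(table$significant_in[keep] == "a"),
    b = sum(table$significant_in[keep] == "b"))
}

#' Write an enrichment table to TSV
#' @param table An `enrichment_table`.
#' @param path Output path.
#' @export
write_enrichment <- function(table, path) {
  write_tsv(as.data.frame(table), path)
  invisible(path)
}
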