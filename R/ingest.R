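#' IP sample design
#'
#' Describes each quantified sample of an IP-QMS experiment: which protein was
#' pulled down (`ip_target`, or `"IgG"` for the non-specific control), the cell
#' context (e.g. MLS, EWS), and the replicate index. Every non-control IP must
#' have at least two replicates and a matching IgG control group in the same
#' context.
#'
#' @param sample_id Character, unique sample identifiers (matrix column names).
#' @param ip_target Character, bait gene symbol or `"IgG"`.
#' @param cell_context Character, cell context label.
#' @param replicate Positive integer replicate index.
#' @param is_control Logical; defaults to `ip_target == "IgG"`.
#' @return An `ip_design` data frame.
#' @export
ip_design <- function(sample_id, ip_target, cell_context, replicate,
                      is_control = ip_target == "IgG") {
  df <- data.frame(sample_id = as.character(sample_id),
                   ip_target = as.character(ip_target),
                   cell_context = as.character(cell_context),
                   replicate = as.integer(replicate),
                   is_control = as.logical(is_control),
                   stringsAsFactors = FALSE)
  validate_design(df)
  class(df) <- c("ip_design", "data.frame")
  df
}

validate_design <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    abort_ipqms("duplicate sample_id in design")
  }
  key <- paste(df$ip_target, df$cell_context, df$replicate)
  if (anyDuplicated(key)) {
    abort_ipqms("(ip_target, cell_context, replicate) must be unique")
  }
  if (any(df$replicate < 1L)) abort_ipqms("replicate indices must be >= 1")
  baits <- unique(df[!df$is_control, c("ip_target", "cell_context")])
  for (i in seq_len(nrow(baits))) {
    sel <- !df$is_control & df$ip_target == baits$ip_target[i] &
      df$cell_context == baits$cell_context[i]
    if (sum(sel) < 2L) {
      abort_ipqms(sprintf("IP %s in %s has fewer than 2 replicates",
                          baits$ip_target[i], baits$cell_context[i]))
    }
    if (!any(df$is_control & df$cell_context == baits$cell_context[i])) {
      abort_ipqms(sprintf("no IgG control group in context %s",
                          baits$cell_context[i]))
    }
  }
  invisible(df)
}

#' Read a design table from TSV/CSV
#' @param path File with columns sample_id, ip_target, cell_context,
#'   replicate, is_control (optional).
#' @return An `ip_design` data frame.
#' @export
read_design <- function(path) {
  df <- read_table_auto(path)
  need <- c("sample_id", "ip_target", "cell_context", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_ipqms(paste0("design is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  ic <- if ("is_control" %in% names(df)) as.logical(df$is_control)
        else df$ip_target == "IgG"
  ip_design(df$sample_id, df$ip_target, df$cell_context, df$replicate, ic)
}

design_samples <- function(design, target, context, control = FALSE) {
  if (control) {
    design$sample_id[design$is_control & design$cell_context == context]
  } else {
    design$sample_id[!design$is_control & design$ip_target == target &
                       design$cell_context == context]
  }
}

#' Read an abundance matrix and validate it against a design
#'
#' The table must have one protein-identifier column (first column, or a
#' column named `protein`) and one numeric column per sample. The column set
#' must equal the design's sample set; mismatches are reported by name.
#'
#' @param table_path TSV/CSV abundance table.
#' @param design_path Design table (see [read_design()]), or an `ip_design`
#'   object.
#' @return Numeric matrix (proteins x samples) with `provenance` attribute
#'   `"raw"`; missing values allowed.
#' @export
read_abundance <- function(table_path, design_path) {
  design <- if (inherits(design_path, "ip_design")) design_path
            else read_design(design_path)
  df <- read_table_auto(table_path)
  idcol <- if ("protein" %in% names(df)) "protein" else names(df)[1]
  prot <- as.character(df[[idcol]])
  vals <- df[names(df) != idcol]
  extra <- setdiff(names(vals), design$sample_id)
  absent <- setdiff(design$sample_id, names(vals))
  if (length(extra) || length(absent)) {
    abort_ipqms(paste0(
      "abundance/design sample mismatch",
      if (length(extra)) paste0("; in table but not design: ",
                                paste(extra, collapse = ", ")) else "",
      if (length(absent)) paste0("; in design but not table: ",
                                 paste(absent, collapse = ", ")) else ""))
  }
  m <- as.matrix(vals[design$sample_id])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))) &
                   !is.na(m), arr.ind = TRUE)
    loc <- if (nrow(bad)) paste0(" (e.g. row ", prot[bad[1, 1]],
                                 ", column ", colnames(m)[bad[1, 2]], ")")
           else ""
    abort_ipqms(paste0("non-numeric abundance values", loc))
  }
  if (any(m < 0, na.rm = TRUE)) abort_ipqms("negative abundances in table")
  if (anyDuplicated(prot)) abort_ipqms("duplicate protein ids in table")
  rownames(m) <- prot
  attr(m, "provenance") <- "raw"
  m
}

#' Write an abundance matrix to TSV
#' @param matrix Proteins x samples numeric matrix.
#' @param path Output path.
#' @export
write_abundance <- function(matrix, path) {
  df <- data.frame(protein = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Aggregate unique peptides to protein abundances
#'
#' Shared peptides (matching more than one protein) are excluded; a protein's
#' abundance per sample is the sum of its unique-peptide abundances. Proteins
#' with no unique peptide are dropped and reported, not an error -- this is
#' what happens to e.g. beta-actin, whose peptides are all shared with other
#' actins.
#'
#' @param peptide_table Data frame with columns `protein`, `unique`
#'   (logical/0-1), and one numeric column per sample.
#' @return List with `matrix` (proteins x samples, provenance `"raw"`) and
#'   `dropped` (character vector of proteins with zero unique peptides).
#' @export
aggregate_unique_peptides <- function(peptide_table) {
  need <- c("protein", "unique")
  miss <- setdiff(need, names(peptide_table))
  if (length(miss)) {
    abort_ipqms(paste0("peptide table missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  samples <- setdiff(names(peptide_table), c("protein", "unique", "peptide"))
  uniq <- as.logical(peptide_table$unique)
  all_prot <- unique(peptide_table$protein)
  kept <- peptide_table[uniq, , drop = FALSE]
  if (nrow(kept)) {
    m <- rowsum(as.matrix(kept[samples]), group = kept$protein)
  } else {
    m <- matrix(numeric(), nrow = 0, ncol = length(samples),
                dimnames = list(NULL, samples))
  }
  dropped <- setdiff(all_prot, rownames(m))
  attr(m, "provenance") <- "raw"
  list(matrix = m, dropped = sort(dropped))
}

#' Quantification filter
#'
#' Removes (a) proteins quantified (non-missing) in fewer than
#' `min_quantified_samples` samples and (b, optionally) proteins detected
#' exclusively in control (IgG) samples. The two drop counts are reported
#' separately.
#'
#' @param matrix Raw abundance matrix (missing values allowed).
#' @param design Matching `ip_design`.
#' @param min_quantified_samples Minimum number of non-missing samples.
#' @param drop_control_only Drop proteins detected only in IgG controls.
#' @return List with `matrix` (filtered) and `report` (list with
#'   `n_input`, `n_below_cutoff`, `n_control_only`, `n_retained`, and the
#'   dropped protein ids per reason).
#' @export
apply_quant_filter <- function(matrix, design, min_quantified_samples = 1L,
                               drop_control_only = TRUE) {
  if (min_quantified_samples > ncol(matrix)) {
    abort_ipqms("min_quantified_samples exceeds the number of samples")
  }
  n_obs <- rowSums(!is.na(matrix))
  below <- n_obs < min_quantified_samples
  ctrl_cols <- colnames(matrix) %in% design$sample_id[design$is_control]
  detected_noncontrol <- rowSums(!is.na(matrix[, !ctrl_cols, drop = FALSE])) > 0
  control_only <- !detected_noncontrol & n_obs > 0
  drop <- below | (drop_control_only & control_only)
  out <- matrix[!drop, , drop = FALSE]
  attr(out, "provenance") <- attr(matrix, "provenance") %||% "raw"
  list(
    matrix = out,
    report = list(
      n_input = nrow(matrix),
      n_below_cutoff = sum(below),
      n_control_only = sum(drop_control_only & control_only & !below),
      n_retained = nrow(out),
      below_cutoff = rownames(matrix)[below],
      control_only = rownames(matrix)[drop_control_only & control_only & !below]
    )
  )
}

#' Impute missing values with the lowest detected value
#'
#' Every missing cell is replaced by the global minimum observed abundance of
#' the matrix (the conservative reading of a single detection floor across the
#' multiplexed experiment); `per_sample = TRUE` instead uses each sample's own
#' minimum. Observed values are never modified.
#'
#' @param matrix Abundance matrix with missing values allowed.
#' @param per_sample Use per-sample minima instead of the global minimum.
#' @return Matrix without missing values, provenance `"imputed"`.
#' @export
impute_lowest_detected <- function(matrix, per_sample = FALSE) {
  if (all(is.na(matrix))) abort_ipqms("cannot impute an all-missing matrix")
  out <- matrix
  if (per_sample) {
    for (j in seq_len(ncol(out))) {
      col <- out[, j]
      if (all(is.na(col))) col[] <- min(out, na.rm = TRUE)
      else col[is.na(col)] <- min(col, na.rm = TRUE)
      out[, j] <- col
    }
  } else {
    out[is.na(out)] <- min(matrix, na.rm = TRUE)
  }
  attr(out, "provenance") <- "imputed"
  out
}

#' Bait-IP quality control gate
#'
#' Scores each replicate of a bait IP by the mean enrichment of complex core
#' components over the matched IgG control: for replicate r,
#' `score(r) = mean over core proteins of abundance(r) / mean IgG abundance`.
#' The IP fails the gate when more than `max_failing_replicates` replicates
#' score below `core_enrichment_min`. With the defaults (1.5, 1), two
#' replicates below 1.5 fail the IP -- the rule that excluded a low-yield
#' FLI1 pulldown from comparative analysis.
#'
#' @param matrix Imputed abundance matrix.
#' @param design Matching `ip_design`.
#' @param catalog `swisnf_catalog` defining core components (matched through
#'   aliases).
#' @param ip Length-2 character: `c(target, context)` of the bait IP to score.
#' @param core_enrichment_min Per-replicate score threshold (ratio).
#' @param max_failing_replicates Maximum tolerated replicates below threshold.
#' @return List of class `qc_report`: `ip`, `replicate_scores` (named by
#'   sample), `threshold`, `max_failing_replicates`, `n_failing`, `pass`,
#'   `core_proteins` used.
#' @export
qc_bait_ip <- function(matrix, design, catalog, ip,
                       core_enrichment_min = 1.5,
                       max_failing_replicates = 1L) {
  target <- ip[1]; context <- ip[2]
  ip_cols <- design_samples(design, target, context)
  igg_cols <- design_samples(design, target, context, control = TRUE)
  if (!length(ip_cols)) abort_ipqms(sprintf("no samples for IP %s:%s",
                                            target, context))
  if (!length(igg_cols)) abort_ipqms(sprintf("no IgG control in context %s",
                                             context))
  core <- core_members(catalog)
  mapped <- match_catalog_symbols(catalog, rownames(matrix))
  core_rows <- which(mapped %in% core)
  if (!length(core_rows)) {
    abort_ipqms("no core complex components present in the matrix")
  }
  igg_mean <- rowMeans(matrix[core_rows, igg_cols, drop = FALSE])
  ratios <- matrix[core_rows, ip_cols, drop = FALSE] / igg_mean
  scores <- colMeans(ratios)
  n_fail <- sum(scores < core_enrichment_min)
  structure(list(
    ip = ip_key(target, context),
    replicate_scores = scores,
    threshold = core_enrichment_min,
    max_failing_replicates = as.integer(max_failing_replicates),
    n_failing = n_fail,
    pass = n_fail <= max_failing_replicates,
    core_proteins = rownames(matrix)[core_rows]
  ), class = "qc_report")
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat(sprintf("QC gate for %s: %s (%d/%d replicates below %.2f)\n",
              x$ip, if (x$pass) "PASS" else "FAIL",
              x$n_failing, length(x$replicate_scores), x$threshold))
  print(round(x$replicate_scores, 3))
  invisible(x)
}
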