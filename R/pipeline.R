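#' Pipeline run configuration
#'
#' Bundles everything needed for an end-to-end run: inputs (paths or
#' in-memory objects), the normalization bait, the comparisons, thresholds,
#' QC gate settings and a seed. Validated at construction time.
#'
#' @param abundance Abundance matrix (proteins x samples) or path to a
#'   TSV/CSV table.
#' @param design `ip_design` or path to a design table.
#' @param catalog `swisnf_catalog`, a catalog TSV path, or `NULL` for the
#'   shipped default.
#' @param bait Normalization bait gene symbol (e.g. `"BRG1"`).
#' @param comparisons List of `list(a = c(target, context),
#'   b = c(target, context), label = ...)`.
#' @param thresholds An [ip_thresholds()].
#' @param qc List with `core_enrichment_min` and `max_failing_replicates`.
#' @param min_quantified_samples Quantification cutoff (see
#'   [apply_quant_filter()]).
#' @param annotation An [annotation_lists()] or `NULL`.
#' @param log_scale Run the Welch test on log2 values.
#' @param seed Integer; the single source of randomness for the run.
#' @return List of class `run_config`.
#' @export
run_config <- function(abundance, design, catalog = NULL, bait = "BRG1",
                       comparisons = list(),
                       thresholds = ip_thresholds(),
                       qc = list(core_enrichment_min = 1.5,
                                 max_failing_replicates = 1L),
                       min_quantified_samples = 1L,
                       annotation = NULL,
                       log_scale = FALSE,
                       seed = 1L) {
  if (is.character(abundance) && !file.exists(abundance)) {
    abort_ipqms(sprintf("abundance file not found: %s", abundance))
  }
  if (is.character(design) && !file.exists(design)) {
    abort_ipqms(sprintf("design file not found: %s", design))
  }
  if (is.character(catalog) && !file.exists(catalog)) {
    abort_ipqms(sprintf("catalog file not found: %s", catalog))
  }
  if (!length(comparisons)) abort_ipqms("at least one comparison is required")
  for (cmp in comparisons) {
    if (!all(c("a", "b") %in% names(cmp))) {
      abort_ipqms("each comparison needs sides `a` and `b`")
    }
    if (identical(cmp$a, cmp$b)) abort_ipqms("comparison sides must differ")
  }
  structure(list(abundance = abundance, design = design, catalog = catalog,
                 bait = bait, comparisons = comparisons,
                 thresholds = thresholds, qc = qc,
                 min_quantified_samples = min_quantified_samples,
                 annotation = annotation, log_scale = log_scale,
                 seed = seed),
            class = "run_config")
}

comparison_label <- function(cmp) {
  cmp$label %||% paste0(ip_key(cmp$a[1], cmp$a[2]), "_vs_",
                        ip_key(cmp$b[1], cmp$b[2]))
}

#' Run the full IP-QMS analysis pipeline
#'
#' Stages, in fixed order: ingest -> quantification filter -> lowest-detected
#' imputation -> per-bait-IP QC gate -> per-IP IgG filter -> per comparison:
#' retained-set intersection, bait normalization, Welch/BH differential
#' enrichment, significance counts -> optional annotation summaries. A bait IP
#' failing the QC gate is excluded: comparisons touching it are skipped and
#' logged in the manifest (the treatment a low-yield pulldown receives).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, stage TSVs, a
#'   summary JSON and a manifest JSON are written.
#' @return List with `comparisons` (named list of `enrichment_table`s),
#'   `significant_counts`, `qc` (named list of `qc_report`s),
#'   `skipped_comparisons`, `igg_filters`, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  design <- if (inherits(config$design, "ip_design")) config$design
            else read_design(config$design)
  matrix <- if (is.character(config$abundance)) {
    read_abundance(config$abundance, design)
  } else config$abundance
  catalog <- if (is.null(config$catalog)) load_catalog()
             else if (is.character(config$catalog)) load_catalog(config$catalog)
             else config$catalog

  stages <- list()
  note_stage <- function(name, n_in, n_out, detail = NULL) {
    stages[[name]] <<- list(stage = name, n_input = n_in, n_retained = n_out,
                            n_dropped = n_in - n_out, detail = detail)
  }

  n0 <- nrow(matrix)
  qf <- apply_quant_filter(matrix, design,
                           min_quantified_samples =
                             config$min_quantified_samples)
  note_stage("quant_filter", n0, nrow(qf$matrix),
             list(below_cutoff = qf$report$n_below_cutoff,
                  control_only = qf$report$n_control_only))
  imp <- impute_lowest_detected(qf$matrix)
  note_stage("impute", nrow(qf$matrix), nrow(imp))

  bait_ips <- unique(design[!design$is_control,
                            c("ip_target", "cell_context")])
  qc_reports <- list()
  failed_ips <- character()
  for (i in seq_len(nrow(bait_ips))) {
    ip <- c(bait_ips$ip_target[i], bait_ips$cell_context[i])
    rep_ <- qc_bait_ip(imp, design, catalog, ip,
                       core_enrichment_min = config$qc$core_enrichment_min,
                       max_failing_replicates =
                         config$qc$max_failing_replicates)
    qc_reports[[ip_key(ip[1], ip[2])]] <- rep_
    if (!rep_$pass) failed_ips <- c(failed_ips, ip_key(ip[1], ip[2]))
  }

  filters <- list()
  for (i in seq_len(nrow(bait_ips))) {
    key <- ip_key(bait_ips$ip_target[i], bait_ips$cell_context[i])
    if (key %in% failed_ips) next
    filters[[key]] <- igg_filter(
      imp, design, c(bait_ips$ip_target[i], bait_ips$cell_context[i]),
      igg_fc_min = config$thresholds$igg_fc_min)
    note_stage(paste0("igg_filter.", key), nrow(imp),
               length(filters[[key]]$retained))
  }

  norm <- bait_normalize(imp, design, config$bait, catalog)

  results <- list()
  counts <- list()
  skipped <- list()
  for (cmp in config$comparisons) {
    lab <- comparison_label(cmp)
    ka <- ip_key(cmp$a[1], cmp$a[2]); kb <- ip_key(cmp$b[1], cmp$b[2])
    if (ka %in% failed_ips || kb %in% failed_ips) {
      skipped[[lab]] <- paste0("QC gate failure: ",
                               paste(intersect(c(ka, kb), failed_ips),
                                     collapse = ", "))
      next
    }
    shared <- intersect_for_comparison(filters[[ka]]$retained,
                                       filters[[kb]]$retained)
    note_stage(paste0("intersect.", lab),
               max(length(filters[[ka]]$retained),
                   length(filters[[kb]]$retained)),
               length(shared))
    cols_a <- design_samples(design, cmp$a[1], cmp$a[2])
    cols_b <- design_samples(design, cmp$b[1], cmp$b[2])
    tab <- differential_enrichment(norm[shared, cols_a, drop = FALSE],
                                   norm[shared, cols_b, drop = FALSE],
                                   thresholds = config$thresholds,
                                   log_scale = config$log_scale,
                                   label = lab)
    if (!is.null(config$annotation) || !is.null(catalog)) {
      tab <- annotate_enrichment(tab, catalog,
                                 config$annotation %||% annotation_lists())
    }
    results[[lab]] <- tab
    counts[[lab]] <- significant_counts(tab, bait = config$bait)
    note_stage(paste0("compare.", lab), length(shared), nrow(tab))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ipqms")),
    config_hash = config_hash(config),
    bait = config$bait,
    thresholds = unclass(config$thresholds),
    seed = config$seed,
    qc = lapply(qc_reports, function(r)
      list(pass = r$pass, n_failing = r$n_failing,
           scores = unname(round(r$replicate_scores, 6)))),
    failed_ips = failed_ips,
    skipped_comparisons = skipped,
    stages = unname(stages),
    significant_counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  out <- list(comparisons = results, significant_counts = counts,
              qc = qc_reports, skipped_comparisons = skipped,
              igg_filters = filters, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# stable hash of the configuration (file-backed inputs hashed by path string,
# in-memory objects by their serialized JSON representation)
config_hash <- function(config) {
  repr <- jsonlite::toJSON(rapply(unclass(config), function(x) {
    if (is.matrix(x)) list(dim = dim(x), sum = sum(x, na.rm = TRUE)) else x
  }, how = "replace"), auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(repr), f)
  unname(tools::md5sum(f))
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (lab in names(result$comparisons)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", lab)
    write_enrichment(result$comparisons[[lab]],
                     file.path(out_dir, paste0("enrichment_", safe, ".tsv")))
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$significant_counts,
                       file.path(out_dir, "significant_counts.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(out_dir)
}
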