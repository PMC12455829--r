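#' Annotation gene lists
#'
#' Plain gene-symbol sets used to stratify enrichment results: previously
#' reported bait (BRG1) interaction partners, known human transcription
#' factors, and histone variants. Lists are case-normalized; provenance
#' strings are kept for reporting.
#'
#' @param known_bait_interactors,transcription_factors,histone_variants
#'   Character vectors of gene symbols.
#' @param provenance Named character vector of provenance strings per list.
#' @return List of class `annotation_lists`.
#' @export
annotation_lists <- function(known_bait_interactors = character(),
                             transcription_factors = character(),
                             histone_variants = character(),
                             provenance = c(
                               known_bait_interactors = "user-supplied",
                               transcription_factors = "user-supplied",
                               histone_variants = "user-supplied")) {
  structure(list(
    known_bait_interactors = unique(toupper(known_bait_interactors)),
    transcription_factors = unique(toupper(transcription_factors)),
    histone_variants = unique(toupper(histone_variants)),
    provenance = provenance
  ), class = "annotation_lists")
}

#' Read a one-symbol-per-line gene list
#'
#' Lines starting with `#` are provenance headers and are returned as an
#' attribute.
#'
#' @param path Text file, one gene symbol per line.
#' @return Character vector with attribute `provenance`.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  prov <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
  genes <- trimws(lines[!startsWith(lines, "#")])
  genes <- genes[genes != ""]
  structure(genes, provenance = paste(prov, collapse = " "))
}

#' Annotate an enrichment table with catalog classes and list memberships
#'
#' Adds, per protein: the catalog `subunit_class` and `paralog_group` (via
#' alias-aware matching, `NA` for non-complex proteins) and logical membership
#' flags for each annotation list. Annotation is purely additive: no statistic
#' column is modified.
#'
#' @param table An `enrichment_table`.
#' @param catalog A `swisnf_catalog`.
#' @param lists An [annotation_lists()] object.
#' @return The annotated table; attribute `annotation_counts` reports the
#'   number of detected members per list and per subunit class.
#' @export
annotate_enrichment <- function(table, catalog, lists = annotation_lists()) {
  mapped <- match_catalog_symbols(catalog, table$protein)
  idx <- match(mapped, catalog$gene_symbol)
  out <- table
  out$catalog_symbol <- mapped
  out$subunit_class <- catalog$subunit_class[idx]
  pg <- catalog$paralog_group[idx]
  pg[!is.na(pg) & pg == ""] <- NA_character_
  out$paralog_group <- pg
  up <- toupper(table$protein)
  out$in_known_interactors <- up %in% lists$known_bait_interactors
  out$in_tf_list <- up %in% lists$transcription_factors
  out$in_histones <- up %in% lists$histone_variants
  attr(out, "annotation_counts") <- list(
    known_interactors = sum(out$in_known_interactors),
    transcription_factors = sum(out$in_tf_list),
    histones = sum(out$in_histones),
    by_class = table(out$subunit_class[!is.na(out$subunit_class)])
  )
  class(out) <- class(table)
  out
}

#' Mean fold change over subunit classes
#'
#' Arithmetic mean of the linear fold changes of detected members of the given
#' classes (e.g. PBAF plus GBAF subtype-specific components). A geometric-mean
#' option is available for reanalysis.
#'
#' @param annotated An annotated `enrichment_table` (see
#'   [annotate_enrichment()]).
#' @param classes Character vector of subunit classes to average over.
#' @param geometric Use the geometric mean instead of the arithmetic mean.
#' @return Single numeric; attributes `n` and `members` identify the proteins
#'   averaged.
#' @export
subtype_enrichment_mean <- function(annotated,
                                    classes = c("pbaf_specific",
                                                "gbaf_specific"),
                                    geometric = FALSE) {
  sel <- !is.na(annotated$subunit_class) &
    annotated$subunit_class %in% classes & !is.na(annotated$fold_change)
  if (!any(sel)) abort_ipqms("no detected members of the requested classes")
  fc <- annotated$fold_change[sel]
  m <- if (geometric) exp(mean(log(fc))) else mean(fc)
  structure(m, n = sum(sel), members = annotated$protein[sel])
}

#' Per-complex stoichiometry of a fusion bait
#'
#' After bait normalization, a protein's mean abundance is its amount per
#' pulled-down complex. The ratio of the fusion protein's normalized abundance
#' in its own IP (side A) versus the reference bait IP (side B) measures how
#' many times more fusion protein each complex carries in the fusion pulldown.
#'
#' @param table An `enrichment_table` for the comparison (fusion IP as side A,
#'   reference bait IP as side B).
#' @param fusion_protein Gene symbol of the fusion bait (e.g. DDIT3).
#' @return Single numeric ratio.
#' @export
bait_stoichiometry_ratio <- function(table, fusion_protein) {
  i <- match(toupper(fusion_protein), toupper(table$protein))
  if (is.na(i)) {
    abort_ipqms(sprintf("fusion protein '%s' absent from the table",
                        fusion_protein))
  }
  table$mean_a[i] / table$mean_b[i]
}

#' Mean interactome enrichment
#'
#' Average fold change over all proteins except an excluded set (typically the
#' complex core components and the bait), quantifying how much more of the
#' co-immunoprecipitated interactome one IP carries per complex.
#'
#' @param table An `enrichment_table`.
#' @param exclude Character vector of proteins to exclude.
#' @param geometric Use the geometric mean.
#' @return Single numeric; attribute `n` is the number of proteins averaged.
#' @export
interactome_mean_enrichment <- function(table, exclude = character(),
                                        geometric = FALSE) {
  sel <- !(toupper(table$protein) %in% toupper(exclude)) &
    !is.na(table$fold_change)
  if (!any(sel)) abort_ipqms("no proteins left after exclusion")
  fc <- table$fold_change[sel]
  m <- if (geometric) exp(mean(log(fc))) else mean(fc)
  structure(m, n = sum(sel))
}

#' Overlap between regulated genes and IP-enriched proteins
#'
#' For each condition, counts how many upregulated genes are also enriched in
#' the matching IP, and among the regulated genes that interact with the
#' complex in either condition, the fraction enriched in the matching one.
#'
#' @param upregulated Named list of character vectors: upregulated genes per
#'   condition.
#' @param enriched Named list of character vectors: IP-enriched proteins per
#'   condition (same names).
#' @return Data frame, one row per condition: `condition`, `n_up`,
#'   `n_overlap`, `fraction_up_enriched`, `n_interacting`,
#'   `fraction_matching`.
#' @export
expression_interactome_overlap <- function(upregulated, enriched) {
  conds <- names(upregulated)
  if (is.null(conds) || !setequal(conds, names(enriched))) {
    abort_ipqms("upregulated and enriched must share condition names")
  }
  all_enriched <- toupper(unique(unlist(enriched)))
  rows <- lapply(conds, function(cn) {
    up <- toupper(unique(upregulated[[cn]]))
    en <- toupper(unique(enriched[[cn]]))
    ov <- intersect(up, en)
    interacting <- intersect(up, all_enriched)
    data.frame(condition = cn,
               n_up = length(up),
               n_overlap = length(ov),
               fraction_up_enriched =
                 if (length(up)) length(ov) / length(up) else 0,
               n_interacting = length(interacting),
               fraction_matching =
                 if (length(interacting)) length(ov) / length(interacting)
                 else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
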