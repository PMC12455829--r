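#' SWI/SNF subunit catalog
#'
#' The SWI/SNF (BAF) chromatin remodeling complex is built from roughly 10-15
#' subunits drawn from 29 genes. Three main subtypes are distinguished by
#' subtype-specific subunits assembled around a shared core: the canonical
#' cBAF complex, PBAF, and GBAF (ncBAF). The catalog encodes, per gene, the
#' subunit class and (where applicable) the mutually exclusive paralog group
#' (e.g. BAF60A/B/C occupy the same position in alternative complexes).
#'
#' Classes:
#' \describe{
#'   \item{core_all}{core components present in all three subtypes}
#'   \item{core_cbaf_pbaf}{components shared by cBAF and PBAF but absent from
#'     GBAF (BAF47, BAF57)}
#'   \item{cbaf_specific, pbaf_specific, gbaf_specific}{subtype-defining
#'     components}
#'   \item{atpase_module}{the ATPase module added last during assembly,
#'     including the catalytic paralogs BRG1/BRM}
#' }
#'
#' Primary symbols are the BAF-style names used in the complex literature;
#' the `aliases` column carries HGNC symbols (e.g. SMARCA4 for BRG1) so that
#' quantification tables using either convention can be matched via
#' [match_catalog_symbols()].
#'
#' @param path Path to a catalog TSV with columns `gene_symbol`,
#'   `subunit_class`, `paralog_group`, `aliases` (pipe-separated). When `NULL`
#'   (default) the shipped 29-gene SWI/SNF catalog is loaded.
#' @return A `swisnf_catalog` data frame (one row per gene) with attribute
#'   `default` indicating whether the shipped catalog was used.
#' @examples
#' cat <- load_catalog()
#' nrow(cat)                       # 29
#' subtype_members(cat, "gbaf")    # GLTSCR1, GLTSCR1L, BRD9
#' @export
load_catalog <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    path <- system.file("extdata", "swisnf_catalog.tsv", package = "ipqms",
                        mustWork = TRUE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#", na.strings = character(),
                          colClasses = "character", fill = TRUE)
  validate_catalog(df)
  attr(df, "default") <- default
  class(df) <- c("swisnf_catalog", "data.frame")
  df
}

subunit_classes <- c("core_all", "core_cbaf_pbaf", "cbaf_specific",
                     "pbaf_specific", "gbaf_specific", "atpase_module")

validate_catalog <- function(df) {
  need <- c("gene_symbol", "subunit_class", "paralog_group", "aliases")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_ipqms(paste0("catalog is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  dup <- unique(df$gene_symbol[duplicated(df$gene_symbol)])
  if (length(dup)) {
    abort_ipqms(paste0("duplicate gene_symbol in catalog: ",
                       paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unique(df$subunit_class), subunit_classes)
  if (length(bad)) {
    abort_ipqms(paste0("unknown subunit_class value(s): ",
                       paste(bad, collapse = ", ")))
  }
  # paralog group members must share a single class (mutually exclusive
  # variants of the same complex position)
  grp <- df$paralog_group[!is.na(df$paralog_group) & df$paralog_group != ""]
  for (g in unique(grp)) {
    cls <- unique(df$subunit_class[df$paralog_group == g])
    if (length(cls) > 1L) {
      abort_ipqms(sprintf(
        "paralog_group '%s' spans multiple subunit classes: %s",
        g, paste(cls, collapse = ", ")))
    }
  }
  invisible(df)
}

#' Subtype-specific members of a catalog
#'
#' Returns only the subtype-defining genes (core and ATPase-module components
#' are shared and excluded by definition).
#'
#' @param catalog A `swisnf_catalog` (see [load_catalog()]).
#' @param subtype One of `"cbaf"`, `"pbaf"`, `"gbaf"`.
#' @return Character vector of gene symbols, sorted for deterministic
#'   serialization.
#' @export
subtype_members <- function(catalog, subtype = c("cbaf", "pbaf", "gbaf")) {
  subtype <- match.arg(subtype)
  cls <- paste0(subtype, "_specific")
  sort(catalog$gene_symbol[catalog$subunit_class == cls])
}

#' Core components of the complex
#'
#' The core used for bait-IP quality control: components present in all
#' subtypes plus those shared by cBAF and PBAF. The ATPase module is excluded
#' (it contains the bait itself in a BRG1 IP).
#'
#' @inheritParams subtype_members
#' @param classes Which subunit classes count as core.
#' @return Character vector of gene symbols.
#' @export
core_members <- function(catalog, classes = c("core_all", "core_cbaf_pbaf")) {
  sort(catalog$gene_symbol[catalog$subunit_class %in% classes])
}

#' Map external gene symbols onto catalog symbols
#'
#' Case-insensitive matching with alias expansion: a symbol matches a catalog
#' entry if it equals the primary symbol or any of its pipe-separated aliases
#' (quantification tables typically use HGNC/UniProt symbols such as SMARCA4,
#' while the catalog's primary names are BAF-style, e.g. BRG1).
#'
#' @inheritParams subtype_members
#' @param symbols Character vector of gene symbols to match.
#' @return Character vector, same length as `symbols`: the catalog primary
#'   symbol, or `NA` where unmatched.
#' @export
match_catalog_symbols <- function(catalog, symbols) {
  map <- catalog_alias_map(catalog)
  out <- map[toupper(symbols)]
  names(out) <- symbols
  unname(out[seq_along(symbols)])
}

# named vector: UPPERCASE alias -> primary symbol
catalog_alias_map <- function(catalog) {
  keys <- list()
  vals <- list()
  for (i in seq_len(nrow(catalog))) {
    al <- catalog$aliases[i]
    alv <- if (is.na(al) || al == "") character() else
      strsplit(al, "|", fixed = TRUE)[[1]]
    k <- toupper(c(catalog$gene_symbol[i], alv))
    keys[[i]] <- k
    vals[[i]] <- rep(catalog$gene_symbol[i], length(k))
  }
  stats::setNames(unlist(vals), unlist(keys))
}

#' Write a catalog back to TSV
#'
#' Round-trips: reloading the written file reproduces the catalog.
#'
#' @inheritParams subtype_members
#' @param path Output file path.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv(as.data.frame(catalog), path)
  invisible(path)
}
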