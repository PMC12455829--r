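# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
abort_ipqms <- function(msg, class = "ipqms_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so simulators do not perturb
#' the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_ipqms("`seed` must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Read a delimited table, choosing the separator from the file extension.
read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

write_tsv <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
}

# Canonical ip key used in configs and truth tables, e.g. "BRG1:MLS".
ip_key <- function(target, context) paste0(target, ":", context)

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_ipqms(sprintf("`%s` must be a single number", name))
  }
  if (positive && x <= 0) abort_ipqms(sprintf("`%s` must be > 0", name))
  invisible(x)
}
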