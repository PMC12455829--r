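#' Classify one transcription factor from three evidence streams
#'
#' Integrates direction calls from chromatin-accessibility motif enrichment
#' (`motif_call`: `cond_a`, `cond_b`, `shared_open`, `none`), IP enrichment
#' (`ip_call`: `cond_a`, `cond_b`, `none`) and RNA regulation (`rna_call`:
#' same values). The rule, with precedence:
#'
#' 1. `mixed` -- any two streams call opposite directions, or a directional
#'    call co-occurs with a shared-open motif (hard conflict before
#'    agreement).
#' 2. `a_specific` / `b_specific` -- at least two streams call the same
#'    direction and none calls the other.
#' 3. `shared` -- the motif stream reports enrichment in chromatin open in
#'    both conditions (`shared_open`, the only stream with that option) and no
#'    stream makes a directional call.
#' 4. `unassigned` -- fewer than two informative streams otherwise.
#'
#' @param motif_call,ip_call,rna_call Single evidence values (see above).
#' @return List with `label` (one of `a_specific`, `b_specific`, `shared`,
#'   `mixed`, `unassigned`) and `supporting` (character vector of stream
#'   names that back the label).
#' @export
classify_tf <- function(motif_call, ip_call, rna_call) {
  tab <- classify_tf_vec(motif_call, ip_call, rna_call)
  list(label = tab$label, supporting = strsplit(tab$supporting, ",")[[1]])
}

tf_motif_values <- c("cond_a", "cond_b", "shared_open", "none")
tf_dir_values <- c("cond_a", "cond_b", "none")

# vectorized classifier; returns data.frame(label, supporting)
classify_tf_vec <- function(motif_call, ip_call, rna_call) {
  if (!all(motif_call %in% tf_motif_values)) {
    abort_ipqms("invalid motif_call value")
  }
  if (!all(ip_call %in% tf_dir_values) || !all(rna_call %in% tf_dir_values)) {
    abort_ipqms("invalid ip_call/rna_call value")
  }
  streams <- cbind(motif_call, ip_call, rna_call)
  n_a <- rowSums(streams == "cond_a")
  n_b <- rowSums(streams == "cond_b")
  shared_motif <- motif_call == "shared_open"
  n_informative <- rowSums(streams != "none")

  label <- rep("unassigned", length(motif_call))
  label[(n_a > 0 & n_b > 0) | (shared_motif & (n_a + n_b) > 0)] <- "mixed"
  label[label == "unassigned" & n_a >= 2] <- "a_specific"
  label[label == "unassigned" & n_b >= 2] <- "b_specific"
  label[label == "unassigned" & shared_motif & n_a == 0 & n_b == 0] <- "shared"

  supporting <- character(length(label))
  stream_names <- c("motif", "ip", "rna")
  for (i in seq_along(label)) {
    supporting[i] <- switch(label[i],
      a_specific = paste(stream_names[streams[i, ] == "cond_a"],
                         collapse = ","),
      b_specific = paste(stream_names[streams[i, ] == "cond_b"],
                         collapse = ","),
      shared = "motif",
      mixed = paste(stream_names[streams[i, ] != "none"], collapse = ","),
      unassigned = "")
  }
  data.frame(label = label, supporting = supporting,
             stringsAsFactors = FALSE)
}

#' Classify a table of transcription-factor evidence
#'
#' @param evidence Data frame with columns `tf`, `motif_call`, `ip_call`,
#'   `rna_call`; TFs must be unique.
#' @return List with `labels` (data frame tf/label/supporting), `counts`
#'   (named integer vector over all five labels), and `displayed`: the subset
#'   of TFs informative in at least two streams (the usual display rule for
#'   evidence-integration figures).
#' @export
classify_table <- function(evidence) {
  need <- c("tf", "motif_call", "ip_call", "rna_call")
  miss <- setdiff(need, names(evidence))
  if (length(miss)) {
    abort_ipqms(paste0("evidence missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(evidence$tf)) abort_ipqms("duplicate tf in evidence table")
  res <- classify_tf_vec(evidence$motif_call, evidence$ip_call,
                         evidence$rna_call)
  labels <- data.frame(tf = evidence$tf, label = res$label,
                       supporting = res$supporting,
                       stringsAsFactors = FALSE)
  lev <- c("a_specific", "b_specific", "shared", "mixed", "unassigned")
  counts <- table(factor(labels$label, levels = lev))
  n_informative <- rowSums(cbind(evidence$motif_call, evidence$ip_call,
                                 evidence$rna_call) != "none")
  list(labels = labels,
       counts = stats::setNames(as.integer(counts), lev),
       displayed = labels$tf[n_informative >= 2])
}
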