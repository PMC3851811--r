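#' Scan reads against subject sequences with bounded mismatches
#'
#' Low-level ungapped matcher behind annotation, hairpin alignment and
#' genomic placement. Each pattern (read) is slid end-to-end over every
#' subject; a placement is a hit when it has at most `max_mm` substitutions.
#' Indels are not modelled and any base outside A/C/G/T (including N) always
#' counts as a mismatch.
#'
#' With `best_only = TRUE` only the minimum-mismatch hit per pattern is
#' returned, ties broken by subject name, then offset, then forward strand
#' before reverse complement.
#'
#' @param patterns character vector of read sequences (DNA).
#' @param subjects character vector of subject sequences (DNA).
#' @param max_mm maximum number of substitutions tolerated.
#' @param best_only return only the single best hit per pattern?
#' @param both_strands also try the reverse complement of each pattern?
#' @param subject_names optional names used for reporting and tie-breaking;
#'   defaults to `names(subjects)` or the subject index.
#' @return data.frame with columns `pattern` (index into `patterns`),
#'   `subject` (index into `subjects`), `subject_name`, `start` (0-based
#'   offset on the subject), `mm`, `strand` (`"+"` if the pattern matched
#'   as given, `"-"` if its reverse complement did).
#' @export
scan_reads <- function(patterns, subjects, max_mm, best_only = FALSE,
                       both_strands = TRUE, subject_names = NULL) {
  stopifnot(max_mm >= 0)
  empty <- data.frame(pattern = integer(), subject = integer(),
                      subject_name = character(), start = integer(),
                      mm = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (length(patterns) == 0 || length(subjects) == 0) return(empty)
  subject_names <- subject_names %||% names(subjects) %||% as.character(seq_along(subjects))
  ord <- order(subject_names)
  h <- scan_hits_cpp(as.character(patterns), as.character(subjects)[ord],
                     as.integer(max_mm), isTRUE(best_only), isTRUE(both_strands))
  if (nrow(h) == 0) return(empty)
  h$subject <- ord[h$subject]
  h$subject_name <- subject_names[h$subject]
  h[, c("pattern", "subject", "subject_name", "start", "mm", "strand")]
}

# best hit per pattern aligned back to the pattern vector (NA rows = no hit)
scan_best <- function(patterns, subjects, max_mm, both_strands = TRUE,
                      subject_names = NULL) {
  h <- scan_reads(patterns, subjects, max_mm, best_only = TRUE,
                  both_strands = both_strands, subject_names = subject_names)
  out <- data.frame(subject = rep(NA_integer_, length(patterns)),
                    subject_name = NA_character_, start = NA_integer_,
                    mm = NA_integer_, strand = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(h) > 0) {
    out$subject[h$pattern] <- h$subject
    out$subject_name[h$pattern] <- h$subject_name
    out$start[h$pattern] <- h$start
    out$mm[h$pattern] <- h$mm
    out$strand[h$pattern] <- h$strand
  }
  out
}
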