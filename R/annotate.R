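#' Length-filter a read library
#'
#' Retains reads of length greater than or equal to `min_len` nucleotides
#' (14 nt by default) and recomputes the library total. The input library is
#' not modified.
#'
#' @param lib a [read_library()].
#' @param min_len minimum length retained, in nt.
#' @return A new [read_library()].
#' @export
filter_by_length <- function(lib, min_len = 14L) {
  stopifnot(inherits(lib, "read_library"), min_len >= 1)
  keep <- nchar(lib$reads$sequence) >= min_len
  read_library(lib$reads[keep, , drop = FALSE], lib$sample_id)
}

#' Read length distribution
#'
#' Count-weighted histogram of read lengths, the standard diagnostic for
#' library quality: intact small-RNA libraries peak at 22 nt (the average
#' mature miRNA length) while degraded ones shift towards 17 nt with a heavy
#' short tail. The modal length is the length with maximum mass; ties go to
#' the smallest length.
#'
#' @param lib a [read_library()].
#' @return object of class `length_distribution`: list with `sample_id`,
#'   `histogram` (named integer vector, names are lengths) and
#'   `modal_length` (`NA` with an `empty` flag for an empty library).
#' @export
length_distribution <- function(lib) {
  stopifnot(inherits(lib, "read_library"))
  if (nrow(lib$reads) == 0) {
    return(structure(list(sample_id = lib$sample_id,
                          histogram = integer(0), modal_length = NA_integer_,
                          empty = TRUE), class = "length_distribution"))
  }
  len <- nchar(lib$reads$sequence)
  h <- tapply(lib$reads$count, len, sum)
  hist <- as.integer(h)
  names(hist) <- names(h)
  lens <- as.integer(names(hist))
  mode <- min(lens[hist == max(hist)])
  structure(list(sample_id = lib$sample_id, histogram = hist,
                 modal_length = mode, empty = FALSE),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("<length_distribution> %s: modal length %s nt over %d lengths\n",
              x$sample_id, x$modal_length, length(x$histogram)))
  invisible(x)
}

#' Best database hit for a single read
#'
#' Ungapped end-to-end match of the read (either orientation) at any offset
#' within any sense-strand database record, tolerating up to `max_mm`
#' substitutions. Among hits the minimum-mismatch one is returned, ties
#' broken by record name then offset then forward orientation.
#'
#' @param read a read sequence (character scalar) or a list with a
#'   `sequence` element.
#' @param db data.frame with `name` and `sequence` (an RNA class database).
#' @param max_mm maximum substitutions.
#' @return `NULL` if there is no hit, else a list with `name`, `start`
#'   (0-based offset), `mismatches`, `strand`.
#' @export
match_with_mismatches <- function(read, db, max_mm = 2L) {
  seq <- if (is.list(read)) read$sequence else read
  stopifnot(length(seq) == 1)
  if (is.null(db) || nrow(db) == 0) return(NULL)
  h <- scan_best(seq, db$sequence, max_mm, both_strands = TRUE,
                 subject_names = db$name)
  if (is.na(h$mm[1])) return(NULL)
  list(name = h$subject_name[1], start = h$start[1],
       mismatches = h$mm[1], strand = h$strand[1])
}

#' Hierarchical elimination annotation
#'
#' Classifies every read of a (length-filtered) library into an RNA class.
#' Classes are tried in the fixed priority order miRNA, sn/snoRNA, lincRNA,
#' tRNA, rRNA, mRNA, misc; a read is assigned to the *first* class in which
#' it hits within `max_mismatches` and is removed from the pool, so an early
#' class wins even over a later exact match. Survivors are matched exactly
#' (both strands) against the intergenic/intronic region sequences and become
#' `unannotated_genomic`; whatever remains is `unmatched`. Empty class
#' databases are allowed and simply never match.
#'
#' @param lib a [read_library()], already length filtered.
#' @param ref a [reference_set()] carrying the class databases.
#' @param regions a [genomic_region_set()] or `NULL`.
#' @param cfg a [pipeline_config()]; `class_order` controls the priority.
#' @return object of class `annotation_result`: list with `sample_id`,
#'   `reads` (per-read data.frame with `class`, `mismatches`, `hit_name`),
#'   `apportionment` (class to read-mass fraction over all of
#'   [ALL_READ_CLASSES]) and `total_reads`.
#' @export
eliminate <- function(lib, ref, regions = NULL, cfg = pipeline_config()) {
  stopifnot(inherits(lib, "read_library"), inherits(ref, "reference_set"))
  reads <- lib$reads
  n <- nrow(reads)
  cls <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n)
  hit <- rep(NA_character_, n)
  pool <- seq_len(n)
  for (class_name in cfg$class_order) {
    if (length(pool) == 0) break
    db <- ref$class_dbs[[class_name]]
    if (is.null(db) || nrow(db) == 0) next
    h <- scan_best(reads$sequence[pool], db$sequence, cfg$max_mismatches,
                   both_strands = TRUE, subject_names = db$name)
    got <- !is.na(h$mm)
    cls[pool[got]] <- class_name
    mm[pool[got]] <- h$mm[got]
    hit[pool[got]] <- h$subject_name[got]
    pool <- pool[!got]
  }
  regions <- regions %||% ref$regions
  if (!is.null(regions) && length(pool) > 0) {
    rseqs <- region_sequences(regions)
    h <- scan_best(reads$sequence[pool], rseqs, 0L, both_strands = TRUE)
    got <- !is.na(h$mm)
    cls[pool[got]] <- "unannotated_genomic"
    mm[pool[got]] <- 0L
    pool <- pool[!got]
  }
  cls[pool] <- "unmatched"
  out <- data.frame(read_id = reads$read_id, sequence = reads$sequence,
                    count = reads$count, class = cls, mismatches = mm,
                    hit_name = hit, stringsAsFactors = FALSE)
  mass <- tapply(out$count, factor(out$class, levels = ALL_READ_CLASSES), sum)
  mass[is.na(mass)] <- 0
  total <- lib$total_reads
  app <- if (total > 0) mass / total else mass * 0
  structure(list(sample_id = lib$sample_id, reads = out,
                 apportionment = app, total_reads = total),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %s: %d distinct reads, %d total\n",
              x$sample_id, nrow(x$reads), x$total_reads))
  app <- round(100 * x$apportionment, 1)
  cat(paste(sprintf("  %-20s %5.1f%%", names(app), app), collapse = "\n"), "\n")
  invisible(x)
}

#' Extract the unannotated pool of an annotation result
#'
#' Reads assigned `unannotated_genomic` or `unmatched`, as a library; this is
#' the input of the novel-miRNA pipeline.
#'
#' @param ann an [eliminate()] result.
#' @param classes which terminal classes to keep.
#' @return A [read_library()].
#' @export
unannotated_pool <- function(ann, classes = c("unannotated_genomic", "unmatched")) {
  keep <- ann$reads$class %in% classes
  read_library(ann$reads[keep, c("read_id", "sequence", "count")], ann$sample_id)
}

#' Write annotation outputs as TSV
#'
#' Per-read class table plus the class apportionment (read-mass fractions).
#'
#' @param ann an [eliminate()] result.
#' @param reads_path,apportionment_path output paths (`NULL` to skip one).
#' @return invisibly, the paths written.
#' @export
write_annotation_tsv <- function(ann, reads_path = NULL, apportionment_path = NULL) {
  if (!is.null(reads_path)) {
    write.table(ann$reads, reads_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(apportionment_path)) {
    write.table(data.frame(class = names(ann$apportionment),
                           fraction = as.numeric(ann$apportionment)),
                apportionment_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(reads_path, apportionment_path))
}
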