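#' Construct a read library
#'
#' A read library is one sample's collapsed small-RNA reads: each row is a
#' distinct sequence with its multiplicity. Duplicate sequences passed in are
#' merged with their counts summed (mass is conserved), so sequences are
#' unique within a library.
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `count`.
#' @param sample_id sample label.
#' @return object of class `read_library`: list with `sample_id`, `reads`
#'   (collapsed data.frame) and `total_reads` (sum of counts).
#' @export
read_library <- function(reads, sample_id = "sample") {
  if (is.null(reads) || nrow(reads) == 0) {
    reads <- data.frame(read_id = character(), sequence = character(),
                        count = integer(), stringsAsFactors = FALSE)
    return(structure(list(sample_id = sample_id, reads = reads,
                          total_reads = 0L), class = "read_library"))
  }
  stopifnot(all(c("read_id", "sequence", "count") %in% names(reads)))
  reads$sequence <- normalize_dna(reads$sequence)
  assert_dna(reads$sequence, "read sequence")
  if (any(reads$count < 1)) stop("read counts must be >= 1", call. = FALSE)
  # collapse identical sequences, keeping the first read id seen
  first <- !duplicated(reads$sequence)
  counts <- tapply(reads$count, factor(reads$sequence, levels = reads$sequence[first]), sum)
  out <- data.frame(read_id = reads$read_id[first],
                    sequence = reads$sequence[first],
                    count = as.integer(counts[reads$sequence[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(sample_id = sample_id, reads = out,
                 total_reads = sum(out$count)),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("<read_library> %s: %d distinct sequences, %d total reads\n",
              x$sample_id, nrow(x$reads), x$total_reads))
  invisible(x)
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Ingests raw or collapsed reads. Identical sequences are merged and their
#' counts summed; RNA alphabet (U) is normalised to DNA (T). The collapsed
#' FASTA dialects `>id_xN` and `>id count=N` are both understood. An empty
#' file yields an empty library; a malformed FASTQ record raises a parse
#' error naming the offending line.
#'
#' @param path input file (plain or gzipped).
#' @param format one of `"auto"`, `"fasta"`, `"fastq"`, `"fasta_collapsed"`.
#'   `"auto"` decides from the extension and, for FASTA, uses header counts
#'   when every header carries one.
#' @param sample_id sample label; defaults to the file base name.
#' @return A [read_library()].
#' @export
read_fastq_or_fasta <- function(path,
                                format = c("auto", "fasta", "fastq", "fasta_collapsed"),
                                sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sample_id <- sample_id %||% sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "",
                                  basename(path), ignore.case = TRUE)
  ext_fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  if (format == "auto") format <- if (ext_fastq) "fastq" else "fasta"
  if (format == "fastq") return(parse_fastq(path, sample_id))

  seqs <- read_fasta_file(path)
  if (length(seqs) == 0) return(read_library(NULL, sample_id))
  headers <- names(seqs)
  counts <- parse_collapsed_counts(headers)
  if (format == "fasta_collapsed") {
    bad <- which(is.na(counts))
    if (length(bad) > 0) {
      stop(sprintf("collapsed FASTA record %d ('%s') carries no count suffix",
                   bad[1], headers[bad[1]]), call. = FALSE)
    }
  } else if (any(is.na(counts))) {
    counts <- rep(1L, length(seqs))    # plain FASTA: every record is one read
  }
  read_library(data.frame(read_id = sub("_x[0-9]+$", "", sub(" count=[0-9]+$", "", headers)),
                          sequence = as.character(seqs), count = counts,
                          stringsAsFactors = FALSE), sample_id)
}

# counts from collapsed-FASTA headers; NA where no dialect matches
parse_collapsed_counts <- function(headers) {
  counts <- rep(NA_integer_, length(headers))
  m1 <- regmatches(headers, regexpr("_x([0-9]+)$", headers))
  has1 <- grepl("_x[0-9]+$", headers)
  counts[has1] <- as.integer(sub("^_x", "", m1))
  has2 <- grepl("count=[0-9]+", headers)
  counts[has2] <- as.integer(sub(".*count=([0-9]+).*", "\\1", headers[has2]))
  counts
}

read_fasta_file <- function(path) {
  if (file.exists(path) && file.size(path) == 0) {
    return(Biostrings::BStringSet())
  }
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) {
                  # an empty (whitespace-only) file is an empty library
                  if (length(readLines(path, warn = FALSE)) == 0 ||
                      all(!nzchar(trimws(readLines(path, warn = FALSE))))) {
                    return(Biostrings::BStringSet())
                  }
                  stop("FASTA parse error in ", path, ": ", conditionMessage(e),
                       call. = FALSE)
                })
  x
}

# strict 4-line FASTQ parser; errors carry 1-based line numbers
parse_fastq <- function(path, sample_id) {
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0 && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) return(read_library(NULL, sample_id))
  if (length(lines) %% 4 != 0) {
    stop(sprintf("FASTQ parse error: truncated record starting at line %d",
                 4L * (length(lines) %/% 4L) + 1L), call. = FALSE)
  }
  idx <- seq(1, length(lines), by = 4)
  hdr <- lines[idx]; seq <- lines[idx + 1]; plus <- lines[idx + 2]; qual <- lines[idx + 3]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0) {
    stop(sprintf("FASTQ parse error at line %d: header must start with '@'",
                 idx[bad[1]]), call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0) {
    stop(sprintf("FASTQ parse error at line %d: separator must start with '+'",
                 idx[bad[1]] + 2L), call. = FALSE)
  }
  bad <- which(nchar(qual) != nchar(seq))
  if (length(bad) > 0) {
    stop(sprintf("FASTQ parse error at line %d: quality length %d != sequence length %d",
                 idx[bad[1]] + 3L, nchar(qual[bad[1]]), nchar(seq[bad[1]])),
         call. = FALSE)
  }
  seq <- normalize_dna(seq)
  bad <- which(!grepl("^[ACGTN]+$", seq))
  if (length(bad) > 0) {
    stop(sprintf("FASTQ parse error at line %d: invalid sequence characters",
                 idx[bad[1]] + 1L), call. = FALSE)
  }
  read_library(data.frame(read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
                          sequence = seq, count = 1L, stringsAsFactors = FALSE),
               sample_id)
}

#' Write a read library as collapsed FASTA
#'
#' @param lib a [read_library()].
#' @param path output path.
#' @param dialect count-suffix dialect: `">id_xN"` or `">id count=N"`.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(lib, path, dialect = c("xN", "count")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(lib, "read_library"))
  hdr <- if (dialect == "xN") {
    sprintf(">%s_x%d", lib$reads$read_id, lib$reads$count)
  } else {
    sprintf(">%s count=%d", lib$reads$read_id, lib$reads$count)
  }
  writeLines(as.vector(rbind(hdr, lib$reads$sequence)), path)
  invisible(path)
}

#' Construct a reference set
#'
#' Bundles the hairpin precursors, their located mature miRNAs, the other
#' RNA-class databases and (optionally) the genomic regions used for
#' unannotated-read matching and novel discovery.
#'
#' @param hairpins data.frame with `hairpin_id`, `sequence`.
#' @param matures data.frame with `name`, `sequence`, `hairpin_id`, `start`,
#'   `end` (0-based half-open on the hairpin), `arm` (`"5p"`/`"3p"`),
#'   `located` (logical).
#' @param class_dbs named list of data.frames (`name`, `sequence`), one per
#'   entry of [RNA_CLASSES].
#' @param regions optional [genomic_region_set()].
#' @return object of class `reference_set`.
#' @export
reference_set <- function(hairpins, matures, class_dbs = list(), regions = NULL) {
  hairpins$sequence <- normalize_dna(hairpins$sequence)
  assert_dna(hairpins$sequence, "hairpin sequence")
  matures$sequence <- normalize_dna(matures$sequence)
  assert_dna(matures$sequence, "mature sequence")
  if (!"located" %in% names(matures)) matures$located <- TRUE
  bad <- !names(class_dbs) %in% RNA_CLASSES
  if (any(bad)) stop("unknown RNA class: ", names(class_dbs)[bad][1], call. = FALSE)
  # coordinate consistency for located matures
  loc <- matures[matures$located, , drop = FALSE]
  if (nrow(loc) > 0) {
    hseq <- hairpins$sequence[match(loc$hairpin_id, hairpins$hairpin_id)]
    got <- substr(hseq, loc$start + 1L, loc$end)
    if (any(got != loc$sequence)) {
      stop("mature locus coordinates inconsistent with hairpin sequence for ",
           loc$name[which(got != loc$sequence)[1]], call. = FALSE)
    }
  }
  structure(list(hairpins = hairpins, matures = matures,
                 class_dbs = class_dbs, regions = regions),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d hairpins, %d matures (%d located), classes: %s\n",
              nrow(x$hairpins), nrow(x$matures), sum(x$matures$located),
              paste(names(x$class_dbs), collapse = ", ")))
  invisible(x)
}

#' Read miRBase-style mature and hairpin FASTA files
#'
#' Loads mature miRNAs and pre-miRNA hairpins, converts RNA to DNA alphabet
#' and locates each mature on its hairpin by exact substring search. Matures
#' are matched to hairpins by the miRBase name convention (shared stem, e.g.
#' `hsa-miR-21-5p` on `hsa-mir-21`). The arm is taken from a `-5p`/`-3p`
#' name suffix when present; otherwise a mature wholly within the first half
#' of its hairpin is 5p, wholly within the second half 3p, and borderline
#' loci are assigned by midpoint.
#'
#' Matures that locate nowhere are retained with `located = FALSE` and listed
#' in the `unlocated` attribute of the returned set (they can still be
#' exact-matched by reads, but carry no hairpin coordinates). A mature whose
#' sequence occurs at two positions on its hairpin is an error.
#'
#' @param mature_path FASTA of mature miRNA sequences.
#' @param hairpin_path FASTA of pre-miRNA hairpin sequences.
#' @return A [reference_set()] (no class databases, no regions) with an
#'   `unlocated` attribute naming matures that could not be placed.
#' @export
read_mirbase_fastas <- function(mature_path, hairpin_path) {
  mat <- read_fasta_file(mature_path)
  hp <- read_fasta_file(hairpin_path)
  take_name <- function(x) sub("\\s.*$", "", names(x))
  hairpins <- data.frame(hairpin_id = take_name(hp),
                         sequence = normalize_dna(as.character(hp)),
                         stringsAsFactors = FALSE)
  mnames <- take_name(mat)
  mseqs <- normalize_dna(as.character(mat))
  assert_dna(hairpins$sequence, "hairpin sequence")
  assert_dna(mseqs, "mature sequence")

  stem <- function(x) {
    sub("-(5p|3p|star)$", "", tolower(x))
  }
  hstem <- tolower(hairpins$hairpin_id)
  out <- data.frame(name = mnames, sequence = mseqs,
                    hairpin_id = NA_character_, start = NA_integer_,
                    end = NA_integer_, arm = NA_character_, located = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(mnames)) {
    st <- stem(mnames[i])
    cand <- which(hstem == st)
    if (length(cand) == 0) next
    for (h in cand) {
      pos <- gregexpr(mseqs[i], hairpins$sequence[h], fixed = TRUE)[[1]]
      if (pos[1] == -1) next
      if (length(pos) > 1) {
        stop(sprintf("mature %s locates ambiguously on %s at positions %s",
                     mnames[i], hairpins$hairpin_id[h],
                     paste(pos - 1L, collapse = ", ")), call. = FALSE)
      }
      out$hairpin_id[i] <- hairpins$hairpin_id[h]
      out$start[i] <- pos - 1L
      out$end[i] <- pos - 1L + nchar(mseqs[i])
      out$located[i] <- TRUE
      out$arm[i] <- assign_arm(mnames[i], out$start[i], out$end[i],
                               nchar(hairpins$sequence[h]))
      break
    }
  }
  rs <- reference_set(hairpins, out,
                      class_dbs = list(miRNA = hairpins_as_db(hairpins)))
  attr(rs, "unlocated") <- out$name[!out$located]
  rs
}

hairpins_as_db <- function(hairpins) {
  data.frame(name = hairpins$hairpin_id, sequence = hairpins$sequence,
             stringsAsFactors = FALSE)
}

# 5p/3p from the name when declared, else by position within the hairpin
assign_arm <- function(name, start, end, hairpin_len) {
  if (grepl("-5p$", name)) return("5p")
  if (grepl("-3p$", name)) return("3p")
  half <- hairpin_len / 2
  if (end <= half) return("5p")
  if (start >= half) return("3p")
  if ((start + end) / 2 < half) "5p" else "3p"
}

#' Construct a genomic region set
#'
#' Intergenic/intronic intervals plus the genome sequences they live on.
#' Coordinates are 0-based half-open throughout.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `region_type`
#'   (`"intergenic"` or `"intronic"`), `strand`.
#' @param genome named character vector, chromosome name to sequence.
#' @return object of class `genomic_region_set`.
#' @export
genomic_region_set <- function(regions, genome) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (!"region_type" %in% names(regions)) regions$region_type <- "intergenic"
  if (!"strand" %in% names(regions)) regions$strand <- "+"
  genome <- vapply(genome, normalize_dna, character(1))
  assert_dna(unname(genome), "genome sequence")
  miss <- setdiff(unique(regions$chrom), names(genome))
  if (length(miss) > 0) {
    stop("region references missing chromosome: ", miss[1], call. = FALSE)
  }
  if (any(regions$start >= regions$end)) stop("region with start >= end", call. = FALSE)
  too_long <- regions$end > nchar(genome[regions$chrom])
  if (any(too_long)) {
    stop("region extends past end of chromosome ",
         regions$chrom[which(too_long)[1]], call. = FALSE)
  }
  structure(list(regions = regions, genome = genome),
            class = "genomic_region_set")
}

#' Read genomic regions from BED with a genome FASTA
#'
#' BED intervals (0-based half-open, BED native) are imported with
#' rtracklayer; the BED name column, when present, is taken as the region
#' type (`intergenic`/`intronic`).
#'
#' @param bed_path BED file of intervals.
#' @param genome_path genome FASTA.
#' @return A [genomic_region_set()].
#' @export
read_regions_bed <- function(bed_path, genome_path) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  g <- read_fasta_file(genome_path)
  genome <- normalize_dna(as.character(g))
  names(genome) <- sub("\\s.*$", "", names(g))
  rt <- if (!is.null(gr$name)) as.character(gr$name) else rep("intergenic", length(gr))
  rt[is.na(rt) | !rt %in% c("intergenic", "intronic")] <- "intergenic"
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  regions <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = BiocGenerics::start(gr) - 1L,   # GRanges is 1-based
                        end = BiocGenerics::end(gr),
                        region_type = rt, strand = strand,
                        stringsAsFactors = FALSE)
  genomic_region_set(regions, genome)
}

# sequence of each region, sense strand of the genome
region_sequences <- function(rset) {
  unname(substr(rset$genome[rset$regions$chrom],
                rset$regions$start + 1L, rset$regions$end))
}

#' Write/read a multi-sample expression profile TSV
#'
#' Tab-separated layout with one row per miRNA (lexicographic order) and, per
#' sample, a raw count column `<sample>_count` and a TPM column `<sample>_tpm`
#' printed with 6 decimals. The library totals are preserved in a header
#' comment so the file round-trips to identical profile objects.
#'
#' @param profiles a single expression profile or a list of them (see
#'   [reference_profile()]).
#' @param path output path.
#' @return `path` invisibly for the writer; a named list of profiles for the
#'   reader.
#' @export
write_profile_tsv <- function(profiles, path) {
  if (inherits(profiles, "expression_profile")) profiles <- list(profiles)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  names(profiles) <- ids
  kind <- unique(vapply(profiles, function(p) p$kind, character(1)))
  all_names <- sort(unique(unlist(lapply(profiles, function(p) p$rows$name))))
  out <- data.frame(miRNA = all_names, stringsAsFactors = FALSE)
  for (id in ids) {
    p <- profiles[[id]]
    m <- match(all_names, p$rows$name)
    cnt <- ifelse(is.na(m), 0L, p$rows$count[m])
    tpmv <- ifelse(is.na(m), 0, p$rows$tpm[m])
    out[[paste0(id, "_count")]] <- cnt
    out[[paste0(id, "_tpm")]] <- sprintf("%.6f", tpmv)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s totals=%s", kind[1],
                     paste(sprintf("%s:%.0f", ids,
                                   vapply(profiles, function(p) as.numeric(p$library_total), numeric(1))),
                           collapse = ",")), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  kind <- sub("^# kind=(\\S+).*", "\\1", hdr)
  totals_str <- sub(".*totals=", "", hdr)
  tot <- strsplit(strsplit(totals_str, ",")[[1]], ":")
  totals <- as.numeric(vapply(tot, `[`, character(1), 2))
  names(totals) <- vapply(tot, `[`, character(1), 1)
  tab <- read.delim(path, skip = 1, stringsAsFactors = FALSE, check.names = FALSE)
  profiles <- list()
  for (id in names(totals)) {
    cnt <- tab[[paste0(id, "_count")]]
    keep <- cnt > 0
    rows <- data.frame(name = tab$miRNA[keep], count = as.integer(cnt[keep]),
                       stringsAsFactors = FALSE)
    rows$tpm <- tpm(rows$count, totals[[id]])
    profiles[[id]] <- expression_profile(id, kind, rows, totals[[id]])
  }
  profiles
}
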