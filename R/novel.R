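#' Select candidate reads for novel-miRNA screening
#'
#' Unannotated reads need a collapsed frequency of at least `min_freq`
#' (default 5) before they are matched against the genome.
#'
#' @param lib a [read_library()] (the unannotated pool).
#' @param min_freq minimum count retained.
#' @return A [read_library()] of the retained reads.
#' @export
select_candidate_reads <- function(lib, min_freq = 5L) {
  stopifnot(inherits(lib, "read_library"))
  keep <- lib$reads$count >= min_freq
  read_library(lib$reads[keep, , drop = FALSE], lib$sample_id)
}

#' Exact placements of reads within genomic regions
#'
#' All 0-mismatch placements of each read inside the intergenic/intronic
#' intervals, on both strands. A `-` strand placement means the reverse
#' complement of the read equals the genomic window, i.e. the small RNA reads
#' off the minus strand. Reads with no placement are simply absent from the
#' result. Coordinates are genomic, 0-based half-open.
#'
#' @param lib a [read_library()] (candidate reads).
#' @param regions a [genomic_region_set()].
#' @return data.frame with `read_id`, `sequence`, `count`, `chrom`, `start`,
#'   `end`, `strand`, `region_type`.
#' @export
map_exact_to_regions <- function(lib, regions) {
  stopifnot(inherits(lib, "read_library"), inherits(regions, "genomic_region_set"))
  empty <- data.frame(read_id = character(), sequence = character(),
                      count = integer(), chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      region_type = character(), stringsAsFactors = FALSE)
  if (nrow(lib$reads) == 0 || nrow(regions$regions) == 0) return(empty)
  rseqs <- region_sequences(regions)
  h <- scan_reads(lib$reads$sequence, rseqs, 0L, best_only = FALSE,
                  both_strands = TRUE)
  if (nrow(h) == 0) return(empty)
  reg <- regions$regions[h$subject, , drop = FALSE]
  len <- nchar(lib$reads$sequence[h$pattern])
  data.frame(read_id = lib$reads$read_id[h$pattern],
             sequence = lib$reads$sequence[h$pattern],
             count = lib$reads$count[h$pattern],
             chrom = reg$chrom,
             start = reg$start + h$start,
             end = reg$start + h$start + len,
             strand = h$strand,
             region_type = reg$region_type,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extend a genomic placement into a precursor-length window
#'
#' Adds `flank` nucleotides on both sides (clipped at chromosome bounds, with
#' the clipping recorded) and returns the window sequence oriented so the
#' small RNA reads sense on it: minus-strand placements are reverse
#' complemented. The read's own interval is reported in window coordinates.
#'
#' @param placement one row of [map_exact_to_regions()] (or any list with
#'   `chrom`, `start`, `end`, `strand`).
#' @param flank nt of flank on each side.
#' @param genome named character vector of chromosome sequences.
#' @return list with `chrom`, `start`, `end` (genomic window), `strand`,
#'   `sequence` (read-sense), `read_start`, `read_end` (window coordinates),
#'   `clipped`.
#' @export
extend_flanks <- function(placement, flank, genome) {
  chrom_len <- nchar(genome[[placement$chrom]])
  ws <- max(0L, placement$start - flank)
  we <- min(chrom_len, placement$end + flank)
  clipped <- (placement$start - flank < 0) || (placement$end + flank > chrom_len)
  seq <- substr(genome[[placement$chrom]], ws + 1L, we)
  if (placement$strand == "-") {
    seq <- revcomp(seq)
    rs <- we - placement$end
  } else {
    rs <- placement$start - ws
  }
  list(chrom = placement$chrom, start = ws, end = we,
       strand = placement$strand, sequence = seq,
       read_start = rs, read_end = rs + (placement$end - placement$start),
       clipped = clipped)
}

#' Built-in folding engine (maximum base pairing)
#'
#' Returns a folding engine for [fold_hairpin()]: a function mapping a DNA
#' sequence to a 1-based pairing vector (`NA` = unpaired). The built-in
#' engine maximises Watson-Crick plus G.U pairs over nested structures with a
#' minimum hairpin loop, via the classic cubic dynamic programme. External
#' predictors can be plugged in as any function with the same signature;
#' their scores, if attached as a `score` attribute, are recorded verbatim.
#'
#' @param min_loop minimum hairpin loop size.
#' @return A function of class `fold_engine`.
#' @export
nussinov_engine <- function(min_loop = 3L) {
  f <- function(sequence) {
    r <- nussinov_cpp(sequence, as.integer(min_loop))
    r$pairing
  }
  structure(f, class = "fold_engine", engine_name = "builtin-nussinov")
}

#' Fold a precursor window and test the hairpin criteria
#'
#' Folds the window with the engine and accepts it as a putative pre-miRNA
#' hairpin iff the optimal structure has a single terminal loop, a 5' stem
#' arm spanning at least `stem_min_span` positions and a stem pairing
#' fraction of at least `stem_min_pairing`. Windows shorter than
#' `min_precursor_length` are rejected before folding. Rejections carry a
#' reason.
#'
#' @param sequence precursor window (DNA; N tolerated, never pairs).
#' @param cfg a [pipeline_config()].
#' @param engine a folding engine; defaults to [nussinov_engine()].
#' @return object of class `hairpin_structure`: list with `accepted`,
#'   `reason` (when rejected), `pairing` (1-based partner or `NA`),
#'   `n_pairs`, `single_loop`, `arm5`, `arm3`, `loop` (0-based half-open
#'   intervals), `stem_span`, `pairing_fraction`, `dotbracket`.
#' @export
fold_hairpin <- function(sequence, cfg = pipeline_config(), engine = NULL) {
  sequence <- normalize_dna(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop("precursor contains characters outside A/C/G/T/N", call. = FALSE)
  }
  engine <- engine %||% nussinov_engine(cfg$min_loop)
  n <- nchar(sequence)
  reject <- function(reason, pairing = rep(NA_integer_, n), n_pairs = 0L) {
    structure(list(accepted = FALSE, reason = reason, pairing = pairing,
                   n_pairs = n_pairs, single_loop = FALSE, arm5 = NULL,
                   arm3 = NULL, loop = NULL, stem_span = 0L,
                   pairing_fraction = 0,
                   dotbracket = dotbracket(pairing)),
              class = "hairpin_structure")
  }
  if (n < cfg$min_precursor_length) return(reject("too_short"))
  pairing <- engine(sequence)
  paired <- which(!is.na(pairing))
  n_pairs <- length(paired) %/% 2L
  if (n_pairs == 0) return(reject("no_pairs", pairing))
  # hairpin loops: pairs with no paired base strictly inside them
  closing <- integer(0)
  for (i in paired) {
    j <- pairing[i]
    if (j <= i) next
    if (j - i > 1 && !any(paired > i & paired < j)) closing <- c(closing, i)
  }
  if (length(closing) != 1) return(reject("multiple_loops", pairing, n_pairs))
  a <- closing[1]; b <- pairing[a]           # 1-based closing pair
  i0 <- min(paired); j0 <- max(paired)
  arm5 <- c(i0 - 1L, a)                      # 0-based half-open
  arm3 <- c(b - 1L, j0)
  loop <- c(a, b - 1L)
  stem_span <- a - i0 + 1L
  frac <- 2 * n_pairs / ((arm5[2] - arm5[1]) + (arm3[2] - arm3[1]))
  ok <- stem_span >= cfg$stem_min_span && frac >= cfg$stem_min_pairing
  structure(list(accepted = ok,
                 reason = if (ok) NA_character_ else "weak_stem",
                 pairing = pairing, n_pairs = n_pairs, single_loop = TRUE,
                 arm5 = arm5, arm3 = arm3, loop = loop,
                 stem_span = stem_span, pairing_fraction = frac,
                 dotbracket = dotbracket(pairing)),
            class = "hairpin_structure")
}

dotbracket <- function(pairing) {
  n <- length(pairing)
  if (n == 0) return("")
  ch <- rep(".", n)
  ch[!is.na(pairing) & pairing > seq_len(n)] <- "("
  ch[!is.na(pairing) & pairing < seq_len(n)] <- ")"
  paste(ch, collapse = "")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(sprintf("<hairpin_structure> %s: %d pairs, stem span %d, pairing %.2f%s\n",
              if (x$accepted) "accepted" else paste0("rejected (", x$reason, ")"),
              x$n_pairs, x$stem_span, x$pairing_fraction,
              if (x$single_loop) ", single loop" else ""))
  invisible(x)
}

#' Structural filters for a novel-miRNA candidate
#'
#' Given an accepted hairpin structure and the candidate small RNA's interval
#' in window coordinates, evaluates the three features of a genuine miRNA:
#' `in_stem` - the sRNA lies within one stem arm (at least `in_stem_frac` of
#' its positions in the arm, none in the loop); `has_isomir` - at least one
#' other read places within +/- `isomir_window` nt of both its ends;
#' `has_counterpart` - at least one read lies in the other stem arm.
#' Candidates failing `in_stem` are prediction errors and are discarded by
#' the pipeline; the other two flags are recorded and only gate in strict
#' mode.
#'
#' @param structure an accepted [fold_hairpin()] result.
#' @param read_start,read_end the sRNA's 0-based half-open interval in window
#'   coordinates.
#' @param other_reads data.frame of other reads placed in the same window
#'   (columns `start`, `end`, `sequence`, window coordinates); may be empty.
#' @param cfg a [pipeline_config()].
#' @return list with logical `in_stem`, `has_isomir`, `has_counterpart` and
#'   `arm` (`"5p"`/`"3p"`/`NA`).
#' @export
apply_structural_filters <- function(structure, read_start, read_end,
                                     other_reads = NULL, cfg = pipeline_config()) {
  stopifnot(inherits(structure, "hairpin_structure"), structure$single_loop)
  pos <- read_start:(read_end - 1L)                      # 0-based positions
  in_iv <- function(p, iv) p >= iv[1] & p < iv[2]
  loop_hit <- any(in_iv(pos, structure$loop))
  f5 <- mean(in_iv(pos, structure$arm5))
  f3 <- mean(in_iv(pos, structure$arm3))
  arm <- if (f5 >= f3 && f5 > 0) "5p" else if (f3 > 0) "3p" else NA_character_
  in_stem <- !loop_hit && max(f5, f3) >= cfg$in_stem_frac
  has_isomir <- FALSE
  has_counterpart <- FALSE
  if (!is.null(other_reads) && nrow(other_reads) > 0) {
    has_isomir <- any(abs(other_reads$start - read_start) <= cfg$isomir_window &
                      abs(other_reads$end - read_end) <= cfg$isomir_window)
    other_arm <- if (identical(arm, "5p")) structure$arm3 else structure$arm5
    frac_other <- vapply(seq_len(nrow(other_reads)), function(i) {
      p <- other_reads$start[i]:(other_reads$end[i] - 1L)
      mean(in_iv(p, other_arm))
    }, numeric(1))
    has_counterpart <- any(frac_other >= cfg$in_stem_frac)
  }
  list(in_stem = in_stem, has_isomir = has_isomir,
       has_counterpart = has_counterpart, arm = arm)
}

#' Discover potential novel miRNAs
#'
#' Full per-sample pipeline over the unannotated pool: frequency filter,
#' exact genomic matching within intergenic/intronic regions, flank
#' extension, hairpin folding, structural filters, then cross-sample
#' grouping, redundancy removal and naming via [group_name_dedupe()].
#'
#' @param libs a single [read_library()] or a named list of them (one per
#'   sample), each being a sample's unannotated pool (see
#'   [unannotated_pool()]).
#' @param regions a [genomic_region_set()].
#' @param cfg a [pipeline_config()]; `strict_filters = TRUE` additionally
#'   requires the isomiR and counterpart flags.
#' @param engine folding engine, defaults to [nussinov_engine()].
#' @return The final candidate table from [group_name_dedupe()].
#' @export
discover_novel <- function(libs, regions, cfg = pipeline_config(), engine = NULL) {
  if (inherits(libs, "read_library")) {
    libs <- stats::setNames(list(libs), libs$sample_id)
  }
  engine <- engine %||% nussinov_engine(cfg$min_loop)
  per_sample <- lapply(names(libs), function(id) {
    cand <- select_candidate_reads(libs[[id]], cfg$novel_min_freq)
    pl <- map_exact_to_regions(cand, regions)
    if (nrow(pl) == 0) return(NULL)
    recs <- list()
    for (i in seq_len(nrow(pl))) {
      w <- extend_flanks(pl[i, ], cfg$flank_length, regions$genome)
      st <- fold_hairpin(w$sequence, cfg, engine)
      if (!st$accepted) next
      others <- placements_in_window(pl[-i, , drop = FALSE], w)
      fl <- apply_structural_filters(st, w$read_start, w$read_end, others, cfg)
      if (!fl$in_stem) next                      # prediction error
      if (cfg$strict_filters && !(fl$has_isomir && fl$has_counterpart)) next
      recs[[length(recs) + 1]] <- data.frame(
        sample_id = id, sequence = pl$sequence[i], count = pl$count[i],
        chrom = w$chrom, start = w$start, end = w$end, strand = w$strand,
        precursor = w$sequence, arm = fl$arm,
        in_stem = fl$in_stem, has_isomir = fl$has_isomir,
        has_counterpart = fl$has_counterpart, stringsAsFactors = FALSE)
    }
    if (length(recs) == 0) NULL else do.call(rbind, recs)
  })
  per_sample <- per_sample[!vapply(per_sample, is.null, logical(1))]
  group_name_dedupe(per_sample)
}

# project other placements into a window's coordinate frame
placements_in_window <- function(pl, w) {
  if (nrow(pl) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  keep <- pl$chrom == w$chrom & pl$strand == w$strand &
    pl$start >= w$start & pl$end <= w$end
  pl <- pl[keep, , drop = FALSE]
  if (nrow(pl) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  if (w$strand == "+") {
    data.frame(start = pl$start - w$start, end = pl$end - w$start,
               sequence = pl$sequence, stringsAsFactors = FALSE)
  } else {
    data.frame(start = w$end - pl$end, end = w$end - pl$start,
               sequence = pl$sequence, stringsAsFactors = FALSE)
  }
}

#' Group, deduplicate and name novel candidates
#'
#' Candidates from all samples are pooled; windows from a common precursor
#' (overlapping genomic intervals on the same strand) are merged into one
#' family. Within a family the member with the highest summed count is the
#' major mature miRNA, the remaining members its isomiRs/counterparts.
#' Survivors are named `jnu-pat-hsa-1..N` in descending total-count order,
#' ties broken lexicographically by precursor sequence. Per-sample
#' provenance is retained.
#'
#' @param per_sample_candidates list of per-sample candidate data.frames
#'   (internal layout produced by [discover_novel()]).
#' @return data.frame with `name`, `chrom`, `start`, `end`, `strand`,
#'   `precursor`, `mature_sequence`, `mature_count`, `total_count`,
#'   `n_members`, `members` (collapsed `sequence:count` list),
#'   `sample_ids`, `has_isomir`, `has_counterpart`.
#' @export
group_name_dedupe <- function(per_sample_candidates) {
  empty <- data.frame(name = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      precursor = character(), mature_sequence = character(),
                      mature_count = integer(), total_count = integer(),
                      n_members = integer(), members = character(),
                      sample_ids = character(), has_isomir = logical(),
                      has_counterpart = logical(), stringsAsFactors = FALSE)
  if (length(per_sample_candidates) == 0) return(empty)
  all <- do.call(rbind, per_sample_candidates)
  if (nrow(all) == 0) return(empty)
  # strand-agnostic merging: the two arms of one hairpin are near-reverse
  # complements, so a read from one arm also places on the minus strand of
  # the other; both windows describe the same precursor locus
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start + 1L, all$end),
                               strand = all$strand)
  merged <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, merged, ignore.strand = TRUE)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  fams <- lapply(unique(grp), function(g) {
    rows <- all[grp == g, , drop = FALSE]
    # a read contributes once per sample to its locus even when several of
    # its placements seeded accepted windows
    rows <- rows[!duplicated(rows[, c("sample_id", "sequence")]), , drop = FALSE]
    # summed counts per distinct member sequence across samples
    cnt <- tapply(rows$count, rows$sequence, sum)
    cnt <- cnt[order(-cnt, names(cnt))]
    mature_seq <- names(cnt)[1]
    mrow <- rows[rows$sequence == mature_seq, , drop = FALSE][1, ]
    data.frame(chrom = as.character(GenomicRanges::seqnames(merged[g])),
               start = BiocGenerics::start(merged[g]) - 1L,
               end = BiocGenerics::end(merged[g]),
               strand = mrow$strand,
               precursor = mrow$precursor,
               mature_sequence = mature_seq,
               mature_count = as.integer(cnt[1]),
               total_count = as.integer(sum(cnt)),
               n_members = length(cnt),
               members = paste(sprintf("%s:%d", names(cnt), as.integer(cnt)),
                               collapse = ";"),
               sample_ids = paste(sort(unique(rows$sample_id)), collapse = ","),
               has_isomir = any(rows$has_isomir),
               has_counterpart = any(rows$has_counterpart),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fams)
  # deduplicate sequence-identical precursors (keep the higher-count one)
  out <- out[order(-out$total_count, out$precursor), , drop = FALSE]
  out <- out[!duplicated(out$precursor), , drop = FALSE]
  out$name <- sprintf("jnu-pat-hsa-%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("name", setdiff(names(out), "name"))]
}

#' Write novel candidates and their structures
#'
#' Candidate table as TSV plus, optionally, the precursor structures as
#' dot-bracket text.
#'
#' @param candidates a [discover_novel()] result.
#' @param path TSV output path.
#' @param structures_path optional path for dot-bracket structures.
#' @param cfg a [pipeline_config()] (used to refold for the structure file).
#' @return invisibly, the paths written.
#' @export
write_novel_tsv <- function(candidates, path, structures_path = NULL,
                            cfg = pipeline_config()) {
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(structures_path)) {
    lines <- unlist(lapply(seq_len(nrow(candidates)), function(i) {
      st <- fold_hairpin(candidates$precursor[i], cfg)
      c(paste0(">", candidates$name[i]), candidates$precursor[i], st$dotbracket)
    }))
    writeLines(lines %||% character(0), structures_path)
  }
  invisible(c(path, structures_path))
}
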