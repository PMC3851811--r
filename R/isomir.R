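#' Align reads to pre-miRNA hairpins
#'
#' All ungapped end-to-end placements of each read on each hairpin (sense
#' strand) with at most `max_mm` substitutions, restricted to the
#' best-mismatch stratum per read: if a read places anywhere with 0
#' mismatches, only its 0-mismatch placements are kept, and so on.
#' Multi-mapping reads keep all their best-stratum placements.
#'
#' @param lib a [read_library()].
#' @param ref a [reference_set()] with hairpins loaded.
#' @param max_mm maximum substitutions.
#' @return data.frame with `read_id`, `sequence`, `count`, `hairpin_id`,
#'   `start`, `end` (0-based half-open on the hairpin), `mismatches`.
#' @export
align_to_hairpins <- function(lib, ref, max_mm = 2L) {
  stopifnot(inherits(lib, "read_library"), inherits(ref, "reference_set"))
  empty <- data.frame(read_id = character(), sequence = character(),
                      count = integer(), hairpin_id = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (nrow(lib$reads) == 0 || nrow(ref$hairpins) == 0) return(empty)
  h <- scan_reads(lib$reads$sequence, ref$hairpins$sequence, max_mm,
                  best_only = FALSE, both_strands = FALSE,
                  subject_names = ref$hairpins$hairpin_id)
  if (nrow(h) == 0) return(empty)
  best <- stats::ave(h$mm, h$pattern, FUN = min)
  h <- h[h$mm == best, , drop = FALSE]
  data.frame(read_id = lib$reads$read_id[h$pattern],
             sequence = lib$reads$sequence[h$pattern],
             count = lib$reads$count[h$pattern],
             hairpin_id = h$subject_name,
             start = h$start,
             end = h$start + nchar(lib$reads$sequence[h$pattern]),
             mismatches = h$mm, stringsAsFactors = FALSE)
}

#' Build isomiR families from hairpin alignments
#'
#' Each alignment is assigned to the mature locus on the same hairpin with
#' which it overlaps most, provided the overlap is at least
#' `family_overlap_frac` (default one half) of the shorter of read and
#' mature length. Alignments that overlap no mature sufficiently (e.g. reads
#' centred on the loop) are set aside as "hairpin-other" and reported in the
#' `hairpin_other` attribute, not familied. Members are keyed by read
#' sequence with offsets `offset5 = start - mature_start` and
#' `offset3 = end - mature_end`; multi-mapped reads contribute their full
#' count to every family they enter. Only located matures found families.
#'
#' @param alignments output of [align_to_hairpins()].
#' @param ref a [reference_set()].
#' @param cfg a [pipeline_config()].
#' @return object of class `isomir_families`: named list (by mature name) of
#'   family lists with elements `mirna`, `arm`, `hairpin_id`, `canonical`,
#'   `mature_start`, `mature_end` and `members` (data.frame `sequence`,
#'   `count`, `offset5`, `offset3`, `mismatches`).
#' @export
build_families <- function(alignments, ref, cfg = pipeline_config()) {
  mat <- ref$matures[ref$matures$located, , drop = FALSE]
  fams <- list()
  other_idx <- integer(0)
  if (nrow(alignments) > 0 && nrow(mat) > 0) {
    assigned_to <- rep(NA_integer_, nrow(alignments))
    for (i in seq_len(nrow(alignments))) {
      a <- alignments[i, ]
      cand <- which(mat$hairpin_id == a$hairpin_id)
      if (length(cand) == 0) { other_idx <- c(other_idx, i); next }
      ov <- pmin(a$end, mat$end[cand]) - pmax(a$start, mat$start[cand])
      need <- cfg$family_overlap_frac *
        pmin(a$end - a$start, mat$end[cand] - mat$start[cand])
      ok <- ov >= need & ov > 0
      if (!any(ok)) { other_idx <- c(other_idx, i); next }
      best <- cand[ok][which.max(ov[ok])]
      assigned_to[i] <- best
    }
    for (k in sort(unique(assigned_to[!is.na(assigned_to)]))) {
      rows <- alignments[which(assigned_to == k), , drop = FALSE]
      members <- data.frame(sequence = rows$sequence, count = rows$count,
                            offset5 = rows$start - mat$start[k],
                            offset3 = rows$end - mat$end[k],
                            mismatches = rows$mismatches,
                            stringsAsFactors = FALSE)
      # one member per distinct sequence; counts of duplicate placements of
      # the same sequence on the same mature are not double counted
      members <- members[!duplicated(members$sequence), , drop = FALSE]
      rownames(members) <- NULL
      fams[[mat$name[k]]] <- list(mirna = mat$name[k], arm = mat$arm[k],
                                  hairpin_id = mat$hairpin_id[k],
                                  canonical = mat$sequence[k],
                                  mature_start = mat$start[k],
                                  mature_end = mat$end[k],
                                  members = members)
    }
  } else if (nrow(alignments) > 0) {
    other_idx <- seq_len(nrow(alignments))
  }
  out <- structure(fams, class = "isomir_families")
  attr(out, "hairpin_other") <- alignments[other_idx, , drop = FALSE]
  out
}

#' @export
print.isomir_families <- function(x, ...) {
  cat(sprintf("<isomir_families> %d families, %d hairpin-other alignments\n",
              length(x), nrow(attr(x, "hairpin_other"))))
  invisible(x)
}

#' Dominant isomiR of a family
#'
#' The member with the maximum count; ties are broken towards the smaller
#' absolute 5' offset, then the smaller absolute 3' offset (so the canonical
#' form wins a tie), then lexicographically by sequence.
#'
#' @param family one family from [build_families()].
#' @return The dominant member as a one-row data.frame.
#' @export
select_dominant <- function(family) {
  m <- family$members
  if (is.null(m) || nrow(m) == 0) stop("empty isomiR family", call. = FALSE)
  ord <- order(-m$count, abs(m$offset5), abs(m$offset3), m$sequence)
  m[ord[1], , drop = FALSE]
}

#' Abundant-isomiR expression profile
#'
#' One row per mature miRNA with at least one family member; the raw count is
#' the dominant member's count. Because the canonical sequence, when read at
#' all, is itself a family member, every shared row satisfies
#' `abundant count >= reference count`, and miRNAs whose canonical sequence
#' received no exact reads appear here but not in the reference profile.
#'
#' @param families an [build_families()] result for one sample.
#' @param lib the same sample's [read_library()] (for the library total).
#' @return An [expression_profile()] of kind `"abundant_isomir"` with a
#'   `dominant_sequence` attribute (named character vector).
#' @export
abundant_profile <- function(families, lib) {
  if (length(families) == 0) {
    return(expression_profile(lib$sample_id, "abundant_isomir", NULL,
                              lib$total_reads))
  }
  doms <- lapply(families, select_dominant)
  rows <- data.frame(name = names(families),
                     count = vapply(doms, function(d) as.integer(d$count), integer(1)),
                     stringsAsFactors = FALSE)
  prof <- expression_profile(lib$sample_id, "abundant_isomir", rows,
                             lib$total_reads)
  dom_seq <- vapply(doms, function(d) d$sequence, character(1))
  names(dom_seq) <- names(families)
  attr(prof, "dominant_sequence") <- dom_seq
  prof
}

#' Compare reference and abundant-isomiR profiles across a sample group
#'
#' Per sample, a miRNA is "YES" when its dominant isomiR is exactly the
#' canonical mature sequence and "NO" otherwise. The group-level status is
#' `YES`/`NO` only when the miRNA is expressed in *all* samples of the group
#' (dominant count at least `detection_threshold`) and the per-sample calls
#' are unanimous; expressed everywhere but disagreeing gives `non_uniform`,
#' and missing from any sample gives `low_expression`. The tallies also
#' report `n_not_considered = n_low + n_nonuniform`, the combined bin of the
#' usual summary table.
#'
#' @param families_by_sample named list (sample id) of [build_families()]
#'   results for the samples of one group.
#' @param ref_profiles_by_sample named list of reference
#'   [expression_profile()]s, same samples.
#' @param ref the [reference_set()] (defines the miRNA universe).
#' @param cfg a [pipeline_config()].
#' @return list with `records` (data.frame: `miRNA`, `status`, per-sample
#'   `<id>_reference`, `<id>_abundant`, `<id>_dominant`) and `tallies`
#'   (named integer vector `n_yes`, `n_no`, `n_low`, `n_nonuniform`,
#'   `n_not_considered`).
#' @export
compare_profiles <- function(families_by_sample, ref_profiles_by_sample,
                             ref, cfg = pipeline_config()) {
  ids <- names(families_by_sample)
  if (is.null(ids) || length(ids) == 0) stop("group has zero samples", call. = FALSE)
  universe <- ref$matures$name[ref$matures$located]
  canonical <- ref$matures$sequence[ref$matures$located]
  rec <- data.frame(miRNA = universe, stringsAsFactors = FALSE)
  expressed <- matrix(FALSE, length(universe), length(ids))
  yes <- matrix(NA, length(universe), length(ids))
  for (j in seq_along(ids)) {
    fams <- families_by_sample[[ids[j]]]
    rp <- ref_profiles_by_sample[[ids[j]]]
    dom_cnt <- rep(0L, length(universe))
    dom_seq <- rep(NA_character_, length(universe))
    if (length(fams) > 0) {
      doms <- lapply(fams, select_dominant)
      idx <- match(names(fams), universe)
      dom_cnt[idx] <- vapply(doms, function(d) as.integer(d$count), integer(1))
      dom_seq[idx] <- vapply(doms, function(d) d$sequence, character(1))
    }
    ref_cnt <- rep(0L, length(universe))
    if (!is.null(rp) && nrow(rp$rows) > 0) {
      m <- match(rp$rows$name, universe)
      ref_cnt[m[!is.na(m)]] <- rp$rows$count[!is.na(m)]
    }
    expressed[, j] <- dom_cnt >= cfg$detection_threshold & !is.na(dom_seq)
    yes[, j] <- dom_seq == canonical
    rec[[paste0(ids[j], "_reference")]] <- ref_cnt
    rec[[paste0(ids[j], "_abundant")]] <- dom_cnt
    rec[[paste0(ids[j], "_dominant")]] <- dom_seq
  }
  status <- character(length(universe))
  all_exp <- rowSums(expressed) == length(ids)
  status[!all_exp] <- "low_expression"
  uni_yes <- all_exp & rowSums(yes) == length(ids)
  uni_no <- all_exp & rowSums(yes) == 0
  status[uni_yes] <- "YES"
  status[uni_no] <- "NO"
  status[all_exp & !uni_yes & !uni_no] <- "non_uniform"
  rec$status <- status
  tallies <- c(n_yes = sum(status == "YES"), n_no = sum(status == "NO"),
               n_low = sum(status == "low_expression"),
               n_nonuniform = sum(status == "non_uniform"))
  tallies["n_not_considered"] <- tallies["n_low"] + tallies["n_nonuniform"]
  list(records = rec[, c("miRNA", "status",
                         setdiff(names(rec), c("miRNA", "status")))],
       tallies = tallies)
}

#' Number of distinct isomiRs per miRNA
#'
#' Highly expressed miRNAs typically display more isomiRs; this table feeds
#' that diagnostic. Unknown names are reported with 0 members and flagged.
#'
#' @param families a [build_families()] result.
#' @param mirna_names miRNA names to tabulate.
#' @return data.frame with `miRNA`, `n_isomirs`, `known`.
#' @export
isomir_count_distribution <- function(families, mirna_names) {
  known <- mirna_names %in% names(families)
  n <- vapply(mirna_names, function(nm) {
    f <- families[[nm]]
    if (is.null(f)) 0L else nrow(f$members)
  }, integer(1))
  if (any(!known)) {
    warning("unknown or unexpressed miRNA name(s): ",
            paste(head(mirna_names[!known], 3), collapse = ", "), call. = FALSE)
  }
  data.frame(miRNA = mirna_names, n_isomirs = n, known = known,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write isomiR families as TSV
#'
#' Long layout: one row per family member with sequence, count, hairpin
#' position and offsets, the per-miRNA analogue of a family listing.
#'
#' @param families a [build_families()] result.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_families_tsv <- function(families, path) {
  rows <- lapply(names(families), function(nm) {
    f <- families[[nm]]
    data.frame(miRNA = nm, hairpin_id = f$hairpin_id, arm = f$arm,
               sequence = f$members$sequence, count = f$members$count,
               offset5 = f$members$offset5, offset3 = f$members$offset3,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(miRNA = character(), hairpin_id = character(), arm = character(),
               sequence = character(), count = integer(),
               offset5 = integer(), offset3 = integer())
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
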