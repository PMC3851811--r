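#' Pipeline configuration
#'
#' Houses every tunable constant of the pipeline. Defaults are the values the
#' analysis is defined with: reads of at least 14 nt are kept, up to 2
#' substitutions are tolerated when annotating or aligning, unannotated reads
#' need a frequency of at least 5 to enter novel-miRNA screening, genomic
#' matches are extended by 70 nt on both sides to precursor length, and
#' "highly expressed" means a raw count strictly above 10,000. The TPM scale
#' factor is a fixed constant (10^6), not a tunable.
#'
#' @param min_read_length minimum read length retained (nt).
#' @param max_mismatches maximum substitutions for class annotation and
#'   hairpin alignment.
#' @param novel_min_freq minimum collapsed read count for a read to be a
#'   novel-miRNA candidate.
#' @param flank_length nt of genomic flank added on each side of an exact
#'   genomic match before folding.
#' @param high_expression_threshold raw-count threshold; expression is
#'   "high" when strictly greater.
#' @param class_order elimination priority order over [RNA_CLASSES].
#' @param detection_threshold minimum dominant-isomiR count for a miRNA to
#'   count as expressed in a sample.
#' @param family_overlap_frac minimum overlap with a mature locus, as a
#'   fraction of the shorter of read and mature length, for family membership.
#' @param isomir_window +/- nt window used for the novel-pipeline isomiR flag.
#' @param min_precursor_length windows shorter than this are rejected before
#'   folding.
#' @param stem_min_span minimum positions spanned by the 5' stem arm of an
#'   accepted hairpin.
#' @param stem_min_pairing minimum fraction of stem-arm positions that are
#'   paired in an accepted hairpin.
#' @param min_loop minimum hairpin loop size for the folding engine.
#' @param in_stem_frac fraction of a read's positions that must lie inside
#'   one stem arm for the `in_stem` filter.
#' @param strict_filters if `TRUE` the novel pipeline requires all three
#'   structural filters (in-stem, isomiR present, counterpart present); by
#'   default only in-stem is a hard gate and the others are recorded.
#' @param rng_seed optional integer seed recorded for provenance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_read_length = 14L,
                            max_mismatches = 2L,
                            novel_min_freq = 5L,
                            flank_length = 70L,
                            high_expression_threshold = 10000L,
                            class_order = RNA_CLASSES,
                            detection_threshold = 1L,
                            family_overlap_frac = 0.5,
                            isomir_window = 3L,
                            min_precursor_length = 40L,
                            stem_min_span = 16L,
                            stem_min_pairing = 0.6,
                            min_loop = 3L,
                            in_stem_frac = 0.9,
                            strict_filters = FALSE,
                            rng_seed = NULL) {
  stopifnot(min_read_length >= 1, max_mismatches >= 0, novel_min_freq >= 0,
            flank_length >= 0, high_expression_threshold >= 0,
            detection_threshold >= 0, min_loop >= 0,
            family_overlap_frac > 0, family_overlap_frac <= 1,
            all(class_order %in% RNA_CLASSES))
  structure(list(
    min_read_length = as.integer(min_read_length),
    max_mismatches = as.integer(max_mismatches),
    novel_min_freq = as.integer(novel_min_freq),
    flank_length = as.integer(flank_length),
    high_expression_threshold = as.integer(high_expression_threshold),
    tpm_scale = 1e6,
    class_order = class_order,
    detection_threshold = as.integer(detection_threshold),
    family_overlap_frac = family_overlap_frac,
    isomir_window = as.integer(isomir_window),
    min_precursor_length = as.integer(min_precursor_length),
    stem_min_span = as.integer(stem_min_span),
    stem_min_pairing = stem_min_pairing,
    min_loop = as.integer(min_loop),
    in_stem_frac = in_stem_frac,
    strict_filters = isTRUE(strict_filters),
    rng_seed = rng_seed
  ), class = "pipeline_config")
}
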