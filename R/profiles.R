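#' Construct an expression profile
#'
#' One sample's per-miRNA raw counts and TPM. Only observed miRNAs are listed
#' (raw count at least 1); TPM is `count / library_total * 1e6` for every row.
#'
#' @param sample_id sample label.
#' @param kind `"reference"` (exact matches to canonical matures) or
#'   `"abundant_isomir"` (dominant family member counts).
#' @param rows data.frame with `name`, `count` and optionally `tpm`
#'   (recomputed if absent).
#' @param library_total post-filter total read count of the sample.
#' @return object of class `expression_profile`.
#' @export
expression_profile <- function(sample_id, kind = c("reference", "abundant_isomir"),
                               rows, library_total) {
  kind <- match.arg(kind)
  if (is.null(rows) || nrow(rows) == 0) {
    rows <- data.frame(name = character(), count = integer(), tpm = numeric(),
                       stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("name", "count") %in% names(rows)))
    if (anyDuplicated(rows$name)) {
      stop("duplicate miRNA names in profile rows: ",
           rows$name[duplicated(rows$name)][1], call. = FALSE)
    }
    if (any(rows$count < 1)) stop("profile rows must have count >= 1", call. = FALSE)
    rows$tpm <- tpm(rows$count, library_total)
    rows <- rows[order(rows$name), c("name", "count", "tpm")]
    rownames(rows) <- NULL
  }
  structure(list(sample_id = sample_id, kind = kind, rows = rows,
                 library_total = library_total),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s (%s): %d miRNAs, library total %s\n",
              x$sample_id, x$kind, nrow(x$rows),
              format(x$library_total, big.mark = ",")))
  invisible(x)
}

#' Transcripts per million
#'
#' `TPM = count / library_total * 1e6`, at full floating precision.
#'
#' @param raw raw count(s).
#' @param library_total total reads in the sample (post length filter).
#' @return numeric vector of TPM values.
#' @examples
#' tpm(50, 1e6)   # 50
#' @export
tpm <- function(raw, library_total) {
  if (length(library_total) != 1 || is.na(library_total) || library_total < 1) {
    stop("library_total must be a single count >= 1", call. = FALSE)
  }
  if (any(raw < 0) || any(raw > library_total)) {
    stop("raw counts must lie in [0, library_total]", call. = FALSE)
  }
  raw / library_total * 1e6
}

#' Reference miRNA expression profile
#'
#' For every mature miRNA in the reference, the raw count is the total count
#' of reads whose sequence is exactly the canonical mature sequence; miRNAs
#' with no exactly matching read are omitted. Several mature names can share
#' one sequence (database duplicates): each name receives the full count and
#' the affected name groups are reported in the `duplicated_sequences`
#' attribute so the double counting is visible.
#'
#' @param lib a length-filtered [read_library()].
#' @param ref a [reference_set()]; mature names must be unique.
#' @param cfg a [pipeline_config()].
#' @return An [expression_profile()] of kind `"reference"`.
#' @export
reference_profile <- function(lib, ref, cfg = pipeline_config()) {
  stopifnot(inherits(lib, "read_library"), inherits(ref, "reference_set"))
  mat <- ref$matures
  if (anyDuplicated(mat$name)) {
    stop("duplicate mature names in reference: ",
         mat$name[duplicated(mat$name)][1], call. = FALSE)
  }
  m <- match(mat$sequence, lib$reads$sequence)
  cnt <- ifelse(is.na(m), 0L, lib$reads$count[m])
  keep <- cnt > 0
  rows <- data.frame(name = mat$name[keep], count = as.integer(cnt[keep]),
                     stringsAsFactors = FALSE)
  prof <- expression_profile(lib$sample_id, "reference", rows, lib$total_reads)
  dup_seq <- mat$sequence[keep][duplicated(mat$sequence[keep])]
  if (length(dup_seq) > 0) {
    groups <- lapply(unique(dup_seq), function(s) mat$name[keep][mat$sequence[keep] == s])
    attr(prof, "duplicated_sequences") <- groups
  }
  prof
}

#' Expression summary of a profile
#'
#' Reports the number of expressed miRNAs, the singletons (raw count exactly
#' 1), the highly expressed set (raw count strictly greater than the
#' threshold) and an order-of-magnitude histogram of raw counts
#' (`floor(log10(count))` bins), which typically spans five to six decades in
#' deep small-RNA libraries.
#'
#' @param profile an [expression_profile()].
#' @param high_threshold strict raw-count threshold for "highly expressed".
#' @return list with `n_expressed`, `n_singletons`, `highly_expressed`
#'   (character vector of names) and `log10_histogram` (named counts).
#' @export
expression_summary <- function(profile, high_threshold = 10000L) {
  cnt <- profile$rows$count
  bins <- floor(log10(pmax(cnt, 1)))
  hist <- table(factor(bins, levels = 0:max(c(bins, 0))))
  list(n_expressed = nrow(profile$rows),
       n_singletons = sum(cnt == 1),
       highly_expressed = profile$rows$name[cnt > high_threshold],
       log10_histogram = hist)
}

#' Hierarchical clustering of samples by expression profile
#'
#' Profiles are laid out on the union of their miRNA names (absent = 0 TPM),
#' transformed as `log2(TPM + 1)` so the several-decade dynamic range does
#' not let a few miRNAs dominate, and clustered with average linkage on
#' `1 - Spearman correlation`. Both the correlation method and the linkage
#' are configurable.
#'
#' @param profiles list of at least two [expression_profile()] objects.
#' @param method correlation method passed to [stats::cor()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return object of class `sample_linkage`: list with `labels` and the
#'   `hclust` tree.
#' @export
cluster_samples <- function(profiles, method = "spearman", linkage = "average") {
  if (length(profiles) < 2) stop("need at least two profiles", call. = FALSE)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  all_names <- sort(unique(unlist(lapply(profiles, function(p) p$rows$name))))
  m <- sapply(profiles, function(p) {
    v <- numeric(length(all_names))
    idx <- match(p$rows$name, all_names)
    v[idx] <- p$rows$tpm
    log2(v + 1)
  })
  colnames(m) <- ids
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression profile (zero variance): sample ",
         ids[which(sds == 0)[1]], call. = FALSE)
  }
  d <- 1 - cor(m, method = method)
  hc <- hclust(as.dist(d), method = linkage)
  structure(list(labels = ids, hclust = hc), class = "sample_linkage")
}

#' @export
print.sample_linkage <- function(x, ...) {
  cat(sprintf("<sample_linkage> %d samples: %s\n", length(x$labels),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Write a sample dendrogram as newick text
#'
#' @param linkage a [cluster_samples()] result.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_newick <- function(linkage, path) {
  ape::write.tree(ape::as.phylo(linkage$hclust), file = path)
  invisible(path)
}
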