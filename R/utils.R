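# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

# validate a character vector of DNA sequences (A/C/G/T/N, non-empty)
assert_dna <- function(x, what = "sequence") {
  if (length(x) == 0) return(invisible(x))
  bad <- !grepl("^[ACGTN]+$", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside A/C/G/T/N (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

# uppercase + RNA-to-DNA normalisation applied to every ingested sequence
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# run code under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# random DNA strings
rand_dna <- function(n, len, prob = NULL) {
  if (length(len) == 1) len <- rep(len, n)
  vapply(len, function(l) {
    paste(sample(DNA_BASES, l, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
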