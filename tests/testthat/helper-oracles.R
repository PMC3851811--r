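# independent brute-force oracles and tiny fixtures used across the suite

rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# exhaustive sliding-window Hamming scan; N never matches anything
oracle_hits <- function(pattern, subjects, max_mm, both_strands = TRUE) {
  hits <- list()
  oris <- list(c("+", pattern))
  if (both_strands) oris <- c(oris, list(c("-", rc_oracle(pattern))))
  for (s in seq_along(subjects)) {
    sub <- strsplit(subjects[s], "")[[1]]
    for (ori in oris) {
      p <- strsplit(ori[2], "")[[1]]
      if (length(p) > length(sub)) next
      for (st in 0:(length(sub) - length(p))) {
        w <- sub[(st + 1):(st + length(p))]
        mm <- sum(!(p == w & p %in% c("A", "C", "G", "T")))
        if (mm <= max_mm) {
          hits[[length(hits) + 1]] <- data.frame(
            subject = s, start = st, mm = mm, strand = ori[1],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0) {
    data.frame(subject = integer(), start = integer(), mm = integer(),
               strand = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, hits)
  }
}

# maximum nested base pairing by explicit recursion over all structures
# (no memoisation; checks the dynamic programme on short sequences)
enum_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(seq, "")[[1]]
  pairable <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (pairable(ch[i], ch[k])) {
        v <- 1L + rec(i + 1L, k - 1L) + (if (k < j) rec(k + 1L, j) else 0L)
        if (v > best) best <- v
      }
    }
    best
  }
  if (length(ch) <= min_loop + 1L) 0L else rec(1L, length(ch))
}

rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# a two-hairpin reference with matures planted 3 nt in from each arm end
tiny_ref <- function(arm1 = "GATTACAGATTACAGATTACAGATTACAGA",
                     arm2 = "CCTGAGTTCAAGTCCTGAGTTCAAGTCCAA") {
  mk <- function(i, arm) {
    loop <- "ACACACACAC"
    hp <- paste0(arm, loop, rc_oracle(arm))
    m5 <- substr(hp, 4, 25)
    s3 <- nchar(arm) + nchar(loop) + 3L
    m3 <- substr(hp, s3 + 1, s3 + 22)
    list(hp = data.frame(hairpin_id = sprintf("syn-mir-%d", i), sequence = hp,
                         stringsAsFactors = FALSE),
         mat = data.frame(name = sprintf("syn-miR-%d-%s", i, c("5p", "3p")),
                          sequence = c(m5, m3),
                          hairpin_id = sprintf("syn-mir-%d", i),
                          start = c(3L, s3), end = c(25L, s3 + 22L),
                          arm = c("5p", "3p"), located = TRUE,
                          stringsAsFactors = FALSE))
  }
  a <- mk(1, arm1); b <- mk(2, arm2)
  hairpins <- rbind(a$hp, b$hp)
  matures <- rbind(a$mat, b$mat)
  reference_set(hairpins, matures,
                class_dbs = list(miRNA = data.frame(name = hairpins$hairpin_id,
                                                    sequence = hairpins$sequence,
                                                    stringsAsFactors = FALSE)))
}

make_lib <- function(seqs, counts = rep(1L, length(seqs)), sample_id = "s1") {
  read_library(data.frame(read_id = sprintf("r%d", seq_along(seqs)),
                          sequence = seqs, count = as.integer(counts),
                          stringsAsFactors = FALSE), sample_id)
}

write_tmp_fasta <- function(headers, seqs) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}
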