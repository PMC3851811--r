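test_that("candidate selection applies the frequency threshold inclusively", {
  lib <- make_lib(c("ACGTACGTACGTACGTACGTAC", "TGCATGCATGCATGCATGCATG",
                    "GGGGCCCCAAAATTTTGGGGCC"), c(5, 4, 1))
  sel <- select_candidate_reads(lib, 5)
  expect_equal(sel$reads$count, 5L)          # count 5 retained, 4 dropped
  expect_equal(nrow(select_candidate_reads(lib, 1)$reads), 3)  # identity
  expect_equal(nrow(select_candidate_reads(make_lib(character(0)), 5)$reads), 0)
})

test_that("exact genomic mapping reports every placement on both strands", {
  withr::local_seed(201)
  left <- rand_seq(40); mid <- rand_seq(30); right <- rand_seq(40)
  read <- rand_seq(22)
  chrom <- paste0(left, read, mid, read, right)           # twice, + strand
  genome <- c(chr1 = chrom, chr2 = paste0(rand_seq(50), rc_oracle(read), rand_seq(50)))
  regions <- genomic_region_set(
    data.frame(chrom = c("chr1", "chr2"), start = c(0L, 0L),
               end = c(nchar(chrom), 122L),
               region_type = c("intronic", "intronic"), strand = "+"),
    genome)
  pl <- map_exact_to_regions(make_lib(read, 9), regions)
  expect_equal(nrow(pl), 3)
  plus <- pl[pl$chrom == "chr1", ]
  expect_equal(sort(plus$start), c(40L, 92L))
  expect_true(all(plus$strand == "+"))
  minus <- pl[pl$chrom == "chr2", ]
  expect_equal(minus$strand, "-")
  expect_equal(substr(genome[["chr2"]], minus$start + 1, minus$end),
               rc_oracle(read))
  # against the brute-force oracle
  want <- oracle_hits(read, mirnome:::region_sequences(regions), 0, TRUE)
  expect_equal(nrow(pl), nrow(want))
})

test_that("flank extension does precursor-window arithmetic with clipping", {
  withr::local_seed(203)
  genome <- c(chr1 = rand_seq(300))
  w <- extend_flanks(list(chrom = "chr1", start = 100L, end = 122L, strand = "+"),
                     70, genome)
  expect_equal(c(w$start, w$end), c(30L, 192L))
  expect_equal(nchar(w$sequence), 162L)
  expect_false(w$clipped)
  expect_equal(substr(w$sequence, w$read_start + 1, w$read_end),
               substr(genome[["chr1"]], 101, 122))

  wc <- extend_flanks(list(chrom = "chr1", start = 10L, end = 32L, strand = "+"),
                      70, genome)
  expect_equal(wc$start, 0L)
  expect_equal(wc$end, 102L)
  expect_true(wc$clipped)

  # minus-strand windows contain the read verbatim after reverse complement
  read <- rand_seq(22)
  g2 <- c(chr1 = paste0(rand_seq(100), rc_oracle(read), rand_seq(100)))
  wm <- extend_flanks(list(chrom = "chr1", start = 100L, end = 122L, strand = "-"),
                      70, g2)
  expect_equal(substr(wm$sequence, wm$read_start + 1, wm$read_end), read)
})

test_that("perfect inverted repeats fold as hairpins; weak sequences are rejected", {
  withr::local_seed(207)
  arm <- rand_seq(30)
  hp <- paste0(arm, "ACACACAC", rc_oracle(arm))
  st <- fold_hairpin(hp)
  expect_true(st$accepted)
  expect_true(st$single_loop)
  expect_gte(st$n_pairs, 30)
  expect_equal(nchar(st$dotbracket), nchar(hp))

  # A/C-only sequence cannot pair at all
  ac <- paste(sample(c("A", "C"), 80, replace = TRUE), collapse = "")
  stc <- fold_hairpin(ac)
  expect_false(stc$accepted)
  expect_equal(stc$reason, "no_pairs")

  # composition-preserving shuffles of a real hairpin are rejected
  rejected <- 0L
  for (i in 1:5) {
    shuf <- paste(sample(strsplit(hp, "")[[1]]), collapse = "")
    if (!fold_hairpin(shuf)$accepted) rejected <- rejected + 1L
  }
  expect_gte(rejected, 4L)

  expect_false(fold_hairpin(rand_seq(30))$accepted)  # below minimum length
  expect_error(fold_hairpin("ACGTXACGTACGTACGTACGTACGTACGTACGTACGTACGT"), "A/C/G/T/N")
})

test_that("maximum pairing equals brute-force enumeration on short sequences", {
  withr::local_seed(211)
  for (i in 1:40) {
    s <- rand_seq(sample(4:12, 1))
    got <- mirnome:::nussinov_cpp(s, 3L)
    expect_equal(got$n_pairs, enum_max_pairs(s, 3L), info = s)
    # the traceback is a consistent involution realising the optimum
    p <- got$pairing
    paired <- which(!is.na(p))
    expect_true(all(p[p[paired]] == paired))
  }
})

test_that("structural filters gate loop-spanning reads and flag family structure", {
  withr::local_seed(213)
  arm <- rand_seq(30, alphabet = c("C", "G"))   # stem alphabet orthogonal to all-A context
  hp <- paste0(arm, strrep("A", 10), rc_oracle(arm))
  win <- paste0(strrep("A", 50), hp, strrep("A", 50))
  st <- fold_hairpin(win)
  expect_true(st$accepted)
  # read within the 5' arm
  fl <- apply_structural_filters(st, 53L, 75L,
                                 data.frame(start = c(54L, 94L), end = c(76L, 116L),
                                            sequence = c("x", "y")))
  expect_true(fl$in_stem)
  expect_equal(fl$arm, "5p")
  expect_true(fl$has_isomir)       # the (54, 76) read is within +/- 3 of both ends
  expect_true(fl$has_counterpart)  # the (94, 116) read sits in the 3' arm
  # read alone in one arm
  fl2 <- apply_structural_filters(st, 53L, 75L, NULL)
  expect_true(fl2$in_stem)
  expect_false(fl2$has_isomir)
  expect_false(fl2$has_counterpart)
  # read spanning the loop is discarded as a prediction error
  fl3 <- apply_structural_filters(st, 72L, 94L, NULL)
  expect_false(fl3$in_stem)
})

test_that("the novel pipeline recovers planted hairpins and rejects decoys", {
  spec <- simulation_spec(n_hairpins = 6, seed = 217)
  ref <- generate_reference(spec)
  regions <- generate_regions(spec)
  pl <- plant_novel_hairpins(spec, regions, n_novel = 3, n_decoys = 3, ref = ref)
  lib <- read_library(data.frame(read_id = sprintf("n%d", seq_len(nrow(pl$reads))),
                                 sequence = pl$reads$sequence,
                                 count = pl$reads$count), "s1")
  cands <- discover_novel(lib, pl$regions)
  expect_equal(nrow(cands), 3)
  expect_equal(cands$name, sprintf("jnu-pat-hsa-%d", 1:3))
  planted <- pl$truth[pl$truth$kind == "novel", ]
  expect_setequal(cands$mature_sequence, planted$mature_sequence)
  # no decoy locus contributes a candidate
  for (i in which(pl$truth$kind == "decoy")) {
    expect_false(any(cands$chrom == pl$truth$chrom[i] &
                       cands$start < pl$truth$end[i] &
                       cands$end > pl$truth$start[i]))
  }
  # each family carries the planted isomiR and counterpart
  expect_true(all(cands$n_members == 3))
  expect_true(all(cands$has_isomir))
  expect_true(all(cands$has_counterpart))
})

test_that("raising thresholds never increases the candidate count", {
  spec <- simulation_spec(n_hairpins = 6, seed = 219)
  ref <- generate_reference(spec)
  regions <- generate_regions(spec)
  pl <- plant_novel_hairpins(spec, regions, n_novel = 2, n_decoys = 1, ref = ref)
  lib <- read_library(data.frame(read_id = sprintf("n%d", seq_len(nrow(pl$reads))),
                                 sequence = pl$reads$sequence,
                                 count = pl$reads$count), "s1")
  n_default <- nrow(discover_novel(lib, pl$regions))
  n_high_freq <- nrow(discover_novel(lib, pl$regions,
                                     pipeline_config(novel_min_freq = 50L)))
  n_strict_stem <- nrow(discover_novel(lib, pl$regions,
                                       pipeline_config(stem_min_pairing = 0.99)))
  expect_lte(n_high_freq, n_default)
  expect_lte(n_strict_stem, n_default)
})

test_that("cross-sample grouping pools provenance and picks the abundant mature", {
  spec <- simulation_spec(n_hairpins = 6, seed = 223)
  ref <- generate_reference(spec)
  regions <- generate_regions(spec)
  pl <- plant_novel_hairpins(spec, regions, n_novel = 1, n_decoys = 0, ref = ref)
  mk <- function(id) read_library(
    data.frame(read_id = sprintf("n%d", seq_len(nrow(pl$reads))),
               sequence = pl$reads$sequence, count = pl$reads$count), id)
  cands <- discover_novel(list(a = mk("a"), b = mk("b")), pl$regions)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$sample_ids, "a,b")
  # the mature is the highest-count member (12 per sample, summed)
  expect_equal(cands$mature_count, 24L)
  expect_equal(cands$mature_sequence,
               pl$truth$mature_sequence[pl$truth$kind == "novel"])
})
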