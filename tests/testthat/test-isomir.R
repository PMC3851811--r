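test_that("hairpin alignment reports exact placements with coordinates", {
  ref <- tiny_ref()
  hp <- ref$hairpins$sequence[1]
  read <- substr(hp, 6, 27)
  al <- align_to_hairpins(make_lib(read), ref, 2)
  expect_equal(nrow(al), 1)
  expect_equal(al$start, 5L)
  expect_equal(al$end, 27L)
  expect_equal(al$mismatches, 0L)
  expect_equal(al$hairpin_id, "syn-mir-1")
})

test_that("alignment keeps only the best-mismatch stratum but all equal hits", {
  ref <- tiny_ref()
  # read exact on hairpin 1, 1 mm from a window of hairpin 2: only hairpin 1
  r <- substr(ref$hairpins$sequence[1], 4, 25)
  ref2 <- ref
  w <- substr(ref$hairpins$sequence[2], 4, 25)
  ref2$hairpins$sequence[2] <- paste0(substr(r, 1, 21),
                                      if (substr(r, 22, 22) == "A") "C" else "A",
                                      substr(ref$hairpins$sequence[2], 23, 1000))
  al <- align_to_hairpins(make_lib(r), ref2, 2)
  expect_equal(unique(al$hairpin_id), "syn-mir-1")
  expect_true(all(al$mismatches == 0))

  # read exact on both hairpins: both placements reported
  ref3 <- ref
  ref3$hairpins$sequence[2] <- paste0(r, substr(ref$hairpins$sequence[2], 23, 1000))
  al3 <- align_to_hairpins(make_lib(r), ref3, 2)
  expect_setequal(al3$hairpin_id, c("syn-mir-1", "syn-mir-2"))
})

test_that("alignment agrees with the exhaustive oracle on random fixtures", {
  withr::local_seed(99)
  for (i in 1:10) {
    hp <- data.frame(hairpin_id = sprintf("h%d", 1:4),
                     sequence = vapply(sample(60:90, 4, replace = TRUE),
                                       rand_seq, character(1)))
    ref <- reference_set(hp, data.frame(name = character(), sequence = character(),
                                        hairpin_id = character(), start = integer(),
                                        end = integer(), arm = character(),
                                        located = logical()),
                         class_dbs = list())
    read <- substr(hp$sequence[sample(4, 1)], 10, 31)
    al <- align_to_hairpins(make_lib(read), ref, 2)
    want <- oracle_hits(read, hp$sequence, 2, both_strands = FALSE)
    want <- want[want$mm == min(want$mm), ]
    expect_equal(nrow(al), nrow(want))
    expect_setequal(paste(al$hairpin_id, al$start, al$mismatches),
                    paste(hp$hairpin_id[want$subject], want$start, want$mm))
  }
})

test_that("family membership uses offsets and the overlap rule", {
  ref <- tiny_ref()
  hp <- ref$hairpins$sequence[1]
  m <- ref$matures[1, ]                                 # [3, 25) on hairpin 1
  exact <- substr(hp, m$start + 1, m$end)
  shifted <- substr(hp, m$start - 1, m$end - 1)         # offsets (-2, -1)
  loopy <- substr(hp, 27, 48)                           # centred on the loop
  lib <- make_lib(c(exact, shifted, loopy), c(10, 4, 3))
  fams <- build_families(align_to_hairpins(lib, ref, 2), ref)
  f <- fams[["syn-miR-1-5p"]]
  expect_equal(nrow(f$members), 2)
  expect_equal(f$members$offset5[f$members$sequence == exact], 0L)
  expect_equal(f$members$offset3[f$members$sequence == exact], 0L)
  expect_equal(f$members$offset5[f$members$sequence == shifted], -2L)
  expect_equal(f$members$offset3[f$members$sequence == shifted], -1L)
  other <- attr(fams, "hairpin_other")
  expect_equal(other$sequence, loopy)
})

test_that("family mass is conserved on uniquely-mapping fixtures", {
  spec <- simulation_spec(n_hairpins = 12, total_reads = 6000, seed = 71,
                          class_proportions = c(miRNA = 1))
  ref <- generate_reference(spec)
  g <- generate_reads(spec, ref)
  al <- align_to_hairpins(g$library, ref, 2)
  fams <- build_families(al, ref)
  fam_mass <- sum(unlist(lapply(fams, function(f) sum(f$members$count))))
  other_mass <- sum(attr(fams, "hairpin_other")$count)
  aligned_mass <- sum(g$library$reads$count[g$library$reads$sequence %in% al$sequence])
  expect_equal(fam_mass + other_mass, aligned_mass)
  expect_equal(aligned_mass, g$library$total_reads)  # all planted reads align
})

test_that("dominant selection maximises count with canonical-friendly tie-breaks", {
  fam <- list(members = data.frame(
    sequence = c("AAAA", "CCCC", "GGGG"), count = c(10L, 7L, 7L),
    offset5 = c(1L, 0L, 0L), offset3 = c(1L, 0L, 1L)))
  expect_equal(select_dominant(fam)$sequence, "AAAA")

  tie <- list(members = data.frame(
    sequence = c("CANON", "SHIFT"), count = c(5L, 5L),
    offset5 = c(0L, -1L), offset3 = c(0L, 0L)))
  expect_equal(select_dominant(tie)$sequence, "CANON")

  single <- list(members = data.frame(sequence = "AA", count = 1L,
                                      offset5 = 0L, offset3 = 0L))
  expect_equal(select_dominant(single)$sequence, "AA")
  expect_error(select_dominant(list(members = NULL)), "empty")
})

test_that("abundant profile dominates the reference profile row-wise", {
  spec <- simulation_spec(n_hairpins = 20, total_reads = 10000, seed = 73,
                          class_proportions = c(miRNA = 1))
  ref <- generate_reference(spec)
  g <- generate_reads(spec, ref)
  fams <- build_families(align_to_hairpins(g$library, ref, 2), ref)
  ab <- abundant_profile(fams, g$library)
  rp <- reference_profile(g$library, ref)
  expect_true(all(rp$rows$name %in% ab$rows$name))
  m <- match(rp$rows$name, ab$rows$name)
  expect_true(all(ab$rows$count[m] >= rp$rows$count))
  # excess rows = planted miRNAs whose canonical sequence got no exact read
  tm <- g$truth$members
  has_canon <- vapply(split(tm, tm$mirna), function(x) {
    canon <- ref$matures$sequence[ref$matures$name == x$mirna[1]]
    any(x$sequence == canon)
  }, logical(1))
  expect_equal(nrow(ab$rows) - nrow(rp$rows), sum(!has_canon))
  # miRNA with no aligned reads is absent
  expect_false(any(!names(fams) %in% ab$rows$name))
})

test_that("group comparison implements the YES/NO/low/non-uniform rules", {
  ref <- tiny_ref()
  m1 <- ref$matures[1, ]
  hp <- ref$hairpins$sequence[1]
  canon <- m1$sequence
  shift <- substr(hp, m1$start + 2, m1$end + 1)   # offsets (+1,+1)
  mk_sample <- function(seqs, counts, id) {
    lib <- make_lib(seqs, counts, id)
    fams <- build_families(align_to_hairpins(lib, ref, 2), ref)
    list(fams = fams, rp = reference_profile(lib, ref), lib = lib)
  }
  s1 <- mk_sample(c(canon, shift), c(10, 4), "a")   # dominant = canonical
  s2 <- mk_sample(c(canon, shift), c(8, 3), "b")
  cmp <- compare_profiles(list(a = s1$fams, b = s2$fams),
                          list(a = s1$rp, b = s2$rp), ref)
  rec <- cmp$records
  expect_equal(rec$status[rec$miRNA == "syn-miR-1-5p"], "YES")
  expect_equal(rec$status[rec$miRNA == "syn-miR-2-5p"], "low_expression")

  # dominant flips between samples -> non_uniform
  s2b <- mk_sample(c(canon, shift), c(3, 9), "b")
  cmp2 <- compare_profiles(list(a = s1$fams, b = s2b$fams),
                           list(a = s1$rp, b = s2b$rp), ref)
  expect_equal(cmp2$records$status[cmp2$records$miRNA == "syn-miR-1-5p"],
               "non_uniform")

  # both samples dominated by the shifted isomiR -> NO
  s1c <- mk_sample(c(canon, shift), c(2, 9), "a")
  cmp3 <- compare_profiles(list(a = s1c$fams, b = s2b$fams),
                           list(a = s1c$rp, b = s2b$rp), ref)
  expect_equal(cmp3$records$status[cmp3$records$miRNA == "syn-miR-1-5p"], "NO")
  tl <- cmp3$tallies
  expect_equal(unname(tl["n_not_considered"]), unname(tl["n_low"] + tl["n_nonuniform"]))
  expect_error(compare_profiles(list(), list(), ref), "zero samples")
})

test_that("isomiR count distribution tabulates members and flags unknowns", {
  ref <- tiny_ref()
  hp <- ref$hairpins$sequence[1]
  m <- ref$matures[1, ]
  seqs <- c(substr(hp, m$start + 1, m$end),
            substr(hp, m$start, m$end),
            substr(hp, m$start + 1, m$end + 1))
  fams <- build_families(align_to_hairpins(make_lib(seqs, c(5, 3, 2)), ref, 2), ref)
  expect_warning(
    tab <- isomir_count_distribution(fams, c("syn-miR-1-5p", "nope")),
    "unknown")
  expect_equal(tab$n_isomirs[tab$miRNA == "syn-miR-1-5p"], 3L)
  expect_equal(tab$n_isomirs[tab$miRNA == "nope"], 0L)
  expect_false(tab$known[tab$miRNA == "nope"])
})

test_that("planted expression and isomiR counts correlate positively", {
  spec <- simulation_spec(n_hairpins = 30, total_reads = 20000, seed = 77,
                          class_proportions = c(miRNA = 1))
  ref <- generate_reference(spec)
  g <- generate_reads(spec, ref)
  fams <- build_families(align_to_hairpins(g$library, ref, 2), ref)
  tab <- isomir_count_distribution(fams, names(fams))
  planted <- g$truth$mirna
  m <- merge(tab, planted, by.x = "miRNA", by.y = "mirna")
  expect_gt(cor(m$n_isomirs, m$count, method = "spearman"), 0)
})
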