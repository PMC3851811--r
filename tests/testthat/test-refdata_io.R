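test_that("identical FASTA records collapse with counts summed", {
  p <- write_tmp_fasta(c("a", "b", "c"), rep("AAAA", 3))
  lib <- read_fastq_or_fasta(p, "fasta")
  expect_equal(nrow(lib$reads), 1)
  expect_equal(lib$reads$count, 3)
  expect_equal(lib$total_reads, 3)
})

test_that("collapsed FASTA count dialects are parsed and round-trip", {
  p <- write_tmp_fasta(c("r1_x25", "r2_x3"),
                       c("TAGCTTATCAGACTGATGTTGA", "ACGTACGTACGTACGT"))
  lib <- read_fastq_or_fasta(p, "fasta_collapsed")
  expect_equal(lib$reads$count, c(25L, 3L))
  expect_equal(lib$total_reads, 28L)

  p2 <- write_tmp_fasta("r1 count=7", "ACGTACGTACGTAAAA")
  lib2 <- read_fastq_or_fasta(p2, "fasta_collapsed")
  expect_equal(lib2$reads$count, 7L)

  # writer -> reader round-trip, both dialects
  for (dialect in c("xN", "count")) {
    out <- withr::local_tempfile(fileext = ".fa")
    write_collapsed_fasta(lib, out, dialect = dialect)
    back <- read_fastq_or_fasta(out, "fasta_collapsed", sample_id = lib$sample_id)
    expect_equal(back$reads, lib$reads)
    expect_equal(back$total_reads, lib$total_reads)
  }
})

test_that("collapsed FASTA without a count suffix is an error, plain FASTA is not", {
  p <- write_tmp_fasta("r1", "ACGT")
  expect_error(read_fastq_or_fasta(p, "fasta_collapsed"), "count")
  expect_equal(read_fastq_or_fasta(p, "fasta")$reads$count, 1L)
})

test_that("U is normalised to T on ingestion and outputs are DNA", {
  p <- write_tmp_fasta("r1", "UAGCUUAUCAGACUGAUGUUGA")
  lib <- read_fastq_or_fasta(p, "fasta")
  expect_equal(lib$reads$sequence, "TAGCTTATCAGACTGATGTTGA")
})

test_that("empty input yields an empty library, not an error", {
  p <- withr::local_tempfile(fileext = ".fa")
  file.create(p)
  lib <- read_fastq_or_fasta(p, "fasta")
  expect_equal(lib$total_reads, 0L)
  expect_equal(nrow(lib$reads), 0L)
})

test_that("malformed FASTQ records raise parse errors naming the line", {
  p <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIII"), p)   # quality too short
  expect_error(read_fastq_or_fasta(p, "fastq"), "line 4.*quality length")
  writeLines(c("r1", "ACGT", "+", "IIII"), p)          # missing @
  expect_error(read_fastq_or_fasta(p, "fastq"), "line 1")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), p)  # truncated
  expect_error(read_fastq_or_fasta(p, "fastq"), "line 5")
  writeLines(c("@r1", "ACGT", "+", "IIII"), p)
  lib <- read_fastq_or_fasta(p, "fastq")
  expect_equal(lib$reads$sequence, "ACGT")
})

test_that("miRBase-style matures are located on hairpins with arms assigned", {
  ref0 <- tiny_ref()
  hp_path <- write_tmp_fasta(ref0$hairpins$hairpin_id, ref0$hairpins$sequence)
  mat_path <- write_tmp_fasta(ref0$matures$name, ref0$matures$sequence)
  rs <- read_mirbase_fastas(mat_path, hp_path)
  expect_equal(nrow(rs$hairpins), 2)
  expect_equal(sum(rs$matures$located), 4)
  expect_equal(attr(rs, "unlocated"), character(0))
  # coordinate consistency: hairpin[start:end) == mature sequence
  hseq <- rs$hairpins$sequence[match(rs$matures$hairpin_id, rs$hairpins$hairpin_id)]
  expect_equal(substr(hseq, rs$matures$start + 1, rs$matures$end),
               rs$matures$sequence)
  expect_equal(rs$matures$arm, ref0$matures$arm)
})

test_that("unlocatable and ambiguous matures are handled as specified", {
  hp_path <- write_tmp_fasta("syn-mir-1", "ACGTTTTTTTTTTTTTTTTTTTTTTT")
  mat_path <- write_tmp_fasta(c("syn-miR-1-5p", "syn-miR-9-5p"),
                              c("ACGT", "GGGG"))
  rs <- read_mirbase_fastas(mat_path, hp_path)
  expect_equal(attr(rs, "unlocated"), "syn-miR-9-5p")
  expect_true(rs$matures$located[rs$matures$name == "syn-miR-1-5p"])
  expect_equal(rs$matures$start[1], 0L)
  expect_equal(rs$matures$arm[1], "5p")

  # same mature occurring twice on its hairpin is ambiguous
  hp2 <- write_tmp_fasta("syn-mir-1", "ACGTTTTTTTTTACGTTTTTTTTT")
  expect_error(read_mirbase_fastas(mat_path, hp2), "ambiguous")
})

test_that("arm fallback uses hairpin halves for unsuffixed names", {
  expect_equal(mirnome:::assign_arm("x", 0L, 20L, 60L), "5p")
  expect_equal(mirnome:::assign_arm("x", 40L, 60L, 60L), "3p")
  expect_equal(mirnome:::assign_arm("x", 25L, 47L, 60L), "3p")  # midpoint 36 > 30
  expect_equal(mirnome:::assign_arm("x", 13L, 35L, 60L), "5p")  # midpoint 24 < 30
})

test_that("profile TSV writes fixed-precision TPM and round-trips exactly", {
  prof <- expression_profile("s1", "reference",
                             data.frame(name = "syn-miR-1-5p", count = 50L),
                             1000000)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, p)
  lines <- readLines(p)
  expect_match(lines[3], "50\t50.000000")
  back <- read_profile_tsv(p)
  expect_equal(back$s1$rows, prof$rows)
  expect_equal(back$s1$library_total, prof$library_total)

  # empty profile -> header-only table
  empty <- expression_profile("s1", "reference", NULL, 100)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(empty, p2)
  expect_length(readLines(p2), 2)  # comment + header
  expect_equal(nrow(read_profile_tsv(p2)$s1$rows), 0)
})

test_that("region sets validate coordinates against the genome", {
  genome <- c(chr1 = "ACGTACGTACGTACGTACGT")
  rs <- genomic_region_set(data.frame(chrom = "chr1", start = 0L, end = 10L,
                                      region_type = "intronic", strand = "+"),
                           genome)
  expect_equal(mirnome:::region_sequences(rs), "ACGTACGTAC")
  expect_error(genomic_region_set(data.frame(chrom = "chr2", start = 0L, end = 5L),
                                  genome), "missing chromosome")
  expect_error(genomic_region_set(data.frame(chrom = "chr1", start = 0L, end = 50L),
                                  genome), "past end")
})
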