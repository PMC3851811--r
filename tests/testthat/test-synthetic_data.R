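test_that("reference generation is deterministic and structurally sound", {
  spec <- simulation_spec(n_hairpins = 10, seed = 101)
  ref1 <- generate_reference(spec)
  ref2 <- generate_reference(spec)
  expect_identical(ref1, ref2)
  expect_equal(nrow(ref1$hairpins), 10)
  expect_equal(nrow(ref1$matures), 20)
  expect_true(all(ref1$matures$located))
  # coordinate consistency and fold acceptance of every hairpin
  hseq <- ref1$hairpins$sequence[match(ref1$matures$hairpin_id,
                                       ref1$hairpins$hairpin_id)]
  expect_equal(substr(hseq, ref1$matures$start + 1, ref1$matures$end),
               ref1$matures$sequence)
  for (hp in ref1$hairpins$sequence) {
    expect_true(fold_hairpin(hp)$accepted)
  }
  # empty reference
  ref0 <- generate_reference(simulation_spec(n_hairpins = 0, seed = 1))
  expect_equal(nrow(ref0$hairpins), 0)
})

test_that("read generation conserves mass and honours the seed", {
  spec <- simulation_spec(n_hairpins = 12, total_reads = 5000, seed = 103)
  ref <- generate_reference(spec)
  regions <- generate_regions(spec)
  g1 <- generate_reads(spec, ref, regions = regions)
  g2 <- generate_reads(spec, ref, regions = regions)
  expect_identical(g1, g2)
  expect_equal(sum(g1$truth$class_mass), g1$library$total_reads)
  expect_equal(unname(g1$library$total_reads), 5000)
  # zero reads -> empty library and truth
  g0 <- generate_reads(simulation_spec(n_hairpins = 2, total_reads = 0, seed = 1),
                       ref, regions = regions)
  expect_equal(g0$library$total_reads, 0L)
  expect_equal(nrow(g0$truth$read_truth), 0)
})

test_that("class proportions are respected at sampling accuracy", {
  spec <- simulation_spec(n_hairpins = 20, total_reads = 1e5, seed = 107)
  ref <- generate_reference(spec)
  regions <- generate_regions(spec)
  g <- generate_reads(spec, ref, regions = regions)
  frac <- g$truth$class_mass / sum(g$truth$class_mass)
  expect_equal(unname(frac["miRNA"]), 0.74, tolerance = 0.01 / 0.74)
})

test_that("forcing the canonical dominant yields all-YES truth labels", {
  spec <- simulation_spec(n_hairpins = 10, total_reads = 4000, seed = 109,
                          dominant_is_reference_prob = 1,
                          class_proportions = c(miRNA = 1))
  ref <- generate_reference(spec)
  g <- generate_reads(spec, ref)
  expect_true(all(g$truth$mirna$label == "YES"))
  expect_true(all(g$truth$mirna$dominant_sequence == g$truth$mirna$canonical))
})

test_that("planted dominant members hold a two-fold margin", {
  spec <- simulation_spec(n_hairpins = 15, total_reads = 10000, seed = 113,
                          class_proportions = c(miRNA = 1))
  ref <- generate_reference(spec)
  g <- generate_reads(spec, ref)
  for (mb in split(g$truth$members, g$truth$members$mirna)) {
    if (nrow(mb) < 2) next
    dom <- mb$count[mb$is_dominant]
    expect_true(all(2L * mb$count[!mb$is_dominant] <= dom))
  }
})

test_that("length modes set the modal read length (22 normal, 17 degraded)", {
  spec <- simulation_spec(n_hairpins = 25, total_reads = 12000, seed = 127)
  ref <- generate_reference(spec)
  regions <- generate_regions(spec)
  g <- generate_reads(spec, ref, regions = regions)
  expect_equal(length_distribution(g$library)$modal_length, 22L)
  spec$length_mode <- "degraded_17"
  gd <- generate_reads(spec, ref, regions = regions)
  expect_equal(length_distribution(gd$library)$modal_length, 17L)
  expect_equal(sum(gd$truth$class_mass), gd$library$total_reads)  # degradation conserves mass
})

test_that("reference FASTA output is byte-identical across runs with one seed", {
  spec <- simulation_spec(n_hairpins = 6, seed = 131)
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  for (p in c(p1, p2)) {
    ref <- generate_reference(spec)
    writeLines(as.vector(rbind(paste0(">", ref$hairpins$hairpin_id),
                               ref$hairpins$sequence)), p)
  }
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("planting novel hairpins modifies only the chosen loci", {
  spec <- simulation_spec(n_hairpins = 6, seed = 137)
  ref <- generate_reference(spec)
  regions <- generate_regions(spec)
  pl0 <- plant_novel_hairpins(spec, regions, n_novel = 0, n_decoys = 0, ref = ref)
  expect_identical(pl0$regions, regions)
  expect_equal(nrow(pl0$reads), 0)

  pl <- plant_novel_hairpins(spec, regions, n_novel = 3, n_decoys = 2, ref = ref)
  expect_equal(sum(pl$truth$kind == "novel"), 3)
  expect_equal(sum(pl$truth$kind == "decoy"), 2)
  # precursors are embedded verbatim at the recorded genomic coordinates
  for (i in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[i, ]
    expect_equal(substr(pl$regions$genome[[tr$chrom]], tr$start + 1, tr$end),
                 tr$precursor)
  }
  # planted reads carry candidate-level frequencies
  expect_true(all(pl$reads$count >= 5))

  # intervals too short are refused with the interval named
  small <- generate_regions(spec, chrom_length = 1200, region_length = 100)
  expect_error(plant_novel_hairpins(spec, small, n_novel = 1, ref = ref),
               "intronic interval")
})

test_that("cohort truth labels plant all four comparison outcomes", {
  spec <- simulation_spec(n_hairpins = 30, total_reads = 8000, seed = 139)
  ref <- generate_reference(spec)
  regions <- generate_regions(spec)
  co <- generate_cohort(spec, ref, regions = regions,
                        groups = list(g1 = c("a", "b")),
                        n_low = 2, n_nonuniform = 2, seed = 139)
  expect_setequal(names(co$libraries), c("a", "b"))
  tab <- table(co$group_truth$label)
  expect_gte(tab[["YES"]], 1)
  expect_gte(tab[["NO"]], 1)
  expect_gte(tab[["non_uniform"]], 2)
  expect_gte(tab[["low_expression"]], 2)
})
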