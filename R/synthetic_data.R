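#' Simulation specification
#'
#' Parameters of the synthetic small RNA-seq generator. The defaults emulate
#' the statistical structure of deep-sequenced PBMC libraries: miRNAs
#' dominate the read mass (74%), the read length distribution peaks at 22 nt
#' for intact libraries (or at 17 nt under the degraded, patient-like mode),
#' per-miRNA expression spans several orders of magnitude, each expressed
#' miRNA carries an isomiR family whose planted dominant member has at least
#' a two-fold count margin, and the dominant member equals the canonical
#' mature sequence for about a third of miRNAs (so roughly 68% are
#' dominated by a non-reference isomiR).
#'
#' @param n_hairpins number of synthetic pre-miRNA hairpins.
#' @param arm_length stem arm length (nt) of generated hairpins.
#' @param loop_length_range hairpin loop length range (nt).
#' @param arm_mutation_rate per-base substitution rate applied to the 3' arm
#'   relative to the perfect reverse complement of the 5' arm.
#' @param mature_length_range,mature_length_weights mature length support and
#'   probability weights (mode 22 nt).
#' @param isomir_offset_range isomiR 5'/3' offsets are drawn uniformly from
#'   `[-range, range]^2` unless `isomir_offset_distribution` is given.
#' @param isomir_offset_distribution optional data.frame (`offset5`,
#'   `offset3`, `prob`) overriding the uniform table.
#' @param dominant_is_reference_prob probability that a miRNA's planted
#'   dominant isomiR is the canonical (offset 0,0) form.
#' @param class_proportions probability vector over [ALL_READ_CLASSES]
#'   (must sum to 1).
#' @param length_mode `"normal_like_22"` or `"degraded_17"`; degradation is
#'   modelled as 3' truncation of a fraction of reads down to a length drawn
#'   geometrically at or below the degradation attractor.
#' @param degraded_fraction,degraded_target_length,degraded_geom_p truncation
#'   parameters: the affected fraction, the modal truncated length, and the
#'   geometric decay of further shortening below it.
#' @param expression_sdlog log-normal sd of per-miRNA expression weights.
#' @param n_species_per_class distinct read species per contaminant class.
#' @param n_db_records records per non-miRNA class database.
#' @param total_reads total read mass of a generated library.
#' @param fixture_mode deterministic largest-remainder counts instead of
#'   multinomial sampling (used by unit fixtures).
#' @param seed integer RNG seed; every generator call is reproducible from it.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_hairpins = 40L,
                            arm_length = 30L,
                            loop_length_range = c(8L, 15L),
                            arm_mutation_rate = 0.10,
                            mature_length_range = c(20L, 24L),
                            mature_length_weights = c(0.04, 0.15, 0.62, 0.15, 0.04),
                            isomir_offset_range = 2L,
                            isomir_offset_distribution = NULL,
                            dominant_is_reference_prob = 0.32,
                            class_proportions = c(miRNA = 0.74, sn_sno = 0.02,
                                                  lincRNA = 0.03, tRNA = 0.03,
                                                  rRNA = 0.01, mRNA = 0.04,
                                                  misc = 0.02,
                                                  unannotated_genomic = 0.05,
                                                  unmatched = 0.06),
                            length_mode = c("normal_like_22", "degraded_17"),
                            degraded_fraction = 0.65,
                            degraded_target_length = 17L,
                            degraded_geom_p = 0.5,
                            expression_sdlog = 1.5,
                            n_species_per_class = 40L,
                            n_db_records = 12L,
                            total_reads = 20000L,
                            fixture_mode = FALSE,
                            seed = 1L) {
  length_mode <- match.arg(length_mode)
  stopifnot(n_hairpins >= 0, arm_length >= 16,
            length(mature_length_weights) == diff(mature_length_range) + 1)
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  if (!all(names(class_proportions) %in% ALL_READ_CLASSES)) {
    stop("unknown class in class_proportions", call. = FALSE)
  }
  if (is.null(isomir_offset_distribution)) {
    r <- isomir_offset_range
    grid <- expand.grid(offset5 = -r:r, offset3 = -r:r)
    isomir_offset_distribution <- data.frame(grid, prob = 1 / nrow(grid))
  }
  if (abs(sum(isomir_offset_distribution$prob) - 1) > 1e-9) {
    stop("isomir offset distribution must sum to 1", call. = FALSE)
  }
  if (max(abs(c(isomir_offset_distribution$offset5,
                isomir_offset_distribution$offset3))) > 3) {
    stop("isomiR offsets must lie in [-3, 3]", call. = FALSE)
  }
  structure(list(n_hairpins = as.integer(n_hairpins),
                 arm_length = as.integer(arm_length),
                 loop_length_range = as.integer(loop_length_range),
                 arm_mutation_rate = arm_mutation_rate,
                 mature_length_range = as.integer(mature_length_range),
                 mature_length_weights = mature_length_weights,
                 isomir_offset_distribution = isomir_offset_distribution,
                 dominant_is_reference_prob = dominant_is_reference_prob,
                 class_proportions = class_proportions,
                 length_mode = length_mode,
                 degraded_fraction = degraded_fraction,
                 degraded_target_length = as.integer(degraded_target_length),
                 degraded_geom_p = degraded_geom_p,
                 expression_sdlog = expression_sdlog,
                 n_species_per_class = as.integer(n_species_per_class),
                 n_db_records = as.integer(n_db_records),
                 total_reads = as.integer(total_reads),
                 fixture_mode = isTRUE(fixture_mode),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# typical record lengths of the non-miRNA class databases (nt)
CLASS_DB_LENGTHS <- c(sn_sno = 130L, lincRNA = 600L, tRNA = 75L,
                      rRNA = 1500L, mRNA = 800L, misc = 200L)

# largest-remainder integer apportionment (fixture mode)
round_counts <- function(total, p) {
  if (sum(p) == 0) return(rep(0L, length(p)))
  raw <- total * p / sum(p)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

draw_counts <- function(total, p, fixture) {
  if (total == 0 || sum(p) == 0) return(rep(0L, length(p)))
  if (fixture) round_counts(total, p) else as.integer(rmultinom(1, total, p))
}

mutate_bases <- function(seq, rate = NULL, n_mm = NULL) {
  ch <- strsplit(seq, "")[[1]]
  idx <- if (!is.null(n_mm)) {
    if (n_mm == 0) integer(0) else sample.int(length(ch), min(n_mm, length(ch)))
  } else {
    which(runif(length(ch)) < rate)
  }
  for (i in idx) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Generate a synthetic reference set
#'
#' Hairpins are built as stem-loops: a random 5' arm, a loop (drawn A/C-rich
#' so it cannot base-pair internally and the optimal fold has a single clean
#' terminal loop), and the reverse complement of the arm with substitutions
#' at `arm_mutation_rate` as the 3' arm. One mature is planted per arm, at
#' least 3 nt away from the hairpin ends and the loop margins so that every
#' isomiR offset stays on the hairpin. Each hairpin is checked against the
#' built-in folding engine's hairpin criteria and redrawn if it fails, so
#' generated precursors are guaranteed to fold. Class databases for the
#' non-miRNA classes are random records of class-typical lengths; the miRNA
#' class database is the hairpin set itself (so 5'/3'-extended isomiRs still
#' annotate as miRNA).
#'
#' @param spec a [simulation_spec()].
#' @param cfg a [pipeline_config()] (hairpin acceptance criteria).
#' @return A [reference_set()] (no regions).
#' @export
generate_reference <- function(spec, cfg = pipeline_config()) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    hp <- character(spec$n_hairpins)
    mrows <- list()
    seen_matures <- character(0)
    lens <- spec$mature_length_range[1]:spec$mature_length_range[2]
    for (i in seq_len(spec$n_hairpins)) {
      for (try in 1:50) {
        arm <- rand_dna(1, spec$arm_length)
        loop_len <- sample(spec$loop_length_range[1]:spec$loop_length_range[2], 1)
        loop <- rand_dna(1, loop_len, prob = c(0.45, 0.45, 0.05, 0.05))
        arm3 <- mutate_bases(revcomp(arm), rate = spec$arm_mutation_rate)
        hairpin <- paste0(arm, loop, arm3)
        st <- fold_hairpin(hairpin, cfg)
        if (!st$accepted) next
        l5 <- sample(lens, 1, prob = spec$mature_length_weights)
        l3 <- sample(lens, 1, prob = spec$mature_length_weights)
        s5 <- 3L; e5 <- s5 + l5
        if (e5 > spec$arm_length - 3L) next
        s3 <- spec$arm_length + loop_len + 3L; e3 <- s3 + l3
        if (e3 > nchar(hairpin) - 3L) next
        m5 <- substr(hairpin, s5 + 1L, e5)
        m3 <- substr(hairpin, s3 + 1L, e3)
        if (m5 %in% seen_matures || m3 %in% seen_matures || m5 == m3) next
        # matures must locate uniquely on their hairpin
        if (length(gregexpr(m5, hairpin, fixed = TRUE)[[1]]) != 1 ||
            length(gregexpr(m3, hairpin, fixed = TRUE)[[1]]) != 1) next
        hp[i] <- hairpin
        hid <- sprintf("syn-mir-%d", i)
        mrows[[length(mrows) + 1]] <- data.frame(
          name = sprintf("syn-miR-%d-5p", i), sequence = m5, hairpin_id = hid,
          start = s5, end = e5, arm = "5p", located = TRUE,
          stringsAsFactors = FALSE)
        mrows[[length(mrows) + 1]] <- data.frame(
          name = sprintf("syn-miR-%d-3p", i), sequence = m3, hairpin_id = hid,
          start = s3, end = e3, arm = "3p", located = TRUE,
          stringsAsFactors = FALSE)
        seen_matures <- c(seen_matures, m5, m3)
        break
      }
      if (hp[i] == "") stop("failed to generate a folding hairpin", call. = FALSE)
    }
    hairpins <- data.frame(hairpin_id = sprintf("syn-mir-%d", seq_len(spec$n_hairpins)),
                           sequence = hp, stringsAsFactors = FALSE)
    matures <- if (length(mrows) > 0) do.call(rbind, mrows) else {
      data.frame(name = character(), sequence = character(),
                 hairpin_id = character(), start = integer(), end = integer(),
                 arm = character(), located = logical(),
                 stringsAsFactors = FALSE)
    }
    class_dbs <- list(miRNA = hairpins_as_db(hairpins))
    for (cls in names(CLASS_DB_LENGTHS)) {
      class_dbs[[cls]] <- data.frame(
        name = sprintf("%s-%d", cls, seq_len(spec$n_db_records)),
        sequence = rand_dna(spec$n_db_records, CLASS_DB_LENGTHS[[cls]]),
        stringsAsFactors = FALSE)
    }
    reference_set(hairpins, matures, class_dbs)
  })
}

#' Generate a synthetic genome with intergenic/intronic regions
#'
#' Random chromosomes tiled with alternating intergenic and intronic
#' intervals separated by gaps; the resulting region set is the matching
#' target for unannotated reads and the substrate for planting novel
#' hairpins.
#'
#' @param spec a [simulation_spec()].
#' @param n_chroms,chrom_length,region_length,gap layout parameters (nt).
#' @param seed RNG seed (derived from the spec's by default).
#' @return A [genomic_region_set()].
#' @export
generate_regions <- function(spec, n_chroms = 2L, chrom_length = 12000L,
                             region_length = 1000L, gap = 200L,
                             seed = spec$seed + 1L) {
  with_seed(seed, {
    genome <- rand_dna(n_chroms, chrom_length)
    names(genome) <- sprintf("chr%d", seq_len(n_chroms))
    rows <- list()
    for (ch in names(genome)) {
      starts <- seq(gap, chrom_length - region_length, by = region_length + gap)
      types <- rep(c("intergenic", "intronic"), length.out = length(starts))
      rows[[ch]] <- data.frame(chrom = ch, start = as.integer(starts),
                               end = as.integer(starts + region_length),
                               region_type = types, strand = "+",
                               stringsAsFactors = FALSE)
    }
    genomic_region_set(do.call(rbind, rows), genome)
  })
}

# draw read lengths with the library's modal structure
draw_lengths <- function(n, spec) {
  lens <- spec$mature_length_range[1]:spec$mature_length_range[2]
  sample(lens, n, replace = TRUE, prob = spec$mature_length_weights)
}

# family count allocation with a guaranteed >= 2x dominant margin
alloc_family <- function(total, k_other) {
  k_other <- min(k_other, max(0L, total - 2L))
  if (k_other <= 0 || total <= 3) {
    return(list(dom = total, others = integer(0)))
  }
  o <- rep(1L, k_other)
  s <- k_other
  target <- floor(0.4 * total)
  guard <- 0L
  while (s < target && guard < 10L * total) {
    i <- sample.int(k_other, 1)
    newmax <- max(max(o), o[i] + 1L)
    if (newmax <= (total - s - 1L) %/% 2L) {
      o[i] <- o[i] + 1L
      s <- s + 1L
    }
    guard <- guard + 1L
  }
  list(dom = total - s, others = o)
}

# rejection-sample distinct species sequences failing a veto predicate
sample_species <- function(n, gen_fun, veto_fun, max_tries = 25L) {
  out <- character(0)
  for (try in seq_len(max_tries)) {
    if (length(out) >= n) break
    cand <- setdiff(unique(gen_fun(n - length(out))), out)
    if (length(cand) == 0) next
    ok <- !veto_fun(cand)
    out <- c(out, cand[ok])
  }
  head(out, n)
}

# TRUE for candidates hitting any of the given subjects within max_mm
hits_any <- function(cands, subjects, max_mm, both_strands = TRUE) {
  if (length(subjects) == 0 || length(cands) == 0) {
    return(rep(FALSE, length(cands)))
  }
  h <- scan_best(cands, subjects, max_mm, both_strands = both_strands)
  !is.na(h$mm)
}

#' Generate a synthetic read library with planted truth
#'
#' Draws the per-class read mass from `class_proportions` (multinomially, or
#' by largest remainder in fixture mode), then populates each class:
#'
#' * miRNA reads are isomiR family members: per expressed mature, a planted
#'   dominant offset pair — canonical `(0,0)` with probability
#'   `dominant_is_reference_prob` — receives at least twice the count of any
#'   other member, so dominant recovery is deterministic.
#' * contaminant classes are substrings of their class database records with
#'   0-2 planted substitutions, rejection-sampled so they never hit an
#'   earlier elimination class within the mismatch tolerance.
#' * `unannotated_genomic` reads are exact substrings of the region
#'   sequences (either strand) hitting no class database.
#' * `unmatched` reads are random sequences absent from the genome and all
#'   databases.
#'
#' Under `length_mode = "degraded_17"` a fraction of all reads is 3'
#' truncated by a geometric bite, shifting the modal length from 22 to
#' 17 nt; truncation merges isomiR variants, so per-family dominant truth is
#' only guaranteed in normal mode (the truth table flags this).
#'
#' @param spec a [simulation_spec()].
#' @param ref a [generate_reference()] result (or any [reference_set()]).
#' @param sample_id sample label.
#' @param regions a [genomic_region_set()]; defaults to `ref$regions`.
#'   Required when the genomic or unmatched proportion is positive.
#' @param seed RNG seed, defaults to the spec's.
#' @param expression_weights optional named per-mature expression weights
#'   (cohort generation uses these to plant group structure).
#' @param dominant_pairs optional named list of `c(offset5, offset3)`
#'   overriding the per-mature dominant draw.
#' @param drop_matures mature names forced to zero expression.
#' @param extra_reads optional data.frame (`sequence`, `count`, `class`)
#'   appended verbatim (used for planted novel loci).
#' @return list with `library` (a [read_library()]) and `truth` (list with
#'   `class_mass`, `read_truth`, `mirna`, `members`, `degraded`).
#' @export
generate_reads <- function(spec, ref, sample_id = "sample1", regions = NULL,
                           seed = spec$seed, expression_weights = NULL,
                           dominant_pairs = NULL, drop_matures = character(),
                           extra_reads = NULL) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(ref, "reference_set"))
  regions <- regions %||% ref$regions
  p <- stats::setNames(numeric(length(ALL_READ_CLASSES)), ALL_READ_CLASSES)
  p[names(spec$class_proportions)] <- spec$class_proportions
  empty_truth <- list(class_mass = stats::setNames(numeric(0), character(0)),
                      read_truth = data.frame(sequence = character(),
                                              class = character(),
                                              ambiguous = logical()),
                      mirna = NULL, members = NULL,
                      degraded = spec$length_mode == "degraded_17")
  if (spec$total_reads == 0) {
    return(list(library = read_library(NULL, sample_id), truth = empty_truth))
  }
  mat <- ref$matures[ref$matures$located, , drop = FALSE]
  if (p["miRNA"] > 0 && nrow(mat) == 0) {
    stop("miRNA proportion > 0 but the reference has no located matures",
         call. = FALSE)
  }
  for (cls in setdiff(RNA_CLASSES, "miRNA")) {
    if (p[cls] > 0 &&
        (is.null(ref$class_dbs[[cls]]) || nrow(ref$class_dbs[[cls]]) == 0)) {
      stop("class proportion > 0 with empty database: ", cls, call. = FALSE)
    }
  }
  if ((p["unannotated_genomic"] > 0 || p["unmatched"] > 0) && is.null(regions)) {
    stop("genomic/unmatched proportions > 0 require a genomic_region_set",
         call. = FALSE)
  }

  with_seed(seed, {
    n_cls <- stats::setNames(draw_counts(spec$total_reads, p, spec$fixture_mode),
                             ALL_READ_CLASSES)
    rows <- list()       # data.frames: sequence, count, class
    mirna_truth <- list()
    member_truth <- list()
    seen <- new.env(hash = TRUE)
    remember <- function(seqs) for (s in seqs) assign(s, TRUE, envir = seen)
    known <- function(seqs) {
      vapply(seqs, function(s) exists(s, envir = seen, inherits = FALSE),
             logical(1), USE.NAMES = FALSE)
    }

    ## ---- miRNA isomiR families -------------------------------------------
    if (n_cls["miRNA"] > 0) {
      w <- expression_weights %||%
        stats::setNames(rlnorm(nrow(mat), 0, spec$expression_sdlog), mat$name)
      w <- w[mat$name]
      w[is.na(w)] <- 0
      w[mat$name %in% drop_matures] <- 0
      cnts <- draw_counts(n_cls[["miRNA"]], w, spec$fixture_mode)
      off_tab <- spec$isomir_offset_distribution
      for (i in which(cnts > 0)) {
        m <- mat[i, ]
        hseq <- ref$hairpins$sequence[ref$hairpins$hairpin_id == m$hairpin_id]
        dom_pair <- dominant_pairs[[m$name]] %||% {
          if (runif(1) < spec$dominant_is_reference_prob) c(0L, 0L) else {
            nz <- off_tab[off_tab$offset5 != 0 | off_tab$offset3 != 0, ]
            k <- sample.int(nrow(nz), 1, prob = nz$prob)
            c(nz$offset5[k], nz$offset3[k])
          }
        }
        # families of highly expressed miRNAs carry more detectable isomiRs
        k_max <- min(6L, max(1L, floor(log2(cnts[i]))))
        k_other <- sample.int(k_max, 1)
        al <- alloc_family(cnts[i], k_other)
        pairs <- matrix(dom_pair, nrow = 1)
        if (length(al$others) > 0) {
          pool <- off_tab[!(off_tab$offset5 == dom_pair[1] &
                            off_tab$offset3 == dom_pair[2]), ]
          ks <- sample.int(nrow(pool), min(length(al$others), nrow(pool)),
                           prob = pool$prob)
          pairs <- rbind(pairs, cbind(pool$offset5[ks], pool$offset3[ks]))
          al$others <- al$others[seq_len(length(ks))]
          al$dom <- cnts[i] - sum(al$others)
        }
        counts <- c(al$dom, al$others)
        seqs <- substr(rep(hseq, nrow(pairs)),
                       m$start + pairs[, 1] + 1L, m$end + pairs[, 2])
        # repeats can make two offset pairs spell the same sequence: merge
        # into the first occurrence (the dominant keeps its margin because
        # merging only ever adds to an earlier, larger member)
        agg <- tapply(counts, factor(seqs, levels = unique(seqs)), sum)
        useqs <- names(agg)
        ucounts <- as.integer(agg)
        # restore the dominant's 2x margin if merging inflated a lesser member
        while (length(ucounts) > 1 && any(2L * ucounts[-1] > ucounts[1])) {
          j <- which.max(ucounts[-1]) + 1L
          t <- as.integer(ceiling(ucounts[j] / 2))
          ucounts[1] <- ucounts[1] + t
          ucounts[j] <- ucounts[j] - t
        }
        drop0 <- ucounts == 0L
        useqs <- useqs[!drop0]
        ucounts <- ucounts[!drop0]
        first_idx <- match(useqs, seqs)
        member_truth[[length(member_truth) + 1]] <- data.frame(
          mirna = m$name, sequence = useqs, count = ucounts,
          offset5 = pairs[first_idx, 1], offset3 = pairs[first_idx, 2],
          is_dominant = seq_along(useqs) == 1, stringsAsFactors = FALSE)
        dom_seq <- seqs[1]
        mirna_truth[[length(mirna_truth) + 1]] <- data.frame(
          mirna = m$name, canonical = m$sequence, dominant_sequence = dom_seq,
          dominant_offset5 = dom_pair[1], dominant_offset3 = dom_pair[2],
          label = if (dom_seq == m$sequence) "YES" else "NO",
          count = cnts[i], stringsAsFactors = FALSE)
        rows[[length(rows) + 1]] <- data.frame(sequence = useqs,
                                               count = ucounts,
                                               class = "miRNA",
                                               stringsAsFactors = FALSE)
        remember(useqs)
      }
    }

    ## ---- contaminant classes ---------------------------------------------
    order_all <- RNA_CLASSES
    all_db_seqs <- unlist(lapply(ref$class_dbs, function(d) d$sequence),
                          use.names = FALSE)
    for (cls in setdiff(RNA_CLASSES, "miRNA")) {
      n_c <- n_cls[[cls]]
      if (n_c == 0) next
      db <- ref$class_dbs[[cls]]
      earlier <- order_all[seq_len(match(cls, order_all) - 1)]
      earlier_seqs <- unlist(lapply(ref$class_dbs[earlier],
                                    function(d) d$sequence), use.names = FALSE)
      gen <- function(k) {
        rec <- db$sequence[sample.int(nrow(db), k, replace = TRUE)]
        len <- pmin(draw_lengths(k, spec), nchar(rec))
        pos <- floor(runif(k) * (nchar(rec) - len + 1))
        s <- substr(rec, pos + 1, pos + len)
        n_mm <- sample(0:2, k, replace = TRUE, prob = c(0.6, 0.3, 0.1))
        vapply(seq_len(k), function(j) mutate_bases(s[j], n_mm = n_mm[j]),
               character(1))
      }
      k <- min(spec$n_species_per_class, n_c)
      species <- sample_species(k, gen, function(cands) {
        known(cands) | hits_any(cands, earlier_seqs, 2L)
      })
      if (length(species) == 0) {
        stop("could not generate read species for class ", cls, call. = FALSE)
      }
      sw <- rlnorm(length(species), 0, 1)
      sc <- draw_counts(n_c, sw, spec$fixture_mode)
      keep <- sc > 0
      rows[[length(rows) + 1]] <- data.frame(sequence = species[keep],
                                             count = sc[keep], class = cls,
                                             stringsAsFactors = FALSE)
      remember(species[keep])
    }

    ## ---- genomic-but-unannotated reads -----------------------------------
    if (n_cls[["unannotated_genomic"]] > 0) {
      rseqs <- region_sequences(regions)
      gen <- function(k) {
        ri <- sample.int(length(rseqs), k, replace = TRUE,
                         prob = nchar(rseqs))
        len <- pmin(draw_lengths(k, spec), nchar(rseqs)[ri])
        pos <- floor(runif(k) * (nchar(rseqs)[ri] - len + 1))
        s <- substr(rseqs[ri], pos + 1, pos + len)
        flip <- runif(k) < 0.5
        s[flip] <- revcomp(s[flip])
        s
      }
      species <- sample_species(min(spec$n_species_per_class,
                                    n_cls[["unannotated_genomic"]]),
                                gen, function(cands) {
        known(cands) | hits_any(cands, all_db_seqs, 2L)
      })
      sw <- rlnorm(length(species), 0, 1)
      sc <- draw_counts(n_cls[["unannotated_genomic"]], sw, spec$fixture_mode)
      keep <- sc > 0
      rows[[length(rows) + 1]] <- data.frame(sequence = species[keep],
                                             count = sc[keep],
                                             class = "unannotated_genomic",
                                             stringsAsFactors = FALSE)
      remember(species[keep])
    }

    ## ---- unmatched reads --------------------------------------------------
    if (n_cls[["unmatched"]] > 0) {
      genome_seqs <- if (!is.null(regions)) unname(regions$genome) else character(0)
      gen <- function(k) rand_dna(k, draw_lengths(k, spec))
      species <- sample_species(min(spec$n_species_per_class,
                                    n_cls[["unmatched"]]),
                                gen, function(cands) {
        known(cands) | hits_any(cands, all_db_seqs, 2L) |
          hits_any(cands, genome_seqs, 0L)
      })
      sw <- rlnorm(length(species), 0, 1)
      sc <- draw_counts(n_cls[["unmatched"]], sw, spec$fixture_mode)
      keep <- sc > 0
      rows[[length(rows) + 1]] <- data.frame(sequence = species[keep],
                                             count = sc[keep],
                                             class = "unmatched",
                                             stringsAsFactors = FALSE)
      remember(species[keep])
    }

    if (!is.null(extra_reads) && nrow(extra_reads) > 0) {
      rows[[length(rows) + 1]] <- extra_reads[, c("sequence", "count", "class")]
    }

    long <- if (length(rows) > 0) do.call(rbind, rows) else {
      data.frame(sequence = character(), count = integer(),
                 class = character(), stringsAsFactors = FALSE)
    }

    ## ---- degradation ------------------------------------------------------
    if (spec$length_mode == "degraded_17" && nrow(long) > 0) {
      long <- degrade_reads(long, spec)
    }

    ## ---- assemble ---------------------------------------------------------
    # per-sequence truth: merge collisions keep the earliest class
    key <- factor(long$sequence, levels = unique(long$sequence))
    agg_count <- as.integer(tapply(long$count, key, sum))
    cls_of <- tapply(long$class, key, function(x) {
      ux <- unique(x)
      ux[which.min(match(ux, ALL_READ_CLASSES))]
    })
    ambiguous <- as.logical(tapply(long$class, key,
                                   function(x) length(unique(x)) > 1))
    useq <- levels(key)
    lib <- read_library(data.frame(read_id = sprintf("r%06d", seq_along(useq)),
                                   sequence = useq, count = agg_count,
                                   stringsAsFactors = FALSE), sample_id)
    class_mass <- tapply(long$count, factor(long$class, levels = ALL_READ_CLASSES), sum)
    class_mass[is.na(class_mass)] <- 0
    truth <- list(class_mass = class_mass,
                  read_truth = data.frame(sequence = useq,
                                          class = as.character(cls_of),
                                          ambiguous = ambiguous,
                                          stringsAsFactors = FALSE),
                  mirna = if (length(mirna_truth) > 0) do.call(rbind, mirna_truth) else NULL,
                  members = if (length(member_truth) > 0) do.call(rbind, member_truth) else NULL,
                  degraded = spec$length_mode == "degraded_17")
    list(library = lib, truth = truth)
  })
}

# 3' truncation of a fraction of the read mass down to a geometrically
# distributed length at or below the degradation attractor (17 nt)
degrade_reads <- function(long, spec) {
  n_t <- rbinom(nrow(long), long$count, spec$degraded_fraction)
  keep <- data.frame(sequence = long$sequence, count = long$count - n_t,
                     class = long$class, stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(long)), n_t)
  if (length(idx) > 0) {
    len <- nchar(long$sequence[idx])
    target <- spec$degraded_target_length - rgeom(length(idx), spec$degraded_geom_p)
    newlen <- pmin(len, pmax(target, 8L))
    trunc <- data.frame(sequence = substr(long$sequence[idx], 1, newlen),
                        count = 1L, class = long$class[idx],
                        stringsAsFactors = FALSE)
    keep <- rbind(keep, trunc)
  }
  keep <- keep[keep$count > 0, , drop = FALSE]
  key <- paste(keep$sequence, keep$class, sep = "\r")
  agg <- tapply(keep$count, factor(key, levels = unique(key)), sum)
  first <- !duplicated(key)
  data.frame(sequence = keep$sequence[first], count = as.integer(agg),
             class = keep$class[first], stringsAsFactors = FALSE)
}

#' Generate a multi-sample cohort with planted group structure
#'
#' Per group, one log-normal expression vector and one dominant-isomiR
#' choice per mature miRNA are drawn and shared by the group's samples, so
#' samples correlate strongly within groups and weakly across them (the
#' planted substrate of the sample-clustering diagnostic). A chosen number
#' of miRNAs per group is planted as `low_expression` (dropped from one
#' sample) and as `non_uniform` (canonical-dominant in one sample,
#' shifted-dominant in the other). Group-level YES/NO truth labels are
#' derived from the realised planted counts with the same unanimity rule the
#' comparison applies; for degraded groups (where truncation invalidates the
#' planted margins) labels are `NA`.
#'
#' @param spec a [simulation_spec()].
#' @param ref a [reference_set()].
#' @param regions optional [genomic_region_set()].
#' @param groups named list: group name to character vector of sample ids.
#' @param n_low,n_nonuniform planted miRNAs per group for the two
#'   non-uniform statuses.
#' @param group_length_modes optional named character vector overriding
#'   `spec$length_mode` per group.
#' @param seed RNG seed.
#' @return list with `libraries`, `truths` (both named by sample id),
#'   `groups`, and `group_truth` (data.frame `miRNA`, `group`, `label`).
#' @export
generate_cohort <- function(spec, ref, regions = NULL,
                            groups = list(normal = c("normal1", "normal2"),
                                          patient = c("patient1", "patient2")),
                            n_low = 3L, n_nonuniform = 3L,
                            group_length_modes = NULL, seed = spec$seed) {
  mat <- ref$matures[ref$matures$located, , drop = FALSE]
  libraries <- list()
  truths <- list()
  gt <- list()
  off_tab <- spec$isomir_offset_distribution
  gi <- 0L
  for (gname in names(groups)) {
    gi <- gi + 1L
    samples <- groups[[gname]]
    gspec <- spec
    if (!is.null(group_length_modes) && gname %in% names(group_length_modes)) {
      gspec$length_mode <- group_length_modes[[gname]]
    }
    plan <- with_seed(seed + 1000L * gi, {
      w <- stats::setNames(rlnorm(nrow(mat), 0, spec$expression_sdlog), mat$name)
      dom <- lapply(mat$name, function(nm) {
        if (runif(1) < spec$dominant_is_reference_prob) c(0L, 0L) else {
          nz <- off_tab[off_tab$offset5 != 0 | off_tab$offset3 != 0, ]
          k <- sample.int(nrow(nz), 1, prob = nz$prob)
          c(nz$offset5[k], nz$offset3[k])
        }
      })
      names(dom) <- mat$name
      top <- names(sort(w, decreasing = TRUE))
      n_plant <- min(n_low + n_nonuniform, length(top))
      planted <- top[seq_len(n_plant)]
      list(w = w, dom = dom,
           low = head(planted, min(n_low, n_plant)),
           nonuni = planted[setdiff(seq_len(n_plant),
                                    seq_len(min(n_low, n_plant)))])
    })
    for (si in seq_along(samples)) {
      dp <- plan$dom
      for (nm in plan$nonuni) {
        dp[[nm]] <- if (si == 1) c(0L, 0L) else c(1L, 1L)
      }
      drop <- plan$low[((seq_along(plan$low) - 1) %% length(samples)) + 1 == si]
      g <- generate_reads(gspec, ref, sample_id = samples[si],
                          regions = regions,
                          seed = seed + 1000L * gi + si,
                          expression_weights = plan$w,
                          dominant_pairs = dp, drop_matures = drop)
      libraries[[samples[si]]] <- g$library
      truths[[samples[si]]] <- g$truth
    }
    # group truth from realised planted families
    degraded <- gspec$length_mode == "degraded_17"
    labels <- vapply(mat$name, function(nm) {
      if (degraded) return(NA_character_)
      per <- lapply(samples, function(sid) {
        tm <- truths[[sid]]$mirna
        if (is.null(tm)) NULL else tm[tm$mirna == nm, , drop = FALSE]
      })
      expressed <- vapply(per, function(x) !is.null(x) && nrow(x) == 1 &&
                            x$count >= 1, logical(1))
      if (!all(expressed)) return("low_expression")
      yes <- vapply(per, function(x) x$dominant_sequence == x$canonical,
                    logical(1))
      if (all(yes)) "YES" else if (!any(yes)) "NO" else "non_uniform"
    }, character(1))
    gt[[gname]] <- data.frame(miRNA = mat$name, group = gname,
                              label = unname(labels), stringsAsFactors = FALSE)
  }
  list(libraries = libraries, truths = truths, groups = groups,
       group_truth = do.call(rbind, gt))
}

#' Plant novel miRNA hairpins (and non-folding decoys) in the genome
#'
#' Embeds `n_novel` perfect stem-loop precursors (30 bp C/G-only stem,
#' poly-A loop) inside intronic intervals, each wrapped in poly-A flanks.
#' Because the resulting fold window contains no T, adenines cannot pair and
#' the planted stem is the unique optimal structure of the window. Reads are
#' generated from the 5' arm (a mature of count 12 plus a +1/+1 isomiR of
#' count 6) and from the 3' arm (a counterpart of count 8), all at or above
#' the default novel-candidate frequency. `n_decoys` non-folding loci (A/C
#' sequence, which cannot base-pair in its all-A context) with one mapped
#' read of count 9 are planted the same way as negative controls. Every planted window is
#' verified against the built-in fold and in-stem filters at generation time
#' (and, when `ref` is given, planted reads are verified to hit no
#' annotation database) and redrawn on failure.
#'
#' @param spec a [simulation_spec()].
#' @param regions a [genomic_region_set()]; intronic intervals must be long
#'   enough for precursor plus flanks.
#' @param n_novel,n_decoys numbers of planted true and decoy loci.
#' @param ref optional [reference_set()] used to veto annotatable reads.
#' @param cfg a [pipeline_config()].
#' @param seed RNG seed.
#' @return list with `regions` (genome updated in place), `reads`
#'   (data.frame `sequence`, `count`, `class = "unannotated_genomic"`) and
#'   `truth` (data.frame `kind` (`"novel"`/`"decoy"`), `chrom`, `start`,
#'   `end`, `strand`, `precursor`, `mature_sequence`).
#' @export
plant_novel_hairpins <- function(spec, regions, n_novel = 3L, n_decoys = 3L,
                                 ref = NULL, cfg = pipeline_config(),
                                 seed = spec$seed + 7L) {
  stopifnot(inherits(regions, "genomic_region_set"))
  if (n_novel == 0 && n_decoys == 0) {
    return(list(regions = regions,
                reads = data.frame(sequence = character(), count = integer(),
                                   class = character(), stringsAsFactors = FALSE),
                truth = data.frame(kind = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   strand = character(), precursor = character(),
                                   mature_sequence = character(),
                                   stringsAsFactors = FALSE)))
  }
  pad <- 6L
  prec_len <- 2L * 30L + 10L
  block_len <- 2L * (cfg$flank_length + pad) + prec_len
  reg <- regions$regions
  ok_rows <- which(reg$region_type == "intronic" & (reg$end - reg$start) >= block_len)
  if (length(ok_rows) < n_novel + n_decoys) {
    short <- which(reg$region_type == "intronic")[1]
    stop(sprintf("not enough intronic intervals of >= %d nt for planting (e.g. %s:%d-%d is too short)",
                 block_len, reg$chrom[short], reg$start[short], reg$end[short]),
         call. = FALSE)
  }
  db_seqs <- if (!is.null(ref)) {
    unlist(lapply(ref$class_dbs, function(d) d$sequence), use.names = FALSE)
  } else character(0)
  with_seed(seed, {
    rows_used <- sample(ok_rows, n_novel + n_decoys)
    genome <- regions$genome
    reads <- list()
    truth <- list()
    ac <- function(n) rand_dna(1, n, prob = c(0.5, 0.5, 0, 0))   # A/C: pairs nothing without G or T around
    cg <- function(n) rand_dna(1, n, prob = c(0, 0.5, 0.5, 0))   # C/G stem alphabet
    aaa <- function(n) strrep("A", n)
    for (i in seq_len(n_novel + n_decoys)) {
      r <- reg[rows_used[i], ]
      is_novel <- i <= n_novel
      for (try in 1:30) {
        if (is_novel) {
          # C/G-only stem arms inside all-A flanks and loop: the fold window
          # then contains no T, so A pairs nothing and the only pairable bases
          # are the planted stem itself -- its 30 pairs are the unique optimum
          arm <- cg(30)
          prec <- paste0(arm, aaa(10), revcomp(arm))
        } else {
          prec <- ac(prec_len)   # A/C decoy: zero pairable bases in its window
        }
        block <- paste0(aaa(cfg$flank_length + pad), prec, aaa(cfg$flank_length + pad))
        offset <- r$start + sample(0:(r$end - r$start - block_len), 1)
        prec_start <- offset + cfg$flank_length + pad
        if (is_novel) {
          mature <- substr(prec, 4, 25)          # arm5, 0-based [3, 25)
          isomir <- substr(prec, 5, 26)
          counterpart <- substr(prec, 45, 66)    # arm3, 0-based [44, 66)
          new_reads <- data.frame(sequence = c(mature, isomir, counterpart),
                                  count = c(12L, 6L, 8L),
                                  class = "unannotated_genomic",
                                  stringsAsFactors = FALSE)
        } else {
          new_reads <- data.frame(sequence = substr(prec, 11, 32),
                                  count = 9L, class = "unannotated_genomic",
                                  stringsAsFactors = FALSE)
        }
        if (anyDuplicated(new_reads$sequence) > 0) next
        if (any(hits_any(new_reads$sequence, db_seqs, cfg$max_mismatches))) next
        if (length(reads) > 0 &&
            any(new_reads$sequence %in% unlist(lapply(reads, `[[`, "sequence")))) next
        # verify the pipeline-side window behaves as planted
        g2 <- genome
        substr(g2[[r$chrom]], offset + 1L, offset + block_len) <- block
        win <- extend_flanks(list(chrom = r$chrom, start = prec_start + 3L,
                                  end = prec_start + 25L, strand = "+"),
                             cfg$flank_length, g2)
        st <- fold_hairpin(win$sequence, cfg)
        if (is_novel) {
          if (!st$accepted) next
          fl <- apply_structural_filters(st, win$read_start, win$read_end,
                                         NULL, cfg)
          if (!fl$in_stem) next
        } else if (st$accepted) next
        genome <- g2
        reads[[length(reads) + 1]] <- new_reads
        truth[[length(truth) + 1]] <- data.frame(
          kind = if (is_novel) "novel" else "decoy", chrom = r$chrom,
          start = prec_start, end = prec_start + nchar(prec), strand = "+",
          precursor = prec,
          mature_sequence = if (is_novel) substr(prec, 4, 25) else
            substr(prec, 11, 32),
          stringsAsFactors = FALSE)
        break
      }
      if (length(truth) < i) {
        stop("failed to plant locus ", i, " after 30 attempts", call. = FALSE)
      }
    }
    list(regions = genomic_region_set(reg, genome),
         reads = do.call(rbind, reads),
         truth = do.call(rbind, truth))
  })
}

#' Write a truth table as TSV files
#'
#' @param truth the `truth` element of a [generate_reads()] result.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_truth_tsv <- function(truth, dir, prefix = "truth") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, paste0(prefix, "_reads.tsv"))
  write.table(truth$read_truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(truth$mirna)) {
    p <- file.path(dir, paste0(prefix, "_mirna.tsv"))
    write.table(truth$mirna, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(truth$members)) {
    p <- file.path(dir, paste0(prefix, "_members.tsv"))
    write.table(truth$members, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
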