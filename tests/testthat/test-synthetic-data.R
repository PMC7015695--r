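# Allele-population and read-library simulators: truth bookkeeping,
# statistical calibration, determinism, zero-noise identities.

test_that("degenerate mixes produce uniform populations", {
  ref <- default_reference()
  par <- simulate_alleles(ref, allele_mix(parental = 1), 50, seed = 4)
  expect_equal(nrow(par), 50)
  expect_true(all(par$truth_label == "parental"))
  expect_true(all(par$sequence == ref$locus$sequence))

  hdr <- simulate_alleles(ref, allele_mix(parental = 0, hdr = 1), 10, seed = 4)
  expect_true(all(hdr$truth_label == "hdr"))
  expect_true(all(nchar(hdr$sequence) ==
                    nchar(ref$locus$sequence) + attr(ref$hdr_allele, "cassette_length")))
})

test_that("allele mixture validation rejects bad fractions and weights", {
  expect_error(allele_mix(parental = 0.5, indel = 0.4), "sum to 1")
  expect_error(allele_mix(parental = 1.2, indel = -0.2), "non-negative")
  expect_error(allele_mix(fragment_sources = c(ITR_L = 0)), "at least one positive")
})

test_that("category counts are multinomial in the mixture", {
  ref <- default_reference()
  mix <- allele_mix(parental = 0.25, indel = 0.25, hdr = 0.25,
                    vector_fragment = 0.25)
  al <- simulate_alleles(ref, mix, 1e4, seed = 8)
  counts <- table(al$truth_label)
  sigma <- sqrt(1e4 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) < 3 * sigma))
  # detail fields consistent with labels
  expect_true(all(!is.na(al$indel_size[al$truth_label == "indel"])))
  expect_true(all(is.na(al$indel_size[al$truth_label != "indel"])))
  expect_true(all(al$frag_len[al$truth_label == "vector_fragment"] >= 10 &
                    al$frag_len[al$truth_label == "vector_fragment"] <= 200))
})

test_that("zero-noise reads reconstruct their source molecules exactly", {
  ref <- default_reference()
  al <- simulate_alleles(ref, allele_mix(parental = 1), 40, seed = 4)
  cfg <- sim_config(n_molecules = 40, sub_error_rate = 0, indel_error_rate = 0,
                    seed = 5)
  ir <- simulate_indel_reads(al, ref, cfg)
  expect_equal(nrow(ir$r1), 40) # duplication constant 1 for the indel assay
  expect_true(all(vapply(ir$r1$seq, grepl, logical(1),
                         x = ref$locus$sequence, fixed = TRUE)))
  expect_true(all(vapply(revcomp(ir$r2$seq), grepl, logical(1),
                         x = ref$locus$sequence, fixed = TRUE)))

  lmu <- simulate_lmu_library(al, ref, "HaeIII", cfg)
  frag <- ligation_fragment(ref$locus$sequence, "HaeIII", ref$locus$gsp3_site)
  expect_true(all(lmu$r1$seq == substr(frag$sequence, 1, cfg$read_length)))
  # R2 layout: UMI + adapter + reverse-complemented fragment end
  expect_true(all(substr(lmu$r2$seq, 9, 8 + nchar(lmu_adapter())) == lmu_adapter()))
  tail_len <- cfg$read_length - 8 - nchar(lmu_adapter())
  expect_true(all(substr(lmu$r2$seq, 9 + nchar(lmu_adapter()), cfg$read_length) ==
                    substr(revcomp(frag$sequence), 1, tail_len)))
})

test_that("substitution errors are calibrated to the configured rate", {
  ref <- default_reference()
  al <- simulate_alleles(ref, allele_mix(parental = 1), 400, seed = 4)
  cfg <- sim_config(n_molecules = 400, sub_error_rate = 0.01,
                    indel_error_rate = 0, seed = 6)
  ir <- simulate_indel_reads(al, ref, cfg)
  clean <- simulate_indel_reads(al, ref,
                                sim_config(n_molecules = 400, sub_error_rate = 0,
                                           indel_error_rate = 0, seed = 6))
  nbases <- sum(nchar(ir$r1$seq))
  mism <- sum(vapply(seq_len(nrow(ir$r1)), function(i) {
    sum(strsplit(ir$r1$seq[i], "")[[1]] != strsplit(clean$r1$seq[i], "")[[1]])
  }, numeric(1)))
  expect_gt(nbases, 1e5 - 1)
  # a few same-position double hits can revert, hence the tolerance below
  expect_lt(abs(mism - nbases * 0.01), 3 * sqrt(nbases * 0.01 * 0.99) + 5)
})

test_that("simulators are byte-deterministic for a fixed seed", {
  ref <- default_reference()
  mix <- allele_mix(parental = 0.6, indel = 0.3, hdr = 0.1)
  al <- simulate_alleles(ref, mix, 100, seed = 12)
  al2 <- simulate_alleles(ref, mix, 100, seed = 12)
  expect_identical(al, al2)
  cfg <- sim_config(n_molecules = 100, seed = 13)
  lmu1 <- simulate_lmu_library(al, ref, "HaeIII", cfg)
  lmu2 <- simulate_lmu_library(al, ref, "HaeIII", cfg)
  expect_identical(lmu1, lmu2)

  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.fastq"); f2 <- file.path(dir, "b.fastq")
  write_fastq(lmu1$r1$id, lmu1$r1$seq, lmu1$r1$qual, f1)
  write_fastq(lmu2$r1$id, lmu2$r1$seq, lmu2$r1$qual, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # round trip
  back <- read_fastq(f1)
  expect_identical(back$seq, lmu1$r1$seq)
  expect_identical(back$qual, lmu1$r1$qual)
})

test_that("every read name maps to exactly one truth-table row", {
  ref <- default_reference()
  mix <- allele_mix(parental = 0.5, indel = 0.3, hdr = 0.1, vector_fragment = 0.1)
  al <- simulate_alleles(ref, mix, 200, seed = 14)
  cfg <- sim_config(n_molecules = 200, seed = 15)
  lmu <- simulate_lmu_library(al, ref, "HaeIII", cfg)
  mol <- sub(":.*$", "", lmu$r1$id)
  expect_true(all(mol %in% lmu$truth$id))
  expect_identical(unname(table(mol)[lmu$truth$id[lmu$truth$n_reads > 0]]),
                   unname(table(factor(mol, levels = lmu$truth$id))[lmu$truth$n_reads > 0]))
  # emitted read counts match the truth table
  expect_equal(as.integer(table(factor(mol, levels = lmu$truth$id))),
               lmu$truth$n_reads)
})

test_that("UMI labelling behaves as configured", {
  ref <- default_reference()
  al <- simulate_alleles(ref, allele_mix(parental = 1), 10, seed = 4)
  cfg <- sim_config(n_molecules = 10, sub_error_rate = 0, indel_error_rate = 0,
                    duplication = list(dist = "constant", n = 3), seed = 16)
  lmu <- simulate_lmu_library(al, ref, "HaeIII", cfg)
  expect_equal(nrow(lmu$r1), 30)
  expect_lte(length(unique(lmu$truth$umi)), 10)

  # birthday bound: expected collisions among 100 molecules in a 4^8 space
  expect_lt(choose(100, 2) / 4^8, 0.1)
  al100 <- simulate_alleles(ref, allele_mix(parental = 1), 100, seed = 4)
  lmu100 <- simulate_lmu_library(al100, ref, "HaeIII",
                                 sim_config(n_molecules = 100, seed = 17))
  expect_equal(length(unique(lmu100$truth$umi)), 100)

  # collision-free mode: pairwise Hamming distance >= 2
  cfgu <- sim_config(n_molecules = 60, unique_umis = TRUE, seed = 18)
  lmuu <- simulate_lmu_library(al100[1:60, ], ref, "HaeIII", cfgu)
  u <- strsplit(lmuu$truth$umi, "")
  dmin <- min(vapply(seq_along(u), function(i) {
    min(vapply(seq_along(u)[-i], function(j) sum(u[[i]] != u[[j]]), numeric(1)))
  }, numeric(1)))
  expect_gte(dmin, 2)
})
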