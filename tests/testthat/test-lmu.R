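# LMU-PCR filtering rules, soft-clip classification, and the HDR percentage.

# hand-built molecule table for rule-level tests
toy_molecule <- function(consensus, mapq, aligned, ...) {
  data.frame(consensus = consensus, mapq = mapq, aligned = aligned, ...,
             stringsAsFactors = FALSE)
}

test_that("filters partition a hand-built six-molecule set as counted by hand", {
  primer <- "ACGTACGTACGTACGTACGT"
  good <- paste0(primer, strrep("A", 80))
  mols <- toy_molecule(
    consensus = rep(good, 6),
    mapq = c(5, 12, 60, 60, 60, 60),       # two mapq failures
    aligned = c(100, 100, 40, 100, 100, 100)) # one length failure (HaeIII)
  f <- filter_molecules(mols, "HaeIII", primer)
  expect_equal(sum(f$kept), 3)
  expect_equal(sum(!f$kept), 3)
  expect_equal(f$filter_reason[1:3], c("mapq", "mapq", "length"))
  expect_true(all(f$kept[4:6]))

  # a primer-mangled molecule fails on primer_prefix (and mapq outranks it)
  mangled <- toy_molecule(paste0("TTTT", substr(good, 5, nchar(good))),
                          mapq = c(60, 5), aligned = 100)
  fm <- filter_molecules(mangled, "HaeIII", primer)
  expect_identical(fm$filter_reason, c("primer_prefix", "mapq"))
})

test_that("the aligned-length rule is assay-specific: 58 bp passes TaqI, fails HaeIII", {
  primer <- "ACGTACGTACGTACGTACGT"
  m <- toy_molecule(paste0(primer, strrep("A", 60)), mapq = 60, aligned = 58)
  expect_true(filter_molecules(m, "TaqI", primer)$kept)
  expect_false(filter_molecules(m, "HaeIII", primer)$kept)
  expect_identical(filter_molecules(m, "HaeIII", primer)$filter_reason, "length")
  # 70 bp passes the HaeIII rule
  m70 <- toy_molecule(paste0(primer, strrep("A", 60)), mapq = 60, aligned = 70)
  expect_true(filter_molecules(m70, "HaeIII", primer)$kept)
})

test_that("the arm-prefix extension tolerates one mismatch", {
  primer <- "ACGTACGTACGTACGTACGT"
  arm <- "GGGGGGGGGG"
  ok <- toy_molecule(paste0(primer, "GGGGGTGGGG", strrep("A", 40)),
                     mapq = 60, aligned = 60)
  expect_true(filter_molecules(ok, "HaeIII", primer, arm_prefix = arm)$kept)
  bad <- toy_molecule(paste0(primer, "GGTGGTGGGG", strrep("A", 40)),
                      mapq = 60, aligned = 60)
  expect_false(filter_molecules(bad, "HaeIII", primer, arm_prefix = arm)$kept)
})

test_that("classification routes unaligned portions to the element panel", {
  ref <- default_reference()
  loc <- ref$locus
  decoy <- make_decoy(loc$sequence)
  frag <- ligation_fragment(loc$sequence, "HaeIII", loc$gsp3_site)$sequence
  parental_read <- substr(frag, 1, 250)
  hdr_frag <- ligation_fragment(as.character(ref$hdr_allele), "HaeIII",
                                loc$gsp3_site)$sequence
  hdr_read <- substr(hdr_frag, 1, 250)
  # 40-bp exact junction clip built by hand: arm prefix + cassette start
  junction40 <- paste0(substr(frag, 1, 120), substr(ref$panel[["HDR_left"]],
                                                    151, 190))
  reads <- c(parental_read, hdr_read, junction40)
  aln <- align_to_reference(reads, loc$sequence, decoy = decoy)
  st <- editquant:::cpp_cigar_stats(aln$cigar)
  mols <- data.frame(consensus = reads, mapq = aln$mapq,
                     read_start = aln$read_start, read_end = aln$read_end,
                     aligned = st$aligned, clip_left = st$clip_left,
                     clip_right = st$clip_right, max_ins = st$max_ins,
                     max_ins_pos = st$max_ins_pos, stringsAsFactors = FALSE)
  cl <- classify_molecules(mols, ref$panel)
  expect_identical(cl$category, c("mOTC_locus", "HDR", "HDR"))
  expect_error(classify_molecules(transform(mols, consensus = ""), ref$panel),
               "empty consensus")
})

test_that("HDR percentage follows its formula and reports the breakdown", {
  mols <- data.frame(
    kept = rep(TRUE, 100),
    filter_reason = NA_character_,
    category = c(rep("mOTC_locus", 90), rep("HDR", 6), rep("ITR", 4)))
  res <- hdr_percentage(mols, "HaeIII")
  expect_equal(res$hdr_percent, 6.0)
  expect_equal(res$total_after_filtering, 100)
  expect_equal(unname(res$counts[c("mOTC_locus", "HDR", "ITR")]), c(90L, 6L, 4L))

  none <- data.frame(kept = TRUE, filter_reason = NA_character_,
                     category = "mOTC_locus")
  expect_equal(hdr_percentage(none, "TaqI")$hdr_percent, 0)

  all_filtered <- data.frame(kept = FALSE, filter_reason = "mapq",
                             category = NA_character_)
  expect_error(hdr_percentage(all_filtered, "HaeIII"),
               class = "editquant_undefined_percentage")
})

test_that("zero-noise molecules classify according to their truth structure", {
  ref <- default_reference()
  mix <- allele_mix(parental = 0.4, indel = 0.2, hdr = 0.2, vector_fragment = 0.2,
                    fragment_sources = c(ITR_L = 1, SaCas9 = 1),
                    fragment_length_range = c(120L, 200L))
  al <- simulate_alleles(ref, mix, 150, seed = 61)
  cfg <- sim_config(n_molecules = 150, sub_error_rate = 0, indel_error_rate = 0,
                    unique_umis = TRUE, seed = 62)
  lmu <- simulate_lmu_library(al, ref, "HaeIII", cfg)
  qh <- quantify_hdr(lmu$r1, lmu$r2, ref, assay = "HaeIII")
  m <- qh$molecules
  expect_equal(nrow(m), 150) # collision-free UMIs: one molecule each
  m$truth <- lmu$truth$truth_label[match(m$umi, lmu$truth$umi)]
  m$frag_len <- lmu$truth$fragment_length[match(m$umi, lmu$truth$umi)]
  tr <- al[match(lmu$truth$id[match(m$umi, lmu$truth$umi)], al$id), ]

  # structural expectation: parental and deletions/small insertions are
  # mOTC locus; HDR shows the junction; captured fragments >= 120 bp fill
  # the read tail and classify to their source element -- unless the enzyme
  # cuts inside the captured fragment so close to the junction that fewer
  # than 10 insert bases remain in the molecule; NHEJ insertions of random
  # sequence have no panel hit
  tail_bases <- pmin(m$frag_len, 250) - 120 # insert bases visible in the read
  expected <- ifelse(tr$truth_label == "parental", "mOTC_locus",
              ifelse(tr$truth_label == "hdr", "HDR",
              ifelse(tr$truth_label == "indel",
                     ifelse(!is.na(tr$indel_size) & tr$indel_size >= 10,
                            "unclassified", "mOTC_locus"),
              ifelse(tail_bases < 10, "mOTC_locus",
                     c(ITR_L = "ITR", SaCas9 = "SaCas9")[tr$frag_source]))))
  expect_identical(m$category, unname(expected))
})

test_that("HaeIII and TaqI assays agree on the same population", {
  ref <- default_reference()
  mix <- allele_mix(parental = 0.85, indel = 0.05, hdr = 0.10)
  al <- simulate_alleles(ref, mix, 400, seed = 63)
  cfg <- sim_config(n_molecules = 400, sub_error_rate = 0, indel_error_rate = 0,
                    unique_umis = TRUE, seed = 64)
  h <- quantify_hdr(simulate_lmu_library(al, ref, "HaeIII", cfg)$r1,
                    simulate_lmu_library(al, ref, "HaeIII", cfg)$r2,
                    ref, assay = "HaeIII")
  t <- quantify_hdr(simulate_lmu_library(al, ref, "TaqI", cfg)$r1,
                    simulate_lmu_library(al, ref, "TaqI", cfg)$r2,
                    ref, assay = "TaqI")
  expect_equal(h$result$hdr_percent, t$result$hdr_percent)
  expect_equal(h$result$hdr_percent, 100 * mean(al$truth_label == "hdr"))
})
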