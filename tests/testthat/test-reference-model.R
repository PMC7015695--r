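# Locus/donor construction, restriction-site scanning, digestion, HDR allele
# assembly, and ligation fragments.

test_that("restriction site scanning matches its definition and the matchPattern oracle", {
  expect_equal(find_restriction_sites("AAGGCCAA", "HaeIII"), 4L)
  expect_equal(find_restriction_sites("AAAA", "HaeIII"), integer(0))
  expect_equal(find_restriction_sites("GGCCGGCC", "HaeIII"), c(2L, 6L))
  expect_error(find_restriction_sites("aaggccaa", "HaeIII"), "uppercase")
  expect_error(find_restriction_sites("AANGCC", "HaeIII"), "uppercase")

  set.seed(42)
  for (enz in lmu_enzymes()) {
    for (i in 1:25) {
      s <- random_seq(200)
      expect_identical(find_restriction_sites(s, enz),
                       oracle_sites(s, enz$recognition, enz$cut_offset))
    }
  }
})

test_that("digestion conserves the sequence and fragment count equals cuts + 1", {
  expect_equal(digest_sequence("AAGGCCAA", "HaeIII"), c("AAGG", "CCAA"))
  expect_equal(digest_sequence("AAAA", "HaeIII"), "AAAA")
  expect_equal(digest_sequence("GGCCGGCC", "HaeIII"), c("GG", "CCGG", "CC"))

  set.seed(7)
  for (i in 1:50) {
    s <- random_seq(sample(50:400, 1))
    enz <- lmu_enzymes()[[sample(2, 1)]]
    frags <- digest_sequence(s, enz)
    expect_identical(paste(frags, collapse = ""), s)
    expect_length(frags, length(find_restriction_sites(s, enz)) + 1L)
  }
})

test_that("synthetic locus satisfies its construction postconditions", {
  loc <- small_locus()
  cut <- loc$cleavage_pos
  expect_equal(loc$left_arm[["end"]], cut)
  expect_equal(loc$right_arm[["start"]], cut)
  expect_equal(diff(loc$left_arm), diff(loc$right_arm))

  # exactly one site per enzyme per arm, at the requested cut distance
  for (nm in names(loc$enzyme_layout)) {
    cuts <- find_restriction_sites(loc$sequence, loc$enzymes[[nm]])
    arm_cuts <- cuts[cuts > loc$left_arm[["start"]] & cuts < loc$right_arm[["end"]]]
    expect_equal(arm_cuts, cut + c(-1, 1) * loc$enzyme_layout[[nm]],
                 ignore_attr = TRUE)
  }
  # GSP3 site inside the left arm
  expect_gte(loc$gsp3_site[["start"]], loc$left_arm[["start"]])
  expect_lte(loc$gsp3_site[["end"]], loc$left_arm[["end"]])

  # determinism and independence from the caller's RNG state
  set.seed(99); runif(3)
  again <- build_synthetic_locus(arm_length = 200, seed = 5,
                                 enzyme_layout = c(HaeIII = 150, TaqI = 120),
                                 gsp3_offset = 60)
  expect_identical(again$sequence, loc$sequence)

  expect_error(build_synthetic_locus(arm_length = 200, seed = 1,
                                     enzyme_layout = c(HaeIII = 250)),
               "arm_length")
  expect_error(build_synthetic_locus(arm_length = 50, seed = 1), ">= 100")
})

test_that("donor model tiles its features and embeds the arms verbatim", {
  ref <- default_reference()
  f <- ref$donor$features
  expect_equal(f$name, c("ITR_L", "U6_sgRNA", "HA_L", "TBG", "hOTCco",
                         "polyA", "HA_R", "ITR_R"))
  expect_equal(f$start[-1], f$end[-nrow(f)]) # contiguous tiling
  expect_equal(f$end[nrow(f)], nchar(ref$donor$sequence))

  loc <- ref$locus
  arm_l <- substr(loc$sequence, loc$left_arm[["start"]] + 1, loc$left_arm[["end"]])
  ha_l <- substr(ref$donor$sequence, f$start[f$name == "HA_L"] + 1,
                 f$end[f$name == "HA_L"])
  expect_identical(ha_l, arm_l)

  proto <- substr(loc$sequence, loc$protospacer[["start"]] + 1,
                  loc$protospacer[["end"]])
  expect_true(grepl(proto, ref$donor$sequence, fixed = TRUE))
  untargeted <- build_synthetic_donor(loc, seed = 2, targeted = FALSE)
  expect_false(grepl(proto, untargeted$sequence, fixed = TRUE))
})

test_that("HDR allele is a seamless cassette insertion and round-trips", {
  ref <- default_reference()
  loc <- ref$locus
  hdr <- ref$hdr_allele
  cas_len <- attr(hdr, "cassette_length")
  expect_equal(nchar(hdr), nchar(loc$sequence) + cas_len)

  # removing the inserted cassette reproduces the parental locus exactly
  cut <- loc$cleavage_pos
  stripped <- paste0(substr(hdr, 1, cut), substr(hdr, cut + cas_len + 1, nchar(hdr)))
  expect_identical(stripped, loc$sequence)

  # planted arm sites keep their distances from the insertion boundaries
  for (nm in names(loc$enzyme_layout)) {
    cuts <- find_restriction_sites(as.character(hdr), loc$enzymes[[nm]])
    d <- loc$enzyme_layout[[nm]]
    expect_true((cut - d) %in% cuts)              # left arm, unchanged
    expect_true((cut + cas_len + d) %in% cuts)    # right arm, shifted by cassette
  }
})

test_that("ligation fragments run from the primer to the first downstream cut", {
  # plus strand: primer at [0,10), single HaeIII cut at 100
  set.seed(11)
  s <- random_seq(160)
  s <- gsub("GGCC", "GGAC", s, fixed = TRUE)
  substr(s, 99, 102) <- "GGCC" # cut offset 2 -> cut position 100
  fr <- ligation_fragment(s, "HaeIII", c(start = 0, end = 10, strand = 1))
  expect_equal(nchar(fr$sequence), 100)
  expect_identical(fr$sequence, substr(s, 1, 100))

  # minus strand: fragment taken leftward and reverse-complemented
  fr2 <- ligation_fragment(s, "HaeIII", c(start = 120, end = 140, strand = -1))
  expect_identical(fr2$sequence, revcomp(substr(s, 101, 140)))

  expect_error(
    ligation_fragment("ACGTACGTACGTACGT", "HaeIII", c(start = 0, end = 8, strand = 1)),
    class = "editquant_no_fragment")

  # default layout: parental and HDR fragments differ by cassette length
  # minus the planted-site distance shift (near-equal amplicon rationale)
  ref <- default_reference()
  loc <- ref$locus
  fp <- ligation_fragment(loc$sequence, "HaeIII", loc$gsp3_site)
  fh <- ligation_fragment(as.character(ref$hdr_allele), "HaeIII", loc$gsp3_site)
  gsp3_to_cut <- loc$cleavage_pos - loc$gsp3_site[["start"]]
  expect_equal(nchar(fp$sequence), gsp3_to_cut + loc$enzyme_layout[["HaeIII"]])
  expect_equal(nchar(fh$sequence),
               gsp3_to_cut + ref$donor$cassette_layout[["HaeIII"]])
  # HDR fragment: cassette bases between the arm prefix and the cut
  cas <- substr(ref$donor$sequence, ref$donor$cassette[["start"]] + 1,
                ref$donor$cassette[["end"]])
  expect_identical(substr(fh$sequence, gsp3_to_cut + 1, nchar(fh$sequence)),
                   substr(cas, 1, ref$donor$cassette_layout[["HaeIII"]]))
})

test_that("reference FASTA round-trips through files", {
  ref <- default_reference()
  dir <- withr::local_tempdir()
  write_reference_fasta(ref, dir)
  expect_identical(read_fasta(file.path(dir, "locus.fasta"))[[1]],
                   ref$locus$sequence)
  panel <- read_fasta(file.path(dir, "panel.fasta"))
  expect_identical(panel, ref$panel)
})
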