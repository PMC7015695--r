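---
title: "Quantifying CRISPR editing outcomes with editquant: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR editing outcomes with editquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editquant)
```

## The measurement problem

A gene-targeting experiment delivers a nuclease (SaCas9) and a donor
template carrying a promoter–transgene–polyA cassette between ~0.9-kb
homology arms.  At the cleavage site in the target intron, repair leaves a
mixture of outcomes per haploid genome: unedited (parental) sequence, NHEJ
indels, HDR knock-in of the cassette, and NHEJ capture of fragments of the
delivered AAV genomes (promoter, transgene, polyA, ITR, nuclease ORF).
Two quantities summarise the editing:

* the **on-target indel frequency**, measured by deep sequencing of a short
  PCR amplicon spanning the cut, and
* the **HDR-mediated targeting efficiency**, which cannot be measured by a
  spanning amplicon because the homology arms make donor-derived and
  genomic templates indistinguishable over ~0.9 kb.  Instead, genomic DNA
  is digested with a restriction enzyme (HaeIII or TaqI), ligated to
  Y-adapters carrying unique molecular indices (UMIs), and amplified by
  nested PCR from a gene-specific primer (GSP3) — ligation-mediated
  UMI-PCR (LMU-PCR).  Each sequenced unique molecule is then classified by
  what its junction sequence contains.

`editquant` implements both estimators and a generator of synthetic
populations with known truth, so every rule in the pipelines can be
verified end to end.

## The indel estimator

Read pairs are assembled by maximal-scoring ungapped overlap (score =
overlap − 2·mismatches, minimum overlap 20 bp, mismatch fraction ≤ 0.1,
higher-quality base at disagreements).  Merged reads are aligned to the
amplicon reference by local affine-gap alignment; with the default scoring
(match +1, mismatch −4, gap open 6, gap extend 1, a gap of length $L$
costing $6 + L$) alignment behaves like common short-read aligners.  The
mapping-quality proxy is $\min(60,\, S_{\mathrm{ref}} - S_{\mathrm{decoy}})$
where the decoy is a fixed column shuffle of the reference; reads below 20
are discarded, mirroring the MAPQ ≥ 20 convention.

The target window is the closed interval
$[\mathrm{cut}-w, \mathrm{cut}+w]$ with $w = 20$ by default (41 reference
positions).  A read is indel-containing iff it has at least one I or D
operation *located in the window* — any deleted base for D, the anchor
point for I, boundary positions included.  Substitutions never count.  The
frequency is the ratio of indel-containing reads to reads whose alignment
overlaps the window.

Two consequences worth knowing:

* Pairs that fail assembly are excluded from numerator and denominator.
  HDR alleles lengthen the amplicon by the cassette (beyond the span of a
  250-bp pair), so they drop out at this step — exactly as in the wet
  assay, where the short-product PCR cannot amplify them.  The indel
  frequency is therefore a fraction of *assayable* (parental + indel)
  molecules.
* PCR duplicates are invisible to a read-level ratio, so the simulator's
  indel-assay default is one read pair per molecule; the LMU simulator,
  whose entire point is duplicate structure, defaults to a geometric
  per-molecule duplication with mean 5 (collapsing the three nested
  touchdown-PCR rounds into a single draw).

## The LMU-PCR estimator

1. **UMI extraction.** The adapter-side mate reads `[8-nt UMI][adapter]
   [insert]`; the adapter is located allowing one mismatch per 10 adapter
   bases, and the UMI excised.  The primer-side read (R1) is the analysis
   unit: the ligation fragments (~0.9–1.0 kb here) exceed the span of a
   250-bp pair, so overlap assembly is structurally impossible (it can be
   enabled for short-fragment layouts).
2. **Anchoring and grouping.** Reads are grouped by (alignment start
   position, UMI network).  The start position comes from an exact 15-mer
   lookup near the read start; with a single GSP3 primer all reads share
   one position, so the stratification is trivial by design.  The UMI
   network is directional: $a \to b$ iff the UMIs differ at exactly one
   position and $\mathrm{count}(a) \ge 2\,\mathrm{count}(b) - 1$; seeds are
   taken in (count desc, UMI asc) order and clusters grow by breadth-first
   search.  The molecule consensus is the per-column majority over the
   group's reads (reads of the modal length vote; base ties resolve
   alphabetically).
3. **Filtering.** A molecule is kept iff mapq ≥ 20, its aligned portion is
   ≥ 60 bp (HaeIII) or ≥ 55 bp (TaqI), and its consensus starts with the
   GSP3 primer (exact) plus 10 homology-arm bases (≤ 1 mismatch).  Failures
   record the first failing rule in the order mapq, length, primer_prefix.
4. **Classification.** If the unaligned portion (the longest of the two
   terminal soft clips and the largest internal insertion — both are
   evidence of non-locus sequence at the junction) is shorter than 10 bp
   the molecule is the parental locus (`mOTC_locus`).  Otherwise it is
   aligned in both orientations against the element panel; the best-scoring
   reference covering ≥ 80% of the portion at ≥ 90% identity assigns the
   category, with score ties resolved HDR > hOTCco > TBG > polyA > ITR >
   SaCas9 > other_vector.  The HDR references are the two expected
   arm–cassette junctions (±150 bp), not the whole cassette, so HDR remains
   distinguishable from NHEJ-captured cassette fragments; the precedence
   order resolves the deliberate overlap (a junction clip also matches the
   promoter or transgene partially).  No qualifying hit yields
   `unclassified`.
5. **Statistic.** HDR % = 100 × (unique HDR molecules) / (unique molecules
   after filtering); all non-filtered categories — including captured
   vector fragments and unclassified junctions — stay in the denominator,
   which is how "total number of unique molecules after filtering" reads.

## The synthetic-data generator

The generator is first-class code, and its defaults *are* the study
conditions the package is verified under:

* **Locus**: uniform-random sequence, 0.9-kb arms abutting the cut, a 21-nt
  protospacer with an NNGRRT-compatible PAM and a blunt cut 3 bp 5′ of the
  PAM (the usual SaCas9 model; the offset is a parameter), a surrogate
  disease-mutation position 47 bp upstream, and a 20-nt GSP3 site ending
  100 bp before the cut so that a 250-bp primer-side read shows ~130 bp of
  junction sequence.
* **Restriction geometry**: one planted site per enzyme per arm (HaeIII cut
  880 bp, TaqI 860 bp from the cleavage site) and one per enzyme inside the
  donor cassette (780 / 760 bp from the cassette start); all other
  occurrences in arms and cassette are removed by rejection masking.
  Parental and HDR ligation fragments then come out at 1000/980 bp and
  900/880 bp — the near-equal amplicon sizes the two-enzyme design aims
  for.  All distances are configuration values, not claims about any real
  locus.
* **Donor and nuclease vectors**: ITR–U6.sgRNA–arm–TBG–hOTCco–polyA–arm–ITR
  and ITR–SaCas9–ITR, with element sizes scaled down (145/250/250/400/150
  and 600 bp) so that a full analysis runs in seconds; the ITRs are shared
  between the two vectors and the arms are copied verbatim from the locus.
  The untargeted control donor simply lacks the protospacer.
* **Outcomes**: multinomial category draws; deletions centred on the cut
  and insertions of random bases at it, sizes uniform on ±1..20;
  vector-fragment capture inserts a 10–200-bp sub-interval of a random
  vector element in either orientation; HDR is the seamless knock-in.
* **Libraries**: per-molecule PCR duplication (geometric, mean 5 for LMU;
  1 for the amplicon assay), fresh random 8-nt UMIs (collisions permitted
  by chance; a collision-free mode with pairwise Hamming distance ≥ 2
  exists for PCR-bias studies), flat Phred qualities encoding the
  configured substitution rate (0.005 by default, with a 10⁻⁵ 1-bp indel
  error rate), and truth tables linking every read name to its molecule.

Each stochastic function mixes a private stream id into the user seed, so
passing the same small integer to the reference builder and the simulators
never replays one function's random draws inside another.

### What the simulation does not model

Bead-cleanup size selection, PhiX spike-ins, chimeric PCR artifacts,
quality-score variation along the read, strand biases, ITR hairpin PCR
suppression, and large deletions that remove the primer or window context
are all absent.  Passing tests therefore demonstrate that the *estimators
implement their definitions correctly* and recover truth under calibrated
noise — not that real libraries are free of the artifacts above.

## Numerical and design choices

* **Coordinates** are 0-based half-open throughout; restriction cuts are
  between-base offsets, which makes `digest` arithmetic exact
  (concatenation of fragments is always the input).
* **Aligner**: exact Smith-Waterman/Gotoh with deterministic tie-breaks
  (smallest reference end, then diagonal before deletion before insertion
  during traceback).  Large problems are banded around exact 15-mer seed
  diagonals with a ±40 pad and fall back to the full DP when no seeds or
  over-wide bands occur; the banded path is validated against the full DP
  in the tests, and small problems (including every decoy used for mapq)
  always take the full DP.
* **Directional UMI networks at a saturated site**: with thousands of
  molecules ligated at one position, chance Hamming-1 adjacency between
  8-nt UMIs is common, and the directional rule then merges some truly
  distinct molecules (the documented conservative behaviour of this
  algorithm).  Unique-molecule counts therefore undercount at high
  per-site loads, and because merged clusters take their plurality
  consensus, minority categories are additionally suppressed by a few
  percent relative (an HDR fraction of 0.057 reads out near 0.052 at a
  5,000-molecule single-site load).  Both effects vanish at realistic
  per-site molecule counts and stay within the calibration confidence
  intervals the tests check.
* **Chance-junction background**: a 10–20-bp unaligned portion can match a
  panel reference by chance, so a population with no true HDR still reads
  out a small positive HDR percentage (on the order of 0.05–0.1% here) —
  the same kind of background the wet assay shows in untargeted controls.
  Calibration is therefore checked as the estimate's 99% confidence
  interval covering the realized truth, which a real sub-0.1% background
  does at truth 0 (an interval around the truth would be degenerate
  there).
* **Structural resolution of junction classification**: a captured
  fragment whose length places the second junction just outside the read,
  or a 10–20-bp insertion of random sequence, produces an unaligned
  portion that mixes insert and resumed-arm bases or matches nothing; the
  80%-coverage/90%-identity rule then returns `unclassified` (or, for very
  short junctions, a chance element hit).  This is the junction-limited
  assay's real resolution limit — one cannot determine the extent of an
  integration from one junction — and the zero-noise tests encode it in
  their expected categories.
* **Thresholds**: the ≥ 60/≥ 55-bp aligned-length rules, MAPQ 20, the
  ±20-bp window, and the ≥ 10-bp unaligned-portion rule follow the assay's
  published conventions ("more than 60 bp" and "≥ 60 bp" are used
  interchangeably there; the package uses ≥ consistently).  The 80%/90%
  panel-hit thresholds and the 10-bp arm-prefix length are not published;
  they are forgiving at the default error rates and exposed as arguments.
* **Error handling**: zero window-mapped reads and zero post-filter
  molecules raise typed conditions (`editquant_undefined_frequency`,
  `editquant_undefined_percentage`) rather than returning NaN; a fragment
  with no downstream restriction cut raises `editquant_no_fragment` and is
  logged as unrecoverable by the simulator.

## Problem sizes used in verification

The test suite exercises the full geometry (0.9-kb arms) with 5,000-molecule
populations for exactness and recovery checks (20 seeds per operating point,
true HDR 0–10%, true indel 5–40%, 0.5% substitution noise), 300-molecule
populations for PCR-bias immunity at geometric mean depth 20, and hundreds
of randomised instances for the alignment and digestion oracles.  These
sizes make the whole suite run on one CPU in well under half an hour while
keeping binomial confidence intervals tight enough to detect percent-level
bias.

## Known limitations

* Only palindromic recognition sites are scanned (forward strand); the two
  default enzymes are palindromic.
* A single GSP3 site serves both restriction assays; a two-primer layout
  (left- and right-arm primers, as a two-sided wet design would use)
  changes only the geometry configuration, not the code paths.
* The mapq proxy is a score-gap against a shuffled decoy — a uniqueness
  surrogate adequate for a single-locus assay, not a genome-scale mapping
  quality.
* Unique-molecule counts at heavily saturated ligation sites undercount,
  as discussed above; ratios remain unbiased.
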