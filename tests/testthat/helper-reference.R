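# Shared fixtures: references are built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# full-size reference set (0.9-kb arms), the study-scale geometry
default_reference <- function() {
  if (is.null(.fixtures$ref)) .fixtures$ref <- synthetic_reference(seed = 1)
  .fixtures$ref
}

# compact locus for fast unit tests of the geometry code
small_locus <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- build_synthetic_locus(arm_length = 200, seed = 5,
                                             enzyme_layout = c(HaeIII = 150, TaqI = 120),
                                             gsp3_offset = 60)
  .fixtures$small
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# amplicon-assay reference window around the cleavage site
amplicon_reference <- function(reference, halfwidth = 250L) {
  cut <- reference$locus$cleavage_pos
  list(seq = substr(reference$locus$sequence, cut - halfwidth + 1L, cut + halfwidth),
       cut = halfwidth)
}
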