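test_that("translation follows the standard code, drops the trailing stop, flags internal stops", {
  rec <- genome_record("t", "AUGUAAAUGGGUUAAGG")
  expect_equal(translate_orf(rec, interval(1, 6)), "M")
  expect_equal(translate_orf(rec, interval(7, 15)), "MG")
  expect_error(translate_orf(rec, interval(1, 15)), "internal stop codon at genome position 4")
  expect_equal(translate_orf(rec, interval(1, 15), allow_internal_stops = TRUE), "M*MG")
  expect_error(translate_orf(rec, interval(1, 5)), "multiple of 3")

  # cross-check against an independent translation route on random CDSs
  set.seed(606)
  for (rep in 1:20) {
    n_codons <- sample(5:60, 1)
    s <- paste(sample(setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA")),
                      n_codons, replace = TRUE), collapse = "")
    s <- chartr("T", "U", s)
    rec <- genome_record("cds", s)
    got <- translate_orf(rec, interval(1, nchar(s)))
    want <- as.character(Biostrings::translate(Biostrings::RNAString(s)))
    expect_equal(got, want)
  }

  # fixture ORF1 translates to 765 residues
  g <- fixture_paper()
  expect_equal(nchar(translate_orf(g$record, g$truth$layout$orf1$interval)), 765L)
  expect_equal(nchar(translate_orf(g$record, g$truth$layout$orf2$interval)), 718L)
})

test_that("molecular mass is the residue sum plus one water, additive up to a water", {
  expect_equal(molecular_mass(""), 18.02, tolerance = 1e-3)
  expect_equal(molecular_mass("G"), 75.07, tolerance = 1e-3)
  expect_equal(molecular_mass("GG"), 132.12, tolerance = 1e-3)
  expect_error(molecular_mass("GXG"), "unknown residue 'X' at position 2")

  set.seed(707)
  aas <- names(ORACLE_AVG_MASS)
  for (rep in 1:25) {
    p1 <- paste(sample(aas, sample(3:50, 1), replace = TRUE), collapse = "")
    p2 <- paste(sample(aas, sample(3:50, 1), replace = TRUE), collapse = "")
    expect_equal(molecular_mass(p1), oracle_mass(p1), tolerance = 1e-8)
    expect_equal(molecular_mass(paste0(p1, p2)),
                 molecular_mass(p1) + molecular_mass(p2) - molecular_mass(""),
                 tolerance = 1e-8)
  }
  expect_lt(molecular_mass("G", monoisotopic = TRUE), molecular_mass("G"))
})

test_that("product modelling emits separate, fusion and bridge-extended models", {
  g <- fixture_paper()
  lay <- g$truth$layout

  # no slippery hit: exactly the two separate models
  p0 <- model_products(g$record, lay)
  expect_named(p0, c("separate_cp", "separate_rdrp"))
  expect_equal(p0$separate_cp$aa_length, 765L)
  expect_equal(p0$separate_rdrp$aa_length, 718L)
  # masses match an independent residue-summation oracle to < 0.01 Da
  expect_equal(p0$separate_cp$mass_da,
               oracle_mass(translate_orf(g$record, lay$orf1$interval)),
               tolerance = 0.01 / p0$separate_cp$mass_da)

  # fusion at the planted slippery site: resumes one nt back from the
  # heptamer end, continuing in the frame of the resumption point
  slip <- data.frame(start = 2555L, end = 2561L)
  pf <- model_products(g$record, lay, slippery_hit = slip, shift = -1L)
  fus <- pf$fusion
  expect_equal(fus$genomic_path$start, c(267L, 2560L))
  expect_equal(fus$genomic_path$end[1], 2560L)
  expect_equal(fus$genomic_path$frame, c(3L, 1L))
  # hand count: 764 complete ORF1-frame codons before the resumption point,
  # then codons from 2560 to the next in-frame stop
  cont_end <- fus$genomic_path$end[2]
  expect_equal((cont_end - 2560L + 1L) %% 3L, 0L)
  hand_aa <- (2560L - 267L) %/% 3L + (cont_end - 2560L + 1L) %/% 3L - 1L
  expect_equal(fus$aa_length, hand_aa)
  expect_gte(fus$aa_length, 764L)  # monotone extension over the CP portion
  # readthrough fixture: the shifted frame is ORF2's and reaches its stop
  expect_true(fus$reaches_orf2_frame)
  expect_false(fus$terminated_in_bridge)
  expect_equal(cont_end, lay$orf2$interval[["end"]])

  # bridge-extended model from the first stop-free in-phase start
  bs <- find_bridge_extension_start(g$record, lay)
  expect_false(is.na(bs))
  expect_equal((bs - lay$orf2$interval[["start"]]) %% 3L, 0L)
  pb <- model_products(g$record, lay, bridge_start = bs)
  expect_equal(pb$bridge_extended$aa_length,
               (lay$orf2$interval[["end"]] - bs + 1L) %/% 3L - 1L)
  expect_gt(pb$bridge_extended$mass_da, pb$separate_rdrp$mass_da)
})

test_that("a fusion whose shifted frame meets an immediate stop is flagged, not dropped", {
  # custom genome without readthrough protection: find a case where the
  # shifted reading terminates inside the bridge
  found <- FALSE
  for (seed in 1:30) {
    g <- generate_genome("custom", params = list(
      utr5_len = 30L, orf1_nt = 150L, bridge_len = 60L, orf2_nt = 150L,
      utr3_len = 20L, motif = NULL), seed = seed)
    lay <- g$truth$layout
    slip <- data.frame(start = g$truth$slippery$interval[["start"]],
                       end = g$truth$slippery$interval[["end"]])
    pf <- model_products(g$record, lay, slippery_hit = slip)
    if (isTRUE(pf$fusion$terminated_in_bridge)) {
      found <- TRUE
      expect_lt(pf$fusion$genomic_path$end[2], lay$orf2$interval[["start"]])
      break
    }
  }
  expect_true(found)
})
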