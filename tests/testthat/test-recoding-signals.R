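test_that("slippery scan agrees with the exhaustive consensus oracle", {
  expect_equal(slippery_distance("AAAUUUA"), 0L)
  expect_equal(slippery_distance("CCAAAAU"), 1L)
  set.seed(202)
  s <- rand_rna(200)
  rec <- genome_record("w", s)
  for (mm in 0:2) {
    got <- scan_slippery(rec, interval(1, 200), max_mismatch = mm)
    want_mm <- vapply(seq_len(194), function(i)
      oracle_slippery_distance(substr(s, i, i + 6L)), integer(1))
    want <- which(want_mm <= mm)
    expect_setequal(got$start, want)
    expect_equal(got$mismatches, want_mm[got$start])
    # reported heptamers re-extract from the genome at their intervals
    expect_equal(got$heptamer,
                 vapply(got$start, function(i) substr(s, i, i + 6L), character(1)))
  }
  # monotonicity in tolerance
  h0 <- scan_slippery(rec, interval(1, 200), 0)
  h1 <- scan_slippery(rec, interval(1, 200), 1)
  expect_true(all(h0$start %in% h1$start))
  expect_error(scan_slippery(rec, interval(1, 6)), "shorter than 7")
})

test_that("the junction of the paper-layout fixture carries the slippery-like heptamer", {
  g <- fixture_paper()
  stop_iv <- interval(2562, 2564)
  win <- interval(stop_iv[["start"]] - 40L, stop_iv[["end"]] + 10L)
  hits <- scan_slippery(g$record, win, max_mismatch = 1, orf1 = g$truth$layout$orf1)
  planted <- hits[hits$start == 2555, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$heptamer, "CCAAAAU")
  expect_equal(planted$end, 2561)
  expect_equal(planted$mismatches, 1L)
  # heptamer starts one nt before an ORF1 codon boundary
  expect_equal(planted$phase_note, (2555L - 267L) %% 3L)
})

test_that("facilitator scanning finds AUGA/UAAUG with frame-consistency flags", {
  # UAAUG spanning an in-phase stop
  rec <- genome_record("f1", paste0("GGGGG", "GAUAAUGGC", "GGGGG"))
  hits <- scan_facilitators(rec, orf1_stop = interval(8, 10), window_up = 5, window_down = 5)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif, "UAAUG")
  expect_equal(hits$start, 8L)
  expect_true(hits$stop_frame_consistent)

  # AUGA alone
  rec2 <- genome_record("f2", "CCAUGACC")
  hits2 <- scan_facilitators(rec2, orf1_stop = interval(4, 6), window_up = 3, window_down = 3)
  expect_true("AUGA" %in% hits2$motif)
  a <- hits2[hits2$motif == "AUGA", ]
  expect_equal(a$start, 3L)
  expect_true(a$stop_frame_consistent)  # UGA at [4,6] is the anchored stop itself

  # out-of-phase stop triplet is flagged inconsistent
  hits3 <- scan_facilitators(rec2, orf1_stop = interval(4, 6), window_up = 3,
                             window_down = 3, orf1_frame_anchor = 5L)
  expect_false(hits3[hits3$motif == "AUGA", "stop_frame_consistent"])

  # the paper-layout fixture is built without facilitators
  g <- fixture_paper()
  fac <- scan_facilitators(g$record, interval(2562, 2564))
  expect_equal(nrow(fac), 0L)
})

test_that("UTR motif scan reports both the octamer and its 15-nt extension", {
  g <- fixture_paper()
  hits <- scan_utr_motifs(g$record, g$truth$layout)
  expect_equal(nrow(hits), 2L)
  oct <- hits[hits$motif_id == "AGGGUUCC", ]
  expect_equal(unname(c(oct$start, oct$end)), c(204L, 211L))
  expect_equal(oct$distance_to_orf1_start, 55L)
  ext <- hits[hits$motif_id == "AGGGUUCCGUUGAUC", ]
  expect_equal(unname(c(ext$start, ext$end)), c(204L, 218L))
  # coordinate fidelity: re-extraction equals the stored motif
  for (i in seq_len(nrow(hits))) {
    expect_equal(subseq_at(g$record, interval(hits$start[i], hits$end[i])),
                 hits$motif_id[i])
  }
  # absent motif
  none <- scan_utr_motifs(g$record, g$truth$layout, motif_set = "AGGGGGGGGC")
  expect_equal(nrow(none), 0L)
})

test_that("Ala/Gly/Pro-rich detection equals a sliding-window recount", {
  r <- find_agp_rich("AAAAAGGGGG", window_aa = 5, threshold = 0.8)
  expect_equal(unname(unlist(r)), c(1, 10, 1.0))
  expect_equal(nrow(find_agp_rich(strrep("L", 50), window_aa = 5, threshold = 0.5)), 0L)
  expect_warning(find_agp_rich("AG", window_aa = 5, threshold = 0.5), "shorter")

  set.seed(303)
  aas <- names(ORACLE_AVG_MASS)
  for (rep in 1:20) {
    prot <- paste(sample(aas, 120, replace = TRUE), collapse = "")
    got <- find_agp_rich(prot, window_aa = 10, threshold = 0.6)
    # oracle: recount every window, take the union of qualifying windows
    ch <- strsplit(prot, "")[[1]] %in% c("A", "G", "P")
    qual <- vapply(1:111, function(i) mean(ch[i:(i + 9)]) >= 0.6, logical(1))
    covered <- rep(FALSE, 120)
    for (i in which(qual)) covered[i:(i + 9)] <- TRUE
    got_cov <- rep(FALSE, 120)
    if (nrow(got) > 0) for (i in seq_len(nrow(got))) got_cov[got$start[i]:got$end[i]] <- TRUE
    expect_equal(got_cov, covered, info = sprintf("rep %d", rep))
    if (nrow(got) > 0) {
      for (i in seq_len(nrow(got))) {
        expect_equal(got$fraction[i], mean(ch[got$start[i]:got$end[i]]))
      }
    }
  }
})
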