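test_that("stem enumeration matches the anti-diagonal pairing oracle", {
  rec <- genome_record("h", "GGGGAAAACCCC")
  st <- enumerate_stems(rec, interval(1, 12), min_pairs = 3)
  expect_equal(nrow(st), 1L)
  expect_equal(unname(unlist(st[1, 1:5])), c(1, 4, 9, 12, 4))
  expect_equal(st$score, 4 * 3)

  expect_equal(nrow(enumerate_stems(genome_record("a", strrep("A", 30)),
                                    interval(1, 30), 3)), 0L)

  set.seed(404)
  for (rep in 1:25) {
    s <- rand_rna(60)
    rec <- genome_record(sprintf("r%d", rep), s)
    for (mp in 2:4) {
      got <- enumerate_stems(rec, interval(1, 60), min_pairs = mp)
      want <- oracle_stems(s, min_pairs = mp)
      expect_equal(got, want, info = sprintf("rep %d min_pairs %d", rep, mp))
    }
    # monotonicity: lowering min_pairs never removes a structure
    g2 <- enumerate_stems(rec, interval(1, 60), min_pairs = 2)
    g4 <- enumerate_stems(rec, interval(1, 60), min_pairs = 4)
    expect_true(all(do.call(paste, g4) %in% do.call(paste, g2)))
  }
})

test_that("stem-loops are reported 5' first and respect loop bounds", {
  rec <- genome_record("h", "GGGGAAAACCCC")
  sl <- find_stem_loops(rec, interval(1, 12), min_pairs = 3)
  expect_equal(nrow(sl), 1L)
  expect_equal(c(sl$loop_start, sl$loop_end), c(5L, 8L))

  # tandem hairpins: both reported, in genome order
  s <- paste0("GGCGC", "AAAA", "GCGCC", "AAA", "GGGUGU", "AAAAA", "ACACCC")
  rec2 <- genome_record("tandem", s)
  sl2 <- find_stem_loops(rec2, interval(1, nchar(s)), min_pairs = 4)
  expect_gte(nrow(sl2), 2L)
  expect_true(all(diff(sl2$arm5_start) > 0))
  expect_equal(sl2$arm5_start[1:2], sort(sl2$arm5_start[1:2]))

  expect_equal(nrow(find_stem_loops(genome_record("n", strrep("AC", 20)),
                                    interval(1, 40), 3)), 0L)
})

test_that("planted H-type pseudoknots are recovered (arm overlap >= 80% in >= 95/100)", {
  hits <- 0L
  for (seed in 1:100) {
    fx <- make_pk_fixture(seed)
    rec <- genome_record(sprintf("pk%d", seed), fx$seq)
    pks <- find_pseudoknots(rec, interval(1, nchar(fx$seq)), min_pairs = 3,
                            max_span = nchar(fx$seq))
    if (nrow(pks) == 0L) next
    top <- pks[pks$primary, ][1, ]
    ok <- iv_overlap_frac(fx$truth$s1_arm5, c(top$s1_arm5_start, top$s1_arm5_end)) >= 0.8 &&
      iv_overlap_frac(fx$truth$s1_arm3, c(top$s1_arm3_start, top$s1_arm3_end)) >= 0.8 &&
      iv_overlap_frac(fx$truth$s2_arm5, c(top$s2_arm5_start, top$s2_arm5_end)) >= 0.8 &&
      iv_overlap_frac(fx$truth$s2_arm3, c(top$s2_arm3_start, top$s2_arm3_end)) >= 0.8
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("pseudoknot output satisfies the crossing topology and pairing consistency", {
  fx <- make_pk_fixture(7)
  rec <- genome_record("pk", fx$seq)
  pks <- find_pseudoknots(rec, interval(1, nchar(fx$seq)), min_pairs = 3,
                          max_span = nchar(fx$seq))
  expect_gt(nrow(pks), 0L)
  for (i in seq_len(nrow(pks))) {
    p <- pks[i, ]
    # H-type crossing: stem2 5' arm inside stem1 loop, 3' arm beyond stem1
    expect_gt(p$s2_arm5_start, p$s1_arm5_end)
    expect_lt(p$s2_arm5_end, p$s1_arm3_start)
    expect_gt(p$s2_arm3_start, p$s1_arm3_end)
    # no position paired twice
    pos <- c(p$s1_arm5_start:p$s1_arm5_end, p$s1_arm3_start:p$s1_arm3_end,
             p$s2_arm5_start:p$s2_arm5_end, p$s2_arm3_start:p$s2_arm3_end)
    expect_equal(anyDuplicated(pos), 0L)
  }
  # a single hairpin cannot form a pseudoknot
  solo <- genome_record("solo", "GGGGAAAACCCC")
  expect_equal(nrow(find_pseudoknots(solo, interval(1, 12), 3)), 0L)
  # dot-bracket serialization marks the two stems distinctly
  db <- pk_dotbracket(pks[pks$primary, ][1, ])
  expect_match(db, "^\\(+.*\\[+.*\\)+.*\\]+$")
})

test_that("small-window pseudoknot search equals brute-force crossing enumeration", {
  set.seed(505)
  for (rep in 1:10) {
    s <- rand_rna(40)
    rec <- genome_record(sprintf("bf%d", rep), s)
    got <- find_pseudoknots(rec, interval(1, 40), min_pairs = 2, max_span = 40)
    stems <- oracle_stems(s, min_pairs = 2)
    want <- 0L
    if (nrow(stems) >= 2) {
      for (a in seq_len(nrow(stems))) for (b in seq_len(nrow(stems))) {
        if (a == b) next
        s1 <- stems[a, ]; s2 <- stems[b, ]
        if (s2$arm5_start > s1$arm5_end && s2$arm5_end < s1$arm3_start &&
            s2$arm3_start > s1$arm3_end && (s2$arm3_end - s1$arm5_start + 1L) <= 40L) {
          want <- want + 1L
        }
      }
    }
    expect_equal(nrow(got), want, info = sprintf("rep %d", rep))
  }
})
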