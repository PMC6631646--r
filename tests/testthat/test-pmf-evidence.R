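test_that("tryptic digestion follows cleave-after-K/R-not-before-P", {
  expect_equal(digest_protein("MKRAPK")$sequence, c("MK", "R", "APK"))
  expect_equal(digest_protein("AAA")$sequence, "AAA")
  expect_equal(digest_protein("AKPA")$sequence, "AKPA")

  set.seed(808)
  aas <- names(ORACLE_AVG_MASS)
  for (rep in 1:50) {
    prot <- paste(sample(aas, sample(1:200, 1), replace = TRUE), collapse = "")
    d0 <- digest_protein(prot, 0L)
    expect_equal(d0$sequence, oracle_digest(prot), info = sprintf("rep %d", rep))
    # conservation: fragments concatenate back to the protein
    expect_equal(paste(d0$sequence, collapse = ""), prot)
    expect_equal(d0$start, c(1L, head(d0$end, -1) + 1L))
    # missed cleavages: concatenations of <= m+1 adjacent fragments
    m <- sample(1:3, 1)
    dm <- digest_protein(prot, m)
    base <- d0$sequence
    want <- unlist(lapply(seq_along(base), function(i)
      vapply(0:min(m, length(base) - i), function(k)
        paste(base[i:(i + k)], collapse = ""), character(1))))
    expect_setequal(paste(dm$sequence, dm$start),
                    paste(want, rep(d0$start, pmin(m, length(base) - seq_along(base)) + 1L)))
  }
})

test_that("frame index back-maps round-trip through translation", {
  rec <- genome_record("fi", "AUGGCA")
  idx <- build_frame_index(rec)
  expect_equal(idx$translations[["F1"]], "MA")
  expect_equal(unname(frame_backmap(idx, "F1", 2, 2)), c(4L, 6L))
  expect_length(idx$translations, 3L)
  expect_length(build_frame_index(rec, reverse = TRUE)$translations, 6L)

  set.seed(909)
  for (rep in 1:15) {
    s <- rand_rna(sample(90:300, 1))
    rec <- genome_record(sprintf("g%d", rep), s)
    idx <- build_frame_index(rec)
    for (fn in names(idx$translations)) {
      tr <- idx$translations[[fn]]
      for (i in sample(seq_len(nchar(tr)), min(10, nchar(tr)))) {
        gi <- frame_backmap(idx, fn, i, i)
        want <- substr(tr, i, i)
        if (want == "*") {
          # a lone stop codon translates to the empty product
          expect_true(subseq_at(rec, gi) %in% c("UAA", "UAG", "UGA"))
        } else {
          expect_equal(translate_orf(rec, gi, allow_internal_stops = TRUE), want)
        }
      }
    }
  }
})

test_that("peptides map to exact frame placements with correct regions", {
  g <- fixture_paper()
  idx <- build_frame_index(g$record)
  lay <- g$truth$layout

  m <- map_peptides(c("TASDLDLYLK", "WWWWWWWW"), idx, lay)
  expect_equal(m$unmatched, "WWWWWWWW")
  hit <- m$matches[m$matches$peptide == "TASDLDLYLK", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$frame, 1L)
  expect_equal(unname(c(hit$start, hit$end)), c(2593L, 2622L))
  expect_equal(hit$region, "bridge")
  expect_equal(interval_length(interval(hit$start, hit$end)), 3L * nchar("TASDLDLYLK"))
  # coordinate fidelity: re-translation from the genome equals the peptide
  expect_equal(translate_orf(g$record, interval(hit$start, hit$end)), "TASDLDLYLK")

  # peptides digested from the capsid map inside ORF1 in ORF1's frame
  cp <- translate_orf(g$record, lay$orf1$interval)
  peps <- digest_protein(cp)$sequence
  peps <- peps[nchar(peps) >= 8][1:5]
  mm <- map_peptides(peps, idx, lay)
  expect_equal(length(mm$unmatched), 0L)
  own <- mm$matches[mm$matches$frame == lay$orf1$frame & mm$matches$region == "ORF1", ]
  expect_true(all(peps %in% own$peptide))
})

test_that("multi-placement peptides yield one match per occurrence", {
  s <- paste0("G", "AUGGCAGCUGCC", "GG", "AUGGCAGCUGCC", "G")
  rec <- genome_record("dup", s)
  idx <- build_frame_index(rec)
  lay <- list(orf1 = list(interval = interval(1, 3)),
              bridge = list(kind = "gap", interval = interval(4, 6)),
              orf2 = list(interval = interval(7, 9)))
  m <- map_peptides("MAAA", idx, lay)
  expect_equal(nrow(m$matches), 2L)
  expect_equal(sort(m$matches$start), c(2L, 16L))
})

test_that("adjudication applies the rules in order on constructed evidence", {
  g <- fixture_paper()
  lay <- g$truth$layout
  slip <- data.frame(start = 2555L, end = 2561L)
  bs <- find_bridge_extension_start(g$record, lay)
  products <- model_products(g$record, lay, slippery_hit = slip, bridge_start = bs)
  idx <- build_frame_index(g$record)

  cp_peps <- digest_protein(products$separate_cp$residues)$sequence
  rdrp_peps <- digest_protein(products$separate_rdrp$residues)$sequence
  cp_peps <- cp_peps[nchar(cp_peps) >= 6]
  rdrp_peps <- rdrp_peps[nchar(rdrp_peps) >= 6]

  # both ORFs represented at the separate-product band mass
  m <- map_peptides(c(cp_peps[1:8], rdrp_peps[1:8]), idx, lay)
  v <- adjudicate(m, products$separate_cp$mass_da, products)
  expect_equal(v$verdict, "two_separate_products")

  # band at the fusion mass
  fus_peps <- digest_protein(products$fusion$residues)$sequence
  fus_peps <- fus_peps[nchar(fus_peps) >= 6]
  mf <- map_peptides(fus_peps[1:15], idx, lay)
  vf <- adjudicate(mf, products$fusion$mass_da, products)
  expect_equal(vf$verdict, "fusion_product")

  # ORF1-only evidence is inconclusive
  m1 <- map_peptides(cp_peps[1:8], idx, lay)
  v1 <- adjudicate(m1, products$separate_cp$mass_da, products)
  expect_equal(v1$verdict, "inconclusive")

  # no matches at all: inconclusive with a warning
  expect_warning(
    v0 <- adjudicate(map_peptides("WWWWWWWW", idx, lay), 80000, products),
    "inconclusive")
  expect_equal(v0$verdict, "inconclusive")
})
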