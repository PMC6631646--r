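# Codons by amino acid (RNA alphabet), for seed-determined synonymous
# reverse translation of planted peptide anchors.
.codons_for <- local({
  inv <- NULL
  function(aa) {
    if (is.null(inv)) {
      tbl <- .codon_table()
      inv <<- split(names(tbl), unname(tbl))
    }
    inv[[aa]]
  }
})

.NONSTOP_CODONS <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) tbl <<- setdiff(paste0(
      rep(c("A", "C", "G", "U"), each = 16),
      rep(rep(c("A", "C", "G", "U"), each = 4), 4),
      rep(c("A", "C", "G", "U"), 16)), c("UAA", "UAG", "UGA"))
    tbl
  }
})

.rand_bases <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.rev_translate <- function(peptide) {
  paste(vapply(strsplit(peptide, "")[[1]],
               function(a) sample(.codons_for(a), 1L), character(1)),
        collapse = "")
}

# overwrite s[at .. at+nchar(piece)-1] with piece
.splice <- function(s, at, piece) {
  paste0(substr(s, 1L, at - 1L), piece, substr(s, at + nchar(piece), nchar(s)))
}

#' Default parameters of the victorivirus-like genome presets
#'
#' The `paper_layout` preset emulates the canonical victorivirus
#' organization: 266-nt 5'UTR, 2298-nt capsid ORF at [267, 2564], 322-nt
#' inter-ORF bridge at [2565, 2886], 2157-nt RdRp ORF at [2887, 5043] and
#' 77-nt 3'UTR, totalling 5120 nt; the conserved 15-nt 5'UTR motif
#' AGGGUUCCGUUGAUC planted at [204, 218] (so the core octanucleotide sits
#' at [204, 211], 55 nt upstream of the ORF1 AUG), the slippery-like
#' heptamer CCAAAAU at [2555, 2561] immediately upstream of the ORF1 stop,
#' no stop-restart facilitator, and bridge codons for the tryptic peptide
#' TASDLDLYLK at [2593, 2622] in the RdRp frame.
#'
#' @param preset `"paper_layout"` or `"custom"`.
#' @return Named list of generator parameters.
#' @export
genome_preset <- function(preset = c("paper_layout", "custom")) {
  preset <- match.arg(preset)
  base <- list(
    utr5_len = 266L, orf1_nt = 2298L, bridge_len = 322L,
    orf2_nt = 2157L, utr3_len = 77L,
    gc = 0.5,
    motif = "AGGGUUCCGUUGAUC", motif_start = 204L,
    slippery = "CCAAAAU", slippery_start = NULL,  # NULL: ends 3 nt before ORF1 stop
    orf1_stop = "UAG", orf2_stop = "UAA",
    facilitator = "none",              # "none", "AUGA" or "UAAUG"
    peptide_anchor = "TASDLDLYLK", anchor_start = 2593L,
    # stop- and AUG-free bridge in ORF2's codon phase, so frame-indexed
    # translation of the RdRp frame runs from the junction through the
    # bridge into ORF2 (the junction arrangement this layout emulates)
    bridge_readthrough = TRUE
  )
  if (preset == "custom") {
    base$motif <- "AGGGUUCC"
    base$peptide_anchor <- NULL
    base$anchor_start <- NULL
    base$bridge_readthrough <- FALSE
  }
  base
}

.validate_params <- function(p) {
  if (p$orf1_nt %% 3L != 0L || p$orf2_nt %% 3L != 0L) {
    stop("infeasible params: ORF lengths must be multiples of 3")
  }
  if (p$orf1_nt < 12L || p$orf2_nt < 12L) stop("infeasible params: ORFs too short")
  if (!is.null(p$motif)) {
    if (p$motif_start < 1L || p$motif_start + nchar(p$motif) - 1L > p$utr5_len) {
      stop("infeasible params: motif outside the 5'UTR")
    }
  }
  if (!p$facilitator %in% c("none", "AUGA", "UAAUG")) {
    stop("infeasible params: unknown facilitator")
  }
  if (p$facilitator == "UAAUG" && p$bridge_len < 2L) {
    stop("infeasible params: UAAUG facilitator needs a bridge of >= 2 nt")
  }
  invisible(p)
}

.assemble_genome <- function(p, coords) {
  n_inner1 <- p$orf1_nt %/% 3L - 2L
  n_inner2 <- p$orf2_nt %/% 3L - 2L
  utr5 <- .rand_bases(p$utr5_len, p$gc)
  if (!is.null(p$motif)) utr5 <- .splice(utr5, p$motif_start, p$motif)
  orf1 <- paste0("AUG", paste(sample(.NONSTOP_CODONS(), n_inner1, replace = TRUE),
                              collapse = ""), p$orf1_stop)
  if (!is.null(p$slippery)) {
    slip_at <- coords$slippery_start - coords$orf1_start + 1L
    orf1 <- .splice(orf1, slip_at, p$slippery)
  }
  if (p$facilitator == "AUGA") {
    # A immediately before the UGA stop: ...A|UGA...
    orf1 <- .splice(orf1, p$orf1_nt - 3L, "A")
  }
  if (isTRUE(p$bridge_readthrough)) {
    # build the bridge as ORF2-phase codons drawn from {non-stop, non-AUG},
    # so the RdRp-frame reading crosses the bridge without terminating and
    # the annotated ORF2 still starts at its own AUG
    p0 <- coords$bridge_start +
      ((coords$orf2_start - coords$bridge_start) %% 3L)
    lead <- p0 - coords$bridge_start
    n_codons <- (coords$orf2_start - p0) %/% 3L
    tail_len <- p$bridge_len - lead - 3L * n_codons
    allowed <- setdiff(.NONSTOP_CODONS(), "AUG")
    bridge <- paste0(.rand_bases(lead, p$gc),
                     paste(sample(allowed, n_codons, replace = TRUE), collapse = ""),
                     .rand_bases(tail_len, p$gc))
  } else {
    bridge <- .rand_bases(p$bridge_len, p$gc)
  }
  if (p$facilitator == "UAAUG") bridge <- .splice(bridge, 1L, "UG")
  if (!is.null(p$peptide_anchor)) {
    anchor_at <- p$anchor_start - coords$bridge_start + 1L
    bridge <- .splice(bridge, anchor_at, .rev_translate(p$peptide_anchor))
  }
  orf2 <- paste0("AUG", paste(sample(.NONSTOP_CODONS(), n_inner2, replace = TRUE),
                              collapse = ""), p$orf2_stop)
  utr3 <- .rand_bases(p$utr3_len, p$gc)
  paste0(utr5, orf1, bridge, orf2, utr3)
}

# truth-recovery check for one assembled candidate; returns TRUE/FALSE
.verify_genome <- function(rec, p, coords) {
  min_aa_chk <- min(100L, p$orf1_nt %/% 3L - 1L, p$orf2_nt %/% 3L - 1L)
  lay <- tryCatch(classify_layout(rec, min_aa = min_aa_chk), error = function(e) NULL)
  if (is.null(lay)) return(FALSE)
  ok <- lay$orf1$interval[["start"]] == coords$orf1_start &&
    lay$orf1$interval[["end"]] == coords$orf1_end &&
    lay$orf2$interval[["start"]] == coords$orf2_start &&
    lay$orf2$interval[["end"]] == coords$orf2_end
  if (!ok) return(FALSE)
  # facilitator content of the default junction scan window must match intent
  fac <- scan_facilitators(rec, interval(coords$orf1_end - 2L, coords$orf1_end))
  if (p$facilitator == "none") {
    if (nrow(fac) > 0L) return(FALSE)
  } else {
    planted_start <- if (p$facilitator == "AUGA") coords$orf1_end - 3L else coords$orf1_end - 2L
    if (!(nrow(fac) == 1L && fac$motif[1] == p$facilitator &&
          fac$start[1] == planted_start)) return(FALSE)
  }
  # UTR motif must occur exactly where planted (unique core occurrence)
  if (!is.null(p$motif)) {
    core <- substr(p$motif, 1L, 8L)
    occ <- gregexpr(core, substr(rec$sequence, 1L, p$utr5_len), fixed = TRUE)[[1]]
    if (length(occ) != 1L || occ[1] != p$motif_start) return(FALSE)
  }
  # planted peptide anchor must be unique in its frame translation
  if (!is.null(p$peptide_anchor)) {
    idx <- build_frame_index(rec)
    fn <- paste0("F", frame_of(p$anchor_start))
    hits <- .aa_matches(idx$translations[[fn]], p$peptide_anchor)
    other <- setdiff(names(idx$translations), fn)
    extra <- sum(vapply(other, function(f)
      length(.aa_matches(idx$translations[[f]], p$peptide_anchor)), integer(1)))
    if (length(hits) != 1L || extra > 0L) return(FALSE)
    gi <- frame_backmap(idx, fn, hits[1], hits[1] + nchar(p$peptide_anchor) - 1L)
    if (gi[["start"]] != p$anchor_start) return(FALSE)
  }
  TRUE
}

#' Generate a victorivirus-like genome with a known truth layout
#'
#' Builds 5'UTR + ORF1 + bridge + ORF2 + 3'UTR from random codons (uniform
#' over non-stop codons inside ORFs) with the configured signals planted,
#' then self-certifies: the candidate is re-annotated and re-scanned, and
#' random regions are resampled (deterministically, from the seeded RNG)
#' until the truth layout is recovered exactly, the junction scan window
#' contains exactly the intended facilitators, and planted motifs/anchors
#' are unique. Deterministic for a fixed seed.
#'
#' @param preset `"paper_layout"` or `"custom"`.
#' @param params Named overrides of [genome_preset()] values.
#' @param seed Integer seed.
#' @param id Record id.
#' @param max_tries Resampling budget before giving up.
#' @return List: `record` (a `genome_record`), `truth` (a `truth_layout`:
#'   the `bicistronic_layout` plus planted-signal coordinates and the
#'   seed), `params`.
#' @export
generate_genome <- function(preset = c("paper_layout", "custom"), params = list(),
                            seed = 1L, id = NULL, max_tries = 60L) {
  preset <- match.arg(preset)
  p <- utils::modifyList(genome_preset(preset), params, keep.null = TRUE)
  # a facilitator dictates the ORF1 stop codon it overlaps
  if (identical(p$facilitator, "UAAUG")) p$orf1_stop <- "UAA"
  if (identical(p$facilitator, "AUGA")) p$orf1_stop <- "UGA"
  .validate_params(p)

  glen <- p$utr5_len + p$orf1_nt + p$bridge_len + p$orf2_nt + p$utr3_len
  coords <- list(
    orf1_start = p$utr5_len + 1L,
    orf1_end = p$utr5_len + p$orf1_nt,
    bridge_start = p$utr5_len + p$orf1_nt + 1L,
    orf2_start = p$utr5_len + p$orf1_nt + p$bridge_len + 1L,
    orf2_end = p$utr5_len + p$orf1_nt + p$bridge_len + p$orf2_nt
  )
  if (is.null(p$slippery_start) && !is.null(p$slippery)) {
    p$slippery_start <- coords$orf1_end - 3L - nchar(p$slippery) + 1L
  }
  coords$slippery_start <- p$slippery_start
  if (!is.null(p$slippery)) {
    if (p$slippery_start <= coords$orf1_start + 2L ||
        p$slippery_start + nchar(p$slippery) - 1L > coords$orf1_end - 3L) {
      stop("infeasible params: slippery site must lie inside ORF1, before its stop")
    }
    if (p$facilitator == "AUGA" &&
        p$slippery_start + nchar(p$slippery) - 1L >= coords$orf1_end - 3L &&
        substr(p$slippery, nchar(p$slippery), nchar(p$slippery)) != "A") {
      stop("infeasible params: AUGA facilitator conflicts with the planted slippery site")
    }
  }
  if (!is.null(p$peptide_anchor)) {
    if (is.null(p$anchor_start)) stop("infeasible params: anchor without anchor_start")
    a_end <- p$anchor_start + 3L * nchar(p$peptide_anchor) - 1L
    if (p$anchor_start < coords$bridge_start || a_end > coords$orf2_start - 1L) {
      stop("infeasible params: peptide anchor outside the bridge")
    }
    if ((p$anchor_start - coords$orf2_start) %% 3L != 0L) {
      stop("infeasible params: peptide anchor not in ORF2's codon phase")
    }
  }
  if (is.null(id)) id <- sprintf("synthetic_victorivirus_%s_seed%d", preset, seed)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  rec <- NULL
  for (try in seq_len(max_tries)) {
    cand <- genome_record(id, .assemble_genome(p, coords))
    if (.verify_genome(cand, p, coords)) { rec <- cand; break }
  }
  if (is.null(rec)) stop("failed to generate a verifiable genome within max_tries")

  min_aa_chk <- min(100L, p$orf1_nt %/% 3L - 1L, p$orf2_nt %/% 3L - 1L)
  layout <- classify_layout(rec, min_aa = min_aa_chk)
  truth <- structure(list(
    layout = layout,
    genome_length = glen,
    motif = if (is.null(p$motif)) NULL else list(
      sequence = p$motif,
      interval = interval(p$motif_start, p$motif_start + nchar(p$motif) - 1L)),
    slippery = if (is.null(p$slippery)) NULL else list(
      heptamer = p$slippery,
      interval = interval(p$slippery_start, p$slippery_start + nchar(p$slippery) - 1L),
      mismatches = slippery_distance(p$slippery)),
    facilitator = if (p$facilitator == "none") NULL else list(
      motif = p$facilitator,
      interval = if (p$facilitator == "AUGA") interval(coords$orf1_end - 3L, coords$orf1_end)
                 else interval(coords$orf1_end - 2L, coords$orf1_end + 2L)),
    peptide_anchor = if (is.null(p$peptide_anchor)) NULL else list(
      peptide = p$peptide_anchor,
      interval = interval(p$anchor_start, p$anchor_start + 3L * nchar(p$peptide_anchor) - 1L),
      frame = frame_of(p$anchor_start)),
    seed = as.integer(seed), preset = preset
  ), class = "truth_layout")
  list(record = rec, truth = truth, params = p)
}

#' Simulate peptide-mass-fingerprint observations for a gel band
#'
#' Digests the scenario's true product(s) in silico, samples peptides of at
#' least `min_peptide_len` residues uniformly without replacement (then
#' with replacement once the pool is exhausted), and injects random decoy
#' peptides at `contamination_rate`. Scenarios: `separate` — capsid and
#' RdRp co-migrating in one band at the capsid mass; `fusion` — the -1
#' frameshift fusion product at its mass; `bridge_extended` — a
#' bridge-extended RdRp band at its mass.
#'
#' @param record,truth From [generate_genome()].
#' @param scenario `"separate"`, `"fusion"` or `"bridge_extended"`.
#' @param n_peptides Number of true peptides sampled (>= 1).
#' @param seed Integer seed.
#' @param contamination_rate Decoy fraction in [0, 0.5).
#' @param missed_cleavages Passed to [digest_protein()].
#' @param min_peptide_len Shortest peptide considered identifiable.
#' @return List: `peptides` (data.frame `sequence`, `source` in
#'   {product, decoy}), `band_mass_da`, `scenario`, `products` (the
#'   product-model list used).
#' @export
simulate_pmf <- function(record, truth, scenario = c("separate", "fusion", "bridge_extended"),
                         n_peptides = 30L, seed = 1L, contamination_rate = 0,
                         missed_cleavages = 0L, min_peptide_len = 6L) {
  scenario <- match.arg(scenario)
  stopifnot(n_peptides >= 1L, contamination_rate >= 0, contamination_rate < 0.5)
  layout <- truth$layout

  slip <- if (!is.null(truth$slippery)) {
    data.frame(start = truth$slippery$interval[["start"]],
               end = truth$slippery$interval[["end"]],
               heptamer = truth$slippery$heptamer,
               mismatches = truth$slippery$mismatches)
  } else NULL
  if (scenario == "fusion" && is.null(slip)) {
    stop("fusion scenario requires a slippery site in the truth layout")
  }
  bridge_start <- if (scenario == "bridge_extended") {
    bs <- find_bridge_extension_start(record, layout)
    if (is.na(bs)) stop("bridge_extended scenario: no stop-free upstream extension exists")
    bs
  } else NULL
  products <- model_products(record, layout, slippery_hit = slip,
                             bridge_start = bridge_start)

  digested <- switch(scenario,
    separate = list(products$separate_cp, products$separate_rdrp),
    fusion = list(products$fusion),
    bridge_extended = list(products$bridge_extended))
  band_mass <- switch(scenario,
    separate = products$separate_cp$mass_da,
    fusion = products$fusion$mass_da,
    bridge_extended = products$bridge_extended$mass_da)

  pool <- unique(unlist(lapply(digested, function(pr) {
    # digest each stop-free segment (bridge-extended chains may contain *)
    unlist(lapply(strsplit(pr$residues, "*", fixed = TRUE)[[1]], function(seg) {
      if (nchar(seg) == 0L) character(0) else digest_protein(seg, missed_cleavages)$sequence
    }))
  })))
  pool <- pool[nchar(pool) >= min_peptide_len]
  if (length(pool) == 0L) stop("scenario product yields no identifiable peptides")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  take <- min(n_peptides, length(pool))
  sampled <- sample(pool, take, replace = FALSE)
  if (n_peptides > take) {
    sampled <- c(sampled, sample(pool, n_peptides - take, replace = TRUE))
  }
  out <- data.frame(sequence = sampled, source = "product", stringsAsFactors = FALSE)

  n_decoy <- round(contamination_rate * n_peptides)
  if (n_decoy > 0L) {
    idx <- build_frame_index(record)
    decoys <- character(0)
    while (length(decoys) < n_decoy) {
      d <- paste(sample(names(.AVG_RESIDUE_MASS), sample(8:12, 1L), replace = TRUE),
                 collapse = "")
      hits <- sum(vapply(idx$translations, function(tr) length(.aa_matches(tr, d)),
                         integer(1)))
      if (hits == 0L) decoys <- c(decoys, d)
    }
    out <- rbind(out, data.frame(sequence = decoys, source = "decoy",
                                 stringsAsFactors = FALSE))
  }
  list(peptides = out, band_mass_da = band_mass, scenario = scenario,
       products = products)
}
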