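# Average and monoisotopic residue masses (Da) for the 20 standard amino
# acids, plus the mass of water added once per chain.
.AVG_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.MONO_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.WATER_AVG <- 18.0153
.WATER_MONO <- 18.010565

# Codon -> amino acid, standard genetic code; stops translate to "*".
.codon_table <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) {
      tbl <- Biostrings::GENETIC_CODE
      names(tbl) <- chartr("T", "U", names(tbl))
      gc <<- tbl
    }
    gc
  }
})

#' Translate a genomic interval with the standard genetic code
#'
#' The trailing stop codon, if present, is dropped from the product. An
#' internal stop is an error (with its codon position) unless
#' `allow_internal_stops` is set, in which case stops appear as `*`.
#'
#' @param record A `genome_record`.
#' @param iv `interval` to translate (plus strand).
#' @param frame_check When `TRUE` (default), require the interval length to
#'   be a multiple of 3.
#' @param allow_internal_stops Translate internal stops as `*` instead of
#'   erroring.
#' @return Residue string (uppercase one-letter code).
#' @export
translate_orf <- function(record, iv, frame_check = TRUE, allow_internal_stops = FALSE) {
  len <- interval_length(iv)
  if (frame_check && len %% 3L != 0L) {
    stop(sprintf("interval length %d is not a multiple of 3", len))
  }
  s <- subseq_at(record, iv)
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(s, starts, starts + 2L)
  aa <- .codon_table()[codons]
  if (anyNA(aa)) stop("interval contains a non-translatable codon")
  if (aa[n_codons] == "*") aa <- aa[-n_codons]  # trailing stop dropped
  internal <- which(aa == "*")
  if (length(internal) > 0L && !allow_internal_stops) {
    pos <- iv[["start"]] + (internal[1] - 1L) * 3L
    stop(sprintf("internal stop codon at genome position %d", pos))
  }
  paste(aa, collapse = "")
}

#' Molecular mass of a protein
#'
#' Sum of residue masses plus one water. Average isotopic masses by default
#' (the right scale for comparison with SDS-PAGE band estimates);
#' monoisotopic on request for mass-spectrometry work.
#'
#' @param protein Residue string over the 20-letter alphabet (empty allowed:
#'   returns the water mass).
#' @param monoisotopic Use monoisotopic masses instead of average.
#' @return Mass in Daltons.
#' @export
molecular_mass <- function(protein, monoisotopic = FALSE) {
  tbl <- if (monoisotopic) .MONO_RESIDUE_MASS else .AVG_RESIDUE_MASS
  water <- if (monoisotopic) .WATER_MONO else .WATER_AVG
  if (nchar(protein) == 0L) return(water)
  res <- strsplit(protein, "")[[1]]
  m <- tbl[res]
  if (anyNA(m)) {
    stop(sprintf("unknown residue '%s' at position %d", res[which(is.na(m))[1]],
                 which(is.na(m))[1]))
  }
  sum(m) + water
}

# Translate a -1/+1-shifted continuation: codons from position j in the
# frame of j, to the first stop (inclusive end returned) or window end.
.shifted_continuation <- function(record, j) {
  n <- record$length
  pos <- j
  aa <- character(0)
  tbl <- .codon_table()
  terminated <- FALSE
  while (pos + 2L <= n) {
    codon <- substr(record$sequence, pos, pos + 2L)
    a <- tbl[[codon]]
    if (a == "*") { terminated <- TRUE; pos <- pos + 2L; break }
    aa <- c(aa, a)
    pos <- pos + 3L
  }
  list(residues = paste(aa, collapse = ""),
       end = if (terminated) pos else pos - 1L,
       terminated = terminated)
}

#' Model the candidate protein products of each translation strategy
#'
#' Always emits the two separate products (capsid from ORF1, RdRp from
#' ORF2). If a slippery-site hit is supplied, additionally emits a -1
#' frameshift fusion product: translation proceeds in ORF1's frame up to
#' the resumption point `J = heptamer end + shift` (for the canonical
#' `shift = -1`, one nucleotide is decoded twice, as in physical -1 PRF),
#' then continues in the frame of `J` to the next stop codon. If the
#' shifted reading hits a stop before reaching ORF2 the model is flagged
#' `terminated_in_bridge` rather than suppressed. Optionally emits a
#' bridge-extended RdRp model beginning at an upstream start in ORF2's
#' frame.
#'
#' @param record A `genome_record`.
#' @param layout A `bicistronic_layout`.
#' @param slippery_hit Optional single row of the [scan_slippery()] table
#'   (the site where the fusion shift is modelled).
#' @param shift Frameshift magnitude in nt (default -1).
#' @param bridge_start Optional genomic position (in ORF2's frame, upstream
#'   of the ORF2 AUG) at which to model a bridge-extended RdRp.
#' @param monoisotopic Passed to [molecular_mass()].
#' @return List of `product_model`s: `strategy`, `genomic_path` (data.frame
#'   of `start`, `end`, `frame` segments), `residues`, `aa_length`,
#'   `mass_da`, and flags.
#' @export
model_products <- function(record, layout, slippery_hit = NULL, shift = -1L,
                           bridge_start = NULL, monoisotopic = FALSE) {
  products <- list()
  mk <- function(strategy, path, residues, ...) {
    structure(list(strategy = strategy, genomic_path = path,
                   residues = residues, aa_length = nchar(residues),
                   mass_da = molecular_mass(residues, monoisotopic), ...),
              class = "product_model")
  }
  o1 <- layout$orf1$interval; o2 <- layout$orf2$interval
  cp <- translate_orf(record, o1)
  rdrp <- translate_orf(record, o2)
  products$separate_cp <- mk(
    "separate_stop_restart",
    data.frame(start = o1[["start"]], end = o1[["end"]], frame = layout$orf1$frame),
    cp, role = "CP")
  products$separate_rdrp <- mk(
    "separate_stop_restart",
    data.frame(start = o2[["start"]], end = o2[["end"]], frame = layout$orf2$frame),
    rdrp, role = "RdRp")

  if (!is.null(slippery_hit)) {
    stopifnot(nrow(slippery_hit) == 1L)
    j <- as.integer(slippery_hit$end) + as.integer(shift)
    if (j <= o1[["start"]]) stop("shift resumption point upstream of ORF1 start")
    n0 <- (j - o1[["start"]]) %/% 3L  # complete 0-frame codons before resumption
    head_res <- translate_orf(record, interval(o1[["start"]], o1[["start"]] + 3L * n0 - 1L),
                              allow_internal_stops = FALSE)
    cont <- .shifted_continuation(record, j)
    path <- data.frame(start = c(o1[["start"]], j),
                       end = c(j, cont$end),
                       frame = c(layout$orf1$frame, frame_of(j)))
    products$fusion <- mk(
      "fusion_minus1_at_slip", path, paste0(head_res, cont$residues),
      role = "CP-RdRp fusion",
      shift = as.integer(shift),
      slip_site = c(start = as.integer(slippery_hit$start), end = as.integer(slippery_hit$end)),
      terminated_in_bridge = cont$terminated && cont$end < o2[["start"]],
      reaches_orf2_frame = frame_of(j) == layout$orf2$frame)
  }

  if (!is.null(bridge_start)) {
    bridge_start <- as.integer(bridge_start)
    if ((bridge_start - o2[["start"]]) %% 3L != 0L) {
      stop("bridge_start is not in ORF2's codon phase")
    }
    if (bridge_start >= o2[["start"]]) stop("bridge_start must be upstream of the ORF2 start")
    ext <- translate_orf(record, interval(bridge_start, o2[["end"]]),
                         allow_internal_stops = TRUE)
    products$bridge_extended <- mk(
      "bridge_extended_orf2",
      data.frame(start = bridge_start, end = o2[["end"]], frame = frame_of(bridge_start)),
      ext, role = "bridge-extended RdRp",
      contains_internal_stop = grepl("*", ext, fixed = TRUE))
  }
  products
}

#' @export
print.product_model <- function(x, ...) {
  cat(sprintf("<product_model> %s (%s): %d aa, %.1f kDa\n",
              x$strategy, if (!is.null(x$role)) x$role else "", x$aa_length,
              x$mass_da / 1000))
  invisible(x)
}

#' First in-frame stop-free extension start upstream of ORF2
#'
#' Finds the 5'-most position in ORF2's codon phase, at or after a lower
#' bound (default the bridge start), from which translation runs into ORF2
#' without meeting a stop codon — the natural start for a bridge-extended
#' RdRp model.
#'
#' @param record A `genome_record`.
#' @param layout A `bicistronic_layout`.
#' @param not_before Lower bound for the search (default: bridge start).
#' @return Genomic position, or `NA` if no stop-free extension exists.
#' @export
find_bridge_extension_start <- function(record, layout, not_before = NULL) {
  if (!identical(layout$bridge$kind, "gap")) return(NA_integer_)
  if (is.null(not_before)) not_before <- layout$bridge$interval[["start"]]
  o2s <- layout$orf2$interval[["start"]]
  k <- ceiling((o2s - not_before) / 3)
  cand <- o2s - 3L * seq_len(max(k, 0L))  # in-phase positions, nearest first
  cand <- cand[cand >= not_before]
  best <- NA_integer_
  tbl <- .codon_table()
  for (p in sort(cand)) {
    codons <- substring(record$sequence, seq.int(p, o2s - 3L, by = 3L),
                        seq.int(p + 2L, o2s - 1L, by = 3L))
    if (!any(tbl[codons] == "*")) { best <- p; break }
  }
  best
}
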