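#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P. With
#' `missed_cleavages = m`, every concatenation of up to `m + 1` adjacent
#' base fragments is also emitted.
#'
#' @param protein Residue string.
#' @param missed_cleavages Maximum number of missed cleavage sites (>= 0).
#' @return data.frame in N- to C-terminal order: `sequence`, `start`, `end`
#'   (1-based aa positions), `n_missed`.
#' @export
digest_protein <- function(protein, missed_cleavages = 0L) {
  stopifnot(missed_cleavages >= 0L)
  n <- nchar(protein)
  if (n == 0L) {
    return(data.frame(sequence = character(), start = integer(), end = integer(),
                      n_missed = integer(), stringsAsFactors = FALSE))
  }
  res <- strsplit(protein, "")[[1]]
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)  # fragment i spans (bounds[i]+1) .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nfrag) break
      st <- bounds[i] + 1L; en <- bounds[j + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(protein, st, en), start = st, end = en,
        n_missed = m, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$n_missed), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a frame-indexed six/three-frame translation
#'
#' For each plus-strand frame (and, optionally, each reverse frame) the
#' full stop-agnostic translation, with stops rendered as the sentinel `*`
#' so no peptide can match across a stop. Residue i of plus frame f
#' back-maps to the codon interval `[f + 3(i-1), f + 3i - 1]`.
#'
#' @param record A `genome_record`.
#' @param reverse Also translate the three reverse-complement frames.
#' @return A `frame_index`: list with `translations` (named character
#'   vector: `F1`..`F3`, optionally `R1`..`R3`) and `genome_length`.
#' @export
build_frame_index <- function(record, reverse = FALSE) {
  stopifnot(record$length >= 3L)
  tbl <- .codon_table()
  translate_from <- function(s, f) {
    n <- nchar(s)
    n_codons <- (n - f + 1L) %/% 3L
    if (n_codons < 1L) return("")
    starts <- seq.int(f, by = 3L, length.out = n_codons)
    paste(tbl[substring(s, starts, starts + 2L)], collapse = "")
  }
  tr <- vapply(1:3, function(f) translate_from(record$sequence, f), character(1))
  names(tr) <- paste0("F", 1:3)
  if (reverse) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(record$sequence)))
    trr <- vapply(1:3, function(f) translate_from(rc, f), character(1))
    names(trr) <- paste0("R", 1:3)
    tr <- c(tr, trr)
  }
  structure(list(translations = tr, genome_length = record$length,
                 genome_id = record$id), class = "frame_index")
}

#' Codon interval of a residue range in a frame translation
#'
#' @param index A `frame_index`.
#' @param frame_name `"F1"`..`"F3"` (or `"R1"`..`"R3"`).
#' @param aa_start,aa_end 1-based residue positions in that translation.
#' @return `interval` of genome coordinates (plus-strand coordinates even
#'   for reverse frames).
#' @export
frame_backmap <- function(index, frame_name, aa_start, aa_end) {
  f <- as.integer(substr(frame_name, 2L, 2L))
  nt_start <- f + 3L * (aa_start - 1L)
  nt_end <- f + 3L * aa_end - 1L
  if (startsWith(frame_name, "R")) {
    n <- index$genome_length
    interval(n - nt_end + 1L, n - nt_start + 1L)
  } else {
    interval(nt_start, nt_end)
  }
}

# all exact occurrence start positions of pep in translation (overlapping).
.aa_matches <- function(translation, pep) {
  k <- nchar(pep); L <- nchar(translation)
  if (k > L) return(integer(0))
  starts <- seq_len(L - k + 1L)
  starts[substring(translation, starts, starts + k - 1L) == pep]
}

.region_of <- function(gi, layout) {
  within <- function(iv) gi[["start"]] >= iv[["start"]] && gi[["end"]] <= iv[["end"]]
  if (within(layout$orf1$interval)) return("ORF1")
  if (within(layout$bridge$interval)) return("bridge")
  if (within(layout$orf2$interval)) return("ORF2")
  overlaps <- function(iv) gi[["start"]] <= iv[["end"]] && gi[["end"]] >= iv[["start"]]
  if (overlaps(layout$orf1$interval) || overlaps(layout$bridge$interval) ||
      overlaps(layout$orf2$interval)) return("spanning")
  "other"
}

#' Map peptides onto frame-indexed translations
#'
#' Exact substring matches of each peptide against each frame translation
#' (the stop sentinel `*` breaks matches); every placement is reported with
#' its genome coordinates and the layout region it falls in. A peptide
#' crossing a region boundary is labelled `spanning`.
#'
#' @param peptides Character vector of peptide sequences (or data.frame
#'   with a `sequence` column).
#' @param index A `frame_index` built on the same genome as `layout`.
#' @param layout A `bicistronic_layout`.
#' @return List: `matches` (data.frame `peptide`, `frame_name`, `frame`,
#'   `start`, `end`, `region`) and `unmatched` (character vector).
#' @export
map_peptides <- function(peptides, index, layout) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- as.character(peptides)
  rows <- list()
  unmatched <- character(0)
  for (pep in peptides) {
    found <- FALSE
    for (fn in names(index$translations)) {
      hits <- .aa_matches(index$translations[[fn]], pep)
      for (h in hits) {
        gi <- frame_backmap(index, fn, h, h + nchar(pep) - 1L)
        region <- if (startsWith(fn, "F")) .region_of(gi, layout) else "other"
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, frame_name = fn,
          frame = as.integer(substr(fn, 2L, 2L)),
          start = gi[["start"]], end = gi[["end"]], region = region,
          stringsAsFactors = FALSE)
        found <- TRUE
      }
    }
    if (!found) unmatched <- c(unmatched, pep)
  }
  matches <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(peptide = character(), frame_name = character(), frame = integer(),
               start = integer(), end = integer(), region = character(),
               stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  list(matches = matches, unmatched = unique(unmatched))
}

#' Adjudicate the translation strategy from band and peptide evidence
#'
#' Applies the decision rules in order:
#' 1. Peptides from both the ORF1 and ORF2 regions, band mass within
#'    tolerance of both separate-product masses, and no single-chain
#'    product model within tolerance of the band that spans both ORFs
#'    implies `two_separate_products` (the two proteins co-migrate in one
#'    band).
#' 2. Band mass within tolerance of the fusion model's mass implies
#'    `fusion_product`.
#' 3. ORF2-frame bridge peptides plus a fitting bridge-extended model
#'    implies `bridge_extended_rdrp`.
#' Otherwise `inconclusive`. The rationale records which rules fired.
#'
#' @param mapped Result of [map_peptides()] (or its `matches` data.frame).
#' @param band_mass_da Apparent mass of the gel band, Da (`NULL`/`NA` if
#'   unknown).
#' @param products Product-model list from [model_products()].
#' @param tolerance Relative band-mass tolerance (default 0.15, reflecting
#'   SDS-PAGE imprecision).
#' @return An `evidence_summary`: `verdict`, `rationale`, `region_counts`,
#'   `band_mass_da`.
#' @export
adjudicate <- function(mapped, band_mass_da, products, tolerance = 0.15) {
  matches <- if (is.data.frame(mapped)) mapped else mapped$matches
  counts <- table(factor(matches$region,
                         levels = c("ORF1", "bridge", "ORF2", "spanning", "other")))
  mk <- function(verdict, rationale) {
    structure(list(verdict = verdict, rationale = rationale,
                   region_counts = counts, band_mass_da = band_mass_da),
              class = "evidence_summary")
  }
  if (nrow(matches) == 0L) {
    warning("no mapped peptides; verdict inconclusive")
    return(mk("inconclusive", "no peptide matched any frame translation"))
  }
  if (is.null(band_mass_da) || is.na(band_mass_da)) {
    return(mk("inconclusive", "no band mass supplied"))
  }
  fits <- function(mass) abs(band_mass_da - mass) <= tolerance * mass
  orf2_frame <- products$separate_rdrp$genomic_path$frame[1]
  has_orf1 <- counts[["ORF1"]] > 0L
  has_orf2 <- counts[["ORF2"]] > 0L
  has_bridge_o2 <- any(matches$region == "bridge" & matches$frame == orf2_frame)

  spans_both <- function(p) {
    path_start <- min(p$genomic_path$start); path_end <- max(p$genomic_path$end)
    path_start <= products$separate_cp$genomic_path$end[1] &&
      path_end >= products$separate_rdrp$genomic_path$start[1]
  }
  chain_explainer <- Filter(function(p) fits(p$mass_da) && spans_both(p), products)

  notes <- character(0)
  if (has_orf1 && has_orf2 &&
      fits(products$separate_cp$mass_da) && fits(products$separate_rdrp$mass_da) &&
      length(chain_explainer) == 0L) {
    notes <- c(notes,
               "rule 1: ORF1- and ORF2-region peptides present;",
               sprintf("band %.0f Da fits both separate products (%.0f / %.0f Da);",
                       band_mass_da, products$separate_cp$mass_da,
                       products$separate_rdrp$mass_da),
               "no single-chain product at the band mass spans both ORFs")
    return(mk("two_separate_products", paste(notes, collapse = " ")))
  }
  if (!is.null(products$fusion) && fits(products$fusion$mass_da)) {
    return(mk("fusion_product",
              sprintf("rule 2: band %.0f Da fits the frameshift fusion model (%.0f Da)",
                      band_mass_da, products$fusion$mass_da)))
  }
  if (has_bridge_o2 && !is.null(products$bridge_extended) &&
      fits(products$bridge_extended$mass_da)) {
    return(mk("bridge_extended_rdrp",
              sprintf(paste("rule 3: ORF2-frame bridge peptides present and band",
                            "%.0f Da fits the bridge-extended RdRp model (%.0f Da)"),
                      band_mass_da, products$bridge_extended$mass_da)))
  }
  mk("inconclusive", "no decision rule fired on the available evidence")
}

#' @export
print.evidence_summary <- function(x, ...) {
  cat(sprintf("<evidence_summary> verdict: %s\n", x$verdict))
  cat("  region counts:", paste(names(x$region_counts), as.integer(x$region_counts),
                                sep = "=", collapse = " "), "\n")
  cat("  ", x$rationale, "\n", sep = "")
  invisible(x)
}

#' Read / write peptide lists as TSV (column 1 = sequence)
#'
#' @param path TSV path; a header line is detected and skipped when its
#'   first field is not a plausible peptide.
#' @return Character vector of peptide sequences.
#' @export
read_peptides_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  peps <- as.character(tab[[1]])
  if (length(peps) > 0L && grepl("[^ACDEFGHIKLMNPQRSTVWY]", peps[1])) peps <- peps[-1]
  peps
}

#' @rdname read_peptides_tsv
#' @param peptides Character vector or data.frame with `sequence` column.
#' @export
write_peptides_tsv <- function(peptides, path) {
  if (is.data.frame(peptides)) {
    utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    writeLines(as.character(peptides), path)
  }
  invisible(path)
}
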