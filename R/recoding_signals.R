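#' Hamming distance of a heptamer to the slippery consensus class
#'
#' The -1 frameshift consensus X XXY YYZ requires positions 1-3 to be one
#' base and positions 4-6 another; position 7 is free. The distance is the
#' minimum number of substitutions needed to reach any instantiation:
#' `(3 - max base count in 1:3) + (3 - max base count in 4:6)`. No
#' base-class restriction (e.g. Z != G) is imposed by default; pass
#' `x_bases` / `y_bases` / `z_bases` to enforce the stricter classical
#' pattern.
#'
#' @param heptamer 7-character RNA string.
#' @param x_bases,y_bases,z_bases Optional allowed base sets for X, Y, Z.
#' @return Integer mismatch count (0 = perfect slippery heptamer).
#' @export
slippery_distance <- function(heptamer, x_bases = NULL, y_bases = NULL, z_bases = NULL) {
  stopifnot(nchar(heptamer) == 7L)
  ch <- strsplit(heptamer, "")[[1]]
  block_cost <- function(block, allowed) {
    bases <- if (is.null(allowed)) c("A", "C", "G", "U") else allowed
    min(vapply(bases, function(b) sum(block != b), integer(1)))
  }
  cost <- block_cost(ch[1:3], x_bases) + block_cost(ch[4:6], y_bases)
  if (!is.null(z_bases) && !(ch[7] %in% z_bases)) cost <- cost + 1L
  as.integer(cost)
}

#' Scan a window for slippery-like heptamers
#'
#' Every 7-mer in the window whose distance to the X XXY YYZ consensus class
#' is at most `max_mismatch` is reported (overlapping hits included), sorted
#' by (mismatches, start). The default tolerance of 1 is what detects
#' "slippery-like" sites that deviate from the consensus at one position.
#'
#' @param record A `genome_record`.
#' @param window An `interval` to scan (must be >= 7 nt and within genome).
#' @param max_mismatch Maximum mismatches to the consensus, in {0, 1, 2}.
#' @param orf1 Optional `orf` object; when given, each hit carries the codon
#'   phase of the heptamer start relative to ORF1 (0 = starts on an ORF1
#'   codon boundary).
#' @inheritParams slippery_distance
#' @return data.frame: `start`, `end`, `heptamer`, `mismatches`, `phase_note`.
#' @export
scan_slippery <- function(record, window, max_mismatch = 1L, orf1 = NULL,
                          x_bases = NULL, y_bases = NULL, z_bases = NULL) {
  stopifnot(max_mismatch %in% 0:2)
  if (interval_length(window) < 7L) stop("scan window shorter than 7 nt")
  if (window[["end"]] > record$length) stop("window exceeds genome length")
  starts <- seq.int(window[["start"]], window[["end"]] - 6L)
  heps <- substring(record$sequence, starts, starts + 6L)
  mm <- vapply(heps, slippery_distance, integer(1),
               x_bases = x_bases, y_bases = y_bases, z_bases = z_bases,
               USE.NAMES = FALSE)
  keep <- mm <= max_mismatch
  phase <- if (is.null(orf1)) {
    frame_of(starts) - 1L
  } else {
    (starts - orf1$interval[["start"]]) %% 3L
  }
  hits <- data.frame(start = starts[keep], end = starts[keep] + 6L,
                     heptamer = heps[keep], mismatches = mm[keep],
                     phase_note = phase[keep], stringsAsFactors = FALSE)
  hits <- hits[order(hits$mismatches, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan for stop-restart reinitiation facilitators near the ORF1 stop
#'
#' Looks for the coupled termination-reinitiation motifs AUGA and UAAUG —
#' in which a stop codon (UGA / UAA) overlaps a start codon — within
#' `window_up` nt upstream through `window_down` nt downstream of the ORF1
#' stop codon. A hit is `stop_frame_consistent` when its embedded stop
#' triplet lies in ORF1's codon phase (i.e. could actually terminate ORF1
#' translation).
#'
#' @param record A `genome_record`.
#' @param orf1_stop `interval` of the ORF1 stop codon (3 nt).
#' @param window_up,window_down Scan extent around the stop, in nt
#'   (defaults 40 and 10, bracketing the span known to suffice for
#'   stop-restart in the prototype victorivirus).
#' @param orf1_frame_anchor Position defining ORF1's codon phase; defaults
#'   to the stop start itself.
#' @return data.frame: `start`, `end`, `motif`, `stop_frame_consistent`.
#' @export
scan_facilitators <- function(record, orf1_stop, window_up = 40L, window_down = 10L,
                              orf1_frame_anchor = NULL) {
  if (window_up + window_down + interval_length(orf1_stop) < 5L) {
    stop("facilitator scan window shorter than 5 nt")
  }
  if (is.null(orf1_frame_anchor)) orf1_frame_anchor <- orf1_stop[["start"]]
  lo <- max(1L, orf1_stop[["start"]] - as.integer(window_up))
  hi <- min(record$length, orf1_stop[["end"]] + as.integer(window_down))
  region <- substr(record$sequence, lo, hi)
  motifs <- c(AUGA = "AUGA", UAAUG = "UAAUG")
  stop_offset <- c(AUGA = 1L, UAAUG = 0L)  # offset of the stop triplet within the motif
  rows <- list()
  for (m in names(motifs)) {
    pos <- gregexpr(motifs[[m]], region, fixed = TRUE)[[1]]
    if (pos[1] == -1L) next
    for (p in as.integer(pos)) {
      st <- lo + p - 1L
      stop_start <- st + stop_offset[[m]]
      consistent <- ((stop_start - orf1_frame_anchor) %% 3L) == 0L
      rows[[length(rows) + 1L]] <- data.frame(
        start = st, end = st + nchar(motifs[[m]]) - 1L, motif = m,
        stop_frame_consistent = consistent, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      stop_frame_consistent = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan the 5'UTR for conserved victorivirus motifs
#'
#' Exact-match occurrences of each motif within the 5'UTR. The default set
#' is the conserved octanucleotide AGGGUUCC and its 15-nt extension
#' AGGGUUCCGUUGAUC; when the extension is present both hits are reported.
#'
#' @param record A `genome_record`.
#' @param layout A `bicistronic_layout` (supplies the UTR bounds and ORF1
#'   start).
#' @param motif_set Character vector of RNA motifs (nonempty).
#' @return data.frame: `start`, `end`, `motif_id`, `distance_to_orf1_start`
#'   (nt between motif end and the ORF1 start codon, exclusive of both).
#' @export
scan_utr_motifs <- function(record, layout,
                            motif_set = c("AGGGUUCC", "AGGGUUCCGUUGAUC")) {
  stopifnot(length(motif_set) >= 1L)
  utr <- subseq_at(record, layout$utr5)
  orf1_start <- layout$orf1$interval[["start"]]
  rows <- list()
  for (m in motif_set) {
    pos <- gregexpr(m, utr, fixed = TRUE)[[1]]
    if (pos[1] == -1L) next
    for (p in as.integer(pos)) {
      st <- layout$utr5[["start"]] + p - 1L
      en <- st + nchar(m) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        start = st, end = en, motif_id = m,
        distance_to_orf1_start = orf1_start - en - 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(), motif_id = character(),
                      distance_to_orf1_start = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find Ala/Gly/Pro-rich regions of a protein
#'
#' Slides a window of `window_aa` residues along the protein, keeps windows
#' whose {A,G,P} fraction is at least `threshold`, and merges overlapping
#' qualifying windows into maximal regions. Victorivirus capsid proteins
#' characteristically carry such a region near the C-terminus.
#'
#' @param protein Residue string (uppercase one-letter code).
#' @param window_aa Window width in residues (>= 5).
#' @param threshold Minimum {A,G,P} fraction in a qualifying window.
#' @return data.frame: `start`, `end` (1-based aa positions of the merged
#'   region) and `fraction` ({A,G,P} fraction over the merged region).
#'   Empty (with a warning) when the protein is shorter than the window.
#' @export
find_agp_rich <- function(protein, window_aa = 20L, threshold = 0.6) {
  stopifnot(window_aa >= 5L, threshold > 0, threshold <= 1)
  n <- nchar(protein)
  empty <- data.frame(start = integer(), end = integer(), fraction = numeric())
  if (n < window_aa) {
    warning(sprintf("protein (%d aa) shorter than window (%d aa)", n, window_aa))
    return(empty)
  }
  is_agp <- strsplit(protein, "")[[1]] %in% c("A", "G", "P")
  cs <- c(0L, cumsum(is_agp))
  starts <- seq_len(n - window_aa + 1L)
  frac <- (cs[starts + window_aa] - cs[starts]) / window_aa
  ok <- frac >= threshold
  if (!any(ok)) return(empty)
  # merge overlapping qualifying windows into maximal runs
  qs <- starts[ok]
  brk <- c(TRUE, diff(qs) > window_aa)  # gap > window => windows disjoint
  grp <- cumsum(brk)
  regions <- lapply(split(qs, grp), function(g) {
    st <- min(g); en <- max(g) + window_aa - 1L
    data.frame(start = st, end = en,
               fraction = (cs[en + 1L] - cs[st]) / (en - st + 1L))
  })
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}
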