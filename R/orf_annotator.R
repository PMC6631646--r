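#' Reading-frame label of a plus-strand position
#'
#' Positions 1, 2, 3 are in frames 1, 2, 3; the label of position p is
#' `((p - 1) mod 3) + 1`. This is the convention used to label frame-indexed
#' translations of the plus strand.
#'
#' @param position Integer position(s), 1-based.
#' @return Integer frame label(s) in {1, 2, 3}.
#' @export
frame_of <- function(position) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L)) stop("position must be >= 1")
  ((position - 1L) %% 3L) + 1L
}

.STOPS <- c("UAA", "UAG", "UGA")

# All codon start offsets of a frame f in sequence of length n (internal).
.codon_starts <- function(f, n) seq.int(f, n - 2L, by = 3L)

#' Find open reading frames on the plus strand
#'
#' Maximal AUG-to-stop ORFs in the three plus-strand frames: for each run
#' between consecutive in-frame stop codons, the ORF starts at the 5'-most
#' start codon in the run and ends with (and includes) the terminating stop.
#' ORFs that run off the 3' end without a stop are not reported.
#'
#' @param record A `genome_record`.
#' @param min_aa Minimum protein length in residues (stop excluded);
#'   default 100 for genome-scale annotation.
#' @param start_codons Set of allowed start codons; default `"AUG"`.
#'   Extended sets support scanning for noncanonical initiation.
#' @return data.frame with one row per ORF: `start`, `end` (1-based
#'   inclusive, stop codon included), `frame`, `nt_length`, `aa_length`.
#'   Sorted by `start`, then `end`.
#' @export
find_orfs <- function(record, min_aa = 100L, start_codons = "AUG") {
  stopifnot(min_aa >= 1L)
  s <- record$sequence
  n <- record$length
  out <- list()
  for (f in 1:3) {
    if (n - f + 1L < 3L) next
    starts <- .codon_starts(f, n)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% .STOPS
    is_start <- codons %in% start_codons
    open_at <- NA_integer_  # 5'-most start codon since last in-frame stop
    for (i in seq_along(codons)) {
      if (is_start[i] && is.na(open_at)) open_at <- starts[i]
      if (is_stop[i]) {
        if (!is.na(open_at)) {
          nt_len <- starts[i] + 2L - open_at + 1L
          out[[length(out) + 1L]] <- c(open_at, starts[i] + 2L, f, nt_len)
        }
        open_at <- NA_integer_
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      nt_length = integer(), aa_length = integer()))
  }
  m <- do.call(rbind, out)
  orfs <- data.frame(start = m[, 1], end = m[, 2], frame = m[, 3],
                     nt_length = m[, 4], aa_length = m[, 4] %/% 3L - 1L)
  orfs <- orfs[orfs$aa_length >= min_aa, , drop = FALSE]
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

# data.frame row -> orf object (internal).
.orf_obj <- function(row, role) {
  structure(list(
    interval = interval(row$start, row$end),
    frame = as.integer(row$frame),
    nt_length = as.integer(row$nt_length),
    aa_length = as.integer(row$aa_length),
    role = role
  ), class = "orf")
}

#' Decompose a genome into the bicistronic victorivirus layout
#'
#' ORF1 (capsid) is the ORF with the 5'-most start among the two longest
#' non-nested ORFs; ORF2 (RdRp) is the longest ORF starting after ORF1's
#' start. Ties break deterministically: earlier start wins, then longer.
#' The 5'UTR, inter-ORF bridge (or overlap) and 3'UTR follow by arithmetic.
#'
#' @param record A `genome_record`.
#' @param orfs ORF table from [find_orfs()]; found with defaults if missing.
#' @param min_aa Passed to [find_orfs()] when `orfs` is missing.
#' @return A `bicistronic_layout`: `utr5`, `orf1`, `bridge` (a list with
#'   `kind` `"gap"` or `"overlap"` and an `interval`), `orf2`, `utr3`, and
#'   `relative_frame_offset` in {0, +1, -1} — the codon-phase offset of ORF2
#'   relative to ORF1, `((orf2.start - orf1.start) mod 3)` mapped
#'   {0 -> 0, 1 -> +1, 2 -> -1}.
#' @export
classify_layout <- function(record, orfs = NULL, min_aa = 100L) {
  if (is.null(orfs)) orfs <- find_orfs(record, min_aa = min_aa)
  if (nrow(orfs) < 2L) stop("not bicistronic: fewer than two qualifying ORFs")

  # two longest non-nested ORFs (longer first; ties by earlier start)
  ord <- order(-orfs$nt_length, orfs$start)
  top <- orfs[ord[1], ]
  second <- NULL
  for (k in ord[-1]) {
    cand <- orfs[k, ]
    nested <- (cand$start >= top$start && cand$end <= top$end) ||
      (top$start >= cand$start && top$end <= cand$end)
    if (!nested) { second <- cand; break }
  }
  if (is.null(second)) stop("not bicistronic: all ORFs nested within the longest")

  pair <- rbind(top, second)
  pair <- pair[order(pair$start, -pair$nt_length), ]
  orf1_row <- pair[1, ]
  # ORF2: the longest ORF starting after ORF1's start
  after <- orfs[orfs$start > orf1_row$start, , drop = FALSE]
  if (nrow(after) == 0L) stop("not bicistronic: no ORF downstream of ORF1")
  after <- after[order(-after$nt_length, after$start), ]
  orf2_row <- after[1, ]

  orf1 <- .orf_obj(orf1_row, "ORF1_CP")
  orf2 <- .orf_obj(orf2_row, "ORF2_RDRP")

  if (orf1_row$start <= 1L) stop("ORF1 starts at position 1: no 5'UTR")
  if (orf2_row$end >= record$length) stop("ORF2 ends at the genome terminus: no 3'UTR")
  utr5 <- interval(1L, orf1_row$start - 1L)
  utr3 <- interval(orf2_row$end + 1L, record$length)
  bridge <- if (orf2_row$start > orf1_row$end) {
    list(kind = "gap", interval = interval(orf1_row$end + 1L, orf2_row$start - 1L))
  } else {
    list(kind = "overlap", interval = interval(orf2_row$start, min(orf1_row$end, orf2_row$end)))
  }
  offset_raw <- (orf2_row$start - orf1_row$start) %% 3L
  offset <- c(`0` = 0L, `1` = 1L, `2` = -1L)[[as.character(offset_raw)]]

  structure(list(
    genome_id = record$id,
    genome_length = record$length,
    utr5 = utr5, orf1 = orf1, bridge = bridge, orf2 = orf2, utr3 = utr3,
    relative_frame_offset = offset
  ), class = "bicistronic_layout")
}

#' @export
print.bicistronic_layout <- function(x, ...) {
  cat(sprintf("<bicistronic_layout> %s (%d nt)\n", x$genome_id, x$genome_length))
  cat(sprintf("  5'UTR  [%d, %d]  (%d nt)\n", x$utr5[["start"]], x$utr5[["end"]],
              interval_length(x$utr5)))
  cat(sprintf("  ORF1   [%d, %d]  frame %d, %d aa\n", x$orf1$interval[["start"]],
              x$orf1$interval[["end"]], x$orf1$frame, x$orf1$aa_length))
  cat(sprintf("  bridge [%d, %d]  (%s, %d nt)\n", x$bridge$interval[["start"]],
              x$bridge$interval[["end"]], x$bridge$kind, interval_length(x$bridge$interval)))
  cat(sprintf("  ORF2   [%d, %d]  frame %d, %d aa\n", x$orf2$interval[["start"]],
              x$orf2$interval[["end"]], x$orf2$frame, x$orf2$aa_length))
  cat(sprintf("  3'UTR  [%d, %d]  (%d nt)\n", x$utr3[["start"]], x$utr3[["end"]],
              interval_length(x$utr3)))
  cat(sprintf("  ORF2 codon-phase offset vs ORF1: %+d\n", x$relative_frame_offset))
  invisible(x)
}
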