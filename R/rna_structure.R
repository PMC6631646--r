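# Watson-Crick + wobble pairing and the toy helix score (GC 3, AU 2, GU 1).
# A deliberately simple stability surrogate: deterministic and
# oracle-checkable, used for presence/absence and topology calls only —
# not a thermodynamic nearest-neighbor model.
.PAIR_SCORE <- c(AU = 2, UA = 2, GC = 3, CG = 3, GU = 1, UG = 1)

.pair_score <- function(a, b) {
  s <- .PAIR_SCORE[paste0(a, b)]
  ifelse(is.na(s), 0, s)
}

#' Enumerate maximal helices in a window
#'
#' A helix pairs positions (i, j), (i+1, j-1), ... under {AU, UA, GC, CG,
#' GU, UG}. Helices are maximal: not extendable outward or inward within
#' the window. Each is scored as the sum of its pair scores (GC/CG = 3,
#' AU/UA = 2, GU/UG = 1) — a documented toy stability score.
#'
#' @param record A `genome_record`.
#' @param window An `interval` to search within.
#' @param min_pairs Minimum helix length in base pairs.
#' @param max_loop Maximum number of unpaired nt enclosed between the two
#'   arms (`Inf` to allow arms at any distance, e.g. as pseudoknot
#'   substrate).
#' @return data.frame, one row per helix: `arm5_start`, `arm5_end`,
#'   `arm3_start`, `arm3_end`, `pairs`, `score`. Sorted by position.
#' @export
enumerate_stems <- function(record, window, min_pairs = 3L, max_loop = Inf) {
  if (window[["end"]] > record$length) stop("window exceeds genome length")
  lo <- window[["start"]]; hi <- window[["end"]]
  ch <- strsplit(substr(record$sequence, lo, hi), "")[[1]]
  n <- length(ch)
  can <- function(i, j) !is.na(.PAIR_SCORE[paste0(ch[i], ch[j])])
  rows <- list()
  if (n >= 2L * min_pairs + 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 2L):n) {
        if (j > n) break
        if (!can(i, j)) next
        # outermost pair of a maximal helix: not extendable outward
        if (i > 1L && j < n && can(i - 1L, j + 1L)) next
        k <- 0L
        # extend inward while at least one unpaired loop position remains
        while (i + k + 1L < j - k - 2L && can(i + k + 1L, j - k - 1L)) k <- k + 1L
        pairs <- k + 1L
        loop_len <- (j - k) - (i + k) - 1L
        if (pairs < min_pairs || loop_len < 1L || loop_len > max_loop) next
        sc <- sum(.pair_score(ch[i:(i + k)], ch[j:(j - k)]))
        rows[[length(rows) + 1L]] <- c(lo + i - 1L, lo + i + k - 1L,
                                       lo + j - k - 1L, lo + j - 1L, pairs, sc)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(arm5_start = integer(), arm5_end = integer(),
                      arm3_start = integer(), arm3_end = integer(),
                      pairs = integer(), score = numeric()))
  }
  m <- do.call(rbind, rows)
  out <- data.frame(arm5_start = as.integer(m[, 1]), arm5_end = as.integer(m[, 2]),
                    arm3_start = as.integer(m[, 3]), arm3_end = as.integer(m[, 4]),
                    pairs = as.integer(m[, 5]), score = m[, 6])
  out <- unique(out)
  out <- .drop_dominated_stems(out)
  out <- out[order(out$arm5_start, out$arm3_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# A shifted sub-register helix whose arms both lie inside a longer helix's
# arms is dominated: only the longer helix is a maximal stem.
.drop_dominated_stems <- function(st) {
  if (nrow(st) < 2L) return(st)
  keep <- rep(TRUE, nrow(st))
  for (i in seq_len(nrow(st))) {
    dom <- st$pairs > st$pairs[i] &
      st$arm5_start <= st$arm5_start[i] & st$arm5_end >= st$arm5_end[i] &
      st$arm3_start <= st$arm3_start[i] & st$arm3_end >= st$arm3_end[i]
    if (any(dom)) keep[i] <- FALSE
  }
  st[keep, , drop = FALSE]
}

#' Find stem-loops (hairpins) in a window
#'
#' Maximal helices whose enclosed loop is at least `min_loop` nt and whose
#' loop contains no arm of a stronger overlapping stem (such a stem is a
#' pseudoknot arm or a competing hairpin, not a simple loop). Sorted 5' to
#' 3' so tandem hairpins are reported in genome order.
#'
#' @inheritParams enumerate_stems
#' @param min_loop Minimum loop length in nt (default 3, the sterically
#'   smallest hairpin loop).
#' @param max_loop Maximum loop length in nt (default 30, a local-hairpin
#'   bound).
#' @return data.frame as [enumerate_stems()] plus `loop_start`, `loop_end`.
#' @export
find_stem_loops <- function(record, window, min_pairs = 3L, min_loop = 3L,
                            max_loop = 30L) {
  stems <- enumerate_stems(record, window, min_pairs = min_pairs, max_loop = max_loop)
  stems <- stems[(stems$arm3_start - stems$arm5_end - 1L) >= min_loop, , drop = FALSE]
  if (nrow(stems) == 0L) {
    stems$loop_start <- integer(); stems$loop_end <- integer()
    return(stems)
  }
  keep <- rep(TRUE, nrow(stems))
  for (i in seq_len(nrow(stems))) {
    li <- stems$arm5_end[i] + 1L; ri <- stems$arm3_start[i] - 1L
    for (j in seq_len(nrow(stems))) {
      if (i == j || stems$score[j] <= stems$score[i]) next
      overlaps <- stems$arm5_start[j] <= stems$arm3_end[i] &&
        stems$arm3_end[j] >= stems$arm5_start[i]
      if (!overlaps) next
      arm_in_loop <- (stems$arm5_start[j] >= li && stems$arm5_end[j] <= ri) ||
        (stems$arm3_start[j] >= li && stems$arm3_end[j] <= ri)
      if (arm_in_loop) { keep[i] <- FALSE; break }
    }
  }
  out <- stems[keep, , drop = FALSE]
  out$loop_start <- out$arm5_end + 1L
  out$loop_end <- out$arm3_start - 1L
  out <- out[order(out$arm5_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find H-type pseudoknots in a window
#'
#' An H-type pseudoknot is a pair of crossing helices: stem 2's 5' arm lies
#' inside stem 1's loop while its 3' arm lies 3' of stem 1's 3' arm. All
#' stem pairs satisfying the crossing condition with disjoint arms and
#' combined score >= `min_score` are returned; a greedy non-overlapping
#' selection by score is flagged in the `primary` column for reporting.
#'
#' @inheritParams enumerate_stems
#' @param max_span Maximum overall span (5' arm start to 3' arm end), nt.
#' @param min_score Minimum combined toy score of the two stems.
#' @return data.frame with stem-1 and stem-2 arm coordinates
#'   (`s1_arm5_start` ... `s2_arm3_end`), `pairs1`, `pairs2`,
#'   `span_start`, `span_end`, `score`, `primary`.
#' @export
find_pseudoknots <- function(record, window, min_pairs = 3L, max_span = 120L,
                             min_score = 0) {
  stems <- enumerate_stems(record, window, min_pairs = min_pairs, max_loop = Inf)
  empty <- data.frame(s1_arm5_start = integer(), s1_arm5_end = integer(),
                      s1_arm3_start = integer(), s1_arm3_end = integer(),
                      s2_arm5_start = integer(), s2_arm5_end = integer(),
                      s2_arm3_start = integer(), s2_arm3_end = integer(),
                      pairs1 = integer(), pairs2 = integer(),
                      span_start = integer(), span_end = integer(),
                      score = numeric(), primary = logical())
  if (nrow(stems) < 2L) return(empty)
  rows <- list()
  for (a in seq_len(nrow(stems))) {
    for (b in seq_len(nrow(stems))) {
      if (a == b) next
      s1 <- stems[a, ]; s2 <- stems[b, ]
      crossing <- s2$arm5_start > s1$arm5_end && s2$arm5_end < s1$arm3_start &&
        s2$arm3_start > s1$arm3_end
      if (!crossing) next
      span <- s2$arm3_end - s1$arm5_start + 1L
      sc <- s1$score + s2$score
      if (span > max_span || sc < min_score) next
      rows[[length(rows) + 1L]] <- data.frame(
        s1_arm5_start = s1$arm5_start, s1_arm5_end = s1$arm5_end,
        s1_arm3_start = s1$arm3_start, s1_arm3_end = s1$arm3_end,
        s2_arm5_start = s2$arm5_start, s2_arm5_end = s2$arm5_end,
        s2_arm3_start = s2$arm3_start, s2_arm3_end = s2$arm3_end,
        pairs1 = s1$pairs, pairs2 = s2$pairs,
        span_start = s1$arm5_start, span_end = s2$arm3_end,
        score = sc)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$span_start, out$span_end), , drop = FALSE]
  # greedy non-overlapping selection by score for the primary report
  out$primary <- FALSE
  taken <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(out))) {
    clash <- nrow(taken) > 0 &&
      any(out$span_start[i] <= taken[, 2] & out$span_end[i] >= taken[, 1])
    if (!clash) {
      out$primary[i] <- TRUE
      taken <- rbind(taken, c(out$span_start[i], out$span_end[i]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Dot-bracket string for a pseudoknot
#'
#' Serializes one pseudoknot row over its span: stem 1 pairs as `(` / `)`,
#' stem 2 pairs as `[` / `]`, unpaired positions as `.` — e.g.
#' `"(((..[[[..)))..]]]"`.
#'
#' @param pk One row of the [find_pseudoknots()] table.
#' @return Character scalar of length `span_end - span_start + 1`.
#' @export
pk_dotbracket <- function(pk) {
  stopifnot(nrow(pk) == 1L)
  off <- pk$span_start - 1L
  n <- pk$span_end - off
  ch <- rep(".", n)
  ch[(pk$s1_arm5_start:pk$s1_arm5_end) - off] <- "("
  ch[(pk$s1_arm3_start:pk$s1_arm3_end) - off] <- ")"
  ch[(pk$s2_arm5_start:pk$s2_arm5_end) - off] <- "["
  ch[(pk$s2_arm3_start:pk$s2_arm3_end) - off] <- "]"
  paste(ch, collapse = "")
}
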