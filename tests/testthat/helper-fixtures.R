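# Shared fixtures and independent brute-force oracles for the test suite.

# memoised canonical synthetic genome (the paper-layout preset, seed 42)
.fixture_env <- new.env(parent = emptyenv())
fixture_paper <- function() {
  if (is.null(.fixture_env$paper)) {
    .fixture_env$paper <- generate_genome("paper_layout", seed = 42)
  }
  .fixture_env$paper
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

# ---- ORF oracle: every AUG paired with the next in-frame stop (via
# findInterval on the stop list); maximal ORFs are the 5'-most start per
# stop codon. A different mechanism from find_orfs's stop-run bookkeeping.
oracle_find_orfs <- function(seq, min_aa = 1L, start_codons = "AUG") {
  n <- nchar(seq)
  stops <- c("UAA", "UAG", "UGA")
  cand <- list()
  for (f in 1:3) {
    if (n - f + 1L < 3L) next
    starts <- seq.int(f, n - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    aug_i <- which(codons %in% start_codons)
    stop_i <- which(codons %in% stops)
    if (length(aug_i) == 0L || length(stop_i) == 0L) next
    # index of the first stop at or after each start codon
    nxt <- findInterval(aug_i - 0.5, stop_i) + 1L
    ok <- nxt <= length(stop_i)
    if (!any(ok)) next
    cand[[f]] <- data.frame(start = starts[aug_i[ok]],
                            end = starts[stop_i[nxt[ok]]] + 2L)
  }
  if (length(cand) == 0L) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, cand)
  # maximal = earliest start per shared stop
  m <- do.call(rbind, lapply(split(m, m$end), function(g) g[which.min(g$start), ]))
  m$aa <- (m$end - m$start + 1L) %/% 3L - 1L
  m <- m[m$aa >= min_aa, c("start", "end"), drop = FALSE]
  m <- m[order(m$start, m$end), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# ---- slippery oracle: minimum Hamming distance over all 4*4*4 consensus
# instantiations X XXY YYZ.
oracle_slippery_distance <- function(hep) {
  bases <- c("A", "C", "G", "U")
  best <- 7L
  for (x in bases) for (y in bases) for (z in bases) {
    patt <- c(x, x, x, y, y, y, z)
    d <- sum(strsplit(hep, "")[[1]] != patt)
    best <- min(best, d)
  }
  best
}

# ---- tryptic digest oracle: regex split after K/R not before P.
oracle_digest <- function(protein) {
  if (nchar(protein) == 0L) return(character(0))
  strsplit(protein, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}

# ---- maximal-helix oracle: anti-diagonal runs of the pairing matrix.
oracle_stems <- function(seq, min_pairs, max_loop = Inf) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  ok <- function(a, b) paste0(ch[a], ch[b]) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  sc <- function(a, b) c(AU = 2, UA = 2, GC = 3, CG = 3, GU = 1, UG = 1)[paste0(ch[a], ch[b])]
  rows <- list()
  for (d in 3:(2L * n - 1L)) {
    imax <- floor((d - 2L) / 2L)          # innermost pair keeps >= 1 loop nt
    is <- seq_len(min(imax, n))
    is <- is[d - is <= n & d - is >= 1L]
    if (length(is) == 0L) next
    v <- vapply(is, function(i) ok(i, d - i), logical(1))
    r <- rle(v)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      a <- is[pos[k]]; b <- is[pos[k] + r$lengths[k] - 1L]
      # maximal: no pairable cell just outside the run (within bounds)
      if (a - 1L >= 1L && d - a + 1L <= n && ok(a - 1L, d - a + 1L)) next
      pairs <- b - a + 1L
      loop <- (d - b) - b - 1L
      if (pairs < min_pairs || loop < 1L || loop > max_loop) next
      rows[[length(rows) + 1L]] <- data.frame(
        arm5_start = a, arm5_end = b, arm3_start = d - b, arm3_end = d - a,
        pairs = pairs, score = sum(vapply(a:b, function(i) sc(i, d - i), numeric(1))))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(arm5_start = integer(), arm5_end = integer(),
                      arm3_start = integer(), arm3_end = integer(),
                      pairs = integer(), score = numeric()))
  }
  out <- do.call(rbind, rows)
  # drop helices whose arms both sit inside a longer helix's arms
  keep <- vapply(seq_len(nrow(out)), function(i) {
    !any(out$pairs > out$pairs[i] &
           out$arm5_start <= out$arm5_start[i] & out$arm5_end >= out$arm5_end[i] &
           out$arm3_start <= out$arm3_start[i] & out$arm3_end >= out$arm3_end[i])
  }, logical(1))
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$arm5_start, out$arm3_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- planted H-type pseudoknot fixture: GC-only arms, A-only linkers, so
# the planted stems are the only strong helices.
make_pk_fixture <- function(seed, min_arm = 5L, max_arm = 7L) {
  set.seed(seed)
  p1 <- sample(min_arm:max_arm, 1L)
  p2 <- sample(min_arm:max_arm, 1L)
  arm <- function(p) paste(sample(c("G", "C"), p, replace = TRUE), collapse = "")
  rc <- function(s) chartr("GC", "CG", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  a1 <- arm(p1); a2 <- arm(p2)
  l <- function(n) strrep("A", n)
  s1a <- a1; s2a <- a2; s1b <- rc(a1); s2b <- rc(a2)
  seq <- paste0(s1a, l(3L), s2a, l(3L), s1b, l(4L), s2b)
  n1 <- nchar(s1a)
  truth <- list(
    s1_arm5 = c(1L, n1),
    s1_arm3 = c(n1 + 3L + p2 + 3L + 1L, n1 + 3L + p2 + 3L + n1),
    s2_arm5 = c(n1 + 4L, n1 + 3L + p2),
    s2_arm3 = c(nchar(seq) - p2 + 1L, nchar(seq)))
  list(seq = seq, truth = truth)
}

iv_overlap_frac <- function(a, b) {
  ov <- max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
  ov / (a[2] - a[1] + 1L)
}

# independent average residue-mass table (standard biochemical values),
# typed separately from the package's table
ORACLE_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
oracle_mass <- function(protein) {
  m <- 18.0153
  for (a in strsplit(protein, "")[[1]]) m <- m + ORACLE_AVG_MASS[[a]]
  m
}
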