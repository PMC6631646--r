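#' Construct a genome record
#'
#' A `genome_record` is a named plus-strand sequence over the RNA alphabet
#' {A,C,G,U}. DNA input (T) is normalized to U; the input alphabet style is
#' remembered so FASTA written back out matches what was read.
#'
#' @param id Record identifier (header up to first whitespace on read).
#' @param sequence Nucleotide string; `T` is converted to `U`, case raised.
#' @param alphabet Either `"RNA"` or `"DNA"`; the style used when writing
#'   FASTA. Defaults to whatever the input looked like.
#' @return An object of class `genome_record` with fields `id`, `sequence`
#'   (RNA alphabet), `length`, `alphabet`.
#' @export
genome_record <- function(id, sequence, alphabet = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq_up <- toupper(gsub("[[:space:]]", "", sequence))
  if (is.null(alphabet)) {
    alphabet <- if (grepl("T", seq_up, fixed = TRUE) && !grepl("U", seq_up, fixed = TRUE)) "DNA" else "RNA"
  }
  seq_rna <- chartr("T", "U", seq_up)
  bad <- regexpr("[^ACGU]", seq_rna)
  if (bad > 0L) {
    stop(sprintf("record '%s': non-ACGU character '%s' at position %d",
                 id, substr(seq_rna, bad, bad), bad))
  }
  if (nchar(seq_rna) < 1L) stop(sprintf("record '%s': empty sequence", id))
  structure(
    list(id = id, sequence = seq_rna, length = nchar(seq_rna), alphabet = alphabet),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d nt (%s input)\n", x$id, x$length, x$alphabet))
  invisible(x)
}

#' 1-based inclusive interval
#'
#' The coordinate contract for every module: intervals are 1-based and
#' inclusive at both ends, matching genome map positions as printed on
#' genome diagrams.
#'
#' @param start,end Integer positions, `1 <= start <= end`.
#' @return Integer vector `c(start, end)` of class `interval`.
#' @export
interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, !is.na(start), !is.na(end))
  if (start < 1L || end < start) {
    stop(sprintf("invalid interval [%d, %d]: need 1 <= start <= end", start, end))
  }
  structure(c(start = start, end = end), class = "interval")
}

#' @rdname interval
#' @param x An `interval`.
#' @export
interval_length <- function(x) unname(x[["end"]] - x[["start"]] + 1L)

#' Extract the subsequence at an interval
#' @param record A `genome_record`.
#' @param iv An `interval` (must lie within the record).
#' @return Character scalar.
#' @export
subseq_at <- function(record, iv) {
  if (iv[["end"]] > record$length) {
    stop(sprintf("interval [%d, %d] exceeds genome length %d",
                 iv[["start"]], iv[["end"]], record$length))
  }
  substr(record$sequence, iv[["start"]], iv[["end"]])
}

#' Read FASTA into genome records
#'
#' One record per FASTA entry. Ids are taken from the header up to the first
#' whitespace. T is normalized to U; any other non-ACGU character is an
#' error naming the record and offending position.
#'
#' @param path Path to a FASTA file.
#' @return List of `genome_record`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) genome_record(ids[i], as.character(set[[i]])))
}

#' Write genome records to FASTA
#'
#' Sequences are written in the alphabet style recorded at read time
#' (default RNA, i.e. U).
#'
#' @param records A `genome_record` or list of them.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  seqs <- vapply(records, function(r) {
    if (identical(r$alphabet, "DNA")) chartr("U", "T", r$sequence) else r$sequence
  }, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# Build a GRanges row set from a feature data.frame (internal).
.features_to_granges <- function(features, record) {
  bad <- features$end > record$length | features$start < 1L
  if (any(bad)) {
    stop(sprintf("feature '%s' [%d, %d] outside genome bounds [1, %d]",
                 features$id[which(bad)[1]], features$start[which(bad)[1]],
                 features$end[which(bad)[1]], record$length))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = record$id,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = "+"
  )
  gr$type <- features$type
  gr$phase <- ifelse(features$type == "CDS", 0L, NA_integer_)
  gr$ID <- features$id
  if (!is.null(features$name)) gr$Name <- features$name
  gr
}

#' Write a bicistronic layout (plus optional signal hits) to GFF3
#'
#' Coordinates in columns 4/5 are 1-based inclusive, the same convention as
#' printed genome map positions. Feature types follow the Sequence Ontology:
#' `five_prime_UTR`, `CDS` (the two ORFs), `region` (the inter-ORF bridge),
#' `three_prime_UTR`, and `sequence_feature` for recoding-signal hits.
#'
#' @param record A `genome_record` the features belong to.
#' @param layout A `bicistronic_layout` from [classify_layout()], or `NULL`
#'   for a header-only file.
#' @param path Output path.
#' @param signals Optional data.frame of signal hits with columns
#'   `start`, `end`, `id` (and optionally `name`), written as
#'   `sequence_feature` rows.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(record, layout, path, signals = NULL) {
  feats <- data.frame(start = integer(), end = integer(),
                      type = character(), id = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(layout)) {
    feats <- layout_features(layout)
  }
  if (!is.null(signals) && nrow(signals) > 0L) {
    sf <- data.frame(start = as.integer(signals$start), end = as.integer(signals$end),
                     type = "sequence_feature", id = as.character(signals$id),
                     stringsAsFactors = FALSE)
    if (!is.null(signals$name)) sf$name <- as.character(signals$name)
    feats <- merge_feature_frames(feats, sf)
  }
  if (nrow(feats) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- .features_to_granges(feats, record)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# rbind two feature frames that may differ in the optional name column.
merge_feature_frames <- function(a, b) {
  if (nrow(a) == 0L) return(b)
  if (is.null(a$name) && !is.null(b$name)) a$name <- NA_character_
  if (is.null(b$name) && !is.null(a$name)) b$name <- NA_character_
  rbind(a, b)
}

#' Flatten a layout into a feature table
#'
#' @param layout A `bicistronic_layout`.
#' @return data.frame with columns `start`, `end`, `type`, `id`.
#' @export
layout_features <- function(layout) {
  stopifnot(inherits(layout, "bicistronic_layout"))
  bridge_type <- if (identical(layout$bridge$kind, "gap")) "region" else "sequence_conflict"
  data.frame(
    start = c(layout$utr5[["start"]], layout$orf1$interval[["start"]],
              layout$bridge$interval[["start"]], layout$orf2$interval[["start"]],
              layout$utr3[["start"]]),
    end = c(layout$utr5[["end"]], layout$orf1$interval[["end"]],
            layout$bridge$interval[["end"]], layout$orf2$interval[["end"]],
            layout$utr3[["end"]]),
    type = c("five_prime_UTR", "CDS", bridge_type, "CDS", "three_prime_UTR"),
    id = c("utr5", "ORF1", "bridge", "ORF2", "utr3"),
    stringsAsFactors = FALSE
  )
}
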