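#' Default pipeline configuration
#'
#' Tunables for every stage, overridable per call or from a YAML/JSON-like
#' named list. Windows are in nt around the ORF1 stop codon.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    min_aa = 100L,                 # minimum ORF length for annotation, aa
    start_codons = "AUG",
    max_mismatch = 1L,             # slippery-consensus tolerance
    slip_window_up = 40L,          # junction scan: nt upstream of the ORF1 stop
    slip_window_down = 10L,        #                nt downstream
    facilitator_window_up = 40L,
    facilitator_window_down = 10L,
    motif_set = c("AGGGUUCC", "AGGGUUCCGUUGAUC"),
    structure_window = 60L,        # nt each side of the stop for structure scans
    structure_min_pairs = 4L,
    structure_max_span = 120L,
    structure_min_score = 12,
    agp_window = 20L,
    agp_threshold = 0.6,
    band_tolerance = 0.15,         # relative SDS-PAGE band-mass tolerance
    missed_cleavages = 0L,
    min_peptide_len = 6L,
    monoisotopic = FALSE,
    shift = -1L,
    seed = NULL
  )
}

.iv_list <- function(iv) list(start = unname(iv[["start"]]), end = unname(iv[["end"]]))

.layout_list <- function(layout) {
  list(
    utr5 = .iv_list(layout$utr5),
    orf1 = list(start = layout$orf1$interval[["start"]], end = layout$orf1$interval[["end"]],
                frame = layout$orf1$frame, aa_length = layout$orf1$aa_length,
                role = layout$orf1$role),
    bridge = c(list(kind = layout$bridge$kind), .iv_list(layout$bridge$interval)),
    orf2 = list(start = layout$orf2$interval[["start"]], end = layout$orf2$interval[["end"]],
                frame = layout$orf2$frame, aa_length = layout$orf2$aa_length,
                role = layout$orf2$role),
    utr3 = .iv_list(layout$utr3),
    relative_frame_offset = layout$relative_frame_offset
  )
}

.product_list <- function(p) {
  out <- list(strategy = p$strategy, role = p$role, aa_length = p$aa_length,
              mass_da = round(p$mass_da, 2), genomic_path = p$genomic_path)
  for (fld in c("terminated_in_bridge", "reaches_orf2_frame", "contains_internal_stop")) {
    if (!is.null(p[[fld]])) out[[fld]] <- p[[fld]]
  }
  out
}

#' Run the full annotation pipeline on one genome
#'
#' Stages run in fixed order: ORF annotation, recoding-signal scans, RNA
#' structure heuristics, product modelling, then (when peptides are given)
#' peptide mapping and strategy adjudication. Failures in optional stages
#' degrade to warnings recorded in the report; a genome that is not
#' bicistronic yields a partial report with the ORF list and an explicit
#' `error` field.
#'
#' @param genome A `genome_record` or path to a FASTA file (first record
#'   used, with a warning if there are several).
#' @param config Named list of overrides of [default_config()].
#' @param peptides Optional character vector / data.frame of observed
#'   peptides, or path to a TSV (column 1 = sequence).
#' @param band_mass_da Optional apparent gel-band mass, Da.
#' @param gff_out,json_out Optional output paths for the GFF3 annotation
#'   and the JSON report.
#' @return An `annotation_report` list; serializes losslessly to JSON.
#' @export
run_pipeline <- function(genome, config = list(), peptides = NULL,
                         band_mass_da = NULL, gff_out = NULL, json_out = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.character(genome)) {
    recs <- read_fasta(genome)
    if (length(recs) > 1L) warning("multiple FASTA records; annotating the first")
    genome <- recs[[1]]
  }
  if (is.character(peptides) && length(peptides) == 1L && file.exists(peptides)) {
    peptides <- read_peptides_tsv(peptides)
  }

  report <- list(
    tool = "vicscan", version = as.character(utils::packageVersion("vicscan")),
    genome = list(id = genome$id, length = genome$length),
    config = cfg[order(names(cfg))],
    seed = cfg$seed,
    warnings = character(0)
  )
  note <- function(msg) report$warnings <<- c(report$warnings, msg)

  orfs <- find_orfs(genome, min_aa = cfg$min_aa, start_codons = cfg$start_codons)
  report$orfs <- orfs
  layout <- tryCatch(classify_layout(genome, orfs), error = function(e) {
    note(conditionMessage(e)); NULL
  })
  if (is.null(layout)) {
    report$error <- "genome is not bicistronic under the current settings"
    report$verdict <- "inconclusive"
    if (!is.null(json_out)) write_report_json(report, json_out)
    return(structure(report, class = "annotation_report"))
  }
  report$layout <- .layout_list(layout)

  stop_iv <- interval(layout$orf1$interval[["end"]] - 2L, layout$orf1$interval[["end"]])
  slip_win <- interval(max(1L, stop_iv[["start"]] - cfg$slip_window_up),
                       min(genome$length, stop_iv[["end"]] + cfg$slip_window_down))
  slippery <- scan_slippery(genome, slip_win, max_mismatch = cfg$max_mismatch,
                            orf1 = layout$orf1)
  facilitators <- scan_facilitators(genome, stop_iv,
                                    window_up = cfg$facilitator_window_up,
                                    window_down = cfg$facilitator_window_down)
  motifs <- scan_utr_motifs(genome, layout, motif_set = cfg$motif_set)
  cp_protein <- translate_orf(genome, layout$orf1$interval)
  agp <- find_agp_rich(cp_protein, window_aa = cfg$agp_window,
                       threshold = cfg$agp_threshold)
  report$signals <- list(slippery = slippery, facilitators = facilitators,
                         utr_motifs = motifs, agp_rich_cp = agp)

  struct_win <- interval(max(1L, stop_iv[["start"]] - cfg$structure_window),
                         min(genome$length, stop_iv[["end"]] + cfg$structure_window))
  stem_loops <- find_stem_loops(genome, struct_win, min_pairs = cfg$structure_min_pairs)
  pks <- find_pseudoknots(genome, struct_win, min_pairs = cfg$structure_min_pairs,
                          max_span = cfg$structure_max_span,
                          min_score = cfg$structure_min_score)
  primary_pks <- pks[pks$primary, , drop = FALSE]
  if (nrow(primary_pks) > 0L) {
    primary_pks$dotbracket <- vapply(seq_len(nrow(primary_pks)),
                                     function(i) pk_dotbracket(primary_pks[i, ]),
                                     character(1))
  }
  report$structures <- list(stem_loops = stem_loops, pseudoknots = primary_pks,
                            n_pseudoknot_candidates = nrow(pks))

  # the junction-relevant slippery site is the one abutting the ORF1 stop:
  # rank by distance of the heptamer end from the last pre-stop nucleotide,
  # then by mismatches
  best_slip <- if (nrow(slippery) > 0L) {
    ord <- order(abs(slippery$end - (stop_iv[["start"]] - 1L)), slippery$mismatches)
    slippery[ord[1], , drop = FALSE]
  } else NULL
  bridge_start <- find_bridge_extension_start(genome, layout)
  products <- tryCatch(
    model_products(genome, layout, slippery_hit = best_slip, shift = cfg$shift,
                   bridge_start = if (is.na(bridge_start)) NULL else bridge_start,
                   monoisotopic = cfg$monoisotopic),
    error = function(e) { note(conditionMessage(e)); NULL })
  if (!is.null(products)) report$products <- lapply(products, .product_list)

  verdict <- "inconclusive"
  if (!is.null(peptides) && length(peptides) > 0L && !is.null(products)) {
    idx <- build_frame_index(genome)
    mapped <- map_peptides(peptides, idx, layout)
    summary <- withCallingHandlers(
      adjudicate(mapped, band_mass_da, products, tolerance = cfg$band_tolerance),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    verdict <- summary$verdict
    report$pmf <- list(
      n_peptides = length(unique(if (is.data.frame(peptides)) peptides$sequence else peptides)),
      matches = mapped$matches, unmatched = mapped$unmatched,
      region_counts = as.list(summary$region_counts),
      band_mass_da = band_mass_da, rationale = summary$rationale)
  } else if (!is.null(peptides) && length(peptides) > 0L) {
    note("peptides supplied but product models unavailable; PMF stage skipped")
  }
  report$verdict <- verdict

  if (!is.null(gff_out)) {
    sig <- data.frame(start = integer(), end = integer(), id = character(),
                      stringsAsFactors = FALSE)
    if (nrow(slippery) > 0L) {
      sig <- rbind(sig, data.frame(start = slippery$start, end = slippery$end,
                                   id = sprintf("slippery_%s", slippery$heptamer)))
    }
    if (nrow(facilitators) > 0L) {
      sig <- rbind(sig, data.frame(start = facilitators$start, end = facilitators$end,
                                   id = sprintf("facilitator_%s", facilitators$motif)))
    }
    if (nrow(motifs) > 0L) {
      sig <- rbind(sig, data.frame(start = motifs$start, end = motifs$end,
                                   id = sprintf("utr_motif_%s", motifs$motif_id)))
    }
    write_gff3(genome, layout, gff_out, signals = if (nrow(sig) > 0L) sig else NULL)
    report$gff3 <- gff_out
  }
  if (!is.null(json_out)) write_report_json(report, json_out)
  structure(report, class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat(sprintf("<annotation_report> %s (%d nt) — verdict: %s\n",
              x$genome$id, x$genome$length, x$verdict))
  if (!is.null(x$error)) cat("  error:", x$error, "\n")
  if (!is.null(x$layout)) {
    cat(sprintf("  ORF1 [%d, %d] %d aa | bridge [%d, %d] | ORF2 [%d, %d] %d aa\n",
                x$layout$orf1$start, x$layout$orf1$end, x$layout$orf1$aa_length,
                x$layout$bridge$start, x$layout$bridge$end,
                x$layout$orf2$start, x$layout$orf2$end, x$layout$orf2$aa_length))
  }
  invisible(x)
}

#' Write / read an annotation report as JSON
#'
#' Serialization is deterministic: identical inputs and config give
#' byte-identical files (the report carries no timestamps).
#'
#' @param report An `annotation_report` (any plain list works).
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
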