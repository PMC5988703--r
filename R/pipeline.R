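#' Run the full transcript-annotation workflow
#'
#' Orchestrates all stages on a set of aligned long reads: 5'-adapter
#' validation (cDNA), poly(A) tail detection with false-priming and
#' double-tail filters, Poisson TSS calling with Bonferroni correction,
#' TES calling with platform-specific thresholds, splice-junction
#' acceptance, transcript assembly and classification, motif annotation,
#' dispersion statistics and overlap analysis. Deterministic: rerunning on
#' identical inputs produces identical results.
#'
#' @param reads Read table from [read_alignments()] / [simulate_reads()],
#'   or a list of such tables (e.g. one cDNA, one dRNA) which are row-bound.
#' @param genome A [genome_model()] or FASTA path.
#' @param ref A `reference_catalog` or GFF3 path.
#' @param adapter Library 5' adapter sequence (required for cDNA reads).
#' @param scheme A [scoring_scheme()].
#' @param alpha,tss_window Poisson test parameters (0.05, 101).
#' @param min_tes_cdna,min_tes_drna TES evidence thresholds (10, 1).
#' @param min_junction_reads cDNA support for splice acceptance (2).
#' @param tol Site matching tolerance for assembly/classification (10).
#' @param tss_ref_tol TSS novelty tolerance (5).
#' @param min_support,min_support_multi Model support thresholds (2, 1).
#' @param filter_five_prime Apply the adapter-validation filter to TSS
#'   evidence (TRUE; disabling treats every cDNA 5' end as real).
#' @param filter_false_prime Apply the genomic 3-A false-priming filter to
#'   cDNA TES evidence (TRUE).
#' @param confirmed_junctions Optional externally confirmed junction list.
#' @return An object of class `viranno_annotation`: a list with
#'   `tss_table`, `tss_calls`, `tes_calls`, `junctions`, `transcripts`,
#'   `motifs`, `start_dispersion`, `tes_dispersion`, `overlaps`,
#'   `overlap_summary`, `log` and `params`.
#' @export
annotate <- function(reads, genome, ref, adapter,
                     scheme = scoring_scheme(),
                     alpha = 0.05, tss_window = 101L,
                     min_tes_cdna = 10L, min_tes_drna = 1L,
                     min_junction_reads = 2L,
                     tol = 10L, tss_ref_tol = 5L,
                     min_support = 2L, min_support_multi = 1L,
                     filter_five_prime = TRUE,
                     filter_false_prime = TRUE,
                     confirmed_junctions = NULL) {
  if (is.character(genome)) genome <- load_genome(genome)
  if (is.character(ref)) ref <- read_reference(ref)
  if (is.list(reads) && !is.data.frame(reads)) reads <- dplyr::bind_rows(reads)
  half_w <- (tss_window - 1L) %/% 2L

  cdna <- reads[reads$platform == "cdna", , drop = FALSE]
  drna <- reads[reads$platform == "drna", , drop = FALSE]

  # stage 1: 5' validation (cDNA only)
  statuses <- classify_five_prime(cdna, adapter, scheme)
  if (!filter_five_prime) statuses$state <- "validated"

  # stage 2: tails and read-level 3' filters
  tails <- detect_tails(reads, genome)
  if (!filter_false_prime) tails$false_primed <- FALSE

  # stage 3: TSS calling from validated cDNA starts
  starts <- collect_validated_starts(cdna, statuses)
  cands <- tss_candidates(starts, genome$length, half_w, genome$circular)
  ref_tss <- tibble::tibble(pos = ref$transcripts$tss,
                            strand = ref$transcripts$strand)
  tss_table <- call_tss(cands, alpha, tss_window, ref_tss, tss_ref_tol,
                        genome$length, genome$circular)
  tss_calls <- tss_table[tss_table$called, , drop = FALSE]

  # stage 4: TES calling
  ends <- collect_tail_ends(tails)
  ref_tes <- tibble::tibble(pos = ref$transcripts$tes,
                            strand = ref$transcripts$strand)
  tes_calls <- call_tes(ends, genome, min_tes_cdna, min_tes_drna, ref_tes,
                        tol)

  # stage 5: splice junctions
  junctions <- accept_junctions(extract_junctions(reads), genome,
                                min_junction_reads, confirmed_junctions)

  # stage 6: assembly and classification
  models <- assemble_models(reads, statuses, tails, tss_calls, tes_calls,
                            junctions, ref, genome, tol, min_support,
                            min_support_multi)
  transcripts <- classify_transcripts(models, ref, genome, tol)

  # stage 7: motifs, kinetic classes, dispersion
  motifs <- annotate_motifs(genome, tss_calls, tes_calls)
  sd_start <- NULL
  if (nrow(tss_calls) > 0L) {
    cl <- dplyr::left_join(
      dplyr::inner_join(cands, tss_calls[, c("pos", "strand")],
                        by = c("pos", "strand")),
      motifs$tss[, c("pos", "strand", "class")], by = c("pos", "strand")
    )
    sd_start <- start_dispersion(cl)
  }
  sd_end <- NULL
  if (nrow(tes_calls) > 0L) {
    te <- dplyr::left_join(tes_calls,
                           motifs$tes[, c("pos", "strand", "pas")],
                           by = c("pos", "strand"))
    sd_end <- tes_dispersion(te, ends, genome$length, genome$circular)
  }

  # stage 8: overlaps among annotated + novel transcripts
  ref_tx <- tibble::tibble(
    id = ref$transcripts$id, strand = ref$transcripts$strand,
    span_start = ref$transcripts$start, span_end = ref$transcripts$end,
    tss = ref$transcripts$tss, tes = ref$transcripts$tes,
    tss_status = "called"
  )
  novel_tx <- transcripts[!transcripts$category %in% "known", , drop = FALSE]
  ov_set <- dplyr::bind_rows(
    ref_tx,
    if (nrow(novel_tx)) novel_tx[, c("id", "strand", "span_start",
                                     "span_end", "tss", "tes", "tss_status")]
  )
  overlaps <- find_overlaps(ov_set, genome$length, genome$circular)
  ov_sum <- summarize_overlaps(overlaps)

  n_validated <- sum(statuses$state == "validated")
  log <- tibble::tibble(
    stage = c("reads_in", "reads_cdna", "reads_drna",
              "cdna_5p_validated", "cdna_5p_uncertain",
              "reads_tailed_3p", "reads_false_primed", "reads_double_tail",
              "tss_candidates", "tss_called", "tes_called",
              "junctions_seen", "junctions_accepted",
              "models_assembled", "overlaps_found"),
    n = c(nrow(reads), nrow(cdna), nrow(drna),
          n_validated, nrow(cdna) - n_validated,
          sum(!is.na(tails$tail3_kind)),
          sum(tails$false_primed & !is.na(tails$tail3_kind) &
                tails$platform == "cdna"),
          sum(tails$double_tail),
          nrow(cands), nrow(tss_calls), nrow(tes_calls),
          nrow(junctions), sum(junctions$accepted),
          nrow(transcripts), nrow(overlaps))
  )

  structure(
    list(
      genome = genome, ref = ref,
      tss_table = tss_table, tss_calls = tss_calls,
      tss_candidates = cands, start_counts = starts,
      end_counts = ends, tes_calls = tes_calls,
      junctions = junctions, transcripts = transcripts,
      motifs = motifs, start_dispersion = sd_start,
      tes_dispersion = sd_end, overlaps = overlaps,
      overlap_summary = ov_sum, log = log,
      params = list(
        adapter = adapter, alpha = alpha, tss_window = tss_window,
        min_tes_cdna = min_tes_cdna, min_tes_drna = min_tes_drna,
        min_junction_reads = min_junction_reads, tol = tol,
        tss_ref_tol = tss_ref_tol, min_support = min_support,
        min_support_multi = min_support_multi,
        filter_five_prime = filter_five_prime,
        filter_false_prime = filter_false_prime,
        scheme = unclass(scheme)
      )
    ),
    class = "viranno_annotation"
  )
}

#' @export
print.viranno_annotation <- function(x, ...) {
  cat("<viranno_annotation>\n")
  cat(sprintf("  genome: %s (%d bp, %s)\n", x$genome$name, x$genome$length,
              if (x$genome$circular) "circular" else "linear"))
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("  %-18s %d\n", x$log$stage[i], x$log$n[i]))
  }
  invisible(x)
}

#' Write all annotation outputs to a directory
#'
#' Emits `transcripts.gff3`, `transcripts.bed12`, per-stage TSV tables, a
#' category summary and the effective parameters (`params.json`). Outputs
#' are byte-stable: rerunning an identical annotation writes identical
#' files.
#'
#' @param ann A `viranno_annotation`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_annotation_dir <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- ann$transcripts
  write_annotation(tx, file.path(dir, "transcripts.gff3"), "gff3", ann$genome)
  write_annotation(tx, file.path(dir, "transcripts.bed12"), "bed12",
                   ann$genome)
  flat <- dplyr::select(tx, -"exons", -"chain")
  readr::write_tsv(flat, file.path(dir, "transcripts.tsv"))
  readr::write_tsv(ann$tss_table, file.path(dir, "tss.tsv"))
  readr::write_tsv(ann$tes_calls, file.path(dir, "tes.tsv"))
  readr::write_tsv(ann$junctions, file.path(dir, "junctions.tsv"))
  readr::write_tsv(ann$overlaps, file.path(dir, "overlaps.tsv"))
  readr::write_tsv(ann$overlap_summary, file.path(dir, "overlap_summary.tsv"))
  if (nrow(ann$motifs$hits)) {
    readr::write_tsv(ann$motifs$hits, file.path(dir, "motifs.tsv"))
  }
  readr::write_tsv(ann$log, file.path(dir, "log.tsv"))
  readr::write_tsv(summary_table(ann), file.path(dir, "summary.tsv"))
  jsonlite::write_json(ann$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

summary_table <- function(ann) {
  tx <- ann$transcripts
  if (nrow(tx) == 0L) {
    return(tibble::tibble(category = character(), n = integer(),
                          mean_length = double(), max_cistrons = integer()))
  }
  tx$len <- tx$span_end - tx$span_start
  tx |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(), mean_length = mean(.data$len),
                     max_cistrons = max(.data$cistron_count),
                     .groups = "drop") |>
    dplyr::arrange(.data$category)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the transcript table of an annotation
#'
#' @param x A `viranno_annotation`.
#' @param ... Unused.
#' @return One row per transcript model (list columns dropped).
#' @export
tidy.viranno_annotation <- function(x, ...) {
  dplyr::select(x$transcripts, -"exons", -"chain")
}

#' One-row summary of an annotation run
#'
#' @param x A `viranno_annotation`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts.
#' @export
glance.viranno_annotation <- function(x, ...) {
  tidyr::pivot_wider(x$log, names_from = "stage", values_from = "n")
}
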