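#' Collect poly(A)-supported read 3' ends
#'
#' A read contributes its 3' end position when it carries a 3' tail.
#' Double-tailed reads are excluded (they are handled on the
#' complex-transcript path), and cDNA reads flagged as false-primed
#' (genomic A-run at the end) are excluded; dRNA evidence is exempt from
#' the false-priming filter.
#'
#' @param tails Tail table from [detect_tails()].
#' @return Tibble `pos`, `strand`, `support_cdna`, `support_drna`.
#' @export
collect_tail_ends <- function(tails) {
  df <- dplyr::filter(
    tails,
    !is.na(.data$tail3_kind),
    !.data$double_tail,
    .data$platform == "drna" | !.data$false_primed
  )
  if (nrow(df) == 0L) {
    return(tibble::tibble(pos = integer(), strand = character(),
                          support_cdna = integer(), support_drna = integer()))
  }
  df |>
    dplyr::count(pos = .data$three_prime_pos, .data$strand, .data$platform) |>
    tidyr::pivot_wider(names_from = "platform", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      if (!"cdna" %in% names(d)) d$cdna <- 0L
      if (!"drna" %in% names(d)) d$drna <- 0L
      d
    })() |>
    dplyr::select("pos", "strand", support_cdna = "cdna",
                  support_drna = "drna") |>
    dplyr::arrange(.data$strand, .data$pos)
}

#' Call transcription end sites
#'
#' A position is a TES when at least `min_cdna` (10) tailed cDNA reads end
#' there, or at least `min_drna` (1) tailed dRNA read does (a single
#' direct-RNA read is confirmatory because the platform has no known bias
#' producing false tails). The genomic false-priming flag is reported for
#' every call; cDNA evidence at flagged positions was already removed at
#' collection, so a flagged call is necessarily dRNA-only.
#'
#' @param ends Tibble from [collect_tail_ends()].
#' @param genome A [genome_model()] (for the false-priming flag).
#' @param min_cdna,min_drna Evidence thresholds (10, 1).
#' @param ref Optional reference TES tibble (`pos`, `strand`).
#' @param tol Reference matching tolerance in nt (10).
#' @return Tibble `pos`, `strand`, `support_cdna`, `support_drna`,
#'   `false_primed`, `novel`, sorted by position.
#' @export
call_tes <- function(ends, genome, min_cdna = 10L, min_drna = 1L,
                     ref = NULL, tol = 10L) {
  called <- dplyr::filter(
    ends,
    .data$support_cdna >= min_cdna | .data$support_drna >= min_drna
  )
  if (nrow(called) == 0L) {
    return(tibble::tibble(pos = integer(), strand = character(),
                          support_cdna = integer(), support_drna = integer(),
                          false_primed = logical(), novel = logical()))
  }
  called$false_primed <- is_false_primed(genome, called$pos, called$strand)
  novel <- rep(NA, nrow(called))
  if (!is.null(ref)) {
    novel <- !purrr::map2_lgl(called$pos, called$strand, function(pp, ss) {
      rp <- ref$pos[ref$strand == ss]
      length(rp) > 0 &&
        any(circ_dist(rp, pp, genome$length, genome$circular) <= tol)
    })
  }
  called$novel <- novel
  dplyr::arrange(called, .data$pos)
}

#' End-position dispersion by polyadenylation signal
#'
#' Same frequency-SD convention as [start_dispersion()], applied to the
#' per-position end-count landscape in a 101-nt window around each called
#' TES, grouped by the PAS sequence found upstream (groups with fewer than
#' two sites are reported as missing). Because every position passing the
#' evidence threshold is called independently, satellite calls inside a
#' stronger site's window are first removed (only local support maxima
#' anchor a window), mirroring the local-maximum convention on the TSS
#' side: nearby secondary ends are the variation being measured, not
#' separate anchors.
#'
#' @param tes_calls Called TES tibble with a `pas` column (e.g. "AATAAA",
#'   "ATTAAA", or NA from [scan_tes_context()] results).
#' @param ends End count map from [collect_tail_ends()] (cDNA + dRNA
#'   support summed).
#' @param genome_length,circular Topology.
#' @param window Half-window (50).
#' @return Tibble `class` (PAS), `sd`, `n_sites`.
#' @export
tes_dispersion <- function(tes_calls, ends, genome_length, circular = TRUE,
                           window = 50L) {
  stopifnot("pas" %in% names(tes_calls))
  support <- tibble::tibble(
    pos = tes_calls$pos, strand = tes_calls$strand,
    n = tes_calls$support_cdna + tes_calls$support_drna
  )
  primary <- find_local_maxima(support, genome_length, window, circular)
  tes_calls <- dplyr::semi_join(tes_calls, primary, by = c("pos", "strand"))
  wc <- purrr::map2(tes_calls$pos, tes_calls$strand, function(p, s) {
    offs <- (-window):window
    gp <- if (s == "+") p + offs else p - offs
    gp <- if (circular) wrap_pos(gp, genome_length) else gp
    key <- ends$pos[ends$strand == s]
    val <- (ends$support_cdna + ends$support_drna)[ends$strand == s]
    out <- integer(length(offs))
    m <- match(gp, key)
    out[!is.na(m)] <- val[m[!is.na(m)]]
    out
  })
  res <- dispersion_by(wc, tes_calls$pas)
  res$sd[res$n_sites < 2L] <- NA_real_
  res
}
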