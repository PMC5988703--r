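#' Extract splice junctions from spliced alignments
#'
#' One junction per inter-block gap (CIGAR `N`). Gaps shorter than
#' `min_intron` nt are treated as alignment noise and ignored (the blocks
#' are effectively merged). Junctions are reported as the intron's 0-based
#' half-open interval on the forward strand, with support split by
#' platform.
#'
#' @param reads Read table from [read_alignments()].
#' @param min_intron Minimum intron length in nt (20).
#' @return Tibble `intron_start`, `intron_end`, `strand`, `support_cdna`,
#'   `support_drna`.
#' @export
extract_junctions <- function(reads, min_intron = 20L) {
  per_read <- purrr::pmap(
    list(reads$blocks, reads$strand, reads$platform),
    function(blk, strand, platform) {
      if (nrow(blk) < 2L) return(NULL)
      gs <- unname(blk[-nrow(blk), "end"])
      ge <- unname(blk[-1L, "start"])
      keep <- (ge - gs) >= min_intron
      if (!any(keep)) return(NULL)
      tibble::tibble(intron_start = gs[keep], intron_end = ge[keep],
                     strand = strand, platform = platform)
    }
  )
  df <- dplyr::bind_rows(per_read)
  if (nrow(df) == 0L) {
    return(tibble::tibble(intron_start = integer(), intron_end = integer(),
                          strand = character(), support_cdna = integer(),
                          support_drna = integer()))
  }
  df |>
    dplyr::count(.data$intron_start, .data$intron_end, .data$strand,
                 .data$platform) |>
    tidyr::pivot_wider(names_from = "platform", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      if (!"cdna" %in% names(d)) d$cdna <- 0L
      if (!"drna" %in% names(d)) d$drna <- 0L
      d
    })() |>
    dplyr::select("intron_start", "intron_end", "strand",
                  support_cdna = "cdna", support_drna = "drna") |>
    dplyr::arrange(.data$intron_start, .data$intron_end)
}

#' Accept splice junctions by consensus and support
#'
#' A junction is accepted when its intron carries the GT..AG boundary
#' consensus on the sense strand AND it is supported by at least
#' `min_cdna` (2) cDNA reads, or by at least one dRNA read, or appears in
#' an external confirmation list (standing in for wet-lab PCR validation).
#' Non-canonical junctions are never accepted regardless of support.
#'
#' @param junctions Tibble from [extract_junctions()].
#' @param genome A [genome_model()].
#' @param min_cdna cDNA read support threshold (2).
#' @param confirmed Optional tibble (`intron_start`, `intron_end`,
#'   `strand`) of externally confirmed junctions.
#' @return Input tibble plus `canonical` and `accepted` columns.
#' @export
accept_junctions <- function(junctions, genome, min_cdna = 2L,
                             confirmed = NULL) {
  if (nrow(junctions) == 0L) {
    return(dplyr::mutate(junctions, canonical = logical(0),
                         accepted = logical(0)))
  }
  canonical <- purrr::pmap_lgl(
    list(junctions$intron_start, junctions$intron_end, junctions$strand),
    function(s, e, strand) {
      if (strand == "+") {
        donor <- genome_window(genome, s, 0L, 1L, "+")
        accept <- genome_window(genome, e - 1L, -1L, 0L, "+")
      } else {
        donor <- genome_window(genome, e - 1L, 0L, 1L, "-")
        accept <- genome_window(genome, s, -1L, 0L, "-")
      }
      donor == "GT" && accept == "AG"
    }
  )
  ext <- rep(FALSE, nrow(junctions))
  if (!is.null(confirmed) && nrow(confirmed) > 0L) {
    key <- paste(junctions$intron_start, junctions$intron_end,
                 junctions$strand)
    ckey <- paste(confirmed$intron_start, confirmed$intron_end,
                  confirmed$strand)
    ext <- key %in% ckey
  }
  junctions$canonical <- canonical
  junctions$accepted <- canonical &
    (junctions$support_cdna >= min_cdna | junctions$support_drna >= 1L | ext)
  junctions
}
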