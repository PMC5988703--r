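# Pairwise transcriptional overlap classification: parallel (tail-to-head,
# same strand), convergent (tail-to-tail) and divergent (head-to-head).
# Overlaps are computed on total transcript spans (TSS to TES), circular-
# aware; spans may be stored unwrapped (end > genome length).

# decompose a possibly-wrapping span into linear arcs within [0, len)
span_arcs <- function(s, e, len) {
  s2 <- wrap_pos(s, len)
  w <- e - s
  if (s2 + w <= len) {
    matrix(c(s2, s2 + w), ncol = 2)
  } else {
    matrix(c(s2, len, 0, s2 + w - len), ncol = 2, byrow = TRUE)
  }
}

# total intersection length of two spans on a circular genome
circ_overlap_len <- function(s1, e1, s2, e2, len, circular = TRUE) {
  if (!circular) {
    return(max(0L, min(e1, e2) - max(s1, s2)))
  }
  a1 <- span_arcs(s1, e1, len)
  a2 <- span_arcs(s2, e2, len)
  tot <- 0L
  for (i in seq_len(nrow(a1))) for (j in seq_len(nrow(a2))) {
    tot <- tot + max(0L, min(a1[i, 2], a2[j, 2]) - max(a1[i, 1], a2[j, 1]))
  }
  tot
}

# is position p covered by span [s, e) (circular-aware)?
circ_covered <- function(p, s, e, len, circular = TRUE) {
  if (!circular) return(p >= s && p < e)
  a <- span_arcs(s, e, len)
  any(p >= a[, 1] & p < a[, 2])
}

#' Classify the overlap between two transcripts
#'
#' Same-strand overlaps are parallel (tail-to-head). Opposite-strand
#' overlaps are convergent when the shared region contains the two 3'
#' ends (tail-to-tail) and divergent when it contains the two 5' ends
#' (head-to-head). When one span entirely contains the other, the class is
#' decided by which end of the container the contained transcript is
#' nearer (ties resolve to convergent).
#'
#' @param a,b One-row transcript tibbles (need `span_start`, `span_end`,
#'   `strand`, `tss`, `tes`, `id`, and `tss_status` if available).
#' @param genome_length Replicon length.
#' @param circular Topology.
#' @return `NULL` when disjoint, else a one-row tibble `id_a`, `id_b`,
#'   `cls`, `length`, `predicted` (TRUE when either TSS was imputed).
#' @export
classify_overlap <- function(a, b, genome_length, circular = TRUE) {
  len <- circ_overlap_len(a$span_start, a$span_end, b$span_start, b$span_end,
                          genome_length, circular)
  if (len <= 0L) return(NULL)
  predicted <- isTRUE(a$tss_status == "undetermined") ||
    isTRUE(b$tss_status == "undetermined")
  if (a$strand == b$strand) {
    cls <- "parallel"
  } else {
    a_in_b <- circ_overlap_len(a$span_start, a$span_end, b$span_start,
                               b$span_end, genome_length, circular) ==
      (a$span_end - a$span_start)
    b_in_a <- circ_overlap_len(b$span_start, b$span_end, a$span_start,
                               a$span_end, genome_length, circular) ==
      (b$span_end - b$span_start)
    if (a_in_b || b_in_a) {
      inner <- if (b_in_a) b else a
      outer <- if (b_in_a) a else b
      mid <- wrap_pos(inner$span_start +
                        (inner$span_end - inner$span_start) %/% 2,
                      genome_length)
      d3 <- circ_dist(mid, wrap_pos(outer$tes, genome_length),
                      genome_length, circular)
      d5 <- circ_dist(mid, wrap_pos(outer$tss, genome_length),
                      genome_length, circular)
      cls <- if (d3 <= d5) "convergent" else "divergent"
    } else {
      a3_in <- circ_covered(wrap_pos(a$tes, genome_length), b$span_start,
                            b$span_end, genome_length, circular)
      b3_in <- circ_covered(wrap_pos(b$tes, genome_length), a$span_start,
                            a$span_end, genome_length, circular)
      cls <- if (a3_in && b3_in) "convergent" else "divergent"
    }
  }
  tibble::tibble(id_a = a$id, id_b = b$id, cls = cls,
                 length = as.integer(len), predicted = predicted)
}

#' Find and classify all pairwise transcript overlaps
#'
#' @param transcripts Classified model tibble (or any tibble with `id`,
#'   `strand`, `span_start`, `span_end`, `tss`, `tes`, optionally
#'   `tss_status`).
#' @param genome_length Replicon length.
#' @param circular Topology.
#' @return Tibble of [classify_overlap()] records (unordered pairs, each
#'   counted once).
#' @export
find_overlaps <- function(transcripts, genome_length, circular = TRUE) {
  n <- nrow(transcripts)
  if (!"tss_status" %in% names(transcripts)) {
    transcripts$tss_status <- "called"
  }
  # transcripts with no resolvable span are skipped
  keep <- !is.na(transcripts$span_start) & !is.na(transcripts$span_end)
  transcripts <- transcripts[keep, , drop = FALSE]
  n <- nrow(transcripts)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      r <- classify_overlap(transcripts[i, ], transcripts[j, ],
                            genome_length, circular)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          cls = character(), length = integer(),
                          predicted = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Summarize overlap records
#'
#' Per-class counts and mean lengths, split into overlaps among
#' transcripts with called TSSs and the separate "predicted" tally where
#' one of the partners' TSSs was only imputed.
#'
#' @param records Tibble from [find_overlaps()].
#' @return Tibble `cls`, `predicted`, `n`, `mean_length`.
#' @export
summarize_overlaps <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(cls = character(), predicted = logical(),
                          n = integer(), mean_length = double()))
  }
  records |>
    dplyr::group_by(.data$cls, .data$predicted) |>
    dplyr::summarise(n = dplyr::n(), mean_length = mean(.data$length),
                     .groups = "drop") |>
    dplyr::arrange(.data$cls, .data$predicted)
}
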