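# Consensus-motif scanning around called sites. Exact string matching by
# design: de-novo motif discovery is out of scope, the scanner looks for
# the field's published consensus elements only.

#' Scan the promoter context of a TSS and infer its kinetic class
#'
#' Positional initiator rules: a late initiator (LIS) fires when the
#' genome reads TAAG with the TSS on the second base (transcription starts
#' on the A); the early initiator CAGT is applied with the same geometry,
#' and the arthropod-like 5-mers ACAGT/ACAGG with the TSS on their central
#' A. TATA is a windowed scan (default -50..-1; the element sits at an
#' average of ~12 bp upstream in this system). Kinetic class: `L` for LIS
#' without early elements, `E` for TATA/CAGT without LIS, `E/L` when both
#' are present, `unknown` otherwise.
#'
#' @param g A [genome_model()].
#' @param tss 0-based TSS position.
#' @param strand Strand.
#' @param tata_window Offsets scanned for TATA, `c(-50, -1)`.
#' @return List with `hits` (tibble `motif`, `offset`, `matched_seq`) and
#'   `class`.
#' @export
scan_tss_context <- function(g, tss, strand, tata_window = c(-50L, -1L)) {
  hits <- list()
  add <- function(motif, offset, seqs) {
    hits[[length(hits) + 1L]] <<- tibble::tibble(
      motif = motif, offset = as.integer(offset), matched_seq = seqs
    )
  }
  core4 <- genome_window(g, tss, -1L, 2L, strand)
  if (core4 == "TAAG") add("LIS_TAAG", -1L, core4)
  if (core4 == "CAGT") add("early_initiator_CAGT", -1L, core4)
  core5 <- genome_window(g, tss, -2L, 2L, strand)
  if (core5 %in% c("ACAGT", "ACAGG")) add("arthropod_ACAGT_like", -2L, core5)
  win <- genome_window(g, tss, tata_window[1], tata_window[2], strand)
  tloc <- stringr::str_locate_all(win, stringr::fixed("TATA"))[[1]]
  if (nrow(tloc) > 0L) {
    offs <- tloc[, "start"] + tata_window[1] - 1L
    add("TATA", offs, rep("TATA", length(offs)))
  }
  hits <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(motif = character(), offset = integer(),
                   matched_seq = character())
  late <- "LIS_TAAG" %in% hits$motif
  early <- any(hits$motif %in% c("TATA", "early_initiator_CAGT",
                                 "arthropod_ACAGT_like"))
  cls <- if (late && early) "E/L" else if (late) "L" else if (early) "E"
         else "unknown"
  list(hits = hits, class = cls)
}

#' Scan the context of a TES for polyadenylation signals and terminators
#'
#' PAS hits are exact AATAAA/ATTAAA occurrences (DNA sense of the RNA
#' consensus) fully within the 50 nt 5'-ward of the TES; the T-rich
#' terminator flag fires when three or more consecutive T lie within
#' offsets -10..+3 of the TES.
#'
#' @param g A [genome_model()].
#' @param tes 0-based TES position (last mapped base before the tail).
#' @param strand Strand.
#' @param pas_window Offsets scanned for PAS, `c(-50, -1)`.
#' @param trich_window Offsets scanned for the T-run, `c(-10, 3)`.
#' @return Tibble `motif`, `offset`, `matched_seq`.
#' @export
scan_tes_context <- function(g, tes, strand, pas_window = c(-50L, -1L),
                             trich_window = c(-10L, 3L)) {
  hits <- list()
  win <- genome_window(g, tes, pas_window[1], pas_window[2], strand)
  for (pat in c("AATAAA", "ATTAAA")) {
    loc <- stringr::str_locate_all(win, stringr::fixed(pat))[[1]]
    loc <- loc[loc[, "end"] <= nchar(win), , drop = FALSE]
    if (nrow(loc) > 0L) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        motif = paste0("PAS_", pat),
        offset = as.integer(loc[, "start"] + pas_window[1] - 1L),
        matched_seq = pat
      )
    }
  }
  twin <- genome_window(g, tes, trich_window[1], trich_window[2], strand)
  tloc <- stringr::str_locate_all(twin, "T{3,}")[[1]]
  if (nrow(tloc) > 0L) {
    hits[[length(hits) + 1L]] <- tibble::tibble(
      motif = "T_rich_terminator",
      offset = as.integer(tloc[, "start"] + trich_window[1] - 1L),
      matched_seq = substr(rep(twin, nrow(tloc)), tloc[, "start"], tloc[, "end"])
    )
  }
  if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(motif = character(), offset = integer(),
                   matched_seq = character())
}

#' Annotate all called TSSs and TESs with motifs and kinetic classes
#'
#' @param g A [genome_model()].
#' @param tss_calls,tes_calls Called site tibbles (`pos`, `strand`).
#' @return List of tibbles: `tss` (per-site class plus hit summary),
#'   `tes` (per-site primary PAS and terminator flag), `hits` (long table
#'   of all motif hits).
#' @export
annotate_motifs <- function(g, tss_calls, tes_calls) {
  tss_rows <- purrr::map2(tss_calls$pos, tss_calls$strand, function(p, s) {
    sc <- scan_tss_context(g, p, s)
    tibble::tibble(
      site = "TSS", pos = p, strand = s, class = sc$class,
      hits = list(sc$hits)
    )
  })
  tes_rows <- purrr::map2(tes_calls$pos, tes_calls$strand, function(p, s) {
    h <- scan_tes_context(g, p, s)
    pas_hits <- h[grepl("^PAS_", h$motif), , drop = FALSE]
    # primary PAS: the one nearest the TES
    pas <- NA_character_
    if (nrow(pas_hits) > 0L) {
      pas <- sub("^PAS_", "", pas_hits$motif[which.max(pas_hits$offset)])
    }
    tibble::tibble(
      site = "TES", pos = p, strand = s, pas = pas,
      t_rich = any(h$motif == "T_rich_terminator"), hits = list(h)
    )
  })
  tss_tbl <- dplyr::bind_rows(tss_rows)
  tes_tbl <- dplyr::bind_rows(tes_rows)
  if (nrow(tss_tbl) == 0L) {
    tss_tbl <- tibble::tibble(site = character(), pos = integer(),
                              strand = character(), class = character(),
                              hits = list())
  }
  if (nrow(tes_tbl) == 0L) {
    tes_tbl <- tibble::tibble(site = character(), pos = integer(),
                              strand = character(), pas = character(),
                              t_rich = logical(), hits = list())
  }
  long <- dplyr::bind_rows(
    if (nrow(tss_tbl)) tidyr::unnest(dplyr::select(tss_tbl, -"class"), "hits"),
    if (nrow(tes_tbl))
      tidyr::unnest(dplyr::select(tes_tbl, -"pas", -"t_rich"), "hits")
  )
  list(
    tss = if (nrow(tss_tbl)) dplyr::select(tss_tbl, -"hits") else tss_tbl,
    tes = if (nrow(tes_tbl)) dplyr::select(tes_tbl, -"hits") else tes_tbl,
    hits = long
  )
}
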