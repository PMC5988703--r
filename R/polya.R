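#' Detect a poly(A)-type tail in one soft clip
#'
#' Poly(A) tails are soft-clipped homopolymer A or T stretches of at least
#' `min_len` (15) nt; for direct-RNA reads, windows of at least `min_len` nt
#' whose C+T (or G+A) fraction reaches `rich_frac` (0.8) are also accepted,
#' covering the base caller's miscalled tails. The run must begin within
#' `edge_tol` (5) nt of the clip's read-internal edge (the start of a 3'
#' clip, the end of a 5' clip), tolerating one or two miscalled bases at the
#' alignment junction.
#'
#' @param clip Soft-clip sequence in read orientation (may be empty).
#' @param side `"five_prime"` or `"three_prime"`.
#' @param platform `"cdna"` or `"drna"` (rich modes are dRNA-only).
#' @param min_len Minimum tail length (15).
#' @param edge_tol Edge anchoring tolerance in nt (5).
#' @param rich_frac Composition fraction for CT/GA-rich dRNA tails (0.8).
#' @return `NULL` when no tail, else a list with `kind` (`"polyA"`,
#'   `"polyT"`, `"ct_rich"`, `"ga_rich"`) and `length`.
#' @export
detect_tail <- function(clip, side = c("three_prime", "five_prime"),
                        platform = c("cdna", "drna"),
                        min_len = 15L, edge_tol = 5L, rich_frac = 0.8) {
  side <- match.arg(side)
  platform <- match.arg(platform)
  if (is.na(clip) || nchar(clip) < min_len) return(NULL)
  # normalize so the read-internal edge is the string start
  s <- if (side == "five_prime") stringi::stri_reverse(clip) else clip
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  n <- length(ch)

  run_from <- function(base) {
    # longest pure run of `base` starting within edge_tol of the edge
    best <- 0L
    for (st in seq_len(min(edge_tol, n))) {
      if (ch[st] != base) next
      en <- st
      while (en < n && ch[en + 1L] == base) en <- en + 1L
      best <- max(best, en - st + 1L)
    }
    best
  }
  la <- run_from("A")
  if (la >= min_len) return(list(kind = "polyA", length = la))
  lt <- run_from("T")
  if (lt >= min_len) return(list(kind = "polyT", length = lt))

  if (platform == "drna") {
    rich_len <- function(bases) {
      # longest prefix window (from the edge) of length >= min_len with
      # composition fraction >= rich_frac
      hits <- cumsum(ch %in% bases)
      lens <- seq_len(n)
      ok <- lens >= min_len & (hits / lens) >= rich_frac
      if (any(ok)) max(lens[ok]) else 0L
    }
    lct <- rich_len(c("C", "T"))
    if (lct >= min_len) return(list(kind = "ct_rich", length = lct))
    lga <- rich_len(c("G", "A"))
    if (lga >= min_len) return(list(kind = "ga_rich", length = lga))
  }
  NULL
}

#' Tail evidence table for a read set
#'
#' Runs [detect_tail()] on both soft clips of every read and summarizes the
#' read-level tail status used by TES calling: the detected tails, whether
#' the read carries tails on both ends (double-tailed reads are discarded
#' from TES evidence except on the complex-transcript path), and the
#' genomic false-priming flag at the read 3' end.
#'
#' @param reads Read table from [read_alignments()].
#' @param genome A [genome_model()] (for the false-priming check).
#' @inheritParams detect_tail
#' @return Tibble: `read_id`, `platform`, `strand`, `three_prime_pos`,
#'   `tail5_kind`, `tail5_len`, `tail3_kind`, `tail3_len`, `double_tail`,
#'   `false_primed`.
#' @export
detect_tails <- function(reads, genome, min_len = 15L, edge_tol = 5L,
                         rich_frac = 0.8) {
  t5 <- purrr::map2(reads$soft5, reads$platform, function(clip, pf) {
    detect_tail(clip, "five_prime", pf, min_len, edge_tol, rich_frac)
  })
  t3 <- purrr::map2(reads$soft3, reads$platform, function(clip, pf) {
    detect_tail(clip, "three_prime", pf, min_len, edge_tol, rich_frac)
  })
  kind_of <- function(x) if (is.null(x)) NA_character_ else x$kind
  len_of <- function(x) if (is.null(x)) NA_integer_ else as.integer(x$length)
  tibble::tibble(
    read_id = reads$read_id,
    platform = reads$platform,
    strand = reads$strand,
    three_prime_pos = reads$three_prime_pos,
    tail5_kind = vapply(t5, kind_of, character(1)),
    tail5_len = vapply(t5, len_of, integer(1)),
    tail3_kind = vapply(t3, kind_of, character(1)),
    tail3_len = vapply(t3, len_of, integer(1)),
    double_tail = !is.na(vapply(t5, kind_of, character(1))) &
      !is.na(vapply(t3, kind_of, character(1))),
    false_primed = is_false_primed(genome, reads$three_prime_pos, reads$strand)
  )
}

#' Internal-priming (false poly(A)) check at a 3' end position
#'
#' A 3' end is a putative oligo(dT) false-priming product when the three
#' genomic sense bases at and immediately 5'-ward of the end position are
#' all A ("three or more mapped A letters" at the read 3' end). Applied to
#' cDNA evidence only by the TES caller; dRNA evidence is exempt but the
#' flag is still reported.
#'
#' @param g A [genome_model()].
#' @param tes_pos 0-based position(s) of the last mapped base.
#' @param strand Strand(s), recycled.
#' @return Logical vector.
#' @export
is_false_primed <- function(g, tes_pos, strand) {
  n <- max(length(tes_pos), length(strand))
  if (n == 0L) return(logical(0))
  tes_pos <- rep_len(tes_pos, n); strand <- rep_len(strand, n)
  vapply(seq_len(n), function(i) {
    genome_window(g, tes_pos[i], -2L, 0L, strand[i]) == "AAA"
  }, logical(1))
}

#' Does a read carry poly(A)-type tails on both ends?
#'
#' @param soft5,soft3 Soft-clip sequences in read orientation.
#' @param platform `"cdna"` or `"drna"`.
#' @inheritParams detect_tail
#' @return Logical scalar.
#' @export
has_double_tail <- function(soft5, soft3, platform = "cdna", min_len = 15L,
                            edge_tol = 5L, rich_frac = 0.8) {
  !is.null(detect_tail(soft5, "five_prime", platform, min_len, edge_tol, rich_frac)) &&
    !is.null(detect_tail(soft3, "three_prime", platform, min_len, edge_tol, rich_frac))
}
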