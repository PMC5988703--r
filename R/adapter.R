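#' Scoring scheme for adapter alignment
#'
#' Defaults are the workflow's published costs: match +2, mismatch -3,
#' gap open -3, gap extension -2, with validation threshold 17. A gap of
#' length L costs `|gap_open| + (L-1) * |gap_extend|` (a length-1 gap
#' costs 3). `N` never matches.
#'
#' @param match,mismatch,gap_open,gap_extend,min_score Scheme values.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = -3L,
                           gap_extend = -2L, min_score = 17L) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0, min_score > 0)
  structure(
    list(match = match, mismatch = mismatch, gap_open = gap_open,
         gap_extend = gap_extend, min_score = min_score),
    class = "scoring_scheme"
  )
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Computes the maximal local alignment score of `query` against `target`
#' under the scheme's affine gap model. Ties between maximal cells are
#' broken toward the smallest target end coordinate (the alignment ending
#' closest to the read's 5' terminus when the target is a 5' window).
#'
#' @param query,target DNA strings over A/C/G/T/N (N scores as mismatch).
#' @param scheme A [scoring_scheme()].
#' @return A list with `score` (0 if no positive-scoring cell) and
#'   `target_end` (1-based index of the last aligned target base, `NA` when
#'   score is 0).
#' @export
local_align <- function(query, target, scheme = scoring_scheme()) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  q <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  t <- strsplit(toupper(target), "", fixed = TRUE)[[1]]
  m <- length(q); n <- length(t)
  open1 <- scheme$gap_open                 # cost of a length-1 gap
  ext <- scheme$gap_extend
  best <- 0; best_j <- NA_integer_
  H_prev <- numeric(n + 1L)                # H[i-1, ]
  E_prev <- rep(-Inf, n + 1L)              # E[i-1, ] (gap in target, vertical)
  for (i in seq_len(m)) {
    H_cur <- numeric(n + 1L)
    E_cur <- rep(-Inf, n + 1L)
    Fj <- -Inf                             # F[i, j] (gap in query, horizontal)
    for (j in seq_len(n)) {
      sub <- if (q[i] == t[j] && q[i] != "N") scheme$match else scheme$mismatch
      e <- max(H_prev[j + 1L] + open1, E_prev[j + 1L] + ext)
      Fj <- max(H_cur[j] + open1, Fj + ext)
      h <- max(0, H_prev[j] + sub, e, Fj)
      E_cur[j + 1L] <- e
      H_cur[j + 1L] <- h
      if (h > best || (h == best && h > 0 && (is.na(best_j) || j < best_j))) {
        best <- h; best_j <- j
      }
    }
    H_prev <- H_cur
    E_prev <- E_cur
  }
  list(score = best, target_end = if (best > 0) best_j else NA_integer_)
}

#' Classify cDNA read 5' ends by adapter evidence
#'
#' Implements the 5'-end validation of the workflow: the last
#' `suffix_len` (16) nucleotides of the library 5' adapter are aligned by
#' Smith-Waterman against a window of -10..+30 around the first mapped
#' nucleotide of each read; reads scoring below `scheme$min_score` (17) are
#' putative false 5' ends from template switching or non-specific priming.
#' The exact 5' terminal base is fixed when the adapter's last four
#' nucleotides occur with their end at read offsets -2..+3 (a 5-nt window
#' tolerating homopolymer miscalls around the adapter junction).
#'
#' The alignment target is built from the read's own sequence: up to 10
#' soft-clipped bases supply the negative offsets and the mapped prefix the
#' non-negative ones (set `target_from = "genome"` to use the reference
#' sequence instead).
#'
#' @param reads Read table from [read_alignments()] (cDNA only; dRNA reads
#'   have no 5' adapter and raise an error).
#' @param adapter Full adapter sequence (>= 16 nt); required, no default.
#' @param scheme A [scoring_scheme()].
#' @param suffix_len Number of adapter 3' bases aligned (16).
#' @param window Search window around the first mapped base, `c(-10, 30)`.
#' @param end_window Allowed end offsets for the last-4-nt rule, `c(-2, 3)`.
#' @param target_from `"read"` (default) or `"genome"`.
#' @param genome Needed when `target_from = "genome"`.
#' @return Tibble: `read_id`, `state` ("validated"/"uncertain"), `score`,
#'   `end_rule_hit`, `terminal_pos` (genomic, `NA` unless the end rule
#'   fired).
#' @export
classify_five_prime <- function(reads, adapter, scheme = scoring_scheme(),
                                suffix_len = 16L, window = c(-10L, 30L),
                                end_window = c(-2L, 3L),
                                target_from = c("read", "genome"),
                                genome = NULL) {
  target_from <- match.arg(target_from)
  if (any(reads$platform == "drna")) {
    stop("dRNA reads carry no 5' adapter; only cDNA reads can be 5'-validated")
  }
  if (nchar(adapter) < suffix_len) {
    stop("adapter must be at least ", suffix_len, " nt")
  }
  if (target_from == "genome" && is.null(genome)) {
    stop("target_from = \"genome\" requires a genome")
  }
  suffix <- substr(adapter, nchar(adapter) - suffix_len + 1L, nchar(adapter))
  last4 <- substr(adapter, nchar(adapter) - 3L, nchar(adapter))
  n5_max <- -window[1]
  n3_max <- window[2]

  one <- function(soft5, mapped_seq, five_prime_pos, strand) {
    if (target_from == "read") {
      n5 <- min(n5_max, nchar(soft5))
      clip_part <- if (n5 > 0) substr(soft5, nchar(soft5) - n5 + 1L, nchar(soft5)) else ""
      mapped_part <- substr(mapped_seq, 1L, n3_max + 1L)
      target <- paste0(clip_part, mapped_part)
    } else {
      n5 <- n5_max
      target <- genome_window(genome, five_prime_pos, window[1], window[2], strand)
    }
    if (nchar(target) == 0L) {
      return(list(score = 0L, end_rule_hit = FALSE, terminal_pos = NA_integer_))
    }
    al <- local_align(suffix, target, scheme)
    hits <- stringr::str_locate_all(target, stringr::fixed(last4))[[1]]
    hit_off <- integer(0)
    if (nrow(hits) > 0) hit_off <- hits[, "end"] - n5 - 1L
    # prefer the junction position expected for an intact adapter (offset 0),
    # then spread outward; deterministic
    pref <- c(0L, -1L, 1L, -2L, 2L, 3L)
    pref <- pref[pref >= end_window[1] & pref <= end_window[2]]
    sel <- pref[pref %in% hit_off]
    if (length(sel) > 0) {
      o_end <- sel[1]
      k <- max(o_end + 1L, 0L)   # first read base 3' of the adapter (clamped to mapped)
      tp <- if (strand == "+") five_prime_pos + k else five_prime_pos - k
      list(score = al$score, end_rule_hit = TRUE, terminal_pos = tp)
    } else {
      list(score = al$score, end_rule_hit = FALSE, terminal_pos = NA_integer_)
    }
  }

  res <- purrr::pmap(
    list(reads$soft5, reads$mapped_seq, reads$five_prime_pos, reads$strand),
    one
  )
  tibble::tibble(
    read_id = reads$read_id,
    state = ifelse(
      vapply(res, `[[`, numeric(1), "score") >= scheme$min_score,
      "validated", "uncertain"
    ),
    score = vapply(res, `[[`, numeric(1), "score"),
    end_rule_hit = vapply(res, `[[`, logical(1), "end_rule_hit"),
    terminal_pos = vapply(res, function(r) as.integer(r$terminal_pos), integer(1))
  )
}

#' Does the genome mimic the adapter 3' terminus upstream of a position?
#'
#' Flags positions where more than three consecutive genomic bases
#' immediately 5'-ward of `pos` (strand-aware) are identical to the
#' adapter's 3' terminus, i.e. loci where template switching and false
#' priming against genomic sequence are possible.
#'
#' @param g A [genome_model()].
#' @param pos 0-based position(s).
#' @param strand Strand(s), recycled.
#' @param adapter Adapter sequence.
#' @param min_match Matches required beyond which the flag fires
#'   (default 3: "more than three").
#' @return Logical vector.
#' @export
genomic_adapter_homology <- function(g, pos, strand, adapter, min_match = 3L) {
  k <- min(nchar(adapter), g$length - 1L)
  asuf <- substr(adapter, nchar(adapter) - k + 1L, nchar(adapter))
  n <- max(length(pos), length(strand))
  pos <- rep_len(pos, n); strand <- rep_len(strand, n)
  vapply(seq_len(n), function(i) {
    up <- genome_window(g, pos[i], -k, -1L, strand[i])
    if (nchar(up) < min_match + 1L) return(FALSE)
    # longest common suffix of adapter and the upstream window
    l <- 0L
    while (l < min(nchar(up), k) &&
           substr(asuf, k - l, k - l) == substr(up, nchar(up) - l, nchar(up) - l)) {
      l <- l + 1L
    }
    l > min_match
  }, logical(1))
}
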