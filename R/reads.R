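#' Read long-read alignments from SAM/BAM into a tidy read table
#'
#' Parses primary alignments into one row per read, extracting alignment
#' blocks (CIGAR `N` gaps split blocks), soft-clipped 5'/3' sequences in
#' *read* orientation, and the strand-aware genomic positions of the first
#' and last mapped bases. For a minus-strand alignment the clip stored at
#' the left (reference) end of the record is the read's 3' clip; the SEQ
#' field is reverse-complemented back into read orientation before the
#' clips and mapped sequence are taken.
#'
#' Secondary, supplementary and unmapped records are skipped; records
#' without a CIGAR are skipped with a warning.
#'
#' @param path SAM or BAM file (SAM is converted in a temporary directory).
#' @param platform `"cdna"` or `"drna"`; stored per read.
#' @param min_mapq Optional minimum mapping quality (default 0, i.e. no
#'   filter, as in the source workflow).
#' @return A tibble with columns `read_id`, `platform`, `strand`, `blocks`
#'   (list of two-column matrices of 0-based half-open intervals), `soft5`,
#'   `soft3`, `mapped_seq` (mapped bases, read orientation),
#'   `five_prime_pos`, `three_prime_pos` (0-based).
#' @export
read_alignments <- function(path, platform = c("cdna", "drna"), min_mapq = 0) {
  platform <- match.arg(platform)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  par <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "pos", "cigar", "seq", "strand", "mapq")
  )
  rec <- Rsamtools::scanBam(bam, param = par)[[1]]
  n <- length(rec$qname)
  if (n == 0L) {
    return(tibble::tibble(
      read_id = character(), platform = character(), strand = character(),
      blocks = list(), soft5 = character(), soft3 = character(),
      mapped_seq = character(), five_prime_pos = integer(),
      three_prime_pos = integer()
    ))
  }
  keep <- !is.na(rec$cigar)
  if (any(!keep)) {
    warning(sum(!keep), " alignment record(s) without CIGAR were skipped")
  }
  if (min_mapq > 0) keep <- keep & !is.na(rec$mapq) & rec$mapq >= min_mapq
  idx <- which(keep)
  cig <- rec$cigar[idx]
  pos1 <- rec$pos[idx]
  seqs <- as.character(rec$seq[idx])
  strand <- as.character(rec$strand[idx])

  blocks_ref <- GenomicAlignments::extractAlignmentRangesOnReference(
    cig, pos = pos1, drop.D.ranges = FALSE
  )
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  left_clip <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]
    if (length(o) && o[1] == "S") lens[[i]][1] else 0L
  }, integer(1))
  right_clip <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]
    k <- length(o)
    if (k && o[k] == "S") lens[[i]][k] else 0L
  }, integer(1))

  rows <- lapply(seq_along(idx), function(i) {
    br <- blocks_ref[[i]]
    blk <- cbind(
      start = IRanges::start(br) - 1L,        # to 0-based half-open
      end = IRanges::end(br)
    )
    len <- nchar(seqs[i])
    clipL <- substr(seqs[i], 1L, left_clip[i])
    clipR <- substr(seqs[i], len - right_clip[i] + 1L, len)
    mapped <- substr(seqs[i], left_clip[i] + 1L, len - right_clip[i])
    if (strand[i] == "+") {
      soft5 <- clipL; soft3 <- clipR
      mseq <- mapped
      fp <- blk[1, "start"]
      tp <- blk[nrow(blk), "end"] - 1L
    } else {
      soft5 <- revcomp(clipR); soft3 <- revcomp(clipL)
      mseq <- revcomp(mapped)
      fp <- blk[nrow(blk), "end"] - 1L
      tp <- blk[1, "start"]
    }
    list(blocks = blk, soft5 = soft5, soft3 = soft3, mapped_seq = mseq,
         five_prime_pos = fp, three_prime_pos = tp)
  })

  tibble::tibble(
    read_id = rec$qname[idx],
    platform = platform,
    strand = strand,
    blocks = lapply(rows, `[[`, "blocks"),
    soft5 = vapply(rows, `[[`, character(1), "soft5"),
    soft3 = vapply(rows, `[[`, character(1), "soft3"),
    mapped_seq = vapply(rows, `[[`, character(1), "mapped_seq"),
    five_prime_pos = vapply(rows, `[[`, integer(1), "five_prime_pos"),
    three_prime_pos = vapply(rows, `[[`, integer(1), "three_prime_pos")
  )
}

# total genomic span of a read (0-based half-open over all blocks)
read_span <- function(blocks) {
  c(blocks[1, "start"], blocks[nrow(blocks), "end"])
}
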