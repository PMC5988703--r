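#' Genome model for a single (optionally circular) replicon
#'
#' A `genome_model` holds one reference sequence together with its topology.
#' All internal coordinates in viranno are 0-based, half-open, on the forward
#' strand; 5'/3' semantics are always strand-aware. Window extraction wraps
#' around the origin for circular genomes and truncates at the edges of
#' linear ones.
#'
#' @param sequence Single DNA string (A/C/G/T/N; upper-cased on input).
#' @param name Sequence name.
#' @param circular Is the replicon circular?
#' @return An object of class `genome_model` with fields `name`, `length`,
#'   `circular` and `sequence`.
#' @export
genome_model <- function(sequence, name = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  if (stringr::str_detect(sequence, "[^ACGTN]")) {
    stop("genome sequence contains characters outside A/C/G/T/N")
  }
  structure(
    list(
      name = as.character(name),
      length = nchar(sequence),
      circular = isTRUE(circular),
      sequence = sequence
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %s: %d bp, %s\n",
    x$name, x$length, if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

#' Load a genome from a single-record FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @param circular Topology flag stored on the returned model.
#' @return A [genome_model()].
#' @export
load_genome <- function(path, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequence records in ", path)
  if (length(seqs) > 1L) {
    stop(
      "expected a single-replicon genome but ", path, " has ",
      length(seqs), " records; extra records: ",
      paste(utils::tail(names(seqs), -1L), collapse = ", ")
    )
  }
  nm <- sub("\\s.*$", "", names(seqs)[1])
  genome_model(as.character(seqs[[1]]), name = nm, circular = circular)
}

#' Write a genome model to FASTA
#'
#' @param g A [genome_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(g, path) {
  x <- Biostrings::DNAStringSet(g$sequence)
  names(x) <- g$name
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# reverse complement of plain character vectors (vectorized, N-safe)
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

# modular position: fold any integer into [0, len)
wrap_pos <- function(pos, len) {
  ((pos %% len) + len) %% len
}

#' Extract a strand-oriented sequence window around a genomic position
#'
#' Offsets are relative to `pos` along the given strand: negative offsets are
#' 5'-ward, positive 3'-ward, and the window covers offsets `off5..off3`
#' inclusive. On the minus strand the returned string is the reverse
#' complement of the forward-strand slice, i.e. it reads 5' to 3' on the
#' transcript sense. Circular genomes wrap across the origin; linear genomes
#' truncate the window at the sequence edges.
#'
#' @param g A [genome_model()].
#' @param pos 0-based anchor position in `[0, length)`.
#' @param off5,off3 Window bounds (`off5 <= off3`).
#' @param strand `"+"` or `"-"`.
#' @return A character scalar (possibly shorter than requested for linear
#'   genomes at the edges).
#' @export
genome_window <- function(g, pos, off5, off3, strand = "+") {
  stopifnot(inherits(g, "genome_model"), off5 <= off3)
  width <- off3 - off5 + 1L
  if (width > g$length) stop("window of ", width, " bp exceeds genome length ", g$length)
  if (strand == "+") {
    lo <- pos + off5
    hi <- pos + off3
  } else {
    lo <- pos - off3
    hi <- pos - off5
  }
  if (g$circular) {
    start <- wrap_pos(lo, g$length)
    doubled_take <- function(s, from0, len) {
      if (from0 + len <= nchar(s)) {
        substr(s, from0 + 1L, from0 + len)
      } else {
        paste0(
          substr(s, from0 + 1L, nchar(s)),
          substr(s, 1L, from0 + len - nchar(s))
        )
      }
    }
    out <- doubled_take(g$sequence, start, width)
  } else {
    lo2 <- max(lo, 0L)
    hi2 <- min(hi, g$length - 1L)
    if (lo2 > hi2) return("")
    out <- substr(g$sequence, lo2 + 1L, hi2 + 1L)
  }
  if (strand == "-") out <- revcomp(out)
  out
}

# Single forward-strand base at a wrapped position (circular-aware).
genome_base <- function(g, pos) {
  p <- if (g$circular) wrap_pos(pos, g$length) else pos
  if (p < 0L || p >= g$length) return("")
  substr(g$sequence, p + 1L, p + 1L)
}

# Strand-aware circular distance between two positions (non-negative).
circ_dist <- function(a, b, len, circular = TRUE) {
  d <- abs(a - b)
  if (circular) pmin(d, len - d) else d
}
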