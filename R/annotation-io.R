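#' Read a reference annotation (GFF3) into a catalog
#'
#' The catalog holds previously annotated transcripts (`mRNA` features)
#' and their ORFs (`CDS` features) with 0-based half-open internal
#' coordinates and strand-aware TSS/TES positions.
#'
#' @param path GFF3 file.
#' @return A list of class `reference_catalog` with tibbles `transcripts`
#'   (`id`, `strand`, `start`, `end`, `tss`, `tes`) and `orfs`
#'   (`id`, `strand`, `start`, `end`).
#' @export
read_reference <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::tibble(
    type = as.character(gr$type),
    start = BiocGenerics::start(gr) - 1L,     # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    id = as.character(gr$ID)
  )
  tx <- dplyr::filter(df, .data$type %in% c("mRNA", "transcript"))
  orf <- dplyr::filter(df, .data$type == "CDS")
  transcripts <- tibble::tibble(
    id = tx$id, strand = tx$strand, start = tx$start, end = tx$end,
    tss = ifelse(tx$strand == "+", tx$start, tx$end - 1L),
    tes = ifelse(tx$strand == "+", tx$end - 1L, tx$start)
  )
  orfs <- tibble::tibble(
    id = sub("\\.cds$", "", orf$id), strand = orf$strand,
    start = orf$start, end = orf$end
  )
  structure(list(transcripts = transcripts, orfs = orfs),
            class = "reference_catalog")
}

#' @export
print.reference_catalog <- function(x, ...) {
  cat(sprintf("<reference_catalog> %d transcripts, %d ORFs\n",
              nrow(x$transcripts), nrow(x$orfs)))
  invisible(x)
}

# split exons that run past the circular origin (coordinates >= len are
# unwrapped); returns a matrix of in-range exons plus a wrap flag
unwrap_exons <- function(exons, len) {
  out <- NULL
  wrapped <- FALSE
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, 1]; e <- exons[i, 2]
    if (e <= len) {
      out <- rbind(out, c(s, e))
    } else {
      wrapped <- TRUE
      out <- rbind(out, c(s, len), c(0L, e - len))
    }
  }
  list(exons = out[order(out[, 1]), , drop = FALSE], wrapped = wrapped)
}

#' Write transcript models to GFF3 or BED12
#'
#' GFF3 uses 1-based inclusive coordinates, BED12 0-based half-open.
#' Transcripts spanning the circular origin are emitted as two-exon
#' features carrying an `origin_spanning=true` attribute. Output is
#' byte-stable for a fixed input ordering.
#'
#' @param transcripts Model tibble from [classify_transcripts()] (needs
#'   `id`, `name`, `strand`, `category`, `exons`, `host_gene`,
#'   `cistron_count`, `tss_status`, `support`).
#' @param path Output file.
#' @param format `"gff3"` or `"bed12"`.
#' @param genome A [genome_model()] (sequence name and length).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(transcripts, path, format = c("gff3", "bed12"),
                             genome) {
  format <- match.arg(format)
  con <- file(path, open = "wb")   # binary connection: stable \n endings
  on.exit(close(con))
  if (format == "gff3") {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", genome$name, genome$length)),
               con, sep = "\n")
    for (i in seq_len(nrow(transcripts))) {
      tr <- transcripts[i, ]
      ux <- unwrap_exons(tr$exons[[1]], genome$length)
      span_s <- min(ux$exons[, 1]); span_e <- max(ux$exons[, 2])
      attrs <- c(
        sprintf("ID=%s", tr$id),
        sprintf("Name=%s", tr$name),
        sprintf("category=%s", tr$category),
        if (!is.na(tr$host_gene)) sprintf("host_gene=%s", tr$host_gene),
        sprintf("cistron_count=%d", tr$cistron_count),
        sprintf("tss_status=%s", tr$tss_status),
        sprintf("evidence_reads=%d", tr$support),
        if (ux$wrapped) "origin_spanning=true"
      )
      writeLines(sprintf(
        "%s\tviranno\tmRNA\t%d\t%d\t.\t%s\t.\t%s",
        genome$name, span_s + 1L, span_e, tr$strand,
        paste(attrs, collapse = ";")
      ), con, sep = "\n")
      for (j in seq_len(nrow(ux$exons))) {
        writeLines(sprintf(
          "%s\tviranno\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
          genome$name, ux$exons[j, 1] + 1L, ux$exons[j, 2], tr$strand, tr$id
        ), con, sep = "\n")
      }
    }
  } else {
    for (i in seq_len(nrow(transcripts))) {
      tr <- transcripts[i, ]
      ux <- unwrap_exons(tr$exons[[1]], genome$length)
      ex <- ux$exons
      span_s <- min(ex[, 1]); span_e <- max(ex[, 2])
      writeLines(paste(
        genome$name, span_s, span_e, tr$name, 0L, tr$strand,
        span_s, span_e, "0,0,0", nrow(ex),
        paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ","),
        paste0(paste(ex[, 1] - span_s, collapse = ","), ","),
        sep = "\t"
      ), con, sep = "\n")
    }
  }
  invisible(path)
}

#' Write a simple site/feature GFF3 (reference catalogs, simulated truth)
#'
#' Internal helper used by the simulator to emit the partial reference
#' catalog: `mRNA` rows for transcripts and `CDS` rows for ORFs.
#' @noRd
write_catalog_gff3 <- function(transcripts, orfs, path, genome) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", genome$name, genome$length)),
             con, sep = "\n")
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    writeLines(sprintf(
      "%s\tviranno\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      genome$name, tr$start + 1L, tr$end, tr$strand, tr$id, tr$id
    ), con, sep = "\n")
  }
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    writeLines(sprintf(
      "%s\tviranno\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
      genome$name, o$start + 1L, o$end, o$strand, o$id, o$id
    ), con, sep = "\n")
  }
  invisible(path)
}
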