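# Shared fixtures: hand-built reads, tiny genomes, and one memoized
# default simulation + annotation reused by the end-to-end tests.

# one-row read tibble in the internal schema
mk_read <- function(read_id = "r1", platform = "cdna", strand = "+",
                    blocks = cbind(start = 100L, end = 200L),
                    soft5 = "", soft3 = "", mapped_seq = NULL,
                    genome = NULL) {
  colnames(blocks) <- c("start", "end")
  if (is.null(mapped_seq)) {
    if (!is.null(genome)) {
      segs <- vapply(seq_len(nrow(blocks)), function(i) {
        substr(genome$sequence, blocks[i, 1] + 1L, blocks[i, 2])
      }, character(1))
      mapped_seq <- paste(segs, collapse = "")
      if (strand == "-") {
        mapped_seq <- stringi::stri_reverse(chartr("ACGT", "TGCA", mapped_seq))
      }
    } else {
      mapped_seq <- strrep("A", sum(blocks[, 2] - blocks[, 1]))
    }
  }
  fp <- if (strand == "+") blocks[1, 1] else blocks[nrow(blocks), 2] - 1L
  tp <- if (strand == "+") blocks[nrow(blocks), 2] - 1L else blocks[1, 1]
  tibble::tibble(
    read_id = read_id, platform = platform, strand = strand,
    blocks = list(blocks), soft5 = soft5, soft3 = soft3,
    mapped_seq = mapped_seq,
    five_prime_pos = as.integer(fp), three_prime_pos = as.integer(tp)
  )
}

random_genome <- function(len, seed = 1, circular = TRUE) {
  withr::with_seed(seed, {
    genome_model(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = ""), circular = circular)
  })
}

# reference catalog built directly from simulator truth (no file round trip)
truth_catalog <- function(truth) {
  g <- truth$genes
  structure(list(
    transcripts = tibble::tibble(
      id = g$id, strand = g$strand, start = g$span_start, end = g$span_end,
      tss = g$tss, tes = g$tes
    ),
    orfs = tibble::tibble(id = g$id, strand = g$strand,
                          start = g$orf_start, end = g$orf_end)
  ), class = "reference_catalog")
}

# memoized default-world run shared by the heavy end-to-end tests
.vr_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.vr_cache$sim)) {
    .vr_cache$cfg <- sim_config(seed = 1L)
    .vr_cache$sim <- simulate_dataset(.vr_cache$cfg)
  }
  .vr_cache$sim
}

default_cfg <- function() {
  default_sim()
  .vr_cache$cfg
}

# full-fidelity run: SAM + GFF3 written to disk and read back
default_ann <- function() {
  if (is.null(.vr_cache$ann)) {
    sim <- default_sim()
    dir <- file.path(tempdir(), "viranno-default-sim")
    if (!dir.exists(dir)) write_sim(sim, dir)
    .vr_cache$sim_dir <- dir
    reads_c <- read_alignments(file.path(dir, "reads.sam"), "cdna")
    drna_ids <- sim$truth_reads$read_id[sim$truth_reads$platform == "drna"]
    reads_c$platform[reads_c$read_id %in% drna_ids] <- "drna"
    .vr_cache$reads <- reads_c
    ref <- read_reference(file.path(dir, "known.gff3"))
    .vr_cache$ref <- ref
    .vr_cache$ann <- annotate(reads_c, sim$genome, ref, default_cfg()$adapter)
  }
  .vr_cache$ann
}

default_reads <- function() {
  default_ann()
  .vr_cache$reads
}

default_ref <- function() {
  default_ann()
  .vr_cache$ref
}
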