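# Artefact-aware long-read simulator for a small circular viral genome.
#
# The generator plants a grid of genes with class-specific promoter motifs
# (TATA/CAGT for early, TAAG for late, both for early-late), AATAAA/ATTAAA
# polyadenylation signals and T-rich terminators, one novel isoform per
# gene (L/S/AT/"0.5"/TR in rotation), one splice isoform, one bicistronic
# and one complex transcript, plus adapter-homologous and A-rich decoy
# tracts inside ORFs. Reads are emitted as already-aligned SAM records
# with the artefacts the annotation workflow filters: template-switching
# false 5' ends at the adapter decoys, oligo(dT) false priming at the
# A-tracts, 5' degradation, dRNA 5' truncation (~23 nt) and dRNA CT-rich
# tail miscalls.

#' Simulation configuration
#'
#' Defaults are the stated desk-scale world: a 50 kb circular genome with
#' 20 genes, 100 cDNA reads per gene, 30 reads per novel isoform, 5 dRNA
#' reads per gene, and artefact rates of 0.1 each. Start/end jitter uses
#' discrete kernels over -2..+2 nt whose spreads are ordered early >
#' early-late > late for TSSs (start variation is widest for early genes)
#' and ATTAAA > AATAAA for TESs (end variation depends on the PAS).
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param genome_length Genome size in bp (50000).
#' @param n_genes Number of planted genes (20).
#' @param reads_per_gene cDNA reads per known gene (100).
#' @param n_reads_novel cDNA reads per novel isoform (30).
#' @param n_drna_per_gene dRNA reads per gene (5).
#' @param n_reads_special Reads for the splice/polycistronic/complex
#'   transcripts (20).
#' @param adapter Library 5' adapter used by the simulator (a synthetic
#'   stand-in; the real kit sequence is proprietary).
#' @param p_template_switch,p_false_prime,p_degraded Artefact rates (0.1).
#' @param degrade_mean Mean of the geometric 5' degradation trim (150 nt).
#' @param tail_range Poly(A) tail length range, inclusive (15..60).
#' @param drna_trunc_mean Mean Poisson 5' truncation of dRNA reads (23).
#' @param drna_ct_miscall Probability a dRNA tail is emitted CT-rich (0.3).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 50000L,
                       n_genes = 20L,
                       reads_per_gene = 100L,
                       n_reads_novel = 30L,
                       n_drna_per_gene = 5L,
                       n_reads_special = 20L,
                       adapter = "ACGCTCTTCCGATCTGTTGCAGGCAGC",
                       p_template_switch = 0.1,
                       p_false_prime = 0.1,
                       p_degraded = 0.1,
                       degrade_mean = 150,
                       tail_range = c(15L, 60L),
                       drna_trunc_mean = 23,
                       drna_ct_miscall = 0.3) {
  stopifnot(p_template_switch >= 0, p_false_prime >= 0, p_degraded >= 0,
            p_template_switch + p_false_prime + p_degraded <= 1,
            drna_ct_miscall >= 0, drna_ct_miscall <= 1,
            tail_range[1] >= 15L)
  structure(
    list(
      seed = as.integer(seed), genome_length = as.integer(genome_length),
      n_genes = as.integer(n_genes),
      reads_per_gene = as.integer(reads_per_gene),
      n_reads_novel = as.integer(n_reads_novel),
      n_drna_per_gene = as.integer(n_drna_per_gene),
      n_reads_special = as.integer(n_reads_special),
      adapter = adapter,
      p_template_switch = p_template_switch,
      p_false_prime = p_false_prime,
      p_degraded = p_degraded,
      degrade_mean = degrade_mean,
      tail_range = as.integer(tail_range),
      drna_trunc_mean = drna_trunc_mean,
      drna_ct_miscall = drna_ct_miscall,
      # architecture constants (per-gene layout within a 2400 bp slot)
      pitch = 2400L, tss_off = 400L, utr5 = 100L, orf_len = 900L,
      span_len = 1250L,
      # jitter kernels over -2..+2
      tss_kernels = list(
        "E" = c(.06, .16, .56, .16, .06),
        "E/L" = c(.04, .13, .66, .13, .04),
        "L" = c(.02, .10, .76, .10, .02)
      ),
      tes_kernels = list(
        "AATAAA" = c(.025, .10, .75, .10, .025),
        "ATTAAA" = c(.075, .175, .50, .175, .075)
      )
    ),
    class = "sim_config"
  )
}

base_probs <- c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)
stop_codons <- c("TAA", "TAG", "TGA")

sample_kernel <- function(n, kernel) {
  sample(-2L:2L, n, replace = TRUE, prob = kernel)
}

#' Build a simulated genome with planted gene models
#'
#' Places `n_genes` genes on alternating strand pairs (+,+,-,-), plants
#' their promoter/initiator/PAS/terminator motifs, one novel isoform per
#' gene, a splice isoform, a bicistronic and a complex transcript, and the
#' artefact decoys. Promoter and PAS scan windows of planted sites are
#' scrubbed of accidental consensus motifs so the planted kinetic classes
#' and PAS assignments are unambiguous ground truth.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (a [genome_model()]) and `truth` (lists of
#'   planted genes, transcripts, TSSs, TESs, junctions and artefacts).
#' @export
build_genome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  L <- cfg$genome_length
  need <- cfg$n_genes * cfg$pitch + cfg$tss_off + cfg$span_len
  if (need > L) {
    stop("cannot pack ", cfg$n_genes, " genes into ", L,
         " bp; increase genome_length to at least ", need)
  }
  chars <- sample(names(base_probs), L, replace = TRUE, prob = base_probs)
  protected <- logical(L)
  if (cfg$n_genes == 0L) {
    return(list(
      genome = genome_model(paste(chars, collapse = ""), name = "simvirus"),
      truth = empty_truth()
    ))
  }

  # write `motif` at sense offsets [off, off+len) relative to anchor/strand
  plant <- function(anchor, off, motif, strand, protect = TRUE) {
    mc <- strsplit(motif, "", fixed = TRUE)[[1]]
    n <- length(mc)
    if (strand == "+") {
      idx <- anchor + off + seq_len(n) - 1L
    } else {
      idx <- anchor - off - (seq_len(n) - 1L)
      mc <- chartr("ACGT", "TGCA", mc)
    }
    idx <- wrap_pos(idx, L)
    chars[idx + 1L] <<- mc
    if (protect) protected[idx + 1L] <<- TRUE
  }
  sense_at <- function(anchor, off, len, strand) {
    if (strand == "+") idx <- anchor + off + seq_len(len) - 1L
    else idx <- anchor - off - (seq_len(len) - 1L)
    idx <- wrap_pos(idx, L)
    s <- chars[idx + 1L]
    if (strand == "-") s <- chartr("ACGT", "TGCA", s)
    paste(s, collapse = "")
  }
  # remove accidental occurrences of `pats` in the sense window
  # [woff, woff+wlen) by flipping one unprotected base to sense-C
  scrub <- function(anchor, woff, wlen, strand, pats) {
    for (iter in 1:10) {
      win <- sense_at(anchor, woff, wlen, strand)
      dirty <- FALSE
      for (pat in pats) {
        loc <- stringr::str_locate_all(win, stringr::fixed(pat))[[1]]
        for (r in seq_len(nrow(loc))) {
          offs <- woff + (loc[r, "start"]:loc[r, "end"]) - 1L
          idx <- if (strand == "+") anchor + offs else anchor - offs
          idx <- wrap_pos(idx, L) + 1L
          free <- which(!protected[idx])
          if (length(free) > 0L) {
            chars[idx[free[1]]] <<- if (strand == "+") "C" else "G"
            dirty <- TRUE
          }
        }
      }
      if (!dirty) break
    }
  }

  n <- cfg$n_genes
  strands <- rep(c("+", "+", "-", "-"), length.out = n)
  classes <- rep(c("E", "L", "E/L"), length.out = n)
  pas <- ifelse(seq_len(n) %% 2L == 0L, "AATAAA", "ATTAAA")
  novel_type <- rep(c("L", "S", "AT", "0.5", "TR"), length.out = n)
  slot <- (seq_len(n) - 1L) * cfg$pitch
  span_start <- slot + cfg$tss_off
  span_end <- span_start + cfg$span_len
  tss <- ifelse(strands == "+", span_start, span_end - 1L)
  tes <- ifelse(strands == "+", span_end - 1L, span_start)
  # sense offsets within the transcript
  orf_off <- cfg$utr5                       # ORF start (sense)
  orf_sense_end <- cfg$utr5 + cfg$orf_len   # half-open
  tes_off <- cfg$span_len - 1L
  orf_start <- ifelse(strands == "+", span_start + orf_off,
                      span_end - orf_sense_end)
  orf_end <- ifelse(strands == "+", span_start + orf_sense_end,
                    span_end - orf_off)

  # sense-offset anchors used below (relative to the gene TSS)
  off_ts_decoy <- orf_off + 120L * 3L           # adapter 6-mer, codons 120..121
  off_ts_start <- orf_off + 122L * 3L           # template-switch read start
  off_fp_end <- orf_off + 203L * 3L - 1L        # last A of the 9-A tract
  off_tss_05 <- orf_off + 50L * 3L + 2L         # "0.5" internal TSS
  off_tes_tr <- orf_off + 180L * 3L - 1L        # TR TES (end of codon 179)
  adapter6 <- substr(cfg$adapter, nchar(cfg$adapter) - 5L, nchar(cfg$adapter))

  plant_tes_context <- function(anchor_tss, off, pa, strand) {
    plant(anchor_tss, off - 16L, pa, strand)
    plant(anchor_tss, off - 4L, "CGCAC", strand)
    plant(anchor_tss, off + 1L, "TTTT", strand)
  }
  plant_tss_motifs <- function(anchor_tss, off, class, strand) {
    if (class %in% c("E", "E/L")) plant(anchor_tss, off - 12L, "TATA", strand)
    core <- if (class == "E") "CAGT" else "TAAG"
    plant(anchor_tss, off - 1L, core, strand)
  }

  for (g in seq_len(n)) {
    st <- strands[g]
    # ORF body: stop-free random codons, ATG start, TAA stop
    codons <- sample(setdiff(mkAllCodons(), stop_codons),
                     cfg$orf_len / 3L - 2L, replace = TRUE)
    orf_seq <- paste0("ATG", paste(codons, collapse = ""), "TAA")
    plant(tss[g], orf_off, orf_seq, st, protect = FALSE)
    # planted in-ORF features (codon-safe spellings)
    plant(tss[g], orf_off + 50L * 3L, "CTAAGC", st)       # TAAG for "0.5"
    plant(tss[g], orf_off + 52L * 3L, "ATG", st)          # in-frame restart
    plant(tss[g], orf_off + 174L * 3L, "AATAAA", st)      # TR PAS
    plant(tss[g], orf_off + 179L * 3L, "TGCTTTTCA", st)   # TR TES context
    plant(tss[g], off_ts_decoy, adapter6, st)             # TS decoy
    plant(tss[g], orf_off + 200L * 3L, "AAAAAAAAA", st)   # FP decoy
    # promoter + TES contexts
    plant_tss_motifs(tss[g], 0L, classes[g], st)
    plant_tes_context(tss[g], tes_off, pas[g], st)
    # novel isoform sites
    nt <- novel_type[g]
    if (nt == "L") plant_tss_motifs(tss[g], -60L, "L", st)
    if (nt == "S") plant_tss_motifs(tss[g], 60L, "L", st)
    if (nt == "AT") plant_tes_context(tss[g], tes_off + 40L, pas[g], st)
  }

  # splice isoform on gene 10 (3' UTR intron, sense offsets 1050..1170)
  sp_gene <- 10L
  plant(tss[sp_gene], 1050L, "GT", strands[sp_gene])
  plant(tss[sp_gene], 1168L, "AG", strands[sp_gene])
  # non-canonical noise gap boundaries (must not look like GT..AG)
  plant(tss[sp_gene], 1060L, "CC", strands[sp_gene])
  plant(tss[sp_gene], 1158L, "TT", strands[sp_gene])

  # complex transcript: plus-strand read-through across gene 2 (+) and
  # gene 3 (-), ending at a dedicated TES past gene 3
  cx_tes <- span_end[3L] + 100L
  plant_tes_context(cx_tes, 0L, "AATAAA", "+")

  # template-switch reads must carry no real adapter signal: suppress
  # chance homology between the adapter suffix and the 31 mapped bases at
  # each planted TS start (the truth label says these 5' ends are false)
  suffix16 <- substr(cfg$adapter, nchar(cfg$adapter) - 15L, nchar(cfg$adapter))
  scrub_adapter <- function(anchor, off, strand) {
    for (iter in 1:25) {
      win <- sense_at(anchor, off, 31L, strand)
      al <- local_align(suffix16, win)
      if (al$score < 13L) break
      woff <- off + al$target_end - 1L
      idx <- wrap_pos(if (strand == "+") anchor + woff else anchor - woff, L) + 1L
      if (protected[idx]) break
      cur <- chars[idx]
      flip <- if (strand == "+") {
        if (cur == "C") "G" else "C"
      } else {
        if (cur == "G") "C" else "G"
      }
      chars[idx] <<- flip
    }
  }
  for (g in seq_len(n)) scrub_adapter(tss[g], off_ts_start, strands[g])

  # scrub scan windows so planted classes/PAS are unambiguous
  tr_tes <- ifelse(strands == "+", tss + off_tes_tr, tss - off_tes_tr)
  for (g in seq_len(n)) {
    st <- strands[g]
    scrub(tss[g], -50L, 50L, st, "TATA")
    scrub(tss[g], tes_off - 50L, 50L, st, c("AATAAA", "ATTAAA"))
    scrub(tss[g], off_tes_tr - 50L, 50L, st, c("AATAAA", "ATTAAA"))
    nt <- novel_type[g]
    if (nt == "L") scrub(tss[g], -110L, 50L, st, "TATA")
    if (nt == "S") scrub(tss[g], 10L, 50L, st, "TATA")
    if (nt == "0.5") scrub(tss[g], off_tss_05 - 50L, 50L, st, "TATA")
    if (nt == "AT") scrub(tss[g], tes_off - 10L, 50L, st, c("AATAAA", "ATTAAA"))
  }
  scrub(cx_tes, -50L, 50L, "+", c("AATAAA", "ATTAAA"))

  genome <- genome_model(paste(chars, collapse = ""), name = "simvirus")

  genes <- tibble::tibble(
    id = paste0("ORF", seq_len(n)), strand = strands, class = classes,
    pas = pas, tss = as.integer(tss), tes = as.integer(tes),
    span_start = as.integer(span_start), span_end = as.integer(span_end),
    orf_start = as.integer(orf_start), orf_end = as.integer(orf_end),
    novel_type = novel_type
  )
  sense_pos <- function(g, off) {
    if (strands[g] == "+") tss[g] + off else tss[g] - off
  }
  novel_rows <- lapply(seq_len(n), function(g) {
    nt <- novel_type[g]
    start_off <- switch(nt, "L" = -60L, "S" = 60L, "0.5" = off_tss_05, 0L)
    end_off <- switch(nt, "AT" = tes_off + 40L, "TR" = off_tes_tr, tes_off)
    cat <- switch(nt, "L" = "L", "S" = "S", "AT" = "AT",
                  "0.5" = "coding_truncated_0_5", "TR" = "TR_noncoding")
    nm <- switch(nt, "0.5" = paste0("ORF", g, ".5"),
                 "TR" = paste0("ORF", g, "-TR1"),
                 paste0("ORF", g, "-", nt))
    tibble::tibble(
      name = nm, category = cat, host = paste0("ORF", g),
      strand = strands[g],
      tss = as.integer(sense_pos(g, start_off)),
      tes = as.integer(sense_pos(g, end_off)),
      start_off = start_off, end_off = end_off
    )
  })
  transcripts <- dplyr::bind_rows(
    tibble::tibble(
      name = genes$id, category = "known", host = genes$id,
      strand = strands, tss = as.integer(tss), tes = as.integer(tes),
      start_off = 0L, end_off = tes_off
    ),
    dplyr::bind_rows(novel_rows),
    tibble::tibble(
      name = "ORF10-SP1", category = "SP", host = "ORF10",
      strand = strands[sp_gene], tss = as.integer(tss[sp_gene]),
      tes = as.integer(tes[sp_gene]), start_off = 0L, end_off = tes_off
    ),
    tibble::tibble(
      name = "ORF5-6", category = "polycistronic", host = "ORF5",
      strand = "+", tss = as.integer(tss[5L]), tes = as.integer(tes[6L]),
      start_off = 0L, end_off = NA_integer_
    ),
    tibble::tibble(
      name = "ORF2-C", category = "complex", host = "ORF2",
      strand = "+", tss = as.integer(tss[2L]), tes = as.integer(cx_tes),
      start_off = 0L, end_off = NA_integer_
    )
  )
  tss_truth <- dplyr::bind_rows(
    tibble::tibble(pos = as.integer(tss), strand = strands, class = classes,
                   source = genes$id),
    dplyr::bind_rows(lapply(seq_len(n), function(g) {
      nt <- novel_type[g]
      if (!nt %in% c("L", "S", "0.5")) return(NULL)
      off <- switch(nt, "L" = -60L, "S" = 60L, "0.5" = off_tss_05)
      tibble::tibble(pos = as.integer(sense_pos(g, off)),
                     strand = strands[g], class = "L",
                     source = paste0("ORF", g, "/", nt))
    }))
  )
  tes_truth <- dplyr::bind_rows(
    tibble::tibble(pos = as.integer(tes), strand = strands, pas = pas,
                   source = genes$id),
    dplyr::bind_rows(lapply(seq_len(n), function(g) {
      nt <- novel_type[g]
      if (nt == "AT") {
        tibble::tibble(pos = as.integer(sense_pos(g, tes_off + 40L)),
                       strand = strands[g], pas = pas[g],
                       source = paste0("ORF", g, "/AT"))
      } else if (nt == "TR") {
        tibble::tibble(pos = as.integer(sense_pos(g, off_tes_tr)),
                       strand = strands[g], pas = "AATAAA",
                       source = paste0("ORF", g, "/TR"))
      } else NULL
    })),
    tibble::tibble(pos = as.integer(cx_tes), strand = "+", pas = "AATAAA",
                   source = "ORF2-C")
  )
  sp_intron <- c(sense_pos(sp_gene, 1050L), sense_pos(sp_gene, 1170L))
  junctions_truth <- tibble::tibble(
    intron_start = min(sp_intron) + c(0L, 10L),
    intron_end = max(sp_intron) - c(0L, 10L),
    strand = strands[sp_gene],
    canonical = c(TRUE, FALSE)
  )
  artefacts <- tibble::tibble(
    type = rep(c("template_switch", "false_prime"), each = n),
    gene = rep(genes$id, 2L),
    pos = as.integer(c(
      vapply(seq_len(n), function(g) sense_pos(g, off_ts_start), numeric(1)),
      vapply(seq_len(n), function(g) sense_pos(g, off_fp_end), numeric(1))
    )),
    strand = rep(strands, 2L)
  )
  truth <- list(
    genes = genes, transcripts = transcripts, tss = tss_truth,
    tes = tes_truth, junctions = junctions_truth, artefacts = artefacts,
    offsets = list(
      ts_start = off_ts_start, fp_end = off_fp_end, tss_05 = off_tss_05,
      tes_tr = off_tes_tr, tes = tes_off, sp_gene = sp_gene,
      sp_intron_off = c(1050L, 1170L), noise_gap_off = c(1060L, 1160L),
      cx_tes = cx_tes
    )
  )
  list(genome = genome, truth = truth)
}

mkAllCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

empty_truth <- function() {
  list(
    genes = tibble::tibble(), transcripts = tibble::tibble(),
    tss = tibble::tibble(pos = integer(), strand = character(),
                         class = character(), source = character()),
    tes = tibble::tibble(pos = integer(), strand = character(),
                         pas = character(), source = character()),
    junctions = tibble::tibble(), artefacts = tibble::tibble(),
    offsets = list()
  )
}

# build one aligned read from sense coordinates relative to a gene TSS
make_read <- function(genome, anchor, strand, start_off, end_off,
                      introns_sense = NULL, soft5 = "", soft3 = "") {
  segs <- if (is.null(introns_sense) || nrow(introns_sense) == 0L) {
    cbind(start_off, end_off + 1L)
  } else {
    ins <- introns_sense[order(introns_sense[, 1]), , drop = FALSE]
    cbind(c(start_off, ins[, 2]), c(ins[, 1], end_off + 1L))
  }
  mapped <- paste(vapply(seq_len(nrow(segs)), function(i) {
    genome_window(genome, anchor, segs[i, 1], segs[i, 2] - 1L, strand)
  }, character(1)), collapse = "")
  if (strand == "+") {
    blk <- cbind(start = anchor + segs[, 1], end = anchor + segs[, 2])
  } else {
    blk <- cbind(start = anchor - segs[, 2] + 1L, end = anchor - segs[, 1] + 1L)
    blk <- blk[rev(seq_len(nrow(blk))), , drop = FALSE]
  }
  fp <- if (strand == "+") anchor + start_off else anchor - start_off
  tp <- if (strand == "+") anchor + end_off else anchor - end_off
  list(strand = strand, blocks = blk, soft5 = soft5, soft3 = soft3,
       mapped_seq = mapped, five_prime_pos = as.integer(fp),
       three_prime_pos = as.integer(tp))
}

#' Simulate cDNA and dRNA long reads with planted artefacts
#'
#' Normal cDNA reads carry the full adapter in their 5' soft clip and a
#' poly(A) tail in the 3' clip, with start/end jitter drawn from the
#' class- and PAS-specific kernels. Template-switch reads start at the
#' in-ORF adapter decoys without an adapter; false-priming reads end at
#' the A-rich decoy tracts; degraded reads lose a geometric 5' stretch but
#' keep their adapter. dRNA reads lack the adapter, are 5'-truncated by a
#' Poisson(~23) trim, and their tails are emitted CT-rich at the
#' configured miscall rate. Reads for the splice isoform, the bicistronic
#' read-through and the complex transcript (half of whose reads are
#' double-tailed) are added on top.
#'
#' @param genome,truth Output of [build_genome()].
#' @param cfg The same [sim_config()].
#' @return List with `reads` (internal read table, same schema as
#'   [read_alignments()]) and `truth_reads` (per-read labels).
#' @export
simulate_reads <- function(genome, truth, cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  genes <- truth$genes
  off <- truth$offsets
  rows <- list()
  labs <- list()
  add <- function(r, platform, transcript, gene, type) {
    rows[[length(rows) + 1L]] <<- c(r, list(platform = platform))
    labs[[length(labs) + 1L]] <<- tibble::tibble(
      transcript = transcript, gene = gene, platform = platform, type = type
    )
  }
  rand_tail <- function() {
    strrep("A", sample(cfg$tail_range[1]:cfg$tail_range[2], 1L))
  }
  ct_tail <- function() {
    paste(sample(c("C", "T"), sample(cfg$tail_range[1]:cfg$tail_range[2], 1L),
                 replace = TRUE), collapse = "")
  }
  tes_off <- off$tes

  sim_cdna_set <- function(n_reads, gene_row, start_base, end_base,
                           transcript, allow_fp = TRUE,
                           tss_class = gene_row$class) {
    g <- gene_row
    kern_s <- cfg$tss_kernels[[tss_class]]
    kern_e <- cfg$tes_kernels[[g$pas]]
    types <- sample(
      c("template_switch", "false_prime", "degraded", "clean"), n_reads,
      replace = TRUE,
      prob = c(cfg$p_template_switch, cfg$p_false_prime, cfg$p_degraded,
               1 - cfg$p_template_switch - cfg$p_false_prime - cfg$p_degraded)
    )
    for (ty in types) {
      s <- start_base + sample_kernel(1L, kern_s)
      e <- end_base + sample_kernel(1L, kern_e)
      soft5 <- cfg$adapter
      soft3 <- rand_tail()
      ty2 <- ty
      if (ty == "false_prime" && (!allow_fp || off$fp_end > end_base)) {
        ty2 <- "clean"
      }
      if (ty2 == "template_switch") {
        s <- off$ts_start
        soft5 <- ""
      } else if (ty2 == "false_prime") {
        e <- off$fp_end
      } else if (ty2 == "degraded") {
        trim <- 1L + stats::rgeom(1L, 1 / cfg$degrade_mean)
        s <- min(s + trim, e - 100L)
      }
      add(make_read(genome, g$tss, g$strand, s, e, NULL, soft5, soft3),
          "cdna", transcript, g$id, ty2)
    }
  }

  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sim_cdna_set(cfg$reads_per_gene, g, 0L, tes_off, g$id)
    # novel isoform reads
    nt <- g$novel_type
    tr <- truth$transcripts[truth$transcripts$host == g$id &
                              truth$transcripts$category != "known" &
                              !truth$transcripts$category %in%
                                c("SP", "polycistronic", "complex"), ]
    if (nrow(tr) == 1L) {
      # L/S/"0.5" isoform TSSs are planted with the late initiator (class
      # L); AT/TR isoforms share the host TSS and its class
      cls <- if (nt %in% c("L", "S", "0.5")) "L" else g$class
      sim_cdna_set(cfg$n_reads_novel, g, tr$start_off, tr$end_off, tr$name,
                   tss_class = cls)
    }
    # dRNA reads of the host transcript
    for (k in seq_len(cfg$n_drna_per_gene)) {
      s <- 0L + stats::rpois(1L, cfg$drna_trunc_mean)
      e <- tes_off + sample_kernel(1L, cfg$tes_kernels[[g$pas]])
      tail <- if (stats::runif(1L) < cfg$drna_ct_miscall) ct_tail() else rand_tail()
      add(make_read(genome, g$tss, g$strand, s, e, NULL, "", tail),
          "drna", g$id, g$id, "drna")
    }
  }

  # splice isoform reads (gene 10): canonical intron + non-canonical noise
  sg <- genes[off$sp_gene, ]
  intr <- matrix(off$sp_intron_off, ncol = 2)
  for (k in seq_len(cfg$n_reads_special)) {
    s <- sample_kernel(1L, cfg$tss_kernels[[sg$class]])
    e <- tes_off + sample_kernel(1L, cfg$tes_kernels[[sg$pas]])
    add(make_read(genome, sg$tss, sg$strand, s, e, intr, cfg$adapter,
                  rand_tail()),
        "cdna", "ORF10-SP1", sg$id, "clean")
  }
  noise <- matrix(off$noise_gap_off, ncol = 2)
  for (k in 1:3) {
    add(make_read(genome, sg$tss, sg$strand, 0L, tes_off, noise,
                  cfg$adapter, rand_tail()),
        "cdna", sg$id, sg$id, "noise_gap")
  }

  # bicistronic read-through: gene 5 TSS -> gene 6 TES
  g5 <- genes[5L, ]; g6 <- genes[6L, ]
  span36 <- g6$tes - g5$tss
  for (k in seq_len(cfg$n_reads_special)) {
    s <- sample_kernel(1L, cfg$tss_kernels[[g5$class]])
    e <- span36 + sample_kernel(1L, cfg$tes_kernels[[g6$pas]])
    add(make_read(genome, g5$tss, "+", s, e, NULL, cfg$adapter, rand_tail()),
        "cdna", "ORF5-6", g5$id, "clean")
  }

  # complex transcript: gene 2 TSS -> TES past gene 3; half double-tailed
  g2 <- genes[2L, ]
  cx_end <- off$cx_tes - g2$tss
  n_single <- ceiling(cfg$n_reads_special * 0.6)
  for (k in seq_len(cfg$n_reads_special)) {
    s <- sample_kernel(1L, cfg$tss_kernels[[g2$class]])
    if (k <= n_single) {
      soft5 <- cfg$adapter
    } else {
      soft5 <- strrep("T", 18L)   # miscalled second tail, no adapter
    }
    add(make_read(genome, g2$tss, "+", s, cx_end, NULL, soft5, rand_tail()),
        "cdna", "ORF2-C", g2$id, "complex")
  }

  n <- length(rows)
  reads <- tibble::tibble(
    read_id = sprintf("r%05d", seq_len(n)),
    platform = vapply(rows, `[[`, character(1), "platform"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    blocks = lapply(rows, `[[`, "blocks"),
    soft5 = vapply(rows, `[[`, character(1), "soft5"),
    soft3 = vapply(rows, `[[`, character(1), "soft3"),
    mapped_seq = vapply(rows, `[[`, character(1), "mapped_seq"),
    five_prime_pos = vapply(rows, `[[`, integer(1), "five_prime_pos"),
    three_prime_pos = vapply(rows, `[[`, integer(1), "three_prime_pos")
  )
  truth_reads <- dplyr::bind_cols(
    tibble::tibble(read_id = reads$read_id), dplyr::bind_rows(labs)
  )
  list(reads = reads, truth_reads = truth_reads)
}

#' Simulate a full dataset (genome + reads)
#'
#' @param cfg A [sim_config()].
#' @return List `genome`, `truth`, `reads`, `truth_reads`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  gb <- build_genome(cfg)
  sr <- simulate_reads(gb$genome, gb$truth, cfg)
  c(gb, sr)
}

#' Write simulated reads as a coordinate-sorted SAM file
#'
#' Soft clips are retained; minus-strand reads are emitted with
#' reverse-complemented SEQ and reference-order CIGAR, as an aligner
#' would. Byte-stable for a fixed read table.
#'
#' @param reads Internal read table (from [simulate_reads()]).
#' @param genome A [genome_model()].
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  n <- nrow(reads)
  pos1 <- vapply(reads$blocks, function(b) b[1, "start"] + 1L, integer(1))
  ord <- order(pos1, reads$read_id, method = "radix")
  lines <- character(n)
  for (k in seq_len(n)) {
    i <- ord[k]
    blk <- reads$blocks[[i]]
    widths <- blk[, "end"] - blk[, "start"]
    gaps <- if (nrow(blk) > 1L) blk[-1L, "start"] - blk[-nrow(blk), "end"]
            else integer(0)
    core <- paste0(widths[1], "M")
    if (length(gaps)) {
      for (j in seq_along(gaps)) {
        core <- paste0(core, gaps[j], "N", widths[j + 1L], "M")
      }
    }
    if (reads$strand[i] == "+") {
      left <- reads$soft5[i]; right <- reads$soft3[i]
      seq <- paste0(left, reads$mapped_seq[i], right)
    } else {
      left <- revcomp(reads$soft3[i]); right <- revcomp(reads$soft5[i])
      seq <- paste0(left, revcomp(reads$mapped_seq[i]), right)
    }
    cigar <- paste0(
      if (nchar(left)) paste0(nchar(left), "S") else "",
      core,
      if (nchar(right)) paste0(nchar(right), "S") else ""
    )
    flag <- if (reads$strand[i] == "+") 0L else 16L
    lines[k] <- paste(reads$read_id[i], flag, genome$name, pos1[i], 60L,
                      cigar, "*", 0L, 0L, seq, "*", sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$name, genome$length),
    lines
  ), con, sep = "\n")
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Emits `genome.fa`, `reads.sam`, `known.gff3` (the partial reference
#' catalog: known transcripts and ORFs only, novel isoforms withheld so
#' novelty detection is testable) and the `truth_*.tsv` tables.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_sam(sim$reads, sim$genome, file.path(dir, "reads.sam"))
  genes <- sim$truth$genes
  cat_tx <- tibble::tibble(
    id = genes$id, strand = genes$strand,
    start = genes$span_start, end = genes$span_end
  )
  cat_orf <- tibble::tibble(
    id = genes$id, strand = genes$strand,
    start = genes$orf_start, end = genes$orf_end
  )
  write_catalog_gff3(cat_tx, cat_orf, file.path(dir, "known.gff3"),
                     sim$genome)
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(dir, name))
  }
  tsv(sim$truth$transcripts, "truth_transcripts.tsv")
  tsv(sim$truth$tss, "truth_tss.tsv")
  tsv(sim$truth$tes, "truth_tes.tsv")
  tsv(sim$truth$junctions, "truth_junctions.tsv")
  tsv(sim$truth$artefacts, "truth_artefacts.tsv")
  tsv(sim$truth_reads, "truth_reads.tsv")
  invisible(dir)
}
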