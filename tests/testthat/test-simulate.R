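small_cfg <- function(seed = 5L, ...) {
  sim_config(seed = seed, genome_length = 26000L, n_genes = 10L,
             reads_per_gene = 20L, n_reads_novel = 10L,
             n_drna_per_gene = 2L, n_reads_special = 10L, ...)
}

test_that("seeded simulation is bit-reproducible", {
  s1 <- simulate_dataset(small_cfg())
  s2 <- simulate_dataset(small_cfg())
  expect_identical(s1$genome$sequence, s2$genome$sequence)
  expect_identical(s1$reads, s2$reads)
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(s1$reads, s1$genome, f1)
  write_sam(s2$reads, s2$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("an empty gene set yields a bare random genome", {
  gb <- build_genome(sim_config(seed = 2, n_genes = 0L,
                                genome_length = 5000L))
  expect_equal(gb$genome$length, 5000L)
  expect_equal(nrow(gb$truth$tss), 0L)
})

test_that("planted promoter grammar is on the genome", {
  gb <- build_genome(small_cfg())
  g <- gb$genome
  truth <- gb$truth
  for (i in seq_len(nrow(truth$genes))) {
    gene <- truth$genes[i, ]
    core <- genome_window(g, gene$tss, -1L, 2L, gene$strand)
    if (gene$class == "E") {
      expect_equal(core, "CAGT")
    } else {
      expect_equal(core, "TAAG")   # late initiator, TSS on its second base
    }
    if (gene$class %in% c("E", "E/L")) {
      expect_equal(genome_window(g, gene$tss, -12L, -9L, gene$strand), "TATA")
    }
    # PAS upstream of the TES and a T-run just past it
    expect_equal(genome_window(g, gene$tes, -16L, -11L, gene$strand),
                 gene$pas)
    expect_equal(genome_window(g, gene$tes, 1L, 4L, gene$strand), "TTTT")
    # reference ORFs begin ATG and end at a stop codon
    orf5 <- if (gene$strand == "+") gene$orf_start else gene$orf_end - 1L
    expect_equal(genome_window(g, orf5, 0L, 2L, gene$strand), "ATG")
    expect_equal(genome_window(g, orf5, 897L, 899L, gene$strand), "TAA")
  }
})

test_that("the clean condition validates every read and every tail", {
  cfg <- small_cfg(p_template_switch = 0, p_false_prime = 0, p_degraded = 0)
  sim <- simulate_dataset(cfg)
  cdna <- sim$reads[sim$reads$platform == "cdna", ]
  st <- classify_five_prime(cdna, cfg$adapter)
  # the only adapterless cDNA reads are double-tailed complex reads
  dbl <- sim$truth_reads$read_id[sim$truth_reads$type == "complex"]
  expect_true(all(st$state[!st$read_id %in% dbl] == "validated"))
  tl <- detect_tails(sim$reads, sim$genome)
  expect_true(all(!is.na(tl$tail3_kind)))
})

test_that("template-switch rate controls the uncertain-read fraction", {
  cfg <- small_cfg(seed = 6, p_template_switch = 0.3, p_false_prime = 0,
                   p_degraded = 0)
  sim <- simulate_dataset(cfg)
  cdna <- sim$reads[sim$reads$platform == "cdna", ]
  st <- classify_five_prime(cdna, cfg$adapter)
  frac <- mean(st$state == "uncertain")
  # 0.3 of the gene/isoform reads plus a handful of double-tailed complex
  # reads; binomial error at n ~ 330
  expect_gt(frac, 0.21)
  expect_lt(frac, 0.38)
  # template-switch reads are never validated (their label says false 5')
  ts_ids <- sim$truth_reads$read_id[sim$truth_reads$type == "template_switch"]
  expect_true(all(st$state[st$read_id %in% ts_ids] == "uncertain"))
})

test_that("write_sim emits a readable, complete dataset", {
  sim <- simulate_dataset(small_cfg())
  dir <- tempfile()
  write_sim(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "reads.sam", "known.gff3", "truth_transcripts.tsv",
    "truth_tss.tsv", "truth_tes.tsv", "truth_junctions.tsv",
    "truth_artefacts.tsv", "truth_reads.tsv"
  )))))
  g <- load_genome(file.path(dir, "genome.fa"))
  expect_identical(g$sequence, sim$genome$sequence)
  ref <- read_reference(file.path(dir, "known.gff3"))
  expect_equal(nrow(ref$transcripts), 10L)
  expect_equal(nrow(ref$orfs), 10L)
  # the catalog withholds the novel isoforms
  expect_false(any(grepl("-", ref$transcripts$id, fixed = TRUE)))
})
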