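test_that("the >10 nt isoform rule is strict at the boundary", {
  # 11 nt longer 5' UTR -> L; 10 nt -> known
  expect_equal(cat_of(mk_model(489, 1499))$category, "L")
  expect_equal(cat_of(mk_model(490, 1499))$category, "known")
  # 11 nt shorter -> S; 10 nt -> known
  expect_equal(cat_of(mk_model(511, 1499))$category, "S")
  expect_equal(cat_of(mk_model(510, 1499))$category, "known")
  # alternative termination: anchored on the shared TSS
  expect_equal(cat_of(mk_model(500, 1510))$category, "AT")
  expect_equal(cat_of(mk_model(500, 1509))$category, "known")
  expect_equal(cat_of(mk_model(489, 1499))$name, "ORF1-L")
})

test_that("5'-truncated coding models become '0.5' with host naming", {
  # TSS inside the ORF, in-frame ATG at 903, reaches the host stop
  m <- cat_of(mk_model(901, 1499))
  expect_equal(m$category, "coding_truncated_0_5")
  expect_equal(m$name, "ORF1.5")
  expect_equal(m$host_gene, "ORF1")
  # no in-frame ATG downstream of the start -> not coding-truncated
  m2 <- cat_of(mk_model(1000, 1499))
  expect_false(m2$category == "coding_truncated_0_5")
})

test_that("3'-truncated non-coding models become TR with ordinal names", {
  m <- cat_of(mk_model(500, 1100))
  expect_equal(m$category, "TR_noncoding")
  expect_equal(m$name, "ORF1-TR1")
  two <- dplyr::bind_rows(mk_model(500, 1100, id = "TX0001"),
                          mk_model(500, 1050, id = "TX0002"))
  out <- cat_of(two)
  expect_setequal(out$name, c("ORF1-TR1", "ORF1-TR2"))
})

test_that("splice isoforms take priority over end-based categories", {
  m <- cat_of(mk_model(500, 1499, introns = cbind(start = 1250L,
                                                  end = 1350L)))
  expect_equal(m$category, "SP")
  expect_equal(m$name, "ORF1-SP1")
})

test_that("cistron counting requires full same-strand ORF containment", {
  expect_equal(count_cistrons(500L, 2400L, "+", two_gene_ref), 2L)
  # 40% of the second ORF is not containment
  expect_equal(count_cistrons(500L, 1940L, "+", two_gene_ref), 1L)
  m <- cat_of(mk_model(500, 2399), ref = two_gene_ref)
  expect_equal(m$category, "polycistronic")
  expect_equal(m$cistron_count, 2L)
  expect_equal(m$name, "ORF1-2")
  # an ORF interrupted by an intron does not count
  expect_equal(
    count_cistrons(500L, 2400L, "+", two_gene_ref,
                   introns = cbind(start = 1800L, end = 1900L)), 1L)
})

test_that("complex transcripts need opposite orientations and name -C", {
  m <- mk_model(480, 2410, complex = TRUE)
  out <- classify_transcripts(m, opposed_ref, cls_genome)
  expect_equal(out$category, "complex")
  expect_equal(out$name, "ORF1-C")
  # spanning two same-strand genes is polycistronic, not complex
  expect_false(is_complex_span(480L, 2410L, two_gene_ref))
  expect_true(is_complex_span(480L, 2410L, opposed_ref))
  # containment slack: starting a few nt inside the first gene still spans
  expect_true(is_complex_span(505L, 2410L, opposed_ref))
  expect_false(is_complex_span(600L, 2410L, opposed_ref))
})

test_that("complex read groups impute the closest upstream annotated TSS", {
  tes_calls <- tibble::tibble(pos = 2500L, strand = "+",
                              support_cdna = 12L, support_drna = 0L)
  tss_calls <- tibble::tibble(pos = integer(), strand = character(),
                              k0 = integer())
  df <- tibble::tibble(
    read_id = c("x1", "x2"), strand = "+",
    span_start = 700L, span_end = 2501L,
    five_prime_pos = 700L, three_prime_pos = 2500L,
    state = "uncertain", end_rule_hit = FALSE,
    terminal_pos = NA_integer_, tail3_kind = "polyA"
  )
  out <- classify_complex_reads(df, tss_calls, tes_calls, opposed_ref,
                                cls_genome)
  expect_equal(nrow(out), 1L)
  expect_equal(out$tss_status, "undetermined")
  # nearest annotated same-strand TSS 5'-ward of 700 is ORF1's at 500
  expect_equal(out$tss, 500L)
  expect_equal(out$span_start, 500L)
  # beyond the horizon nothing is imputed
  out2 <- classify_complex_reads(df, tss_calls, tes_calls, opposed_ref,
                                 cls_genome, horizon = 100L)
  expect_true(is.na(out2$tss))
})

test_that("models with no overlapping reference become review candidates", {
  m <- cat_of(mk_model(2600, 2900))
  expect_equal(m$category, "candidate_novel")
})

test_that("assembled groups get one category each and unique names", {
  ann <- default_ann()
  tx <- ann$transcripts
  expect_true(all(tx$category %in% c(
    "known", "L", "S", "AT", "coding_truncated_0_5", "TR_noncoding", "SP",
    "polycistronic", "complex", "candidate_novel"
  )))
  expect_false(any(duplicated(tx$name)))
  expect_false(any(duplicated(tx$id)))
  # the undetermined-TSS invariant: only multi-gene categories keep them
  und <- tx[tx$tss_status == "undetermined", ]
  expect_true(all(und$category %in% c("polycistronic", "complex", "AT")))
})
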