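motif_genome <- function(plants, len = 400L) {
  # plants: list of c(pos0, "SEQ") on the forward strand
  ch <- rep("C", len)
  for (p in plants) {
    s <- strsplit(p[[2]], "")[[1]]
    ch[(as.integer(p[[1]]) + 1):(as.integer(p[[1]]) + length(s))] <- s
  }
  genome_model(paste(ch, collapse = ""), circular = TRUE)
}

test_that("initiator geometry: transcription starts on the motif's A", {
  # TAAG with the TSS on its second base -> late class
  g <- motif_genome(list(list(199, "TAAG")))
  sc <- scan_tss_context(g, 200L, "+")
  expect_true("LIS_TAAG" %in% sc$hits$motif)
  expect_equal(sc$class, "L")
  # one base off -> no hit
  expect_false("LIS_TAAG" %in% scan_tss_context(g, 201L, "+")$hits$motif)

  # CAGT analogously -> early class
  g2 <- motif_genome(list(list(199, "CAGT")))
  sc2 <- scan_tss_context(g2, 200L, "+")
  expect_true("early_initiator_CAGT" %in% sc2$hits$motif)
  expect_equal(sc2$class, "E")

  # arthropod-like 5-mers centred on the TSS
  g3 <- motif_genome(list(list(198, "ACAGG")))
  sc3 <- scan_tss_context(g3, 200L, "+")
  expect_true("arthropod_ACAGT_like" %in% sc3$hits$motif)
})

test_that("TATA is windowed and combines with initiators into classes", {
  g <- motif_genome(list(list(188, "TATA"), list(199, "CAGT")))
  sc <- scan_tss_context(g, 200L, "+")
  expect_true("TATA" %in% sc$hits$motif)
  expect_equal(sc$hits$offset[sc$hits$motif == "TATA"], -12L)
  expect_equal(sc$class, "E")
  # TATA plus a late initiator -> early-late
  g2 <- motif_genome(list(list(188, "TATA"), list(199, "TAAG")))
  expect_equal(scan_tss_context(g2, 200L, "+")$class, "E/L")
  # neither -> unknown
  g3 <- motif_genome(list())
  expect_equal(scan_tss_context(g3, 200L, "+")$class, "unknown")
})

test_that("TES context finds PAS hexamers and T-rich terminators", {
  g <- motif_genome(list(list(184, "AATAAA"), list(201, "TTTT")))
  h <- scan_tes_context(g, 200L, "+")
  expect_true("PAS_AATAAA" %in% h$motif)
  expect_equal(h$offset[h$motif == "PAS_AATAAA"], -16L)
  expect_true("T_rich_terminator" %in% h$motif)
  # the alternative hexamer
  g2 <- motif_genome(list(list(184, "ATTAAA")))
  expect_true("PAS_ATTAAA" %in% scan_tes_context(g2, 200L, "+")$motif)
  # nothing in the window
  expect_equal(nrow(scan_tes_context(motif_genome(list()), 200L, "+")), 0L)
})

test_that("scanning is strand-symmetric under reverse complement", {
  set.seed(81)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  g <- genome_model(seq, circular = TRUE)
  rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", seq))
  g_rc <- genome_model(rc, circular = TRUE)
  for (pos in c(100L, 250L, 400L)) {
    mirror <- g$length - 1L - pos
    srt <- function(h) h[order(h$motif, h$offset), ]
    a <- scan_tss_context(g, pos, "+")
    b <- scan_tss_context(g_rc, mirror, "-")
    expect_equal(a$class, b$class)
    expect_equal(srt(a$hits), srt(b$hits))
    expect_equal(srt(scan_tes_context(g, pos, "+")),
                 srt(scan_tes_context(g_rc, mirror, "-")))
  }
})

test_that("planted kinetic classes are recovered on the simulation", {
  sim <- default_sim()
  ann <- default_ann()
  truth <- sim$truth$tss
  cls <- ann$motifs$tss
  hit <- dplyr::inner_join(truth, cls, by = c("pos", "strand"))
  expect_equal(nrow(hit), nrow(truth))     # every planted TSS was called
  expect_identical(hit$class.y, hit$class.x)
})
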