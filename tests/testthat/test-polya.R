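test_that("detect_tail applies the 15-nt homopolymer rule edge-anchored", {
  expect_equal(detect_tail(strrep("A", 15), "three_prime", "cdna")$kind,
               "polyA")
  expect_equal(detect_tail(strrep("A", 15), "three_prime", "cdna")$length, 15L)
  expect_null(detect_tail(strrep("A", 14), "three_prime", "cdna"))
  # run may start within 5 nt of the clip edge (miscalled junction bases)
  expect_equal(detect_tail(paste0("CGCG", strrep("A", 20)), "three_prime",
                           "cdna")$length, 20L)
  expect_null(detect_tail(paste0("CGCGCG", strrep("A", 20)), "three_prime",
                          "cdna"))
  # 5' clips are scanned from their read-internal edge (the clip end)
  expect_equal(detect_tail(paste0(strrep("T", 16), "GC"), "five_prime",
                           "cdna")$kind, "polyT")
  # interrupted runs do not count
  expect_null(detect_tail(paste0(strrep("A", 10), "G", strrep("A", 10)),
                          "three_prime", "cdna"))
})

test_that("CT/GA-rich windows are accepted for dRNA only", {
  ct <- "CTTCTCTTTCCTTTCT"   # 16 nt, 100% C/T
  expect_equal(detect_tail(ct, "three_prime", "drna")$kind, "ct_rich")
  expect_null(detect_tail(ct, "three_prime", "cdna"))
  ga <- chartr("CT", "GA", ct)
  expect_equal(detect_tail(ga, "three_prime", "drna")$kind, "ga_rich")
  # composition fraction by direct counting: 12/15 = 0.8 passes, 11/15 fails
  mix_pass <- paste0(strrep("CT", 6), "GGG")
  ch <- strsplit(mix_pass, "")[[1]]
  expect_equal(sum(ch %in% c("C", "T")) / length(ch), 0.8)
  expect_equal(detect_tail(mix_pass, "three_prime", "drna")$kind, "ct_rich")
  mix_fail <- paste0(strrep("CT", 5), "A", "GGGG")
  expect_null(detect_tail(mix_fail, "three_prime", "drna"))
})

test_that("detect_tail is monotone under appending A's", {
  set.seed(41)
  for (k in 1:30) {
    clip <- paste0(paste(sample(c("A", "C", "G", "T"), sample(0:4, 1),
                                replace = TRUE), collapse = ""),
                   strrep("A", sample(15:40, 1)))
    before <- detect_tail(clip, "three_prime", "cdna")
    expect_equal(before$kind, "polyA")
    after <- detect_tail(paste0(clip, strrep("A", 5)), "three_prime", "cdna")
    expect_equal(after$kind, "polyA")
    expect_gte(after$length, before$length)
  }
})

test_that("is_false_primed flags 3+ genomic A at the 3' end", {
  g <- genome_model(paste0(strrep("C", 20), "AAA", strrep("C", 20),
                           "AAT", strrep("C", 14)), circular = FALSE)
  # last mapped base at the third A (0-based pos 22): genomic AAA -> flagged
  expect_true(is_false_primed(g, 22L, "+"))
  # context ...AAT -> not flagged
  expect_false(is_false_primed(g, 45L, "+"))
  # minus strand reads the sense bases as the reverse complement
  gm <- genome_model(paste0(strrep("C", 20), "TTT", strrep("C", 37)),
                     circular = FALSE)
  expect_true(is_false_primed(gm, 20L, "-"))
})

test_that("false-priming flags equal a sliding-window scan oracle", {
  g <- random_genome(800, seed = 42)
  pos <- 10:790
  got <- vapply(pos, function(p) is_false_primed(g, p, "+"), logical(1))
  oracle <- vapply(pos, function(p) {
    substr(g$sequence, p - 1, p + 1) == "AAA"   # 1-based window p-2..p 0-based
  }, logical(1))
  expect_identical(got, oracle)
})

test_that("double-tailed reads are recognized", {
  a15 <- strrep("A", 15)
  t16 <- strrep("T", 16)
  expect_false(has_double_tail(soft5 = "", soft3 = a15))
  expect_true(has_double_tail(soft5 = t16, soft3 = a15))
})

test_that("detect_tails summarizes read-level tail evidence", {
  g <- random_genome(300, seed = 43)
  reads <- dplyr::bind_rows(
    mk_read("a", soft3 = strrep("A", 20), genome = g,
            blocks = cbind(10L, 60L)),
    mk_read("b", soft5 = strrep("T", 18), soft3 = strrep("A", 20),
            genome = g, blocks = cbind(80L, 130L)),
    mk_read("c", platform = "drna", soft3 = strrep("CT", 10), genome = g,
            blocks = cbind(150L, 200L))
  )
  tl <- detect_tails(reads, g)
  expect_equal(tl$tail3_kind, c("polyA", "polyA", "ct_rich"))
  expect_equal(tl$double_tail, c(FALSE, TRUE, FALSE))
})
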