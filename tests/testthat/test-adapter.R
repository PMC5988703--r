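rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# independent oracle: Biostrings pairwiseAlignment with gapOpening=1,
# gapExtension=2 reproduces the affine convention gap(L) = 3 + (L-1)*2
bs_score <- local({
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  function(q, t) {
    s <- Biostrings::pairwiseAlignment(q, t, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 1, gapExtension = 2,
                                       scoreOnly = TRUE)
    max(0, s)
  }
})

test_that("local_align scores basic cases and gap conventions", {
  set.seed(21)
  q <- rand_dna(16)
  expect_equal(local_align(q, q)$score, 32)
  expect_equal(local_align("AAAA", "CCCC")$score, 0)
  # single-base gap costs 3: 7 matches * 2 - 3 = 11
  expect_equal(local_align("ACGTACGT", "ACGACGT")$score, 11)
  # length-2 gap costs 5 but the truncated exact match scores higher
  expect_equal(local_align("ACGTTTACG", "ACGACG")$score, 6)
  # N never matches
  expect_equal(local_align("NNNN", "NNNN")$score, 0)
})

test_that("local_align equals the independent DP oracle on random pairs", {
  set.seed(22)
  for (k in 1:250) {
    q <- rand_dna(sample(4:20, 1))
    t <- rand_dna(sample(4:20, 1))
    expect_equal(local_align(q, t)$score, bs_score(q, t),
                 info = paste(q, t))
  }
})

test_that("local_align is symmetric under reverse-complementing both inputs", {
  rc <- function(x) stringi::stri_reverse(chartr("ACGT", "TGCA", x))
  set.seed(23)
  for (k in 1:50) {
    q <- rand_dna(sample(6:16, 1))
    t <- rand_dna(sample(10:30, 1))
    expect_equal(local_align(q, t)$score, local_align(rc(q), rc(t))$score)
  }
})

test_that("classify_five_prime validates planted adapters and fixes the 5' base", {
  g <- random_genome(400, seed = 31)
  adapter <- sim_config()$adapter
  r <- mk_read(blocks = cbind(100L, 200L), soft5 = adapter, genome = g)
  st <- classify_five_prime(r, adapter)
  expect_equal(st$state, "validated")
  expect_equal(st$score, 20)          # last 10 adapter bases visible in clip
  expect_true(st$end_rule_hit)
  expect_equal(st$terminal_pos, 100L)

  # minus-strand read: terminal position is still the first mapped base
  rm <- mk_read(strand = "-", blocks = cbind(100L, 200L), soft5 = adapter,
                genome = g)
  stm <- classify_five_prime(rm, adapter)
  expect_equal(stm$terminal_pos, 199L)

  # no clip, no homology in the mapped prefix -> uncertain
  r0 <- mk_read(soft5 = "", genome = g, blocks = cbind(100L, 200L))
  expect_equal(classify_five_prime(r0, adapter)$state, "uncertain")

  # dRNA reads have no 5' adapter
  rd <- mk_read(platform = "drna", genome = g)
  expect_error(classify_five_prime(rd, adapter), "dRNA")
})

test_that("degenerate adapter copies behave exactly at the score threshold", {
  # the -10..+30 window shows only 10 clip bases, so a full 16-mer copy is
  # visible only when it straddles the alignment junction: the copy's
  # first 9 bases sit in the clip, its last 7 start the mapped sequence
  adapter <- "ACGCTCTTCCGATCTGTTGCAGGCAGC"
  suffix <- substr(adapter, nchar(adapter) - 15, nchar(adapter))
  set.seed(32)
  mut <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    for (j in at) ch[j] <- setdiff(c("A", "C", "G", "T"), ch[j])[1]
    paste(ch, collapse = "")
  }
  make_case <- function(copy) {
    mk_read(soft5 = substr(copy, 1, 9),
            mapped_seq = paste0(substr(copy, 10, 16), rand_dna(60)),
            blocks = cbind(50L, 117L))
  }
  # 3 spread mismatches: 13*2 - 3*3 = 17 -> validated exactly at threshold
  r3 <- make_case(mut(suffix, c(4, 8, 12)))
  s3 <- classify_five_prime(r3, adapter)
  expect_equal(s3$score, 17)
  expect_equal(s3$state, "validated")
  # 4 spread mismatches -> below threshold -> uncertain
  r4 <- make_case(mut(suffix, c(4, 6, 8, 12)))
  s4 <- classify_five_prime(r4, adapter)
  expect_lt(s4$score, 17)
  expect_equal(s4$state, "uncertain")
  # both scores agree with the independent DP oracle on the exact targets
  t3 <- paste0(r3$soft5, substr(r3$mapped_seq, 1, 31))
  t4 <- paste0(r4$soft5, substr(r4$mapped_seq, 1, 31))
  expect_equal(s3$score, bs_score(suffix, t3))
  expect_equal(s4$score, bs_score(suffix, t4))
})

test_that("genomic_adapter_homology needs more than three matching bases", {
  adapter <- "ACGCTCTTCCGATCTGTTGCAGGCAGC"
  base <- strrep("C", 50)
  # plant the adapter's last 6 bases immediately upstream of pos 30
  seq6 <- paste0(substr(base, 1, 24), "GGCAGC", substr(base, 31, 50))
  g6 <- genome_model(seq6, circular = FALSE)
  expect_true(genomic_adapter_homology(g6, 30L, "+", adapter))
  # exactly 3 matching bases is not enough ("more than three")
  seq3 <- paste0(substr(base, 1, 24), "GGTAGC", substr(base, 31, 50))
  g3 <- genome_model(seq3, circular = FALSE)
  expect_false(genomic_adapter_homology(g3, 30L, "+", adapter))
})

test_that("homology flags match an exhaustive suffix-scan oracle", {
  g <- random_genome(600, seed = 33)
  adapter <- "ACGCTCTTCCGATCTGTTGCAGGCAGC"
  pos <- 30:580
  got <- genomic_adapter_homology(g, pos, "+", adapter)
  asuf <- strsplit(adapter, "")[[1]]
  oracle <- vapply(pos, function(p) {
    k <- 0
    while (k < 20 &&
           substr(g$sequence, p - k, p - k) ==
             asuf[length(asuf) - k]) k <- k + 1
    k > 3
  }, logical(1))
  expect_identical(got, oracle)
})
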