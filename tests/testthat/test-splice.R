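spliced_read <- function(id, intron, platform = "cdna", strand = "+",
                         span = c(100L, 400L), genome = NULL) {
  mk_read(id, platform = platform, strand = strand,
          blocks = cbind(start = c(span[1], intron[2]),
                         end = c(intron[1], span[2])),
          genome = genome)
}

test_that("extract_junctions counts inter-block gaps per platform", {
  r1 <- spliced_read("a", c(200L, 260L))
  r2 <- spliced_read("b", c(200L, 260L))
  jx <- extract_junctions(dplyr::bind_rows(r1, r2))
  expect_equal(nrow(jx), 1L)
  expect_equal(jx$support_cdna, 2L)
  expect_equal(jx$intron_start, 200L)
  expect_equal(jx$intron_end, 260L)

  # a gap below the minimum intron length is alignment noise
  tiny <- spliced_read("c", c(200L, 203L))
  expect_equal(nrow(extract_junctions(tiny)), 0L)

  # gapless input
  expect_equal(nrow(extract_junctions(mk_read("d"))), 0L)
})

test_that("accept_junctions requires GT..AG consensus plus support", {
  set.seed(71)
  chars <- sample(c("A", "C"), 600, replace = TRUE)
  chars[201:202] <- c("G", "T")           # donor (0-based 200)
  chars[259:260] <- c("A", "G")           # acceptor (0-based 258-259)
  g <- genome_model(paste(chars, collapse = ""), circular = FALSE)

  two <- extract_junctions(dplyr::bind_rows(
    spliced_read("a", c(200L, 260L)), spliced_read("b", c(200L, 260L))
  ))
  acc <- accept_junctions(two, g)
  expect_true(acc$canonical)
  expect_true(acc$accepted)

  # one cDNA read alone is not enough...
  one <- extract_junctions(spliced_read("a", c(200L, 260L)))
  expect_false(accept_junctions(one, g)$accepted)
  # ...unless a dRNA read confirms it
  dr <- extract_junctions(dplyr::bind_rows(
    spliced_read("a", c(200L, 260L)),
    spliced_read("d", c(200L, 260L), platform = "drna")
  ))
  expect_true(accept_junctions(dr, g)$accepted)
  # ...or it is on the external confirmation list
  conf <- tibble::tibble(intron_start = 200L, intron_end = 260L,
                         strand = "+")
  expect_true(accept_junctions(one, g, confirmed = conf)$accepted)

  # non-canonical junctions are rejected regardless of support
  chars2 <- chars; chars2[201:202] <- c("C", "C")
  g2 <- genome_model(paste(chars2, collapse = ""), circular = FALSE)
  many <- extract_junctions(dplyr::bind_rows(lapply(1:50, function(i) {
    spliced_read(paste0("r", i), c(200L, 260L))
  })))
  acc2 <- accept_junctions(many, g2)
  expect_false(acc2$canonical)
  expect_false(acc2$accepted)
})

test_that("minus-strand consensus reads GT..AG on the sense strand", {
  # sense GT..AG on '-' means forward CT..AC: acceptor complement at the
  # left edge, donor complement at the right edge
  chars <- rep("A", 600)
  chars[201:202] <- c("C", "T")
  chars[259:260] <- c("A", "C")
  g <- genome_model(paste(chars, collapse = ""), circular = FALSE)
  jx <- extract_junctions(dplyr::bind_rows(
    spliced_read("a", c(200L, 260L), strand = "-"),
    spliced_read("b", c(200L, 260L), strand = "-")
  ))
  expect_true(accept_junctions(jx, g)$accepted)
})

test_that("acceptance is monotone non-decreasing in read support", {
  chars <- rep("C", 600)
  chars[201:202] <- c("G", "T"); chars[259:260] <- c("A", "G")
  g <- genome_model(paste(chars, collapse = ""), circular = FALSE)
  n_accepted <- vapply(c(1L, 2L, 5L), function(n) {
    jx <- extract_junctions(dplyr::bind_rows(lapply(seq_len(n), function(i) {
      spliced_read(paste0("r", i), c(200L, 260L))
    })))
    sum(accept_junctions(jx, g)$accepted)
  }, integer(1))
  expect_true(all(diff(n_accepted) >= 0))
})
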