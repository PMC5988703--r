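mk_counts <- function(pos, n, strand = "+") {
  tibble::tibble(pos = as.integer(pos), strand = strand, n = as.integer(n))
}

test_that("collect_validated_starts counts only validated 5' ends", {
  g <- random_genome(2000, seed = 51)
  reads <- dplyr::bind_rows(lapply(1:20, function(i) {
    mk_read(paste0("r", i), blocks = cbind(500L, 900L), genome = g)
  }))
  st <- tibble::tibble(
    read_id = reads$read_id,
    state = rep(c("validated", "uncertain"), c(15, 5)),
    score = 20, end_rule_hit = FALSE, terminal_pos = NA_integer_
  )
  out <- collect_validated_starts(reads, st)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n, 15L)
  expect_equal(out$pos, 500L)
  # terminal_pos takes precedence when the end rule fixed the base
  st$end_rule_hit[1] <- TRUE; st$terminal_pos[1] <- 502L
  out2 <- collect_validated_starts(reads, st)
  expect_setequal(out2$pos, c(500L, 502L))
  # empty input
  empty <- collect_validated_starts(reads[0, ], st[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("find_local_maxima matches an exhaustive window-scan oracle", {
  expect_equal(find_local_maxima(mk_counts(100, 7), 1000)$pos, 100L)
  # plateau of equal adjacent counts: the 5'-most wins
  plat <- mk_counts(c(100, 101), c(5, 5))
  expect_equal(find_local_maxima(plat, 1000)$pos, 100L)
  plat_m <- mk_counts(c(100, 101), c(5, 5), strand = "-")
  expect_equal(find_local_maxima(plat_m, 1000)$pos, 101L)

  set.seed(52)
  for (k in 1:20) {
    npos <- sample(5:40, 1)
    cs <- mk_counts(sample(0:499, npos), sample(1:10, npos, replace = TRUE))
    got <- find_local_maxima(cs, 500L, window = 50L, circular = TRUE)
    # oracle, pass 1: a position beats every count in its circular +/-50
    # window; pass 2: among tied candidates in one window only the
    # 5'-most survives
    ismax <- vapply(seq_len(nrow(cs)), function(i) {
      d <- pmin(abs(cs$pos - cs$pos[i]), 500L - abs(cs$pos - cs$pos[i]))
      all(cs$n[d <= 50L] <= cs$n[i])
    }, logical(1))
    ok <- ismax
    for (i in which(ismax)) {
      up <- ((cs$pos[i] - cs$pos) %% 500L)
      if (any(ismax & cs$n == cs$n[i] & up > 0L & up <= 50L)) ok[i] <- FALSE
    }
    expect_setequal(got$pos, cs$pos[ok])
  }
})

test_that("poisson_tail matches a log-space series oracle and is monotone", {
  series_tail <- function(k0, lam) {
    if (k0 == 0) return(1)
    if (lam == 0) return(0)
    lt <- k0 * log(lam) - lam - lgamma(k0 + 1)
    terms <- numeric(0)
    j <- 0; t <- lt
    repeat {
      terms <- c(terms, t)
      j <- j + 1
      t <- t + log(lam) - log(k0 + j)
      if (t < max(terms) - 60 || j > 3000) break
    }
    m <- max(terms)
    exp(m) * sum(exp(terms - m))
  }
  expect_equal(poisson_tail(0, 5), 1)
  expect_equal(poisson_tail(3, 0), 0)
  expect_equal(poisson_tail(20, 1), series_tail(20, 1), tolerance = 1e-12)
  for (lam in c(0.01, 0.5, 2, 10, 50)) {
    for (k0 in c(1, 2, 5, 20, 80, 200)) {
      o <- series_tail(k0, lam)
      p <- poisson_tail(k0, lam)
      if (o > 1e-290) {
        expect_equal(p, o, tolerance = 1e-12,
                     info = sprintf("k0=%d lam=%g", k0, lam))
      } else {
        expect_true(p <= 1e-290)
      }
    }
  }
  # strictly decreasing in k0, increasing in lam
  expect_true(all(diff(poisson_tail(1:50, 3)) < 0))
  expect_true(all(diff(poisson_tail(5, c(0.5, 1, 2, 4, 8))) > 0))
})

test_that("call_tss applies the Bonferroni-corrected Poisson test", {
  # the published correction: 0.05 / 101 / 119 = 4.16e-6
  expect_equal(signif(bonferroni_threshold(0.05, 101, 119), 3), 4.16e-6)

  # a flat landscape: k0 equal to lambda is never significant
  flat <- tibble::tibble(
    pos = 100L, strand = "+", k0 = 3L, lambda = 3,
    window_counts = list(rep(3L, 101))
  )
  out <- call_tss(flat, genome_length = 1000L)
  expect_false(out$called)

  # a sharp spike over low background is called
  wc <- integer(101); wc[51] <- 40L; wc[c(20, 80)] <- 1L
  spike <- tibble::tibble(pos = 500L, strand = "+", k0 = 40L,
                          lambda = sum(wc) / 101, window_counts = list(wc))
  out2 <- call_tss(spike, genome_length = 1000L,
                   ref = tibble::tibble(pos = 498L, strand = "+"))
  expect_true(out2$called)
  expect_false(out2$novel)   # reference TSS within 5 nt
  out3 <- call_tss(spike, genome_length = 1000L,
                   ref = tibble::tibble(pos = 480L, strand = "+"))
  expect_true(out3$novel)

  # no candidates: empty result, no division by zero
  expect_equal(nrow(call_tss(flat[0, ], genome_length = 1000L)), 0L)
})

test_that("start_dispersion is 0 for perfectly sharp and uniform landscapes", {
  sharp <- integer(101); sharp[51] <- 50L
  unif <- rep(2L, 101)
  cands <- tibble::tibble(
    pos = c(10L, 20L), strand = "+", k0 = c(50L, 2L),
    lambda = 1, window_counts = list(sharp, unif),
    class = c("E", "L")
  )
  disp <- start_dispersion(cands)
  expect_equal(disp$sd[disp$class == "E"], 0)
  expect_equal(disp$sd[disp$class == "L"], 0)
})
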