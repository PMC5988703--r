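# Shared model/tail/overlap builders and oracles used by the
# per-module tests and the acceptance suite.

# Hand-built world: a circular 3000 bp genome, gene ORF1 '+' spanning
# [500, 1500) with ORF [600, 1200), and (where needed) ORF2 '+' spanning
# [1600, 2400) with ORF [1700, 2300) or ORFB '-' on the same interval.

cls_genome <- local({
  ch <- rep("C", 3000)
  ch[601:603] <- c("A", "T", "G")      # ORF1 start (0-based 600)
  ch[904:906] <- c("A", "T", "G")      # in-frame internal ATG (0-based 903)
  ch[1198:1200] <- c("T", "A", "A")    # ORF1 stop (0-based 1197..1199)
  ch[1701:1703] <- c("A", "T", "G")
  ch[2298:2300] <- c("T", "A", "A")
  genome_model(paste(ch, collapse = ""), circular = TRUE)
})

one_gene_ref <- structure(list(
  transcripts = tibble::tibble(id = "ORF1", strand = "+", start = 500L,
                               end = 1500L, tss = 500L, tes = 1499L),
  orfs = tibble::tibble(id = "ORF1", strand = "+", start = 600L, end = 1200L)
), class = "reference_catalog")

two_gene_ref <- structure(list(
  transcripts = tibble::tibble(
    id = c("ORF1", "ORF2"), strand = "+", start = c(500L, 1600L),
    end = c(1500L, 2400L), tss = c(500L, 1600L), tes = c(1499L, 2399L)
  ),
  orfs = tibble::tibble(id = c("ORF1", "ORF2"), strand = "+",
                        start = c(600L, 1700L), end = c(1200L, 2300L))
), class = "reference_catalog")

opposed_ref <- structure(list(
  transcripts = tibble::tibble(
    id = c("ORF1", "ORFB"), strand = c("+", "-"), start = c(500L, 1600L),
    end = c(1500L, 2400L), tss = c(500L, 2399L), tes = c(1499L, 1600L)
  ),
  orfs = tibble::tibble(id = c("ORF1", "ORFB"), strand = c("+", "-"),
                        start = c(600L, 1700L), end = c(1200L, 2300L))
), class = "reference_catalog")

mk_model <- function(tss, tes, strand = "+", introns = NULL,
                     complex = FALSE, tss_status = "called", id = "TX0001") {
  s <- if (strand == "+") tss else tes
  e <- if (strand == "+") tes + 1L else tss + 1L
  introns <- if (is.null(introns)) cbind(start = integer(0), end = integer(0))
             else introns
  tibble::tibble(
    id = id, strand = strand, tss = as.integer(tss), tes = as.integer(tes),
    tss_status = tss_status, span_start = as.integer(s),
    span_end = as.integer(e),
    exons = list(cbind(start = s, end = e)), chain = list(introns),
    support = 10L, complex = complex
  )
}

cat_of <- function(m, ref = one_gene_ref) {
  classify_transcripts(m, ref, cls_genome)
}

mk_tails <- function(n_cdna, n_drna = 0L, pos = 900L, strand = "+",
                     false_primed = FALSE, double = FALSE) {
  n <- n_cdna + n_drna
  tibble::tibble(
    read_id = sprintf("t%03d", seq_len(n)),
    platform = rep(c("cdna", "drna"), c(n_cdna, n_drna)),
    strand = strand, three_prime_pos = as.integer(pos),
    tail5_kind = NA_character_, tail5_len = NA_integer_,
    tail3_kind = "polyA", tail3_len = 20L,
    double_tail = double, false_primed = false_primed
  )
}

mk_tx <- function(id, strand, span, len_genome = 1000L) {
  # span: forward 0-based half-open (may extend past len for wrap)
  tss <- if (strand == "+") span[1] else span[2] - 1L
  tes <- if (strand == "+") span[2] - 1L else span[1]
  tibble::tibble(id = id, strand = strand,
                 span_start = as.integer(span[1]),
                 span_end = as.integer(span[2]),
                 tss = as.integer(tss), tes = as.integer(tes),
                 tss_status = "called")
}

# independent oracle over explicit position sets (circular membership)
oracle_overlap <- function(a, b, len) {
  posset <- function(tx) (tx$span_start:(tx$span_end - 1L)) %% len
  ia <- posset(a); ib <- posset(b)
  ov <- intersect(ia, ib)
  if (length(ov) == 0L) return(NULL)
  if (a$strand == b$strand) return(list(cls = "parallel", len = length(ov)))
  if (all(ia %in% ib) || all(ib %in% ia)) {
    inner <- if (all(ib %in% ia)) b else a
    outer <- if (all(ib %in% ia)) a else b
    mid <- inner$span_start + (inner$span_end - inner$span_start) %/% 2
    mid <- mid %% len
    cd <- function(x, y) min(abs(x - y), len - abs(x - y))
    cls <- if (cd(mid, outer$tes %% len) <= cd(mid, outer$tss %% len))
      "convergent" else "divergent"
    return(list(cls = cls, len = length(ov)))
  }
  cls <- if ((a$tes %% len) %in% ib && (b$tes %% len) %in% ia)
    "convergent" else "divergent"
  list(cls = cls, len = length(ov))
}
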