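# Transcript assembly and classification against a reference catalog.
#
# Internal coordinates are 0-based; a model's forward-strand span is
# [span_start, span_end). tss/tes are strand-aware base positions.

mode_int <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  as.integer(names(tb)[1])
}

# does the forward-strand span [s, e) fully contain the interval [a, b)?
span_contains <- function(s, e, a, b) a >= s & b <= e

#' Does a span cover at least two opposite-orientation reference transcripts?
#'
#' The defining geometry of a complex transcript: the read (or model) span
#' fully contains two or more previously annotated transcripts of opposite
#' orientations.
#'
#' @param span_start,span_end Forward-strand 0-based half-open span.
#' @param ref A `reference_catalog`.
#' @param tol Containment slack in nt (10), consistent with the site
#'   matching tolerance used elsewhere.
#' @return Logical scalar.
#' @export
is_complex_span <- function(span_start, span_end, ref, tol = 10L) {
  tx <- ref$transcripts
  inside <- span_contains(span_start - tol, span_end + tol, tx$start, tx$end)
  any(inside & tx$strand == "+") && any(inside & tx$strand == "-")
}

#' Count complete same-strand reference ORFs in a model span
#'
#' An ORF counts when it is fully contained in the model's forward-strand
#' span, lies on the model's strand, and is not interrupted by one of the
#' model's introns. Two or more complete same-strand ORFs make a
#' transcript polycistronic.
#'
#' @param span_start,span_end,strand Model span and strand.
#' @param ref A `reference_catalog`.
#' @param introns Optional matrix of intron intervals (cols start, end).
#' @return Integer count.
#' @export
count_cistrons <- function(span_start, span_end, strand, ref, introns = NULL) {
  orf <- ref$orfs[ref$orfs$strand == strand, , drop = FALSE]
  if (nrow(orf) == 0L) return(0L)
  inside <- span_contains(span_start, span_end, orf$start, orf$end)
  if (!is.null(introns) && nrow(introns) > 0L) {
    cut <- vapply(seq_len(nrow(orf)), function(i) {
      any(introns[, 1] < orf$end[i] & introns[, 2] > orf$start[i])
    }, logical(1))
    inside <- inside & !cut
  }
  sum(inside)
}

# nearest called site within tol (strand-aware circular distance),
# preferring higher support; returns NA when none
match_site <- function(pos, strand, calls, support_col, tol, len, circular) {
  cs <- calls[calls$strand == strand, , drop = FALSE]
  if (nrow(cs) == 0L) return(NA_integer_)
  d <- circ_dist(cs$pos, pos, len, circular)
  ok <- which(d <= tol)
  if (length(ok) == 0L) return(NA_integer_)
  ok <- ok[order(-cs[[support_col]][ok], d[ok], cs$pos[ok])]
  cs$pos[ok[1]]
}

# junction-chain key for a read/model: accepted introns it contains
read_chain <- function(blocks, accepted, min_intron = 20L) {
  if (nrow(blocks) < 2L) return(character(0))
  gs <- blocks[-nrow(blocks), "end"]
  ge <- blocks[-1L, "start"]
  keep <- (ge - gs) >= min_intron
  gs <- gs[keep]; ge <- ge[keep]
  if (length(gs) == 0L) return(character(0))
  key <- paste0(gs, "-", ge)
  akey <- paste0(accepted$intron_start, "-", accepted$intron_end)
  sort(key[key %in% akey])
}

# exon matrix for a forward span minus a set of introns
span_exons <- function(span_start, span_end, introns = NULL) {
  if (is.null(introns) || nrow(introns) == 0L) {
    return(cbind(start = span_start, end = span_end))
  }
  introns <- introns[order(introns[, 1]), , drop = FALSE]
  starts <- c(span_start, introns[, 2])
  ends <- c(introns[, 1], span_end)
  cbind(start = starts, end = ends)
}

#' Assemble transcript models from read-level evidence
#'
#' cDNA reads are grouped by strand, accepted-junction chain, and their
#' nearest called TSS and TES (within `tol` nt; the highest-supported call
#' wins when several are in range). Reads whose 3' end matches no called
#' TES are discarded (no polyadenylation evidence); validated reads
#' matching no called TSS leave the group's TSS undetermined.
#' Undetermined-TSS groups are retained only when their span is
#' polycistronic; other such groups are treated as degradation / false-5'
#' products. Reads whose span covers two opposite-orientation reference
#' transcripts are routed to the complex-transcript path
#' ([classify_complex_reads()]), where double-tailed reads are admissible.
#'
#' @param reads Read table (cDNA reads are used for models; dRNA reads
#'   contribute TES/junction evidence upstream, not model membership).
#' @param statuses 5' statuses from [classify_five_prime()].
#' @param tails Tail table from [detect_tails()].
#' @param tss_calls Called TSS rows (from [call_tss()], `called` only).
#' @param tes_calls Called TES rows from [call_tes()].
#' @param junctions Accepted junction rows from [accept_junctions()].
#' @param ref A `reference_catalog`.
#' @param genome A [genome_model()].
#' @param tol Site matching tolerance in nt (10).
#' @param min_support Read support required for a standard model (2).
#' @param min_support_multi Support for complex/polycistronic models (1).
#' @param horizon Upstream search horizon for imputed complex TSSs (5000).
#' @param min_intron Minimum intron length (20).
#' @return Tibble of uncategorized models: `id`, `strand`, `tss`, `tes`,
#'   `tss_status`, `span_start`, `span_end`, `exons` (list), `chain`
#'   (list), `support`, `complex`.
#' @export
assemble_models <- function(reads, statuses, tails, tss_calls, tes_calls,
                            junctions, ref, genome, tol = 10L,
                            min_support = 2L, min_support_multi = 1L,
                            horizon = 5000L, min_intron = 20L) {
  len <- genome$length; circ <- genome$circular
  acc <- junctions[junctions$accepted, , drop = FALSE]
  cdna <- reads[reads$platform == "cdna", , drop = FALSE]
  if (nrow(cdna) == 0L) return(empty_models())
  df <- dplyr::left_join(cdna, statuses, by = "read_id")
  df <- dplyr::left_join(
    df,
    dplyr::select(tails, "read_id", "tail3_kind", "double_tail",
                  "false_primed"),
    by = "read_id"
  )
  spans <- t(vapply(df$blocks, read_span, integer(2)))
  df$span_start <- spans[, 1]; df$span_end <- spans[, 2]
  df$is_complex <- vapply(seq_len(nrow(df)), function(i) {
    is_complex_span(df$span_start[i], df$span_end[i], ref, tol)
  }, logical(1))

  complex_models <- classify_complex_reads(
    df[df$is_complex, , drop = FALSE], tss_calls, tes_calls, ref, genome,
    tol = tol, horizon = horizon, min_support = min_support_multi
  )

  std <- df[!df$is_complex & !df$double_tail, , drop = FALSE]
  if (nrow(std) > 0L) {
    std$tes_m <- vapply(seq_len(nrow(std)), function(i) {
      match_site(std$three_prime_pos[i], std$strand[i], tes_calls,
                 "support_cdna", tol, len, circ)
    }, integer(1))
    std <- std[!is.na(std$tes_m), , drop = FALSE]
  }
  std_models <- NULL
  if (nrow(std) > 0L) {
    start_pos <- ifelse(std$end_rule_hit & !is.na(std$terminal_pos),
                        std$terminal_pos, std$five_prime_pos)
    std$tss_m <- vapply(seq_len(nrow(std)), function(i) {
      if (is.na(std$state[i]) || std$state[i] != "validated") return(NA_integer_)
      match_site(start_pos[i], std$strand[i], tss_calls, "k0", tol, len, circ)
    }, integer(1))
    std$chain_key <- vapply(std$blocks, function(b) {
      paste(read_chain(b, acc, min_intron), collapse = "|")
    }, character(1))
    std$tss_key <- ifelse(is.na(std$tss_m), -1L, std$tss_m)
    grp <- dplyr::group_by(std, .data$strand, .data$tss_key, .data$tes_m,
                           .data$chain_key)
    std_models <- dplyr::summarise(
      grp,
      support = dplyr::n(),
      start_mode = mode_int(.data$span_start),
      end_mode = mode_int(.data$span_end),
      .groups = "drop"
    )
    std_models <- dplyr::rename(std_models, tes = "tes_m")
  }

  rows <- list()
  if (!is.null(std_models) && nrow(std_models) > 0L) {
    for (i in seq_len(nrow(std_models))) {
      m <- std_models[i, ]
      tss <- if (m$tss_key >= 0L) m$tss_key else NA_integer_
      if (m$strand == "+") {
        s <- if (!is.na(tss)) tss else m$start_mode
        e <- m$tes + 1L
      } else {
        s <- m$tes
        e <- if (!is.na(tss)) tss + 1L else m$end_mode
      }
      if (e <= s) next
      introns <- chain_introns(m$chain_key)
      poly <- count_cistrons(s, e, m$strand, ref, introns) >= 2L
      if (is.na(tss)) {
        # undetermined 5' end: keep only polycistronic geometry
        if (!poly || m$support < min_support_multi) next
      } else if (m$support < min_support) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        strand = m$strand, tss = tss, tes = m$tes,
        tss_status = if (is.na(tss)) "undetermined" else "called",
        span_start = s, span_end = e,
        exons = list(span_exons(s, e, introns)),
        chain = list(introns),
        support = m$support, complex = FALSE
      )
    }
  }
  out <- dplyr::bind_rows(c(rows, list(complex_models)))
  if (nrow(out) == 0L) return(empty_models())
  out <- dplyr::arrange(out, .data$span_start, .data$span_end, .data$strand)
  out$id <- sprintf("TX%04d", seq_len(nrow(out)))
  dplyr::relocate(out, "id")
}

empty_models <- function() {
  tibble::tibble(
    id = character(), strand = character(), tss = integer(), tes = integer(),
    tss_status = character(), span_start = integer(), span_end = integer(),
    exons = list(), chain = list(), support = integer(), complex = logical()
  )
}

chain_introns <- function(chain_key) {
  if (is.na(chain_key) || chain_key == "") {
    return(cbind(start = integer(0), end = integer(0)))
  }
  parts <- strsplit(strsplit(chain_key, "|", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  colnames(m) <- c("start", "end")
  m[order(m[, 1]), , drop = FALSE]
}

#' Build complex-transcript models from spanning reads
#'
#' Reads whose span covers two or more opposite-orientation reference
#' transcripts are complex-transcript evidence. Their orientation is taken
#' from the poly(A) tail that passed the TES criteria (the read's 3' end
#' must match a called TES); double-tailed reads are admissible here.
#' When no validated 5' end supports the group, the TSS is imputed to the
#' closest upstream annotated same-strand TSS within `horizon` nt
#' (circular-aware) and the model is flagged `tss_status = "undetermined"`.
#'
#' @param df Read rows (already joined with statuses and tails; needs
#'   `span_start`, `span_end`, `three_prime_pos`, `five_prime_pos`,
#'   `strand`, `state`, `end_rule_hit`, `terminal_pos`, `tail3_kind`).
#' @inheritParams assemble_models
#' @param min_support Support threshold for complex models (1).
#' @return Model tibble rows (see [assemble_models()]).
#' @export
classify_complex_reads <- function(df, tss_calls, tes_calls, ref, genome,
                                   tol = 10L, horizon = 5000L,
                                   min_support = 1L) {
  if (nrow(df) == 0L) return(empty_models())
  len <- genome$length; circ <- genome$circular
  # orientation = strand of the tail that passed TES criteria
  df$tes_m <- vapply(seq_len(nrow(df)), function(i) {
    if (is.na(df$tail3_kind[i])) return(NA_integer_)
    match_site(df$three_prime_pos[i], df$strand[i], tes_calls,
               "support_cdna", tol, len, circ)
  }, integer(1))
  df <- df[!is.na(df$tes_m), , drop = FALSE]
  if (nrow(df) == 0L) return(empty_models())
  grp <- dplyr::group_by(df, .data$strand, .data$tes_m)
  gm <- dplyr::summarise(grp, support = dplyr::n(), .groups = "drop")
  rows <- list()
  for (i in seq_len(nrow(gm))) {
    g <- df[df$strand == gm$strand[i] & df$tes_m == gm$tes_m[i], , drop = FALSE]
    if (nrow(g) < min_support) next
    strand <- gm$strand[i]; tes <- gm$tes_m[i]
    start_pos <- ifelse(g$end_rule_hit & !is.na(g$terminal_pos),
                        g$terminal_pos, g$five_prime_pos)
    vstate <- !is.na(g$state) & g$state == "validated"
    tss <- NA_integer_
    if (any(vstate)) {
      tss <- match_site(mode_int(start_pos[vstate]), strand, tss_calls,
                        "k0", tol, len, circ)
    }
    status <- "called"
    five_most <- if (strand == "+") min(g$span_start) else max(g$span_end) - 1L
    if (is.na(tss)) {
      status <- "undetermined"
      tss <- upstream_annotated_tss(five_most, strand, ref, len, circ, horizon)
    }
    if (strand == "+") {
      s <- if (!is.na(tss)) tss else min(g$span_start)
      e <- tes + 1L
    } else {
      s <- tes
      e <- if (!is.na(tss)) tss + 1L else max(g$span_end)
    }
    if (e <= s) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      strand = strand, tss = tss, tes = tes, tss_status = status,
      span_start = s, span_end = e,
      exons = list(span_exons(s, e)), chain = list(chain_introns("")),
      support = nrow(g), complex = TRUE
    )
  }
  dplyr::bind_rows(rows)
}

# closest annotated same-strand TSS 5'-ward of pos within horizon
upstream_annotated_tss <- function(pos, strand, ref, len, circular, horizon) {
  tx <- ref$transcripts[ref$transcripts$strand == strand, , drop = FALSE]
  if (nrow(tx) == 0L) return(NA_integer_)
  d <- if (strand == "+") pos - tx$tss else tx$tss - pos
  if (circular) d <- wrap_pos(d, len)
  ok <- which(d >= 0 & d <= horizon)
  if (length(ok) == 0L) return(NA_integer_)
  tx$tss[ok[which.min(d[ok])]]
}

#' Classify assembled models against the reference catalog
#'
#' Applies the category rules in strict priority order:
#' complex > polycistronic > splice isoform (SP) > 5'-truncated coding
#' ("0.5") > 3'-truncated non-coding (TR) > length isoforms (L/S/AT) >
#' known. Length isoforms require a `> 10` nt difference (strictly) at one
#' end with the other end and junction chain shared with the host; "0.5"
#' requires the model TSS inside the host ORF plus an in-frame ATG..stop;
#' TR requires a TES 5'-ward of the host ORF stop with no complete ORF.
#' Models with no same-strand overlapping reference transcript become
#' `candidate_novel` (flagged for manual review). Names follow the
#' host-based convention (`-L`, `-S`, `-AT`, `.5`, `-TR<n>`, `-SP<n>`,
#' `-C`; polycistronic names join the constituent gene ids) and are made
#' unique with ordinal suffixes.
#'
#' @param models Model tibble from [assemble_models()].
#' @param ref A `reference_catalog`.
#' @param genome A [genome_model()].
#' @param tol End matching tolerance in nt (10).
#' @param iso_min Strict isoform threshold in nt (10: differences must
#'   exceed this).
#' @return `models` plus `category`, `host_gene`, `cistron_count`, `name`.
#' @export
classify_transcripts <- function(models, ref, genome, tol = 10L,
                                 iso_min = 10L) {
  n <- nrow(models)
  category <- character(n); host <- rep(NA_character_, n)
  cistrons <- integer(n); raw_name <- character(n)
  tx <- ref$transcripts; orfs <- ref$orfs

  for (i in seq_len(n)) {
    m <- models[i, ]
    introns <- m$chain[[1]]
    cc <- count_cistrons(m$span_start, m$span_end, m$strand, ref, introns)
    cistrons[i] <- max(1L, cc)
    same <- tx[tx$strand == m$strand, , drop = FALSE]
    ov <- pmin(same$end, m$span_end) - pmax(same$start, m$span_start)
    hosts <- same[ov > 0, , drop = FALSE]
    hosts <- hosts[order(-(ov[ov > 0])), , drop = FALSE]

    if (isTRUE(m$complex)) {
      category[i] <- "complex"
      inside <- same[span_contains(m$span_start, m$span_end, same$start, same$end), ,
                     drop = FALSE]
      pick <- if (nrow(inside) > 0L) inside else hosts
      if (nrow(pick) > 0L) {
        ord <- if (m$strand == "+") order(pick$start) else order(-pick$end)
        host[i] <- pick$id[ord[1]]
      }
      raw_name[i] <- paste0(ifelse(is.na(host[i]), m$id, host[i]), "-C")
      next
    }
    if (cc >= 2L) {
      category[i] <- "polycistronic"
      inside <- same[span_contains(m$span_start, m$span_end, same$start, same$end), ,
                     drop = FALSE]
      inside <- inside[order(inside$start), , drop = FALSE]
      host[i] <- if (nrow(inside) > 0L) inside$id[1] else NA_character_
      raw_name[i] <- join_gene_ids(inside$id)
      next
    }
    if (nrow(hosts) == 0L) {
      category[i] <- "candidate_novel"
      raw_name[i] <- m$id
      next
    }
    h1 <- hosts[1, ]

    # SP: accepted junction absent from the (unspliced) host chain
    if (nrow(introns) > 0L) {
      category[i] <- "SP"
      host[i] <- h1$id
      raw_name[i] <- paste0(h1$id, "-SP")
      next
    }
    # 0.5: TSS inside host ORF + in-frame ATG running to the host stop
    fiv <- find_truncated_coding_host(m, hosts, orfs, genome)
    if (!is.na(fiv)) {
      category[i] <- "coding_truncated_0_5"
      host[i] <- fiv
      raw_name[i] <- paste0(fiv, ".5")
      next
    }
    # TR: TES 5'-ward of the host ORF stop, no complete ORF
    tr <- find_truncated_noncoding_host(m, hosts, orfs)
    if (!is.na(tr)) {
      category[i] <- "TR_noncoding"
      host[i] <- tr
      raw_name[i] <- paste0(tr, "-TR")
      next
    }
    # L/S: host shares the TES (and chain); strict >10 nt 5' difference
    ls_done <- FALSE
    if (!is.na(m$tss)) {
      for (j in seq_len(nrow(hosts))) {
        h <- hosts[j, ]
        if (circ_dist(h$tes, m$tes, genome$length, genome$circular) > tol) next
        d5 <- if (m$strand == "+") m$tss - h$tss else h$tss - m$tss
        if (d5 < -iso_min) {
          category[i] <- "L"; host[i] <- h$id
          raw_name[i] <- paste0(h$id, "-L"); ls_done <- TRUE
        } else if (d5 > iso_min) {
          category[i] <- "S"; host[i] <- h$id
          raw_name[i] <- paste0(h$id, "-S"); ls_done <- TRUE
        }
        if (ls_done) break
      }
    }
    if (ls_done) next
    # AT: host shares the TSS; strict >10 nt 3' difference
    at_done <- FALSE
    if (!is.na(m$tss)) {
      for (j in seq_len(nrow(hosts))) {
        h <- hosts[j, ]
        if (circ_dist(h$tss, m$tss, genome$length, genome$circular) > tol) next
        if (circ_dist(h$tes, m$tes, genome$length, genome$circular) > iso_min) {
          category[i] <- "AT"; host[i] <- h$id
          raw_name[i] <- paste0(h$id, "-AT"); at_done <- TRUE
        }
        if (at_done) break
      }
    }
    if (at_done) next
    # known: both ends within tol of a host
    kn <- NA_character_
    if (!is.na(m$tss)) {
      for (j in seq_len(nrow(hosts))) {
        h <- hosts[j, ]
        if (circ_dist(h$tss, m$tss, genome$length, genome$circular) <= tol &&
            circ_dist(h$tes, m$tes, genome$length, genome$circular) <= tol) {
          kn <- h$id; break
        }
      }
    }
    if (!is.na(kn)) {
      category[i] <- "known"; host[i] <- kn; raw_name[i] <- kn
    } else {
      category[i] <- "candidate_novel"; raw_name[i] <- m$id
    }
  }

  models$category <- category
  models$host_gene <- host
  models$cistron_count <- cistrons
  models$name <- uniquify_names(raw_name, category)
  models
}

join_gene_ids <- function(ids) {
  if (length(ids) == 0L) return("polycistron")
  m <- regmatches(ids, regexec("^([A-Za-z]+)([0-9]+)$", ids))
  pref <- vapply(m, function(x) if (length(x) == 3L) x[2] else "", character(1))
  if (all(pref == pref[1]) && pref[1] != "") {
    nums <- vapply(m, function(x) x[3], character(1))
    paste0(pref[1], paste(nums, collapse = "-"))
  } else {
    paste(ids, collapse = "-")
  }
}

# TR/SP always numbered; all names made injective with ordinal suffixes
uniquify_names <- function(raw, category) {
  out <- raw
  numbered <- category %in% c("TR_noncoding", "SP")
  for (nm in unique(raw[numbered])) {
    idx <- which(raw == nm & numbered)
    out[idx] <- paste0(nm, seq_along(idx))
  }
  dup <- duplicated(out) | duplicated(out, fromLast = TRUE)
  for (nm in unique(out[dup & !numbered])) {
    idx <- which(out == nm & !numbered)
    if (length(idx) > 1L) out[idx] <- paste0(nm, ".", seq_along(idx))
  }
  out
}

# find a host whose ORF contains the model TSS with an in-frame ATG..stop
find_truncated_coding_host <- function(m, hosts, orfs, genome) {
  if (is.na(m$tss)) return(NA_character_)
  for (j in seq_len(nrow(hosts))) {
    o <- orfs[orfs$id == hosts$id[j] & orfs$strand == m$strand, , drop = FALSE]
    if (nrow(o) == 0L) next
    o <- o[1, ]
    inside <- if (m$strand == "+") {
      m$tss > o$start && m$tss < o$end - 2L
    } else {
      m$tss < o$end - 1L && m$tss > o$start + 2L
    }
    if (!inside) next
    # model must reach the host stop
    reaches <- if (m$strand == "+") m$tes >= o$end - 1L else m$tes <= o$start
    if (!reaches) next
    if (has_inframe_atg(m$tss, o, m$strand, genome)) return(hosts$id[j])
  }
  NA_character_
}

has_inframe_atg <- function(tss, orf, strand, genome) {
  if (strand == "+") {
    # first in-frame codon start at or after the model 5' end
    k0 <- orf$start + 3L * ceiling((tss - orf$start) / 3)
    if (k0 > orf$end - 3L) return(FALSE)
    ks <- seq(k0, orf$end - 3L, by = 3L)
    for (k in ks) if (genome_window(genome, k, 0L, 2L, "+") == "ATG") return(TRUE)
  } else {
    sense_start <- orf$end - 1L
    k0 <- sense_start - 3L * ceiling((sense_start - tss) / 3)
    if (k0 < orf$start + 2L) return(FALSE)
    ks <- seq(k0, orf$start + 2L, by = -3L)
    for (k in ks) if (genome_window(genome, k, 0L, 2L, "-") == "ATG") return(TRUE)
  }
  FALSE
}

find_truncated_noncoding_host <- function(m, hosts, orfs) {
  for (j in seq_len(nrow(hosts))) {
    o <- orfs[orfs$id == hosts$id[j] & orfs$strand == m$strand, , drop = FALSE]
    if (nrow(o) == 0L) next
    o <- o[1, ]
    upstream_of_stop <- if (m$strand == "+") m$tes < o$end - 1L else m$tes > o$start
    complete <- span_contains(m$span_start, m$span_end, o$start, o$end)
    if (upstream_of_stop && !complete) return(hosts$id[j])
  }
  NA_character_
}
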