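---
title: "Methods: long-read transcript annotation on a circular viral genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read transcript annotation on a circular viral genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`viranno` annotates the transcriptome of a small circular viral genome
from coordinate-sorted long-read alignments (ONT cDNA and direct RNA),
using the read ends themselves — soft-clipped adapters and poly(A)
tails — as the primary evidence, and treating the platform's artefacts
as first-class objects with explicit filters. This vignette documents
the model behind each stage, the tunable parameters and their defaults,
the conventions chosen where the method left room, and what the built-in
simulator does and does not establish.

## Coordinates and topology

All internal coordinates are 0-based, half-open, on the forward genome
strand; 5′/3′ semantics are always strand-aware, and `genome_window()`
is the single primitive that turns (anchor, offsets, strand) into
sequence, wrapping across the origin on circular replicons. GFF3 output
converts to 1-based inclusive, BED12 to 0-based half-open; transcripts
crossing the origin are emitted as two-exon features flagged
`origin_spanning=true`. Only primary alignments are used and no mapping
quality filter is applied by default (`min_mapq = 0`), matching the
source workflow.

## 5′-end validation (cDNA only)

The library's strand-switching adapter is appended to every genuine
first-strand 5′ end, so a read whose 5′ soft clip does not end in
adapter sequence most likely acquired its 5′ end by template switching
at an adapter-homologous genomic locus or by non-specific priming. The
test: align the adapter's last 16 nt by Smith–Waterman (match +2,
mismatch −3, gap open −3, gap extension −2; a gap of length $L$ costs
$3 + 2(L-1)$; `N` never matches) against a window of −10..+30 nt around
the first mapped base. Score < 17 ⇒ the 5′ end is *uncertain*; such
reads still contribute TES and junction evidence but never TSS counts.

Conventions worth stating:

* **The window is taken from the read's own sequence** (clip suffix +
  mapped prefix), not the genome: the adapter is a library molecule on
  the cDNA, and basecalling errors live on the read. The genome
  alternative is available via `target_from = "genome"`.
* Only 10 clip bases are visible at negative offsets, so an intact
  adapter scores 20 (ten matches), comfortably above threshold, and a
  full 16-mer can reach the exact threshold of 17 only when it straddles
  the alignment junction.
* The exact 5′ terminal base is fixed when the adapter's last 4 nt end
  within offsets −2..+3 (a 5-nt allowance for homopolymer miscalls at
  the junction); candidate end offsets are tried in the fixed order
  0, −1, +1, −2, +2, +3, preferring the junction an intact adapter
  would produce. Ties between equal-scoring alignments resolve to the
  smallest target end coordinate.
* The adapter sequence is required configuration — kit adapters are
  proprietary, so no default is hard-coded; the simulator declares its
  own synthetic stand-in.

`genomic_adapter_homology()` separately flags loci where more than three
genomic bases immediately 5′-ward of a position match the adapter's 3′
terminus — the loci where template switching is mechanistically
possible. The flag is reported, never used to rescue validation.

## TSS calling

Validated 5′ ends are counted per (position, strand). A position is a
candidate if its count is ≥ every count within ±50 nt (circular
distance); among equal-count candidates within one window only the
5′-most survives. For each candidate, with window counts
$k_i, i = -50..50$ and $\lambda = \sum_i k_i / 101$ (the peak included,
since the sum's bounds include $i=0$), the site is called when

$$P(X \ge k_0), \quad X \sim \text{Pois}(\lambda)$$

falls below $\alpha / 101 / n_\text{candidates}$. The upper tail (not
the point mass) is used: it is the standard conservative reading of
"probability of $k_0$ reads starting". `poisson_tail()` delegates to
`stats::ppois(lower.tail = FALSE)`, which is stable to the smallest
representable doubles; the test suite checks it against an independent
log-space series summation to 10⁻¹² relative error. Calls are `novel`
when no catalog TSS lies within ±5 nt (configurable; start positions
are known to wobble by a few nucleotides).

Direct-RNA reads never contribute TSS evidence: they lack the adapter
and systematically start ~23 nt short of the true terminus.

## Tails, false priming, and TES calling

A poly(A) tail is a soft-clipped homopolymer A (or T, for
reverse-complement presentations) run of ≥ 15 nt beginning within 5 nt
of the clip's read-internal edge; the edge tolerance absorbs one or two
miscalled junction bases, and interrupted runs do not count (both
configurable). For direct RNA only, a clip prefix window of ≥ 15 nt with
C+T (or G+A) fraction ≥ 0.8 also qualifies — the basecaller's known
tail-miscall mode. The 0.8 operationalizes "CT-rich", which the source
method left unquantified: far enough above the ~0.5 random expectation
to be unambiguous, and applied unconditionally for dRNA.

The last mapped base upstream of a tail is a TES when ≥ 10 cDNA reads
end there or ≥ 1 dRNA read does. Two read-level filters precede
counting: reads whose last three genomic sense bases are all A are
false-priming suspects and are removed from cDNA evidence (dRNA is
exempt — no oligo(dT) step — but the flag is still reported), and reads
with tails on both ends are removed entirely, except on the
complex-transcript path. Ends are tested per exact position, not
clustered; that is faithful to the method and means strong sites grow
±1–2 nt satellite calls, which downstream consumers must expect.

## Splice junctions

CIGAR `N` gaps ≥ 20 nt (shorter gaps are treated as long-read alignment
noise and ignored) become junction candidates, accepted only when the
intron reads `GT..AG` on the sense strand **and** has ≥ 2 cDNA reads,
≥ 1 dRNA read, or membership in an externally confirmed list (the
stand-in for wet-lab validation). Support must agree to the exact base.
Non-canonical junctions are never accepted regardless of support.

## Assembly and classification

cDNA reads are grouped by (strand, accepted-junction chain, matched
TSS, matched TES), where matching snaps a read end to the
highest-supported called site within ±10 nt (nearest wins ties) — the
snap-to-strongest rule merges jitter satellites into their parent site.
Reads matching no called TES are dropped (no polyadenylation evidence);
validated reads matching no called TSS leave the group's TSS
undetermined. Undetermined-TSS groups are kept only when their span is
polycistronic or complex — the remaining ones are the expected signature
of RNA degradation and template switching and are intentionally not
annotated as transcripts. Models are built from cDNA reads only; dRNA
contributes TES and junction evidence upstream.

Categories are assigned in strict priority order — complex >
polycistronic > SP > "0.5" > TR > L/S/AT > known — so every model
receives exactly one label:

* **complex**: the span covers ≥ 2 reference transcripts of opposite
  orientations (containment judged with the same ±10 nt slack as site
  matching). Orientation comes from the tail that passed TES criteria;
  double-tailed reads are admissible here. Without a validated 5′ end
  the TSS is imputed to the closest upstream annotated same-strand TSS
  within 5 kb and flagged `undetermined`.
* **polycistronic**: ≥ 2 complete same-strand reference ORFs in the
  span (full containment, not interrupted by an intron); names join the
  constituent gene numbers (`ORF5-6`).
* **SP**: the chain holds an accepted junction absent from the host.
* **"0.5"**: the TSS lies inside the host ORF and an in-frame ATG runs
  to the host stop (named `host.5`).
* **TR**: the TES lies 5′-ward of the host ORF stop and no complete ORF
  remains (non-coding 3′ truncation).
* **L / S / AT**: strictly > 10 nt end difference; L/S anchor on a host
  sharing the TES, AT on a host sharing the TSS (the unchanged end
  identifies the host). Exactly 10 nt ⇒ known.
* Models with no same-strand overlapping reference transcript become
  `candidate_novel`, flagged for manual review.

TR and SP names always carry ordinals (`-TR1`, `-SP1`); all other name
collisions get ordinal suffixes, keeping names injective per run.

## Motifs, kinetic classes, dispersion

Motif annotation is consensus string matching only — de-novo discovery
is out of scope. Initiators are positional: TAAG with the TSS on its
second base (the late polymerase starts there), CAGT with the same
geometry, ACAGT/ACAGG with the TSS on the central A (both arthropod-like
variants are accepted, flagged distinctly). TATA is windowed at
−50..−1 (observed ~12 bp upstream on average); PAS hexamers
AATAAA/ATTAAA at −50..−1 of the TES (observed ~16 bp); T-rich
terminators as ≥ 3 consecutive T within −10..+3. Kinetic class: late
signal alone ⇒ L, early signals alone ⇒ E, both ⇒ E/L, neither ⇒
unknown.

Dispersion statistics summarize how sharply transcription starts and
ends: per site, the 101-nt window counts are normalized by the window
total, the salient peak value itself is dropped, and the per-group
statistic is the SD of the pooled off-peak frequencies. Two deliberate
conventions here: normalizing by the *window total* (not the off-peak
total — off-peak normalization provably inverts the intended ordering,
because a sharp site concentrates its few stray reads), and anchoring
TES windows only on local support maxima of the call set (satellite
calls inside a stronger site's window are the variation being measured,
not separate anchors; the TSS side gets this for free from its
local-maximum rule). Units are arbitrary; only orderings across groups
are meaningful, and only orderings are asserted in the tests.

## Overlaps

Overlaps are computed on total TSS-to-TES spans (not exon-resolved),
circular-aware, each unordered pair once: same strand ⇒ parallel;
opposite strands sharing 3′ ends ⇒ convergent; sharing 5′ ends ⇒
divergent. Opposite-strand full containment is not defined by the
tail-to-tail/head-to-head geometry, so a convention is documented: the
contained transcript's midpoint is compared against the container's two
ends, nearer 3′ ⇒ convergent, ties ⇒ convergent. Overlaps involving an
imputed TSS are tallied separately as `predicted`, keeping the
certain/predicted distinction auditable.

## The simulator: a stated world

`sim_config()` defaults *are* the stated test conditions: a 50 kb
circular genome, 20 genes (2,400 bp pitch; 100 nt 5′ UTR, 900 nt ORF,
249 nt 3′ UTR), 100 cDNA reads per gene, artefact rates 0.1 each
(template switching, false priming at planted 9-A tracts, geometric 5′
degradation with mean 150 nt), 5 dRNA reads per gene with Poisson(23)
5′ truncation and a 0.3 CT-miscall rate ("some" tails in the source
description; 0.3 makes the mode well-populated at 5 reads/gene), 30
reads per novel isoform and 20 per special transcript (comfortably
above the 10-read TES threshold after jitter), tails Uniform(15, 60).
Strands alternate (+,+,−,−); kinetic classes cycle E, L, E/L; PAS
alternates AATAAA/ATTAAA. Each gene also carries one planted novel
isoform (L/S/AT/"0.5"/TR in rotation), and genes 10, 5–6 and 2–3 host
the splice isoform, the bicistronic read-through and the complex
transcript (half of whose reads are double-tailed). Start/end jitter
uses discrete ±2 nt kernels whose spreads order E > E/L > L and
ATTAAA > AATAAA — the orderings the dispersion statistics should
recover.

Generator-correctness measures, to keep truth labels true: promoter and
PAS scan windows of planted sites are scrubbed of accidental consensus
motifs (otherwise ~30% of 50-nt windows on a 59% AT genome contain a
chance TATA, making planted kinetic classes ill-defined), and the 31
mapped bases at each planted template-switch start are scrubbed of
chance adapter homology above Smith–Waterman score 13 (the artefact's
defining property is the *absence* of adapter signal). Complex reads
end exactly at their planted TES: with 12 single-tailed reads, jitter
would spread ends below the 10-read per-position threshold that the
method itself prescribes.

What the simulator does **not** emulate: substitution/indel sequencing
error within reads, alignment ambiguity at the circular junction,
expression-level variation across genes, chimeric reads other than the
planted double-tailed complex form, and genuine overlapping gene
architecture beyond what the planted read-throughs induce. A green
end-to-end test therefore establishes that the statistics and filters
recover a *clean but artefact-bearing* world — not robustness to
basecalling noise or mapper idiosyncrasies.

## Degenerate inputs and numerical notes

Empty read sets, empty count maps, zero candidates (no Bonferroni
division), gapless reads, header-only annotations and empty overlap
sets all produce empty-but-valid results. `poisson_tail(0, λ) = 1` and
`poisson_tail(k ≥ 1, 0) = 0`. Dispersion of an all-zero or constant
off-peak vector is 0; PAS groups with fewer than two sites report `NA`.
Outputs are byte-stable: writers use binary connections with fixed
`\n` endings, radix ordering, and no timestamps.

## Known limitations

* The undetermined-TSS retention rule (polycistronic/complex only)
  deliberately discards low-support degraded 5′ forms that a manual
  IGV-style review might rescue.
* Overlap analysis is span-based; exon-aware overlap is a non-goal.
* Complex transcripts spanning partners only partially are not
  recognized (full containment with ±10 nt slack is required).
* The CT/GA-rich tail acceptance for dRNA is unconditional; a
  signal-level tail caller would be more specific.
* Per-position TES testing means satellite calls at ±1–2 nt of strong
  sites are expected output, not errors; consumers wanting one end per
  gene should use the local-maximum anchors as in `tes_dispersion()`.
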