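Package: viranno
Title: Long-Read Transcript Annotation for Small Circular Viral Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates viral transcriptomes from long cDNA and direct-RNA
    sequencing alignments on small circular genomes. Validates read 5' ends
    against the library adapter with a Smith-Waterman test, calls
    transcription start sites with a Bonferroni-corrected Poisson peak test,
    calls transcription end sites from soft-clipped poly(A) tails with
    false-priming and double-tail filters, accepts GT..AG splice junctions,
    classifies novel transcripts (length isoforms, 5'-truncated coding and
    3'-truncated non-coding forms, splice isoforms, polycistronic and complex
    transcripts), annotates promoter, initiator and polyadenylation motifs,
    and characterizes parallel, convergent and divergent transcriptional
    overlaps. Includes an artefact-aware read simulator with ground truth so
    the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
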