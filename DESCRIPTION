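Package: hml2profiler
Title: Locus-Resolution Transcription Profiling of HERV-K(HML-2)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns amplicon cDNA sequences to individual HERV-K(HML-2)
    proviral loci using locus-specific (diagnostic) nucleotide differences,
    classifies proviruses as type 1 or type 2 via the 292-bp env indel,
    infers rec/np9 splice variants from GT..AG introns, predicts env
    gene-derived protein products (ORFs, signal peptide/SU/TM cleavage
    fragments and their masses, Rec/Np9 coding competence, chimeric
    variants), quantifies relative cloning frequencies with disease-versus-
    control statistics, and performs delta-delta-Ct RT-qPCR quantification.
    Includes a synthetic paralog-family simulator so the whole pipeline is
    testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    Rcpp,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
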