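Package: linkamp
Title: Quantitative Assessment of Linker-Amplification Bias in Low-Input Metagenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the sequence-composition biases introduced by
    PCR-based linker amplification of ultra-low-input (picogram scale) DNA
    samples, as used in viral metagenomics. Provides protocol-design
    calculators (barcode design and validation, PCR cycle-number
    recommendation from input mass, linker validation, demultiplexing), a
    generative simulator of the library-preparation process (shearing,
    GC-dependent amplification, reconditioning PCR, read sampling with
    emulsion-PCR duplicates), read quality control, scaled read-depth and
    GC-bias curve computation for isolate genomes and communities,
    paired-test statistics over treatment designs with trapezoid bias areas,
    and diversity analyses (greedy identity clustering, rarefaction,
    singleton fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
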