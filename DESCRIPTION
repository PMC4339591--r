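Package: cnmscan
Title: Conserved Non-Coding Microsatellite Marker Discovery from Gene
    Upstream Regions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers conserved non-coding microsatellite (CNMS) markers
    from the 1000-bp regions upstream of protein-coding gene start codons.
    Mines perfect simple sequence repeats (SSRs), scans both strands for
    IUPAC signal consensi of known plant regulatory elements, detects
    ungapped conserved non-coding blocks against orthologous or paralogous
    upstream sequences of comparator species, combines the three lines of
    evidence into CNMS marker calls, designs flanking PCR primer pairs
    under product-size, GC and melting-temperature constraints, and
    computes marker informativeness (PIC) and linkage-map summary
    statistics. Includes a seeded simulator of multi-species upstream
    sequence sets with planted SSR/element/conservation composites and
    decoys for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
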