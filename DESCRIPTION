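Package: trackstat
Title: Statistical Analysis of Genomic Tracks with Configurable Null Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A typed genomic-track data model (points, segments, valued
    points/segments and base-pair functions on a reference assembly) together
    with the analytical machinery to interrogate one or two tracks: descriptive
    statistics and hypothesis tests evaluated globally and in local analysis
    bins, configurable null-model randomizers (uniform, gap-preserving,
    intensity-guided, label and value permutation), Monte Carlo p-values with
    sequential MCFDR sampling and asymptotic alternatives where standard, track
    transformation and generation operators (flank expansion, case-control and
    categorical merging, distance tracks, k-mer and GC tracks, intensity tracks
    for confounder control), anchor-relative aggregation profiles, readers and
    writers for BED, bedGraph, WIG and a GTrack subset, and a batch command
    language with alternative expansion for reproducible bulk analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    GenomicRanges,
    rtracklayer,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
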