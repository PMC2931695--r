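Package: nucleoTF
Title: Nucleosome Core vs Linker Classification from TFBS Family Frequencies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how transcription factor binding site (TFBS)
    density discriminates nucleosome core DNA from linker DNA. From a table
    of 147-bp nucleosome core coordinates and a genome, the package derives
    inter-core linker intervals, extracts both sequence classes, counts
    motif-family hits per sequence (length-normalized), ranks families by
    minimum-redundancy maximum-relevance (mRMR) mutual information, locates
    the optimal discriminating subset by incremental feature selection under
    a jackknifed cosine-distance nearest-neighbor classifier, and labels
    selected families as nucleosome-forming or nucleosome-inhibiting via
    point-biserial correlation with a t-test. A synthetic-data module
    generates two-class count matrices and toy genomes with planted
    nucleosome tracks and motifs so the whole pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    stats,
    tools,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
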