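Package: orfex
Title: N-Terminal ORF Extension Discovery and PCR Fidelity Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-annotates prokaryotic translation initiation sites by scanning
    upstream of annotated start codons for in-frame alternative initiators
    (TTG/GTG), with Shine-Dalgarno motif evidence scored in a fixed window and
    a flag for the G at position -3 characteristic of Aeropyrum pernix.
    Also implements the lacZ-alpha blue/white PCR fidelity statistics
    (mutation frequency, template doublings, and error rate per base per
    template doubling), including reconstruction of per-replicate and
    group-summary error rates from colony-count tables. A synthetic-data
    module generates genomes with planted extensions and Shine-Dalgarno
    motifs, and simulates colony counts from a known true error rate, so
    every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
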