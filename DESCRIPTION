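Package: dracoscreen
Title: Terrace and DRACO Ranking for Pooled CRISPR Dropout Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of pooled CRISPR-Cas9 knockout dropout screens run
    under escalating drug pressure: spacer counting from FASTQ, depth
    normalization to a fixed library size, low-abundance noise filtering at
    the baseline timepoint, per-guide log2 fold changes against the matched
    vehicle arm, sign-concordance gene ranking (terrace plots and the
    DRACO most-efficient-guide selection with its four-of-six filter),
    screen quality diagnostics (coverage, replicate correlation,
    essential-gene CDF separation), screen-to-screen comparison, and a
    five-level additive-killing ranking for drug-combination viability
    plates. Includes a negative-binomial screen simulator with
    heterogeneous guide efficiency for ground-truth benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
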