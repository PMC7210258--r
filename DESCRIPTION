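Package: oxbspipe
Title: Paired Bisulfite/Oxidative-Bisulfite Hydroxymethylome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired conventional bisulfite (BS) and
    oxidative bisulfite (oxBS) methylation arrays. Estimates per-CpG
    5-methylcytosine and 5-hydroxymethylcytosine fractions by binomial
    maximum likelihood on paired beta values, calls 5hmC presence peaks
    and differentially (hydroxy)methylated positions with a moderated
    t-statistic and Benjamini-Hochberg control, clusters significant CpGs
    into proximity-based regions with Stouffer-combined statistics,
    annotates positions to gene features, CpG-island context and chromatin
    states, builds strand-aware metagene profiles, and provides the
    closed-form bench-assay computations (delta-delta-Ct expression,
    hMeDIP percent-input, SAM/SAH methylation index). Includes a seeded
    synthetic-data generator producing toy genomes and paired BS/oxBS
    array datasets with binomial measurement noise, detection failures and
    a multi-condition replicate design, so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
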