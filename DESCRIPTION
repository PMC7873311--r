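Package: epimemory
Title: Gestational-Age EWAS, Methylation-Expression Integration and
    Epigenetic Memory Scoring for Cord and Postnatal Blood
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for identifying gestational-age (GA)
    related CpG methylation in cord blood, relating it to transcription, and
    scoring postnatal persistence ("epigenetic memory").  Provides typed
    readers for beta matrices, sample sheets and probe manifests; probe
    filtering and reference-based cell-type deconvolution by constrained
    projection; dual-model per-CpG linear regression EWAS with
    Benjamini-Hochberg FDR and direction-consistent model intersection;
    promoter gene-list construction and hypergeometric gene-set enrichment;
    cis (250 kb) CpG-transcript matching, transcript association and
    methylation-expression correlation with concordant/discordant promoter
    classification; paired cord-postnatal correlation scoring, interval
    confounding checks, 25-state chromatin enrichment and decile trend
    curves; plus a synthetic-data generator that plants every signal the
    pipeline is designed to detect, for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    quadprog,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
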