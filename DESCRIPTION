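Package: depsignal
Title: Annotation-Scheme Analytics for Depression-Related Social Media Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing manually annotated corpora of
    depression-related short social media posts. Provides the 22-category
    annotation scheme (9 DSM-5 depressive-symptom parents, 12 DSM-IV Axis IV
    psychosocial-stressor parents, plus a no-evidence label), a packaged
    keyword lexicon with LIWC-style prefix-wildcard matching, pairwise
    inter-annotator agreement (F score) with third-annotator adjudication,
    per-keyword retrieval precision with five precision bins, category
    frequency and multi-label statistics, phi-coefficient co-occurrence with
    Cohen effect-size binning, information-gain ranking of characteristic
    words averaged over corpus subsets, and a seeded synthetic-corpus
    generator with planted, recoverable ground truth for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
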