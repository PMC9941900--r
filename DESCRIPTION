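Package: anchorscreen
Title: Anchor-Based Semantic Screening of Short Texts for Health Misinformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens short-text corpora (for example tweets) for health
    misinformation by semantic similarity to "anchor" quotes: verbatim
    exemplars of known misleading claims such as those cited in FDA Warning
    Letters. Texts and anchors are embedded as sentence vectors through a
    pluggable encoder, pairwise cosine distances are computed, and a distance
    threshold is calibrated to capture as much labeled misinformation as
    possible while holding precision above a floor. Includes per-anchor
    threshold sweeps, anchor ranking, pooled multi-anchor capture,
    nearest/farthest exemplar reports, n-gram and monthly-volume content
    summaries, a deterministic bag-of-words reference encoder for fully
    reproducible testing, a synthetic labeled-corpus generator with
    controllable anchor overlap and annotator noise, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
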