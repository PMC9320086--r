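Package: semdepth
Title: Semantic Depth of Narrative Speech and Its Cortical Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the taxonomic specificity of words produced
    in connected speech. Computes a Semantic Depth Index (SDI) for open-class
    words from a hypernym ("is-a") taxonomy, derives per-speaker
    microlinguistic feature profiles from annotated narrative transcripts
    (type and token counts, paraphasias, anomic pauses, conduites d'approche,
    lexical frequency, mean SDI), and relates mean SDI to regional cortical
    thickness (Desikan atlas) with Mann-Whitney group contrasts and
    FDR-corrected Pearson correlations over an a-priori semantic-network ROI
    set. Includes a synthetic-cohort generator emulating two primary
    progressive aphasia variants (semantic and logopenic) plus healthy
    controls, so the full pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
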