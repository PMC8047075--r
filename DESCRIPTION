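Package: speechTRF
Title: Forward Encoding Models of EEG Responses to Two-Talker Speech
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Temporal response function (TRF) analysis of multichannel EEG
    recorded during two-talker speech listening, using word-level features:
    word onsets, semantic dissimilarity from word embeddings, lexical
    surprisal from token-conditional probabilities, and word audibility from
    paired speaker waveforms. Implements ridge-regularized lagged regression
    with nested cross-validation for ridge-parameter selection,
    permutation-null feature contributions to model fit, and group-level
    statistics (pointwise t-tests with false-discovery-rate correction,
    N400-window means, spatio-temporal cluster-based permutation tests, and
    Bonferroni-screened correlations). A synthetic-data module generates
    word streams, correlated feature values, toy embeddings, token
    probabilities, two-speaker audio, and linearly convolved EEG with known
    ground-truth kernels, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
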