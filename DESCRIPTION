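Package: netent
Title: Network Entropy Analysis of Dynamic EEG Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence analysis of functional connectivity graphs built from
    multichannel EEG. Sliding-window equal-time cross-correlation matrices are
    summarised per epoch by network entropy (the Shannon entropy of the
    normalised upper-triangular edge-weight distribution, in bits), the
    resulting entropy series is resolved in time-frequency by a Meyer-wavelet
    scalogram, and high-power activities are extracted and matched against
    recorded event times. Also provides connectedness-based binarisation of
    connectivity matrices via the algebraic connectivity (Fiedler value) and
    the four classical comparison metrics (clustering coefficient,
    characteristic path length, global efficiency, vulnerability), a
    wavelet-domain band-selection and artifact-thresholding preprocessor, a
    minimal EDF reader/writer, and a synthetic multichannel generator with
    implanted connectivity-drop events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
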