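Package: speechABR
Title: Subcortical and Cortical Temporal Response Functions from Continuous-Speech EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives auditory-nerve (compound action potential), brainstem
    (ABR) and cortical temporal response functions from EEG recorded during
    continuous speech, by inverse-variance-weighted frequency-domain
    deconvolution of stimulus-feature regressors (glottal pulse trains,
    rectified audio, auditory-nerve-style firing rates). Includes stimulus
    artifact kernel estimation and subtraction for dichotic recordings, the
    complex cross-correlation frequency-following-response metric with
    Hilbert-envelope peak extraction, automated CAP and wave V peak picking,
    and the accompanying inferential battery: pointwise paired t tests with
    Benjamini-Hochberg FDR, directional t tests, default-prior (JZS) Bayes
    factors, exact binomial tests, ratio-versus-unity tests, and paired
    spatiotemporal cluster permutation tests. A synthetic-data module
    simulates speech-like regressors and EEG with known evoked kernels so
    the whole chain is verifiable without raw recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
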