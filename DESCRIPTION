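Package: sleeplfp
Title: Sleep-State LFP Connectivity: Staging, Spectra, Phase Locking and
    Cross-Frequency Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multichannel local field potential (LFP)
    recordings across the sleep-wake cycle. Provides bipolar referencing,
    anti-alias decimation to 1 kHz, harmonic band-stop line-noise filtering,
    spectral-ratio state-map sleep staging with artifact-free slow-wave-sleep
    segment selection, Welch power spectral density, Morlet-wavelet
    phase-locking value (PLV) spectra within and between cortical regions,
    surrogate-normalized phase-amplitude coupling (PAC) comodulograms,
    eigenvector-centrality connectivity networks with linear mixed-effects
    slope analysis against sleep duration, a per-frequency group-comparison
    battery with Benjamini-Hochberg control, and a ground-truthed synthetic
    session generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    graphics,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
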