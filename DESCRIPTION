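Package: respcouple
Title: Respiration-Phase Coupling of Periodic and Aperiodic Neural Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the respiratory cycle modulates periodic
    (oscillatory) and aperiodic (1/f) components of electrophysiological
    recordings. Implements respiration-belt preprocessing with two-way phase
    interpolation, time-resolved spectral parameterization (moving-window
    spectra, robust aperiodic fits, Gaussian peak extraction), overlapping
    respiratory-phase binning, harmonic mixed-effects inference with
    surrogate-based permutation nulls, circular statistics (Rayleigh,
    Watson's U2, circular median test), and a synthetic-data generator with
    known phase-locked modulation for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
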