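Package: nmrarray
Title: Processing and Model-Based Analysis of Arrayed 1D NMR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing single and arrayed one-dimensional NMR
    free induction decays and for the model-based analyses built on such
    arrays: apodisation, Fourier transformation, automatic phasing and
    polynomial baseline correction; reference deconvolution (FIDDLE) against
    singlet, TMS or TSP reference models; pure shift interferogram
    reconstruction; Stejskal-Tanner diffusion fitting (mono- and
    multi-exponential, with non-uniform-gradient correction) and DOSY map
    construction; T1/T2 relaxation fitting and ROSY maps; multivariate
    resolution of arrayed decays by SCORE, OUTSCORE and DECRA; a
    Tikhonov-regularised inverse Laplace transform; PARAFAC trilinear
    decomposition with PowerSlicing; arrayed-spectra diagnostics
    (peak tracking, temperature and phase-deviation estimation, integration,
    binning, alignment); readers and writers for Bruker, Varian and an
    internal plain-text/binary format; and a synthetic-data generator that
    produces every class of test input from closed-form line lists.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
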