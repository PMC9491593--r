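Package: stpdual
Title: Dual Optimization for Stimulation-Induced Short-Term Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring short-term synaptic plasticity dynamics from
    postsynaptic-current (PSC) peak amplitudes recorded during constant-frequency
    (DBS-like) extracellular stimulation. Implements the extended four-parameter
    Tsodyks-Markram model as an exact event-driven continuous system and as a
    discrete per-pulse map, the closed-form steady-state response across
    stimulation frequencies, and a dual optimization algorithm that alternates a
    derivative-based trust-region fit of the analytic steady-state response with
    a derivative-free Nelder-Mead fit of the transient response. Includes a
    frozen-U variant for under-determined (three-frequency) recordings, a
    conventional full-length least-mean-square-error baseline, synthetic dataset
    generation with ground truth, PSC trace processing (peak extraction,
    double-exponential kernel fitting), and a benchmark harness comparing the
    estimation methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
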