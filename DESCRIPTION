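Package: vasoionics
Title: Ion-Channel, Membrane-Potential and Myogenic-Tone Analysis for
    Arterial Myocytes
Version: 0.1.0
Authors@R:
    person("Vasoionics", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of vascular smooth-muscle
    electrophysiology and contractility. Provides a partially coupled
    binary Markov chain model of cooperative L-type Ca2+ channel gating
    (construction, simulation, likelihood and maximum-likelihood fitting),
    half-amplitude idealization of cell-attached single-channel sweeps
    with nPo/Po and coupled-event statistics, whole-cell K+ current
    density extraction with iberiotoxin-sensitive (BK) current
    subtraction, current-clamp membrane-potential metrics, pressure
    myography myogenic-tone quantification with KCl viability gating,
    molecular quantification (PLA puncta density, 2^-ddCt relative
    expression, densitometry), a synthetic-data generator for every input
    modality with known ground truth, and a group-statistics layer with a
    normality gate and post-hoc corrections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
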