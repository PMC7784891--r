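Package: gammasynch
Title: Gamma-Band Synchrony Analysis for Auditory Steady-State, Spike and
    IPSC Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of cortical gamma-band synchrony across
    recording modalities: 40-Hz auditory steady-state response (ASSR)
    evoked, total and baseline band power, intertrial phase coherence and
    N1 amplitude from trial-structured local field potentials; binned
    spike-pair cross-correlation with an interval-shuffle null;
    synchronous spontaneous IPSC detection via a coincidence-window rule;
    and scalar quantifiers for immunofluorescence (corrected total cell
    fluorescence) and behaviour (Y-maze spontaneous alternation, percent
    prepulse inhibition). A synthetic-data module generates
    condition-preset LFP trials, correlated spike pairs, paired IPSC
    event trains and behavioural sessions so that every analysis stage is
    exercisable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
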