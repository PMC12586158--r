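Package: icdecode
Title: Inference Decoding of Illusory-Contour Representations in Neural Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how visual cortical populations represent
    illusory-contour (Kanizsa-type) inference. Renders the parametric
    stimulus battery (illusory, recombined-control and real-edge probe
    images) with pixel-overlap audits; simulates synthetic sessions with
    planted emergent IC-encoders, segment responders, recurrent
    connectivity, spike trains and pupil traces; classifies functional cell
    types by rank tests; trains cross-validated multiclass linear decoders
    and probes them with held-out real-edge stimuli ('inference decoding');
    infers putative excitatory connections from slow-rate-corrected
    spike-train cross-correlograms; and cross-decodes holography-evoked
    activity to quantify pattern completion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
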