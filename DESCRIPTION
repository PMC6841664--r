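Package: affectlink
Title: Cross-Modal Correlation of Audio-Visual, EEG and Facial Affective Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts affective feature cues from multimedia stimuli (eleven
    visual cues and nineteen audio cues), from multi-channel EEG (band
    power spectral density and pairwise conditional entropy), and from
    facial landmark geometry (thirty normalized distance and area
    features); relates the modalities by regularized canonical correlation
    analysis with structure-correlation attribution; correlates canonical
    projections with self-reported valence, arousal and emotion labels;
    and computes layer-wise representational similarity between small
    convolutional networks fed EEG topographic images and fused face
    images. A synthetic-data generator with a planted latent-affect
    linkage provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    tools,
    png,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
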