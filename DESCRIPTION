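Package: ctgfusion
Title: Multimodal Image-Text Fusion for Fetal Distress Diagnosis from
    Cardiotocography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for intelligent cardiotocography classification from
    fetal heart rate (FHR) signals. Converts 4 Hz FHR traces into stacks of
    Gramian angular difference field (GADF) images over a piecewise
    aggregate approximation (PAA) schedule, builds a label-derived text
    modality, and trains a parallel image-encoder/text-decoder transformer
    with a cross-attention multimodal alignment network under a combined
    contrastive and captioning loss. A frozen-encoder, image-only test
    model with record-level majority voting performs the downstream fetal
    distress diagnosis. Includes readers for WFDB/CSV cardiotocography
    records, the clinical inclusion and labelling rules, a synthetic CTG
    generator for fully offline experiments, and evaluation metrics (ACC,
    F1, AUC, R-squared cross-modal alignment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'autograd.R'
    'attention.R'
    'captions.R'
    'fhr_io.R'
    'synthetic_ctg.R'
    'objectives.R'
    'mmif_model.R'
    'training.R'
    'fdd.R'
    'cli.R'
    'ctgfusion-package.R'
    'imaging.R'
    'wfdb.R'
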