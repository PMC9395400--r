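Package: LabelSweep
Title: Iterative Label-Noise Screening for Two-Class Image Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cleaning mislabeled and low-quality images from
    binary-class image collections, such as endoscopy frame datasets. A
    compact network-in-network convolutional classifier (a VGG16-bn trunk
    whose fully connected head is replaced by two 1x1 convolutions and
    global average pooling) is trained repeatedly on the noisy set; images
    the trained model cannot reproduce are flagged and deleted, and the
    loop stops once the flagged proportion falls below a threshold.
    Includes screening precision/recall metrics, an analytic
    parameter-budget oracle for the architectures, a synthetic two-class
    image generator with controlled label flips, out-of-class distractors,
    background degradation and patient-like grouping, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
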