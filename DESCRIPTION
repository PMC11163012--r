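Package: rbpnn
Title: Prototype-Embedded Radial Basis Probabilistic Neural Networks for
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies labeled 2-D images with a radial basis probabilistic
    neural network (RBPNN) whose kernel centers are diverse per-class
    prototype features. A small configurable convolutional backbone with
    feature-pyramid fusion, pyramid pooling and mixed spatial/channel
    self-attention extracts a per-image comprehensive feature matrix; a
    channel cosine-similarity attention (CSA) metric measures distances
    between feature matrices; density-seeded dynamic C-means clustering with
    a coupling/separation validity index selects per-class subclass
    prototypes; the RBPN layer embeds those prototypes as fixed kernel
    centers, aggregates subclass responses by class, and classifies with a
    softmax head trained by mini-batch gradient descent. Includes a synthetic
    image and feature-set generator with planted multi-subclass structure for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
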