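Package: gsreg
Title: Graph Spectral Regularization for Structured Neural Network Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structures the hidden layer of a dense neural network with a
    graph Laplacian smoothness penalty on its activations, so that
    graph-adjacent neurons respond to similar inputs. Provides fixed graph
    constructors (grids, disjoint pairs, complete graphs), an adaptive
    bandwidth Gaussian kernel that estimates a feature graph from neuron
    co-activations, and an alternating procedure that learns and reinforces
    that graph during training. Includes dense autoencoder and classifier
    implementations with seeded, reproducible training, synthetic
    ground-truth generators (binary feature modules, hierarchical Gaussian
    clusters, bifurcating trajectories), and interpretation utilities such
    as per-class activation maps, embedding segmentation, connected
    component analysis, and component-wise marker correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
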