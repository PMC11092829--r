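Package: ddfusion
Title: Disentangled Dense Fusion of Multimodal Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fusion of per-modality embedding tables (image, text, tabular)
    for classification and sliding-window temporal regression. Implements a
    disentangled dense fusion architecture: a Kronecker joint interaction
    between modalities, attention-based decomposition into modality-common
    and modality-specific features, a variational contrastive log-ratio
    upper bound (vCLUB) mutual-information penalty that removes inter-modal
    redundancy, and a dense skip-connected prediction head. Ships the
    supporting machinery end to end: class-weighted focal loss and balanced
    class weights for imbalanced labels, L2 weight decay, early stopping,
    evaluation metrics, per-modality and early-fusion baselines, a
    variational autoencoder embedding extractor for small images, and a
    seeded synthetic multimodal generator with controllable shared/specific
    latent structure so every component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    nnet,
    pROC,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
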