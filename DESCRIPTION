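Package: pemrec
Title: Prescription Recommendation from Plant Electronic Medical Records by
    Contrastive Sentence Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A bi-encoder (twin-tower) pipeline that recommends pesticide
    prescriptions for plant electronic medical records (PEMRs). Records with
    environment, plant and symptom field groups are serialized to text,
    embedded with a small trainable transformer encoder, and matched by
    cosine similarity against an embedded reference set of historical
    records; the top-N distinct prescriptions are returned. Training uses
    contrastive objectives over same-prescription text pairs (the CoSENT
    ranking loss over cosine similarities, supervised SimCSE, or the
    Sentence-BERT softmax objective). Includes stratified splitting,
    balanced pair mining, Pearson/Spearman semantic-matching evaluation,
    closed-set and open-set Top-N recommendation protocols, field-ablation
    experiments, and a seeded synthetic PEMR corpus generator with known
    latent disease classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
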