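Package: nfkbGRM
Title: Gene-Regulatory-Mechanism Inference from Nuclear NFkB Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers the transcriptional regulatory mechanism of TNF-induced
    NFkB target genes from time-course expression data. Four delay-ODE
    transcription models (a simple Hill-activation model, an incoherent
    feedforward loop with a p50-like competitor, a 3-state promoter cycle
    with closed/open/active chromatin states, and their combination) are
    driven by measured or synthetic nuclear-NFkB fold-change trajectories,
    fitted per gene by a two-step bounded multistart optimization of a
    normalized-RMSD objective, reconciled across biological replicates by a
    concordance score, and classified into good-fit and best-fit mechanism
    calls. Includes a synthetic-data generator with known ground truth, the
    trajectory preparation rules (basal subtraction, fold change, 2-100
    rescaling, monotone cubic interpolation to 1-second resolution), and
    TPM/RLE count normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    edgeR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    DESeq2,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
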