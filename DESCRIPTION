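Package: scipk
Title: Noncompartmental Pharmacokinetics for Sparse Oral Scyllo-Inositol Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noncompartmental analysis (NCA) of serum concentration-time data
    from sparse, staggered (destructive-style) sampling designs, built around a
    single-dose oral scyllo-inositol study in rats. Implements linear
    trapezoidal AUClast/AUMClast with explicit below-quantification-limit
    (BLQ) handling, terminal-phase log-linear elimination-rate regression,
    the derived-parameter chain (half-life, mean residence time, apparent
    volume of distribution, clearance), pooled mean-profile analysis across
    staggered subgroups, and per-group summary statistics with
    t-based confidence intervals. A one-compartment first-order-absorption
    simulator with zero-order endogenous input and quantification-limit
    censoring generates study-like datasets with known ground truth for
    validating every pipeline stage.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
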