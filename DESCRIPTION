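Package: ervphylo
Title: Phylogenetic Analysis of ERV Insertion and Solo-LTR Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-based analysis of endogenous retrovirus (ERV) dynamics
    on a six-taxon primate chronogram. Site patterns record, for each
    orthologous ERV locus, whether the element is absent, present in
    full-length (proviral) form, or reduced to a solo-LTR in each species.
    Insertions are modelled as per-branch Poisson processes and solo-LTR
    formation as an exponential or age-dependent Weibull deletion process;
    a pruning-style dynamic program with insertion-branch age tracking gives
    exact pattern likelihoods. The package provides maximum likelihood
    fitting, case-resampling bootstrap intervals, likelihood-ratio comparison
    of the nested deletion models, forward simulation of site patterns with
    goodness-of-fit testing, extraction of site patterns from annotated
    multiple alignments, and a Wright-Fisher simulator of LTR divergence in
    a segregating ERV allele.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
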