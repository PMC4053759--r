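Package: sagpop
Title: Recombination, Gene Flux and Metagenome Recruitment for
    Single-Amplified Genome Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative population genomics for partial single-amplified
    genomes (SAGs). Provides a coalescent-based simulator of clonal
    genealogies with homologous-recombination imports, gene gain/loss and
    amplification dropout; weighted-parsimony (Sankoff/ACCTRAN) ancestral
    gene-content reconstruction with a gain-penalty sweep; codon-aware
    synonymous-divergence (NG86 with Jukes-Cantor correction) estimation
    with coverage filters, microcluster consensus SNP rates and a
    flank-anchored SNP error statistic; an EM-fitted per-branch two-state
    hidden Markov model that detects recombination import tracts and
    estimates the recombination-to-mutation ratio (r/m); and metagenome
    fragment recruitment against a patchwork reference with identity and
    length filters, gene-boundary trimming and microcluster assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
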