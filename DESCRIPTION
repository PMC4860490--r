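Package: glycophylo
Title: Glycolysis-Enzyme Marker Phylogenetics for Bifidobacterium Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multilocus sequence analysis (MLSA) toolkit that types
    Bifidobacterium genomes from the nine canonical glycolysis enzymes.
    It mines annotated genome assemblies (GenBank or FASTA) for glycolytic
    gene orthologs and the 16S rRNA gene, translates and concatenates the
    proteins in pathway order, aligns them with a parameter-ensemble
    progressive aligner, selects and trims a consistent alignment, infers
    corrected-distance neighbor-joining trees with bootstrap support and
    majority-rule consensus, quantifies congruence between trees
    (Robinson-Foulds distances, group monophyly, support audits), and
    analyses genomic and per-gene GC content including the low/medium/high
    GC partition of the genus. A synthetic-genome simulator evolves marker
    genes along a known phylogeny so every stage can be exercised and
    validated without downloading assemblies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
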