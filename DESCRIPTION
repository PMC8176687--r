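Package: crossmode
Title: Inheritance-Mode Classification of Gene Expression in Reciprocal
    Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gene-expression inheritance in reciprocal
    crosses between two breeds or subspecies, modelled on taurine x indicine
    cattle designs. Simulates study-shaped RNA-seq count matrices with
    planted inheritance modes, performs CPM filtering, TMM normalization,
    batch centering and MDS quality control, runs two-group differential
    expression with Benjamini-Hochberg FDR control, and classifies each
    differentially expressed gene into additive, maternally or paternally
    driven, breed-dominant (activation/inhibition) or complex inheritance
    categories from the ratios of pairwise group differences. Includes
    lncRNA-neighbour direction-concordance within a genomic window and
    Fisher's exact gene-set over-representation on user-supplied gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    edgeR,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
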