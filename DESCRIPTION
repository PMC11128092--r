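Package: corealn
Title: Core-Genome Alignment of Microbial Genomes by Partitioned MUM Anchoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and aligns the core genome of a set of closely related
    microbial genome assemblies. Alignment is anchored on maximal unique
    matches (MUMs) found with a suffix-array scan over both strands, chained
    into locally collinear blocks (LCBs) with recursive re-anchoring of large
    gaps, and completed by partial-order alignment (POA) of inter-anchor
    regions. A divide-and-conquer mode partitions the query genomes into
    groups that share the reference, aligns each group independently,
    intersects the per-partition reference intervals, and trims and stitches
    the partition alignments into a single core-genome alignment. Also
    provides SNP extraction with VCF output, XMFA input/output, core-genome
    summary statistics, neighbour-joining trees from core SNP distances,
    Robinson-Foulds tree comparison, and a synthetic genome evolver with
    ground-truth core intervals and species tree for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
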