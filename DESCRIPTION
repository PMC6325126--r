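Package: endovseq
Title: Genome-Wide Off-Target Profiling of Adenine Base Editors from
    EndoV Cleavage Sequencing
Version: 0.1.0
Authors@R:
    person("Endovseq", "Maintainers", email = "endovseq@example.org",
           role = c("aut", "cre"))
Description: Detects adenine-base-editor (ABE) off-target sites from
    whole-genome sequencing of in vitro deaminated, Endonuclease V
    (EndoV) digested genomic DNA.  Reduces read alignments to
    per-position depth and strand-specific read-start counts, computes
    the staggered-nick cleavage score at every genomic position, calls
    and annotates candidate protospacer+PAM sites, assigns
    multiplex-captured sites to guide RNAs by Levenshtein edit
    distance, and summarises captured-site motifs as position frequency
    matrices.  A nick-geometry read simulator generates synthetic
    references, planted cleavage events and WGS-like alignments so the
    whole pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
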