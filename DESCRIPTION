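Package: cubkit
Title: Codon Usage Bias Analysis for Viral Coding Sequences
Version: 1.0.0
Authors@R:
    person("cubkit", "authors", email = "cubkit@example.org",
           role = c("aut", "cre"))
Description: A toolkit for codon usage bias analysis of in-frame coding
    sequences, built around the analysis battery commonly applied to small
    DNA and RNA viruses such as torque teno sus virus (TTSuV): nucleotide
    and codon-position composition, relative synonymous codon usage (RSCU)
    with over-/under-representation calls, Wright's effective number of
    codons (ENC) and the ENC-plot expected curve, GC12-on-GC3s neutrality
    regression partitioning mutation pressure from natural selection, codon
    adaptation index (CAI), relative codon deoptimization index (RCDI),
    similarity index (SiD) against host codon usage references, dinucleotide
    odds ratios, and principal component analysis over 59-dimensional RSCU
    vectors.  Ships reference RSCU profiles for the TTSuV1 and TTSuV2
    genera and the Sus scrofa / Sus scrofa domestica hosts, a Kazusa codon
    usage table parser, a synthetic coding-sequence generator with
    controllable codon-usage structure for ground-truth testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
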