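# Interstrand backbone H-bonds of the cyclic beta-hairpin model peptides.
# Atom identifiers are "RESNAME RESID ATOMNAME", matched case-insensitively.
bonds:
  - label: HB1
    donor: "ALA 2 N"
    hydrogen: "ALA 2 HN"
    acceptor: "VAL 9 O"
  - label: HB2
    donor: "VAL 9 N"
    hydrogen: "VAL 9 HN"
    acceptor: "ALA 2 O"
  - label: HB3
    donor: "VAL 4 N"
    hydrogen: "VAL 4 HN"
    acceptor: "GLN 7 O"
  - label: HB4
    donor: "GLN 7 N"
    hydrogen: "GLN 7 HN"
    acceptor: "VAL 4 O"
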