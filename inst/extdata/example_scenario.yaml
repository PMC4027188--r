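# One transposition reaction: a -1T mutant left end paired with a wild-type
# right end, wild-type transposase, constrained mechanism with additive
# coupling, default calibrated rates (omit `rates:` to use them).
name: "-1T x WT rescue"
mechanism: constrained
coupling_rule: additive
left_end: "-1T"
right_end: "WT"
geometry:
  element_length: 1500
  backbone_length: 2500
  digest_site: 2500
  flank_dinucleotide: TA
transposase: WT
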