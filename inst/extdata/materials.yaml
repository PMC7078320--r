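# Default specimen material library.
# composition: atom counts per formula unit (normalized internally);
# density in g/cm^3.
dna:
  # average monophosphate nucleotide of double-stranded DNA
  # note: element keys are quoted ("N" would otherwise parse as a boolean)
  composition: {"C": 9.75, "H": 12.25, "N": 3.75, "O": 7, "P": 1}
  density: 1.70
carbon:
  composition: {C: 1}
  density: 2.0
gold:
  composition: {Au: 1}
  density: 19.3
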