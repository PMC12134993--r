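# Default tool configuration.  Every field can be overridden from the command
# line or by passing explicit arguments to the package functions.
enzymes_file: enzymes.tsv
tags_file: tags.tsv
codon_usage_file: codon_usage_dmel.tsv
linker_peptide: GSGG
# In-frame spacers between AscI/XhoI and SalI/NotI (see the methods vignette
# for the frame congruences they satisfy).
spacers: [GA, T, GA, A]
seed_copies: 5
rounds: 4
stability:
  stable_max_copies: 20
  high_copy_warning: 80
  max_repeat_span_nt: 6000
knockin:
  min_splice_distance: 50
  arm_length: 1000
  # The B2 recombinase target site sequence is not public; this 30-nt
  # placeholder is SYNTHETIC and must be replaced with the real B2RT sequence
  # for production designs.
  rt_site: ACGTTCGGAATCCTATGACCGGATAACGCA
seed: 1
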