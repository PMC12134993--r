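# tandemtag

Design and in-silico cloning of tandem epitope-tag multimers, with conditional
knock-in donor design.

## The problem

Immunostaining signal for a low-abundance protein scales with the number of
epitope-tag copies fused to it, but long tandem repeats are notoriously hard
to synthesize and clone directly. A doubling strategy solves this: synthesize
a small 5X seed plasmid once, then iteratively digest and re-ligate it so each
round doubles the tandem copy number — 5X → 10X → 20X → 40X → 80X. The
catch is that the sequence around the repeats must be engineered so that every
round regenerates the same cloning geometry: compatible cohesive ends, a
repeat-block junction that neither parent enzyme can cut, a single open
reading frame throughout, and exactly one copy of each restriction site.

`tandemtag` designs seeds that satisfy all of this by construction
(`AscI | XhoI | (tag+linker)×5 | SalI | NotI`, with in-frame spacers derived
in the vignette), and then **simulates the actual cloning** — digestion,
fragment selection, ligation via the compatible XhoI/SalI `TCGA` overhangs —
rather than string-concatenating the expected product. Every returned
construct has passed a unique-site census, a four-clause reading-frame
verification and a protein-level repeat recount. A second module turns a
multimer into a conditional knock-in donor: C-terminal fusion 5′ of the stop
codon, a recombinase-flanked STOP cassette placed mid-intron, synonymous PAM
mutations in the homology arms, and sequence-exact excision simulation.

## Worked example

```r
library(tandemtag)

# Synthetic fixtures: a 2.6 kb circular backbone guaranteed free of
# AscI/XhoI/SalI/NotI sites, and a 3-exon toy gene.
fx <- generate_fixture(seed = 1)

# Design the 5X V5 seed and run four doubling rounds.
series <- run_protocol(default_tags()$V5, fx$backbone, rounds = 4)
vapply(series, function(s) as.integer(count_repeats(s)), integer(1))
#> [1]  5 10 20 40 80

series[[5]]
#> <multimer_construct> 80XV5 on backbone (7089 bp plasmid, insert span 1300..5789)

# The designed repeat unit: V5 peptide + GSGG linker, codon-optimized and
# clean of all four sites even across its self-concatenation junction.
series[[1]]$repeat_unit
#> [1] "GGCAAGCCCATCCCCAACCCCCTGCTGGGCCTGGATAGCACCGGCAGCGGCGGC"

# Diagnostic XhoI/NotI digest of the 20X construct: one insert band whose
# length doubles (minus a constant) each round.
predict_gel(series[[3]], default_enzymes()[c("XhoI", "NotI")])
#>   band length    label
#> 1    1   2617 backbone
#> 2    2   1124   insert

# Knock-in donor: fuse the 40X block to the toy gene's C-terminus, park a
# recombinase-flanked STOP cassette mid-intron, then simulate excision.
fused <- fuse_cterminal_tag(fx$gene, multimer_orf(series[[4]]))
nchar(gene_translation(fused)) - 1L   # 61-aa toy protein + 752-aa tag block
#> [1] 813

donor <- insert_conditional_cassette(fused, intron_index = 1,
                                     cassette = strrep("T", 100),
                                     rt_site = read_config()$knockin$rt_site)
excised <- simulate_excision(donor)
attr(excised, "excised_length")      # cassette (100 nt) + one RT copy (30 nt)
#> [1] 130
identical(gene_translation(attr(excised, "gene_model")),
          gene_translation(fused))   # protein conserved through the cycle
#> [1] TRUE
```

Constructs and donors read and write FASTA and an annotated GenBank dialect
(`write_genbank()` / `read_construct_genbank()` / `read_donor_genbank()`);
gene models load from FASTA + exon tables or minimal GFF3. A command-line
interface with verbs `design-seed`, `double`, `protocol`, `catalog`,
`verify`, `digest-report`, `knockin`, `excise` and `fixture` is installed at
`exec/tandemtag` inside the package library:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "tandemtag", package = "tandemtag"))')
Rscript "$CLI" fixture --seed 1
Rscript "$CLI" design-seed --tag V5 --backbone backbone.fasta --out seed.gb
Rscript "$CLI" double --in seed.gb --out 10x.gb
Rscript "$CLI" verify --in 10x.gb
```

## Documentation

The methods vignette (`vignettes/tandem-multimer-design.Rmd`) derives the
spacer congruences behind the frame guarantees, documents the hybrid-scar
orientation convention, and states precisely what the synthetic fixtures do
and do not emulate. Function-level documentation is in the roxygen comments.
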