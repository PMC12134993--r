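---
title: "Designing tandem epitope-tag multimers and conditional knock-in donors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing tandem epitope-tag multimers and conditional knock-in donors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tandemtag)
```

# The problem

Visualizing low-abundance proteins by immunostaining benefits from fusing many
tandem copies of a short epitope tag to the target: each copy is an antibody
binding site, so signal scales with copy number. Synthesizing a long tandem
repeat directly is hard (repeats are unstable in synthesis and cloning), but a
*doubling* strategy sidesteps this: synthesize a small 5X seed once, then
iteratively digest and re-ligate it so that each round doubles the tandem copy
number: 5X &rarr; 10X &rarr; 20X &rarr; 40X &rarr; 80X.

The scheme only works if the sequence around the repeats is engineered so
that, at *every* round:

1. the two fragments re-ligate through compatible cohesive ends,
2. the junction created between the two repeat blocks is recognized by
   *neither* parent enzyme (otherwise the next digest would shred the array),
3. the whole cassette stays in one open reading frame, and
4. each of the four restriction sites stays unique on the plasmid.

`tandemtag` designs the seed so that all four conditions hold by construction,
and then *simulates the actual cloning* (digest, fragment selection, ligation)
rather than string-concatenating the expected product, so every claim about
the constructs is verified on the sequence the protocol would really produce.

# The doubling geometry

The seed cassette is laid into a site-free circular backbone as

```
AscI | s1 | XhoI | s2 | (tag+linker) x 5 | s3 | SalI | s4 | NotI
```

with four tiny spacers `s1..s4`. One doubling round is:

* **vector**: digest a copy with AscI + XhoI, keep the large fragment;
* **insert**: digest a second copy with AscI + SalI, keep the repeat-bearing
  fragment (the one still carrying the XhoI site);
* **ligate**: AscI ends (overhang `CGCG`) rejoin and regenerate AscI; the
  XhoI end (overhang `TCGA`) anneals to the SalI end (also `TCGA`), producing
  a hybrid junction that neither enzyme recognizes.

```{r doubling}
fx <- generate_fixture(seed = 1)
series <- run_protocol(default_tags()$V5, fx$backbone, rounds = 4)
vapply(series, function(s) as.integer(count_repeats(s)), integer(1))
```

The product again reads `AscI | s1 | XhoI | s2 | repeats ... repeats | s3 |
SalI | s4 | NotI` — the same shape as the seed with twice the copies — which
is why the round can be applied indefinitely. `validate_construct()` runs
inside every builder, so each returned construct has already passed the
unique-site census, the frame verification and the copy-number recount.

## A note on the hybrid scar's orientation

The stored top strand of the plasmid runs 5'&rarr;3' through
`... repeats | s3 | G + TCGA + G | s2 | repeats ...` at each scar, i.e. the
6-mer core reads `GTCGAG`. The same duplex read from the other strand is
`CTCGAC`; diagrams of this protocol often draw that orientation. Both are the
identical double-stranded junction, and `hybrid_junctions()` plus the tests
confirm it contains neither `CTCGAG` (XhoI) nor `GTCGAC` (SalI) on either
strand.

# Reading-frame bookkeeping: the spacer congruences

All frame guarantees are anchored to the nucleotide immediately 5' of the
AscI motif: the codons there read `(N,GG)(CGC)(GCC)...` so the 8-nt motif
spans codons cleanly. Let `|s|` denote spacer lengths and `u` the repeat-unit
length (always a multiple of 3). Three constraints must hold *at every
round r*:

1. **repeat block at a codon boundary**: `1 + 8 + |s1| + 6 + |s2| ≡ 0 (mod 3)`
   so `|s1| + |s2| ≡ 0 (mod 3)`;
2. **NotI at a codon boundary**: additionally
   `|s3| + 6 + |s4| ≡ 0 (mod 3)` so `|s3| + |s4| ≡ 0 (mod 3)`;
3. **doubling preserves 1 and 2**: each round replaces nothing upstream but
   inserts, between the two repeat blocks, the scar
   `s3 + G | TCGA | G + s2`; for the downstream block to stay on frame this
   insertion must be `≡ 0 (mod 3)`, i.e. `|s3| + 6 + |s2| ≡ 0 (mod 3)`.

The minimal solution with non-empty spacers that also keeps every junction
codon stop-free is `s1 = "GA"`, `s2 = "T"`, `s3 = "GA"`, `s4 = "A"`
(lengths 2, 1, 2, 1; congruences 2, 1, 2, 1 mod 3). The scar then translates
as `GAG TCG AGT` (E-S-S across the junction) and the downstream flank as
`GAG TCG ACA ...` — no stop codon can arise at any round, which
`verify_frame()` re-checks clause by clause:

```{r frame}
verify_frame(series[[5]])$clauses
```

A corollary used throughout the package: the AscI&rarr;NotI insert span has
length `25 + (5u + 9) * 2^r`, always `≡ 1 (mod 3)`, and the anchored
translated region (span + 2 nt) is always a whole number of codons.

# Designing the repeat unit

`reverse_translate_unit()` reverse-translates *tag peptide + linker* (default
linker `GSGG`, four residues, chosen to be short, flexible and low-complexity)
with a deterministic greedy chooser — the most frequent codon per residue
from a bundled codon-usage table — followed by bounded backtracking over
synonymous swaps until no forbidden motif (AscI/XhoI/SalI/NotI) occurs in the
unit **or across its self-junction**. The self-concatenation scan is
mandatory: tandem repeats create junction sequences a single-unit scan never
sees. When the codon table leaves no synonymous escape (e.g. a table offering
one codon per residue for an unlucky peptide), the designer refuses with an
error rather than emitting a unit that multimerizes into a cut site.

```{r unit}
as.character(reverse_translate_unit(default_tags()$V5))
```

# Diagnostic digests

`predict_gel()` is the machine-readable analog of a diagnostic agarose gel:
XhoI + NotI release the whole repeat block as one insert band of length
`8 + (5u + 9) * 2^r`, so across rounds the insert band strictly grows and its
increment doubles — a quick identity check for each round's product.

```{r gel}
predict_gel(series[[3]], default_enzymes()[c("XhoI", "NotI")])
```

# Stability heuristics

Long tandem repeats can be unstable in high-copy vectors. The package encodes
this as *advisory* warnings, never errors: `stability_warnings()` flags copy
numbers above 20X (the range generally handled without incident in small
high-copy backbones), adds a stronger flag at 80X-scale (where some tag/level
combinations can prove unobtainable), and flags repeat spans beyond a length
threshold. Vector- and host-dependent instability is real but not modeled;
the heuristics are cheap reminders, not predictions.

# Conditional knock-in donors

The second half of the toolkit turns a multimer into a conditional knock-in
donor for a gene of interest:

1. **C-terminal fusion** — `multimer_orf()` extracts the anchored, stop-free,
   codon-multiple cassette (ending inside the NotI motif, whose `GCN` codon
   keeps the frame open), and `fuse_cterminal_tag()` inserts it immediately
   5' of the stop codon, so the fused protein is *original protein + tags*,
   with the original stop retained.
2. **Conditional STOP cassette** — `insert_conditional_cassette()` places
   `RT + cassette + RT` (direct-repeat recombinase target sites) at an intron
   midpoint, at least 50 nt from both splice sites, leaving every exon and
   splice dinucleotide untouched. The cassette is opaque to the package; its
   transcription-terminating payload is the user's choice. The RT site must
   not occur anywhere else in the gene, or later excision would be ambiguous.
3. **PAM mutations** — for each guide RNA used to cut the genomic locus, the
   donor's homology arms must not be re-cut. `mutate_pams()` finds the unique
   protospacer match (either strand), and disrupts the adjacent `NGG` PAM by
   a single base change: synonymous when the PAM lies in coding sequence,
   falling back to a synonymous seed-region substitution inside the
   protospacer when the PAM codon (e.g. tryptophan's `TGG`) admits no silent
   change. A final re-scan proves no guide retains a match with a functional
   PAM.
4. **Excision** — `simulate_excision()` models recombinase action on the two
   direct repeats: the cassette plus one RT copy leaves (excised length =
   cassette + RT, exactly), one RT scar remains in the intron, and the
   spliced CDS — hence the protein — is unchanged. Inverted-orientation
   sites are refused; only excision is modeled, not inversion.

```{r knockin}
gene <- fx$gene
fused <- fuse_cterminal_tag(gene, multimer_orf(series[[4]]))
donor <- insert_conditional_cassette(fused, intron_index = 1,
                                     cassette = strrep("T", 100),
                                     rt_site = read_config()$knockin$rt_site)
excised <- simulate_excision(donor)
attr(excised, "excised_length")
identical(gene_translation(attr(excised, "gene_model")),
          gene_translation(fused))
```

# What the synthetic fixtures do and do not emulate

No real vector or genomic sequence ships with the package.
`generate_backbone()` emulates only the properties the protocol needs from a
small high-copy vector: circularity, a realistic size (default 2.6 kb), and
the guarantee of zero AscI/XhoI/SalI/NotI sites (by rejection sampling with
local repair). `generate_toy_gene()` emulates only what the knock-in design
consumes from a locus: a multi-exon structure with canonical `GT..AG`
introns, a stop-free CDS split at codon boundaries, and UTRs. Neither fixture
models base composition, chromatin, promoters, replication origins or
selection markers; conclusions that depend on those cannot be drawn here. The
bundled recombinase target site is likewise a clearly labelled synthetic
placeholder to be replaced with a real site for production designs.

# Problem sizes exercised by the test suite

The automated tests run the full protocol (5X to 80X) for all six bundled
tags on a 2.6 kb synthetic backbone; verify the digest/ligate round-trip on
500 random circular plasmids; check the hybrid-junction, census and frame
invariants at every round of every series; and run the knock-in
protein-conservation and excision-arithmetic properties on 100 random toy
genes each. `scripts/acceptance.R` reproduces the headline copy-number
arithmetic end to end from a seeded fixture.

# Design decisions on open points

* **Leading linker**: the linker is part of each repeat unit (tag then
  linker), so the array is `(tag+linker) x n` with no extra linker before the
  first tag; the junction codons of the flanks already provide spacing, and a
  leading-linker variant can be had by passing a custom `unit` to
  `build_seed()`.
* **Synonymity scope for PAM edits**: only CDS positions constrain the edit;
  intronic and UTR PAM positions accept any disrupting base. Regulatory
  motifs outside the CDS are not modeled and are the user's responsibility.
* **Stability**: copy-number and span thresholds are configurable data, not
  code, because repeat stability is vector- and host-dependent.
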