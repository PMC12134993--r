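test_that("gene models enforce exon/CDS invariants at construction", {
  g <- make_two_exon_gene(c("ATG", "GCT", "GAA"), c("AAA", "TAA"))
  expect_s3_class(g, "gene_model")
  expect_equal(gene_translation(g), "MAEK*")
  expect_equal(nchar(spliced_cds(g)), 15L)
  expect_equal(intron_interval(g, 1L), c(g$exons[1, "end"],
                                         g$exons[2, "start"]))
  expect_error(intron_interval(g, 2L), "out of range")

  b <- g$sequence$bases
  expect_error(gene_model(b, rbind(c(0L, 30L), c(20L, 50L)),
                          g$cds_start, g$cds_end), "non-overlapping")
  expect_error(gene_model(b, g$exons, g$cds_start, g$cds_end - 1L),
               "codon multiple")
  # CDS must terminate with a stop codon
  expect_error(make_two_exon_gene(c("ATG", "GCT", "GAA"), c("AAA", "CCC")),
               "stop codon")
})

test_that("C-terminal fusion inserts before the stop and preserves the frame", {
  g <- generate_toy_gene(seed = 5L)
  s20 <- tt_toy_series(2L)[[3]]
  orf <- multimer_orf(s20)
  fused <- fuse_cterminal_tag(g, orf)
  expect_equal(dna_length(fused$sequence),
               dna_length(g$sequence) + nchar(orf))
  pep0 <- gene_translation(g)
  pep1 <- gene_translation(fused)
  # original protein, then the tag cassette, then the original stop
  expect_equal(pep1, paste0(substr(pep0, 1L, nchar(pep0) - 1L),
                            translate_dna(orf), "*"))
  expect_equal(count_nonoverlap(pep1, paste0(s20$tag$peptide,
                                             s20$linker_peptide)), 20L)
  iv <- attr(fused, "tag_insert")
  expect_equal(substr(fused$sequence$bases, iv[1] + 1L, iv[2]), orf)

  expect_error(fuse_cterminal_tag(g, "ATGC"), "multiple of 3")
  expect_error(fuse_cterminal_tag(g, "GGTTAAGGT"), "stop codon")
})

test_that("the conditional cassette lands mid-intron without touching exons", {
  g <- generate_toy_gene(seed = 9L)
  cassette <- strrep("T", 100L)
  d <- insert_conditional_cassette(g, 1L, cassette, tt_rt)
  expect_s3_class(d, "donor_design")
  # total growth = cassette + two RT copies
  expect_equal(dna_length(d$gene$sequence),
               dna_length(g$sequence) + 100L + 2L * nchar(tt_rt))
  # the spliced message is untouched
  expect_equal(spliced_cds(d$gene), spliced_cds(g))
  expect_equal(gene_translation(d$gene), gene_translation(g))
  b <- d$gene$sequence$bases
  for (i in 1:2) {
    expect_equal(substr(b, d$rt_sites[i, 1] + 1L, d$rt_sites[i, 2]), tt_rt)
  }
  expect_equal(substr(b, d$cassette_insert[1] + 1L, d$cassette_insert[2]),
               cassette)
  # payload sits strictly inside the intron, >= 50 nt from both splice sites
  iv <- intron_interval(d$gene, 1L)
  expect_gte(d$rt_sites[1, 1] - iv[1], 50L)
  expect_gte(iv[2] - d$rt_sites[2, 2], 50L)

  short <- make_two_exon_gene(c("ATG", "GCT", "GAA"), c("AAA", "TAA"),
                              intron_len = 80L)
  expect_error(insert_conditional_cassette(short, 1L, cassette, tt_rt),
               "intron too short")
  # a second RT pair would make excision ambiguous
  expect_error(insert_conditional_cassette(d$gene, 1L, cassette, tt_rt),
               "already occurs")
})

test_that("excision removes cassette + one RT copy and conserves the protein", {
  g <- generate_toy_gene(seed = 9L)
  cassette <- strrep("T", 100L)
  d <- insert_conditional_cassette(g, 1L, cassette, tt_rt)
  out <- simulate_excision(d)
  expect_equal(attr(out, "excised_length"), 100L + nchar(tt_rt))
  expect_equal(dna_length(out), dna_length(g$sequence) + nchar(tt_rt))
  # exactly one RT scar remains, in direct orientation
  expect_equal(count_nonoverlap(out$bases, tt_rt), 1L)
  model <- attr(out, "gene_model")
  expect_equal(gene_translation(model), gene_translation(g))

  # a second excision has nothing left to act on
  once <- excised_design(d)
  expect_equal(nrow(once$rt_sites), 1L)
  expect_error(simulate_excision(once), "requires two RT sites")

  # inverted repeats are refused: only direct-repeat excision is modeled
  flipped <- d
  b <- flipped$gene$sequence$bases
  substr(b, flipped$rt_sites[2, 1] + 1L, flipped$rt_sites[2, 2]) <-
    reverse_complement(tt_rt)
  gm <- flipped$gene
  flipped$gene <- gene_model(b, gm$exons, gm$cds_start, gm$cds_end)
  expect_error(simulate_excision(flipped), "inverted orientation")
})

test_that("PAM breaking in coding sequence uses a synonymous substitution", {
  cds1 <- c("ATG", "GCT", "GAA", "GAT", "CTG", "GAT", "GTT", "CGG", "AAA")
  g <- make_two_exon_gene(cds1, c("AAA", "TAA"))
  d <- insert_conditional_cassette(g, 1L, strrep("T", 60L), tt_rt)
  spacer <- "GCTGAAGATCTGGATGTT"  # codons 2-7, PAM codon CGG immediately 3'
  d2 <- mutate_pams(d, guide_spacer(spacer))
  expect_equal(nrow(d2$pam_edits), 1L)
  e <- d2$pam_edits
  p <- 10L + 3L  # protospacer start: 10 nt 5'UTR + ATG
  # only the wobble base of the CGG arginine codon can break the PAM silently
  expect_equal(e$position, p + 20L)
  expect_equal(e$old, "G")
  expect_true(e$new != "G")
  expect_true(e$synonymous)
  expect_false(e$fallback)
  expect_equal(gene_translation(d2$gene), gene_translation(g))
  # guide no longer faces a functional PAM
  b <- d2$gene$sequence$bases
  expect_false(substr(b, p + 20L, p + 21L) == "GG")
})

test_that("a Trp PAM falls back to a synonymous seed substitution", {
  cds1 <- c("ATG", "GCT", "GAA", "GAT", "AAA", "GAT", "CTG", "TGG", "AAA")
  g <- make_two_exon_gene(cds1, c("AAA", "TAA"))
  d <- insert_conditional_cassette(g, 1L, strrep("T", 60L), tt_rt)
  spacer <- "GCTGAAGATAAAGATCTG"  # ends in the Leu codon CTG, PAM = TGG (Trp)
  d2 <- mutate_pams(d, guide_spacer(spacer))
  e <- d2$pam_edits
  expect_equal(nrow(e), 1L)
  p <- 10L + 3L
  # TGG has no synonymous escape, so the seed-proximal Leu wobble base moves
  expect_equal(e$position, p + 17L)
  expect_true(e$synonymous)
  expect_true(e$fallback)
  expect_equal(gene_translation(d2$gene), gene_translation(g))
})

test_that("intronic and minus-strand PAMs accept any disrupting base", {
  spacer <- "TTGACCGGTAGCATAAGC"
  payload <- paste0("CCA", reverse_complement(spacer))
  intron <- paste0("GT", strrep("C", 58L), payload,
                   strrep("C", 300L - 4L - 58L - nchar(payload)), "AG")
  seqs <- paste0(strrep("A", 10L), "ATGGCTGAA", intron, "AAATAA",
                 strrep("A", 10L))
  ex <- rbind(c(0L, 19L), c(319L, 335L))
  g <- gene_model(seqs, ex, 10L, 325L)
  d <- insert_conditional_cassette(g, 1L, strrep("T", 60L), tt_rt,
                                   at = 19L + 230L)
  d2 <- mutate_pams(d, guide_spacer(spacer))
  e <- d2$pam_edits
  expect_equal(nrow(e), 1L)
  p <- 19L + 2L + 58L + 3L  # start of the minus-strand protospacer match
  expect_true(e$position %in% c(p - 2L, p - 3L))
  expect_equal(e$old, "C")
  expect_false(e$new == "C")
  expect_false(e$synonymous)  # intronic: no codon constraint applies
  expect_equal(gene_translation(d2$gene), gene_translation(g))

  # zero or multiple protospacer matches are hard errors
  expect_error(mutate_pams(d, guide_spacer(strrep("A", 18L))), "0 times")
  expect_error(mutate_pams(d, guide_spacer(strrep("C", 18L))), "times")
})

test_that("guides without a functional PAM require no edit", {
  cds1 <- c("ATG", "GCT", "GAA", "GAT", "CTG", "GAT", "GTT", "CGG", "AAA")
  g <- make_two_exon_gene(cds1, c("AAA", "TAA"))
  d <- insert_conditional_cassette(g, 1L, strrep("T", 60L), tt_rt)
  # protospacer shifted so the adjacent bases are AA, not GG
  d2 <- mutate_pams(d, guide_spacer("GAAGATCTGGATGTTCGG"))
  expect_equal(nrow(d2$pam_edits), 0L)
  expect_equal(d2$gene$sequence$bases, d$gene$sequence$bases)
})

test_that("tag fusion + cassette + excision conserves the protein genome-wide", {
  s20 <- tt_toy_series(2L)[[3]]
  orf <- multimer_orf(s20)
  insert_pep <- translate_dna(orf)
  for (i in 1:100) {
    g <- generate_toy_gene(seed = i)
    fused <- fuse_cterminal_tag(g, orf)
    d <- insert_conditional_cassette(fused, 1L, strrep("T", 80L), tt_rt)
    out <- simulate_excision(d)
    pep <- gene_translation(attr(out, "gene_model"))
    pep0 <- gene_translation(g)
    expect_equal(pep, paste0(substr(pep0, 1L, nchar(pep0) - 1L),
                             insert_pep, "*"))
  }
})

test_that("excised length always equals cassette length + one RT copy", {
  set.seed(2024)
  for (i in 1:100) {
    g <- generate_toy_gene(seed = 1000L + i)
    repeat {
      rt <- random_dna(sample(20:40, 1L))
      if (!grepl(rt, g$sequence$bases, fixed = TRUE) &&
          !grepl(reverse_complement(rt), g$sequence$bases, fixed = TRUE)) {
        break
      }
    }
    k <- sample(30:150, 1L)
    d <- insert_conditional_cassette(g, sample(1:2, 1L), random_dna(k), rt)
    out <- simulate_excision(d)
    expect_equal(attr(out, "excised_length"), k + nchar(rt))
    expect_equal(gene_translation(attr(out, "gene_model")),
                 gene_translation(g))
  }
})
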