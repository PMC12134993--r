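test_that("repeat-unit design is clean in the unit and across self-junctions", {
  enz <- tt_enzymes()
  usage <- load_codon_usage()
  for (tg in default_tags()) {
    unit <- reverse_translate_unit(tg, usage = usage, forbidden = enz)
    expect_equal(nchar(unit), 3L * (nchar(tg$peptide) + 4L))
    expect_equal(translate_dna(as.character(unit)),
                 paste0(tg$peptide, "GSGG"))
    # mandatory self-concatenation scan: the doubled unit is also clean
    doubled <- dna(paste0(unit, unit))
    for (e in enz) expect_length(find_sites(doubled, e), 0L)
  }
  expect_error(epitope_tag("SHORT", "ACDE"), "5-30 residues")
  expect_error(epitope_tag("BAD", "AC*DE"), "invalid residue")
})

test_that("codon design fails loudly when no synonymous escape exists", {
  # G/R/A/A/G with no linker under a codon table offering a single codon per
  # residue: the self-junction necessarily contains the NotI motif, so the
  # designer must refuse rather than emit a unit that multimerizes into cut
  # sites.  (The full usage table escapes this trap via a synonymous swap.)
  usage <- data.frame(codon = c("GGC", "CGC", "GCC"),
                      aa = c("G", "R", "A"), per_mille = 1)
  expect_error(
    reverse_translate_unit(epitope_tag("GR", "GRAAG"), linker_peptide = "",
                           usage = usage),
    "no codon assignment avoids the forbidden motif NotI")
  # with synonymous freedom the same peptide designs cleanly
  u <- reverse_translate_unit(epitope_tag("GR", "GRAAG"), linker_peptide = "")
  for (e in tt_enzymes()) {
    expect_length(find_sites(dna(strrep(as.character(u), 2L)), e), 0L)
  }
})

test_that("the seed lays down the canonical cassette architecture", {
  enz <- tt_enzymes()
  seed <- tt_toy_series(0L)[[1]]
  expect_s3_class(seed, "multimer_construct")
  expect_equal(seed$copy_number, 5L)
  b <- seed$plasmid$bases
  a <- seed$insert_span[1]
  e <- seed$insert_span[2]
  # AscI | GA | XhoI | T | 5 x unit | GA | SalI | A | NotI
  u <- seed$repeat_unit
  expect_equal(substr(b, a + 1L, e),
               paste0("GGCGCGCC", "GA", "CTCGAG", "T", strrep(u, 5L),
                      "GA", "GTCGAC", "A", "GCGGCCGC"))
  expect_equal(e - a, 25L + 5L * nchar(u) + 9L)
  # site-free backbone is enforced
  dirty <- dna(paste0(tt_backbone()$bases, "GGCGCGCC"), "circular")
  expect_error(build_seed(tt_toy_tag(), dirty, enzymes = enz), "AscI site")
  expect_error(build_seed(tt_toy_tag(), dna("ACGT"), enzymes = enz),
               "circular")
})

test_that("each doubling round doubles the tandem copy number", {
  for (series in tt_all_series()) {
    copies <- vapply(series, function(s) as.integer(count_repeats(s)),
                     integer(1))
    expect_equal(copies, c(5L, 10L, 20L, 40L, 80L))
    recorded <- vapply(series, `[[`, integer(1), "copy_number")
    expect_equal(recorded, copies)
    dna_lvl <- vapply(series, function(s) attr(count_repeats(s), "dna_level"),
                      integer(1))
    expect_equal(dna_lvl, copies)
  }
})

test_that("insert span length follows the closed form 25 + (5u + 9) * 2^r", {
  for (series in tt_all_series()) {
    u <- nchar(series[[1]]$repeat_unit)
    for (r in 0:4) {
      s <- series[[r + 1L]]
      expect_equal(s$insert_span[2] - s$insert_span[1],
                   25L + (5L * u + 9L) * 2L^r)
    }
  }
})

test_that("every round keeps exactly one site per enzyme and a valid frame", {
  for (series in tt_all_series()) {
    for (s in series) {
      census <- unique_site_census(s$plasmid, s$enzymes)
      expect_equal(unname(census), rep(1L, 4L))
      expect_named(census, c("AscI", "XhoI", "SalI", "NotI"))
      fr <- verify_frame(s)
      expect_true(fr$ok)
      expect_equal(fr$clauses$clause,
                   c("ascI_junction", "notI_junction", "no_internal_stop",
                     "open_downstream"))
      expect_true(all(fr$clauses$pass))
    }
  }
})

test_that("hybrid scars accumulate as 2^r - 1 uncuttable GTCGAG cores", {
  for (series in tt_all_series()) {
    for (r in 0:4) {
      s <- series[[r + 1L]]
      j <- hybrid_junctions(s)
      expect_length(j, 2L^r - 1L)
      for (p in j) {
        expect_equal(substr(s$plasmid$bases, p + 1L, p + 6L), "GTCGAG")
      }
    }
  }
})

test_that("protein-level counting tolerates synonymous substitutions", {
  s <- tt_toy_series(2L)[[2]]  # 10X construct
  u <- s$repeat_unit
  last <- substr(u, nchar(u) - 2L, nchar(u))
  aa <- Biostrings::GENETIC_CODE[[last]]
  alt <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE == aa], last)[1]
  variant <- paste0(substr(u, 1L, nchar(u) - 3L), alt)
  s$plasmid$bases <- sub(u, variant, s$plasmid$bases, fixed = TRUE)
  cnt <- count_repeats(s)
  expect_equal(as.integer(cnt), 10L)        # peptide repeats unchanged
  expect_equal(attr(cnt, "dna_level"), 9L)  # one unit no longer exact DNA
})

test_that("frame verification flags broken junctions and internal stops", {
  s <- tt_toy_series(0L)[[1]]
  # overwrite the first codon of the repeat block with a stop codon
  stopped <- s
  b <- stopped$plasmid$bases
  a <- stopped$insert_span[1]
  substr(b, a + 18L, a + 20L) <- "TAA"
  stopped$plasmid$bases <- b
  fr <- verify_frame(stopped)
  expect_false(fr$ok)
  expect_false(fr$clauses$pass[fr$clauses$clause == "no_internal_stop"])

  # a span not ending on the NotI motif fails the downstream clause
  shifted <- s
  shifted$insert_span[2] <- shifted$insert_span[2] - 1L
  fr2 <- verify_frame(shifted)
  expect_false(fr2$clauses$pass[fr2$clauses$clause == "notI_junction"])
  expect_error(count_repeats(shifted), "frame broken")

  # a span not starting on the AscI motif fails the upstream clause
  offset <- s
  offset$insert_span[1] <- offset$insert_span[1] + 1L
  fr3 <- verify_frame(offset)
  expect_false(fr3$clauses$pass[fr3$clauses$clause == "ascI_junction"])
})

test_that("the ORF cassette is a stop-free codon multiple carrying all copies", {
  series <- tt_all_series()[["V5"]]
  for (s in series) {
    orf <- multimer_orf(s)
    expect_equal(nchar(orf) %% 3L, 0L)
    pep <- translate_dna(orf)
    expect_false(grepl("*", pep, fixed = TRUE))
    expect_equal(count_nonoverlap(pep, paste0(s$tag$peptide,
                                              s$linker_peptide)),
                 s$copy_number)
    # the cassette ends inside the NotI motif, in frame for C-terminal fusion
    expect_equal(substr(orf, nchar(orf) - 5L, nchar(orf)), "GCGGCC")
  }
})

test_that("the catalog enumerates tag x level pairs and applies exclusions", {
  cat29 <- enumerate_catalog(default_tags(), rounds = 4L,
                             exclusions = list(list(
                               tag = "HA", copy_number = 80L,
                               reason = "not obtained")))
  expect_equal(nrow(cat29), 30L)
  expect_equal(sort(unique(cat29$copy_number)), c(5L, 10L, 20L, 40L, 80L))
  expect_equal(attr(cat29, "n_built"), 29L)
  ex <- cat29[cat29$status == "excluded", ]
  expect_equal(nrow(ex), 1L)
  expect_equal(unname(ex$tag), "HA")
  expect_equal(ex$copy_number, 80L)
  expect_equal(ex$reason, "not obtained")
  expect_equal(attr(enumerate_catalog(default_tags(), rounds = 4L),
                    "n_built"), 30L)

  # with a backbone the built entries are actually constructed
  small <- enumerate_catalog(list(tt_toy_tag()), rounds = 1L,
                             backbone = tt_backbone())
  built <- attr(small, "constructs")
  expect_length(built, 2L)
  expect_equal(vapply(built, `[[`, integer(1), "copy_number"),
               c("5XTOY" = 5L, "10XTOY" = 10L))
})

test_that("stability heuristics warn above 20X and at 80X, never error", {
  series <- tt_all_series()[["V5"]]
  expect_length(stability_warnings(series[[1]]), 0L)   # 5X
  expect_length(stability_warnings(series[[3]]), 0L)   # 20X (inclusive bound)
  w40 <- stability_warnings(series[[4]])
  expect_length(w40, 1L)
  expect_match(w40, "rule: copy_gt_20", fixed = TRUE)
  w80 <- stability_warnings(series[[5]])
  expect_length(w80, 2L)
  expect_match(w80[2], "rule: copy_ge_80", fixed = TRUE)
  w_span <- stability_warnings(series[[5]], max_span_nt = 4000L)
  expect_length(w_span, 3L)
  expect_match(w_span[3], "rule: span_gt_4000", fixed = TRUE)
})
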