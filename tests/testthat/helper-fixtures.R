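## Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tt_enzymes <- function() memo("enzymes", default_enzymes())

tt_backbone <- function() {
  memo("backbone", generate_backbone(2600L, seed = 101L))
}

tt_toy_tag <- function() epitope_tag("TOY", "ACDEK")

## Full 6-tag x 5-level protocol series, keyed by tag name.
tt_all_series <- function() {
  memo("all_series", {
    bb <- tt_backbone()
    lapply(default_tags(), function(tg) run_protocol(tg, bb, rounds = 4L))
  })
}

tt_toy_series <- function(rounds = 2L) {
  memo(paste0("toy_series_", rounds),
       run_protocol(tt_toy_tag(), tt_backbone(), rounds = rounds))
}

## Independent naive oracle for find_sites: O(n*m) window scan over the
## doubled string with explicit IUPAC sets.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_sites <- function(bases, motif, circular = FALSE) {
  n <- nchar(bases)
  m <- nchar(motif)
  if (n < m) return(integer(0))
  subject <- if (circular) paste0(bases, substr(bases, 1L, m - 1L)) else bases
  sub_chars <- strsplit(subject, "")[[1]]
  motif_sets <- IUPAC_SETS[strsplit(motif, "")[[1]]]
  hits <- integer(0)
  for (i in 0:(nchar(subject) - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!(sub_chars[i + j] %in% motif_sets[[j]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  if (circular) hits <- hits %% n
  sort(unique(hits))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Random circular plasmid carrying exactly one site for each of two enzymes.
random_two_cutter_plasmid <- function(e1, e2, min_len = 120L, max_len = 400L) {
  repeat {
    n <- sample(min_len:max_len, 1L)
    gap1 <- sample(30:(n - 60L), 1L)
    b <- paste0(e1$recognition, random_dna(gap1), e2$recognition,
                random_dna(n - gap1))
    d <- dna(b, "circular")
    if (length(find_sites(d, e1)) == 1L && length(find_sites(d, e2)) == 1L) {
      return(d)
    }
  }
}

is_rotation <- function(a, b) {
  nchar(a) == nchar(b) && grepl(b, paste0(a, a), fixed = TRUE)
}

## Small hand-made gene: exon1(utr5+cds1) -- intron -- exon2(cds2+utr3).
make_two_exon_gene <- function(cds1_codons, cds2_codons, intron_len = 300L,
                               utr5 = 10L, utr3 = 10L, intron_fill = "C") {
  cds1 <- paste(cds1_codons, collapse = "")
  cds2 <- paste(cds2_codons, collapse = "")
  intron <- paste0("GT", strrep(intron_fill, intron_len - 4L), "AG")
  seqs <- paste0(strrep("A", utr5), cds1, intron, cds2, strrep("A", utr3))
  e1 <- c(0L, utr5 + nchar(cds1))
  e2 <- c(e1[2] + intron_len, e1[2] + intron_len + nchar(cds2) + utr3)
  gene_model(seqs, rbind(e1, e2), utr5, e2[1] + nchar(cds2))
}

tt_rt <- "ACGTTCGGAATCCTATGACCGGATAACGCA"
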