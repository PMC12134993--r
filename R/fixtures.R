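#' Generate a synthetic site-free plasmid backbone
#'
#' Random circular backbone (default 2.6 kb, the size class of small
#' high-copy synthesis vectors) guaranteed free of every supplied enzyme
#' site by rejection sampling with local repair: any residual site has one of
#' its bases resampled until the census is all zero.  Reproducible for a
#' given seed.
#'
#' @param length backbone length in nt (>= 1000).
#' @param gc GC fraction of the sampler.
#' @param enzymes enzymes whose sites are forbidden (set to `list()` to skip
#'   the guarantee).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param max_iter repair budget.
#' @return circular `dna_seq`.
#' @export
generate_backbone <- function(length = 2600L, gc = 0.5,
                              enzymes = default_enzymes(), seed = NULL,
                              max_iter = 100L) {
  if (length < 1000L) stop("backbone length must be >= 1000 nt")
  gen <- function() {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    b <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
    for (iter in seq_len(max_iter)) {
      seqd <- dna(b, "circular")
      dirty <- FALSE
      for (e in enzymes) {
        for (s in find_sites(seqd, e)) {
          dirty <- TRUE
          off <- (s + sample.int(nchar(e$recognition), 1L) - 1L) %% length
          old <- circ_substr(b, off, 1L)
          new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          substr(b, off + 1L, off + 1L) <- new
        }
      }
      if (!dirty) return(dna(b, "circular"))
    }
    stop("could not generate a site-free backbone within the repair budget")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

#' Generate a toy gene model
#'
#' Multi-exon gene with a random stop-free coding sequence (ATG ... TAA),
#' canonical GT..AG introns, and short UTRs; satisfies every [gene_model()]
#' invariant.  CDS splits fall at codon boundaries, so the stop codon always
#' sits whole in the last exon.  Reproducible for a given seed.
#'
#' @param n_exons number of exons (>= 1).
#' @param cds_codons number of internal codons between ATG and TAA.
#' @param intron_length length of each intron (>= 20).
#' @param utr5,utr3 UTR lengths.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [gene_model()].
#' @export
generate_toy_gene <- function(n_exons = 3L, cds_codons = 60L,
                              intron_length = 300L, utr5 = 30L, utr3 = 30L,
                              seed = NULL) {
  stopifnot(n_exons >= 1L, cds_codons >= n_exons * 4L, intron_length >= 20L)
  gen <- function() {
    rand <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
    cds <- paste0("ATG",
                  paste(sample(SENSE_CODONS, cds_codons, replace = TRUE),
                        collapse = ""), "TAA")
    total_codons <- nchar(cds) %/% 3L
    # split at codon boundaries; every chunk >= 2 codons
    if (n_exons > 1L) {
      splits <- sort(sample(seq.int(2L, total_codons - 2L),
                            n_exons - 1L)) * 3L
    } else splits <- integer(0)
    bounds <- c(0L, splits, nchar(cds))
    chunks <- vapply(seq_len(n_exons), function(i) {
      substr(cds, bounds[i] + 1L, bounds[i + 1L])
    }, character(1))
    introns <- vapply(seq_len(max(n_exons - 1L, 0L)), function(i) {
      paste0("GT", rand(intron_length - 4L), "AG")
    }, character(1))
    seq_parts <- character(0)
    exons <- matrix(integer(0), ncol = 2L)
    pos <- 0L
    for (i in seq_len(n_exons)) {
      exon_seq <- chunks[i]
      if (i == 1L) exon_seq <- paste0(rand(utr5), exon_seq)
      if (i == n_exons) exon_seq <- paste0(exon_seq, rand(utr3))
      exons <- rbind(exons, c(pos, pos + nchar(exon_seq)))
      seq_parts <- c(seq_parts, exon_seq)
      pos <- pos + nchar(exon_seq)
      if (i < n_exons) {
        seq_parts <- c(seq_parts, introns[i])
        pos <- pos + nchar(introns[i])
      }
    }
    cds_start <- utr5
    cds_end <- pos - if (n_exons >= 1L) utr3 else 0L
    gene_model(paste(seq_parts, collapse = ""), exons, cds_start, cds_end)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate the bundled toy fixtures
#'
#' Stands in for a small synthesis vector and a genomic locus: a site-free
#' circular backbone plus a toy multi-exon gene model, both reproducible for
#' a given seed.
#'
#' @param backbone_length backbone length (>= 1000 nt).
#' @param gc backbone GC fraction.
#' @param site_free enforce the forbidden-site-free guarantee.
#' @param enzymes enzymes used for the guarantee.
#' @param n_exons,cds_codons,intron_length toy gene layout.
#' @param seed integer seed.
#' @return list with elements `backbone` (circular `dna_seq`) and `gene`
#'   (a `gene_model`).
#' @export
generate_fixture <- function(backbone_length = 2600L, gc = 0.5,
                             site_free = TRUE, enzymes = default_enzymes(),
                             n_exons = 3L, cds_codons = 60L,
                             intron_length = 300L, seed = 1L) {
  withr::with_seed(seed, {
    list(backbone = generate_backbone(backbone_length, gc,
                                      if (site_free) enzymes else list(),
                                      seed = NULL),
         gene = generate_toy_gene(n_exons = n_exons, cds_codons = cds_codons,
                                  intron_length = intron_length, seed = NULL))
  })
}

#' Predict diagnostic digest bands
#'
#' Digests a construct's plasmid and returns the band table sorted by
#' descending length, each band labelled `insert` (carries the repeat unit)
#' or `backbone` -- the machine-readable analog of a diagnostic agarose gel.
#' An enzyme set that does not cut returns a single `uncut` row.  Over the
#' protocol rounds the XhoI/NotI insert band grows strictly and its increment
#' doubles each round.
#'
#' @param c a `multimer_construct`.
#' @param enzymes list of enzymes for the digest (e.g. XhoI + NotI).
#' @return data frame with columns `band`, `length`, `label`.
#' @export
predict_gel <- function(c, enzymes) {
  stopifnot(inherits(c, "multimer_construct"))
  d <- digest(c$plasmid, enzymes)
  if (inherits(d, "uncut_digest")) {
    return(data.frame(band = 1L, length = dna_length(c$plasmid),
                      label = "uncut", stringsAsFactors = FALSE))
  }
  lens <- vapply(d, fragment_length, integer(1))
  labs <- vapply(d, function(f) {
    if (grepl(c$repeat_unit, fragment_top(f), fixed = TRUE)) "insert"
    else "backbone"
  }, character(1))
  ord <- order(-lens)
  data.frame(band = seq_along(ord), length = lens[ord], label = labs[ord],
             stringsAsFactors = FALSE)
}
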