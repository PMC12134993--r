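#' Gene model
#'
#' A linear genomic sequence (top strand = coding strand) with an ordered
#' exon structure and CDS boundaries.  All coordinates are 0-based half-open.
#' Invariants enforced at construction: exons are non-overlapping and
#' ascending, the CDS lies within the exon union, the spliced CDS length is a
#' multiple of 3 and ends with a stop codon, and the stop codon is contained
#' in a single exon.
#'
#' @param sequence a linear `dna_seq` or character string.
#' @param exons two-column matrix or data frame of half-open `start`, `end`
#'   intervals.
#' @param cds_start,cds_end genomic CDS boundaries (half-open).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(sequence, exons, cds_start, cds_end) {
  if (is.character(sequence)) sequence <- dna(sequence, "linear")
  stopifnot(inherits(sequence, "dna_seq"), !is_circular(sequence))
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  colnames(exons) <- c("start", "end")
  storage.mode(exons) <- "integer"
  if (any(exons[, "end"] <= exons[, "start"])) stop("empty exon interval")
  if (nrow(exons) > 1L) {
    if (any(diff(exons[, "start"]) <= 0) ||
        any(exons[-1L, "start"] < exons[-nrow(exons), "end"])) {
      stop("exons must be ascending and non-overlapping")
    }
  }
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  g <- structure(list(sequence = sequence, exons = exons,
                      cds_start = cds_start, cds_end = cds_end),
                 class = "gene_model")
  ivs <- cds_intervals(g)
  if (!length(ivs)) stop("CDS does not overlap any exon")
  covered <- sum(vapply(ivs, function(iv) iv[2] - iv[1], integer(1)))
  in_exon <- function(p) any(exons[, "start"] <= p & p < exons[, "end"])
  if (!in_exon(cds_start) || !in_exon(cds_end - 1L)) {
    stop("CDS boundaries must fall inside exons")
  }
  if (covered %% 3L != 0L) stop("spliced CDS length is not a codon multiple")
  last <- ivs[[length(ivs)]]
  if (last[2] - last[1] < 3L) {
    stop("stop codon split across a splice junction is not supported")
  }
  cds <- spliced_cds(g)
  if (!substr(cds, nchar(cds) - 2L, nchar(cds)) %in% c("TAA", "TAG", "TGA")) {
    stop("spliced CDS does not end with a stop codon")
  }
  g
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %d nt, %d exons, CDS %d..%d\n",
              dna_length(x$sequence), nrow(x$exons), x$cds_start, x$cds_end))
  invisible(x)
}

#' @rdname gene_model
#' @param gene a `gene_model`.
#' @export
cds_intervals <- function(gene) {
  out <- list()
  for (i in seq_len(nrow(gene$exons))) {
    s <- max(gene$exons[i, "start"], gene$cds_start)
    e <- min(gene$exons[i, "end"], gene$cds_end)
    if (e > s) out[[length(out) + 1L]] <- c(s, e)
  }
  out
}

#' @rdname gene_model
#' @export
spliced_cds <- function(gene) {
  b <- gene$sequence$bases
  paste(vapply(cds_intervals(gene),
               function(iv) substr(b, iv[1] + 1L, iv[2]), character(1)),
        collapse = "")
}

#' @rdname gene_model
#' @export
gene_translation <- function(gene) translate_dna(spliced_cds(gene), 0L)

#' @rdname gene_model
#' @param index 1-based intron index.
#' @export
intron_interval <- function(gene, index) {
  k <- nrow(gene$exons) - 1L
  if (index < 1L || index > k) stop("intron index out of range (gene has ",
                                    k, " introns)")
  c(gene$exons[index, "end"], gene$exons[index + 1L, "start"])
}

## Shift all gene-model coordinates at/after an insertion point.
shift_gene_model <- function(gene, at, by) {
  ex <- gene$exons
  ex[, "start"] <- ifelse(ex[, "start"] >= at, ex[, "start"] + by,
                          ex[, "start"])
  ex[, "end"] <- ifelse(ex[, "end"] > at, ex[, "end"] + by, ex[, "end"])
  list(exons = ex,
       cds_start = if (gene$cds_start >= at) gene$cds_start + by
       else gene$cds_start,
       cds_end = if (gene$cds_end > at) gene$cds_end + by else gene$cds_end)
}

insert_into <- function(bases, at, what) {
  paste0(substr(bases, 1L, at), what, substr(bases, at + 1L, nchar(bases)))
}

#' Fuse an in-frame tag cassette onto the carboxy-terminus
#'
#' Inserts `insert_dna` immediately 5' of the stop codon, so the spliced CDS
#' translation becomes the original translation followed by the insert
#' translation, with the original stop codon retained.  Downstream coordinates
#' shift by the insert length.  The insert must be a codon multiple with no
#' in-frame stop.
#'
#' @param gene a `gene_model`.
#' @param insert_dna DNA string (e.g. from [multimer_orf()]).
#' @return the edited `gene_model`, carrying the inserted interval in
#'   attribute `tag_insert`.
#' @export
fuse_cterminal_tag <- function(gene, insert_dna) {
  stopifnot(inherits(gene, "gene_model"))
  insert_dna <- toupper(insert_dna)
  if (!nzchar(insert_dna)) return(gene)
  if (nchar(insert_dna) %% 3L != 0L) {
    stop("insert length must be a multiple of 3")
  }
  if (grepl("*", translate_dna(insert_dna, 0L), fixed = TRUE)) {
    stop("insert contains an in-frame stop codon")
  }
  at <- gene$cds_end - 3L  # immediately 5' of the stop codon
  b <- insert_into(gene$sequence$bases, at, insert_dna)
  sh <- shift_gene_model(gene, at, nchar(insert_dna))
  out <- gene_model(b, sh$exons, sh$cds_start, sh$cds_end)
  attr(out, "tag_insert") <- c(at, at + nchar(insert_dna))
  out
}

#' Conditional knock-in donor design
#'
#' Places a STOP cassette flanked by two direct-repeat recombinase target
#' (RT) sites inside the chosen intron, by default at the intron midpoint and
#' at a configurable minimum distance from both splice sites.  Exon sequences
#' and the splice dinucleotides are untouched, so the spliced CDS is identical
#' before excision (the cassette's transcriptional STOP mechanism is not
#' modeled).  The RT site must not occur anywhere else in the gene (on either
#' strand) or later excision would be ambiguous.
#'
#' @param gene a `gene_model` (optionally already tag-fused).
#' @param intron_index 1-based intron index (between exons `i` and `i + 1`).
#' @param cassette STOP cassette DNA (opaque, user-supplied).
#' @param rt_site recombinase target site DNA.
#' @param at optional insertion point within the intron (0-based genomic);
#'   defaults to the intron midpoint.
#' @param min_splice_dist minimum distance from both splice sites (default
#'   50 nt).
#' @param arm_length homology-arm length recorded on each side of the edited
#'   region (default 1000 nt, clipped at the sequence ends).
#' @return an object of class `donor_design` with fields `gene`, `tag_insert`,
#'   `cassette_insert`, `rt_sites`, `rt_seq`, `pam_edits`, `homology_arms`.
#' @export
insert_conditional_cassette <- function(gene, intron_index, cassette, rt_site,
                                        at = NULL, min_splice_dist = 50L,
                                        arm_length = 1000L) {
  stopifnot(inherits(gene, "gene_model"))
  cassette <- toupper(cassette)
  rt_site <- toupper(rt_site)
  if (!nzchar(cassette) || !nzchar(rt_site)) {
    stop("cassette and rt_site must be non-empty")
  }
  b <- gene$sequence$bases
  if (grepl(rt_site, b, fixed = TRUE) ||
      grepl(reverse_complement(rt_site), b, fixed = TRUE)) {
    stop("rt_site already occurs in the gene; excision would be ambiguous")
  }
  iv <- intron_interval(gene, intron_index)
  if (is.null(at)) at <- iv[1] + (iv[2] - iv[1]) %/% 2L
  at <- as.integer(at)
  if (at - iv[1] < min_splice_dist || iv[2] - at < min_splice_dist) {
    stop("intron too short: insertion point must be >= ", min_splice_dist,
         " nt from both splice sites")
  }
  r <- nchar(rt_site)
  k <- nchar(cassette)
  payload <- paste0(rt_site, cassette, rt_site)
  b2 <- insert_into(b, at, payload)
  sh <- shift_gene_model(gene, at, nchar(payload))
  edited <- gene_model(b2, sh$exons, sh$cds_start, sh$cds_end)

  tag_iv <- attr(gene, "tag_insert")
  if (!is.null(tag_iv) && tag_iv[1] >= at) tag_iv <- tag_iv + nchar(payload)
  rt1 <- c(at, at + r)
  rt2 <- c(at + r + k, at + r + k + r)
  edits <- list(rt1[1], rt2[2])
  if (!is.null(tag_iv)) edits <- c(edits, list(tag_iv[1], tag_iv[2]))
  first <- min(unlist(edits))
  last <- max(unlist(edits))
  arms <- rbind(c(max(0L, first - arm_length), first),
                c(last, min(nchar(b2), last + arm_length)))
  colnames(arms) <- c("start", "end")

  structure(list(gene = edited,
                 tag_insert = tag_iv,
                 cassette_insert = c(at + r, at + r + k),
                 rt_sites = rbind(rt1, rt2),
                 rt_seq = rt_site,
                 pam_edits = data.frame(position = integer(0),
                                        old = character(0),
                                        new = character(0),
                                        synonymous = logical(0),
                                        fallback = logical(0),
                                        guide = character(0)),
                 homology_arms = arms),
            class = "donor_design")
}

#' @export
print.donor_design <- function(x, ...) {
  cat(sprintf(
    "<donor_design> %d nt; cassette %d..%d; %d RT sites; %d PAM edits\n",
    dna_length(x$gene$sequence), x$cassette_insert[1], x$cassette_insert[2],
    nrow(x$rt_sites), nrow(x$pam_edits)))
  invisible(x)
}

locate_rt_sites <- function(design) {
  b <- design$gene$sequence$bases
  m <- gregexpr(design$rt_seq, b, fixed = TRUE)[[1]]
  fwd <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  mr <- gregexpr(reverse_complement(design$rt_seq), b, fixed = TRUE)[[1]]
  rev <- if (mr[1] == -1L) integer(0) else as.integer(mr) - 1L
  list(fwd = fwd, rev = rev)
}

#' Simulate recombinase excision
#'
#' Removes the sequence between the two direct-repeat RT sites together with
#' one RT copy, leaving a single RT scar; the excised length equals cassette
#' length + RT length and the spliced CDS translation is unchanged.  Exactly
#' two identical direct-repeat sites are required: zero or one site (e.g. a
#' second call on an already-excised design) is an error, as are
#' inverted-orientation sites (only excision is modeled, not inversion).
#'
#' @param design a `donor_design`.
#' @return the excised genomic `dna_seq`, with attributes `gene_model` (the
#'   coordinate-shifted model) and `excised_length`.
#' @seealso [excised_design()] for a `donor_design`-returning variant.
#' @export
simulate_excision <- function(design) {
  stopifnot(inherits(design, "donor_design"))
  hits <- locate_rt_sites(design)
  if (length(hits$fwd) + length(hits$rev) < 2L) {
    stop("excision requires two RT sites; found ",
         length(hits$fwd) + length(hits$rev))
  }
  if (length(hits$rev) > 0L && length(hits$fwd) > 0L) {
    stop("RT sites are in inverted orientation; only excision of ",
         "direct repeats is modeled")
  }
  pos <- if (length(hits$fwd)) hits$fwd else hits$rev
  if (length(pos) != 2L) stop("expected exactly two RT sites, found ",
                              length(pos))
  r <- nchar(design$rt_seq)
  from <- pos[1] + r       # keep the first RT copy
  to <- pos[2] + r         # drop cassette + second copy
  b <- design$gene$sequence$bases
  b2 <- paste0(substr(b, 1L, from), substr(b, to + 1L, nchar(b)))
  g <- design$gene
  sh <- list(exons = g$exons, cds_start = g$cds_start, cds_end = g$cds_end)
  removed <- to - from
  sh$exons[, "start"] <- ifelse(sh$exons[, "start"] >= to,
                                sh$exons[, "start"] - removed,
                                sh$exons[, "start"])
  sh$exons[, "end"] <- ifelse(sh$exons[, "end"] >= to,
                              sh$exons[, "end"] - removed, sh$exons[, "end"])
  if (sh$cds_start >= to) sh$cds_start <- sh$cds_start - removed
  if (sh$cds_end >= to) sh$cds_end <- sh$cds_end - removed
  model <- gene_model(b2, sh$exons, sh$cds_start, sh$cds_end)
  out <- dna(b2, "linear")
  attr(out, "gene_model") <- model
  attr(out, "excised_length") <- removed
  out
}

#' @rdname simulate_excision
#' @export
excised_design <- function(design) {
  out <- simulate_excision(design)
  design$gene <- attr(out, "gene_model")
  removed <- attr(out, "excised_length")
  shift_iv <- function(iv, cutoff) {
    if (is.null(iv)) return(NULL)
    ifelse(iv >= cutoff, iv - removed, iv)
  }
  cutoff <- design$rt_sites[2, 2]
  design$cassette_insert <- NULL
  design$rt_sites <- design$rt_sites[1, , drop = FALSE]
  design$tag_insert <- shift_iv(design$tag_insert, cutoff)
  design$homology_arms[, ] <- vapply(design$homology_arms,
                                     function(p) if (p >= cutoff) p - removed
                                     else p, numeric(1))
  design
}

#' Guide RNA spacer
#'
#' @param spacer protospacer DNA, 17-20 nt (the published guides are 18-mers).
#' @param pam PAM motif (default `"NGG"`).
#' @return an object of class `guide_spacer`.
#' @export
guide_spacer <- function(spacer, pam = "NGG") {
  spacer <- toupper(spacer)
  if (nchar(spacer) < 17L || nchar(spacer) > 20L) {
    stop("spacer length must be between 17 and 20 nt")
  }
  if (grepl("[^ACGT]", spacer)) stop("spacer must be plain A/C/G/T")
  structure(list(spacer = spacer, pam = toupper(pam)),
            class = "guide_spacer")
}

in_arms <- function(p, arms) {
  any(arms[, "start"] <= p & p < arms[, "end"])
}

genomic_to_cds_index <- function(gene, pos) {
  off <- 0L
  for (iv in cds_intervals(gene)) {
    if (pos >= iv[1] && pos < iv[2]) return(off + (pos - iv[1]))
    off <- off + (iv[2] - iv[1])
  }
  NA_integer_
}

## Would substituting `base` at genomic `pos` leave the CDS translation
## unchanged?  Returns NA if pos is not in the CDS.
is_synonymous_sub <- function(gene, pos, base) {
  ci <- genomic_to_cds_index(gene, pos)
  if (is.na(ci)) return(NA)
  cds <- spliced_cds(gene)
  cstart <- (ci %/% 3L) * 3L
  codon <- substr(cds, cstart + 1L, cstart + 3L)
  new_codon <- codon
  substr(new_codon, ci - cstart + 1L, ci - cstart + 1L) <- base
  identical(Biostrings::GENETIC_CODE[[codon]],
            Biostrings::GENETIC_CODE[[new_codon]])
}

## Exact matches of a spacer in the sequence restricted to the homology arms;
## returns data.frame(pos, strand) where pos is the top-strand start.
guide_matches <- function(design, guide) {
  b <- design$gene$sequence$bases
  find_all <- function(pat) {
    m <- gregexpr(pat, b, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  }
  fwd <- find_all(guide$spacer)
  rev <- find_all(reverse_complement(guide$spacer))
  keep_arm <- function(pp) pp[vapply(pp, in_arms, logical(1),
                                     arms = design$homology_arms)]
  data.frame(pos = c(keep_arm(fwd), keep_arm(rev)),
             strand = c(rep("+", length(keep_arm(fwd))),
                        rep("-", length(keep_arm(rev)))),
             stringsAsFactors = FALSE)
}

## PAM guanine positions (the two bases that must not both remain G-paired)
## for a match; returns genomic positions of the two critical bases and the
## base that makes the PAM functional there.
pam_critical <- function(match_pos, strand, spacer_len) {
  if (strand == "+") {
    list(pos = c(match_pos + spacer_len + 1L, match_pos + spacer_len + 2L),
         functional_base = "G")
  } else {
    list(pos = c(match_pos - 2L, match_pos - 3L), functional_base = "C")
  }
}

pam_functional <- function(bases, match_pos, strand, spacer_len) {
  pc <- pam_critical(match_pos, strand, spacer_len)
  if (any(pc$pos < 0L) || any(pc$pos >= nchar(bases))) return(FALSE)
  all(substring(bases, pc$pos + 1L, pc$pos + 1L) == pc$functional_base)
}

#' Mutate PAM sites in the homology arms
#'
#' For each guide, the unique protospacer match in the homology arms is found
#' (either strand) and the adjacent NGG PAM is disrupted by a single-base
#' change.  When the PAM lies in coding sequence the change must be
#' synonymous; if no synonymous PAM break exists, a synonymous seed-region
#' substitution inside the protospacer is made instead and recorded as a
#' fallback.  After editing, every guide is re-scanned and must retain no
#' match with a functional adjacent PAM.
#'
#' @param design a `donor_design`.
#' @param guides list of [guide_spacer()] objects.
#' @return the edited `donor_design` with `pam_edits` filled in.
#' @export
mutate_pams <- function(design, guides) {
  stopifnot(inherits(design, "donor_design"))
  if (inherits(guides, "guide_spacer")) guides <- list(guides)
  for (guide in guides) {
    stopifnot(inherits(guide, "guide_spacer"))
    hits <- guide_matches(design, guide)
    if (nrow(hits) != 1L) {
      stop("guide ", guide$spacer, " matches the homology arms ",
           nrow(hits), " times (exactly one match required)")
    }
    b <- design$gene$sequence$bases
    L <- nchar(guide$spacer)
    if (!pam_functional(b, hits$pos, hits$strand, L)) next  # nothing to break
    pc <- pam_critical(hits$pos, hits$strand, L)

    edit <- NULL
    for (p in pc$pos) {
      old <- substring(b, p + 1L, p + 1L)
      for (base in setdiff(c("A", "C", "G", "T"), c(old, pc$functional_base))) {
        syn <- is_synonymous_sub(design$gene, p, base)
        if (is.na(syn) || isTRUE(syn)) {
          edit <- list(pos = p, old = old, new = base,
                       synonymous = isTRUE(syn), fallback = FALSE)
          break
        }
      }
      if (!is.null(edit)) break
    }
    if (is.null(edit)) {
      # fallback: synonymous change inside the protospacer, seed-proximal end
      # first (positions nearest the PAM)
      span <- hits$pos + 0:(L - 1L)
      ordered <- if (hits$strand == "+") rev(span) else span
      for (p in ordered) {
        old <- substring(b, p + 1L, p + 1L)
        for (base in setdiff(c("A", "C", "G", "T"), old)) {
          if (isTRUE(is_synonymous_sub(design$gene, p, base))) {
            edit <- list(pos = p, old = old, new = base,
                         synonymous = TRUE, fallback = TRUE)
            break
          }
        }
        if (!is.null(edit)) break
      }
    }
    if (is.null(edit)) {
      stop("no synonymous disruption found for guide ", guide$spacer,
           " anywhere in spacer + PAM within the CDS")
    }
    substr(b, edit$pos + 1L, edit$pos + 1L) <- edit$new
    g <- design$gene
    design$gene <- gene_model(b, g$exons, g$cds_start, g$cds_end)
    attr(design$gene, "tag_insert") <- attr(g, "tag_insert")
    design$pam_edits <- rbind(design$pam_edits, data.frame(
      position = edit$pos, old = edit$old, new = edit$new,
      synonymous = edit$synonymous, fallback = edit$fallback,
      guide = guide$spacer, stringsAsFactors = FALSE))
  }
  # completeness re-scan
  b <- design$gene$sequence$bases
  for (guide in guides) {
    hits <- guide_matches(design, guide)
    for (i in seq_len(nrow(hits))) {
      if (pam_functional(b, hits$pos[i], hits$strand[i],
                         nchar(guide$spacer))) {
        stop("guide ", guide$spacer,
             " still has a match with a functional PAM after editing")
      }
    }
  }
  design
}
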