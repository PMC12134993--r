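#' Epitope tag
#'
#' A short peptide (5-30 residues, no stop symbol) recognized by a
#' well-characterized antibody.  The six tag peptides shipped with the package
#' (V5, HA, MYC, FLAG, ALFA, OLLAS) are standard published sequences stored as
#' editable config data, not constants; see [default_tags()].
#'
#' @param name tag name.
#' @param peptide single-letter amino-acid string.
#' @return an object of class `epitope_tag`.
#' @export
epitope_tag <- function(name, peptide) {
  peptide <- toupper(peptide)
  stopifnot(is.character(name), nzchar(name))
  if (nchar(peptide) < 5L || nchar(peptide) > 30L) {
    stop("tag peptide must be 5-30 residues")
  }
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", peptide)) {
    stop("tag peptide contains an invalid residue (stops are not allowed)")
  }
  structure(list(name = name, peptide = peptide), class = "epitope_tag")
}

#' Load the bundled epitope tag peptides
#'
#' @param path tab-separated file with columns `name` and `peptide`.
#' @return named list of [epitope_tag()] objects.
#' @export
default_tags <- function(path = system.file("extdata", "tags.tsv",
                                            package = "tandemtag")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tags <- lapply(seq_len(nrow(tab)),
                 function(i) epitope_tag(tab$name[i], tab$peptide[i]))
  stats::setNames(tags, tab$name)
}

#' Load a codon usage table
#'
#' Tab-separated file with columns `codon` and `per_mille`.  The amino acid of
#' each codon is derived from the standard genetic code.  The bundled default
#' holds approximate Drosophila melanogaster frequencies; only the ranking of
#' synonymous codons matters for the deterministic greedy chooser.
#'
#' @param path path to the table; defaults to the bundled Drosophila table.
#' @return data frame with columns `codon`, `aa`, `per_mille`, sorted by
#'   amino acid then descending frequency.
#' @export
load_codon_usage <- function(path = system.file("extdata",
                                                "codon_usage_dmel.tsv",
                                                package = "tandemtag")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$codon <- toupper(tab$codon)
  tab$aa <- unname(Biostrings::GENETIC_CODE[tab$codon])
  if (anyNA(tab$aa)) stop("codon usage table contains an invalid codon")
  tab <- tab[order(tab$aa, -tab$per_mille), ]
  rownames(tab) <- NULL
  tab
}

## Synonymous codons for a residue, most frequent first.
codons_for <- function(aa, usage) usage$codon[usage$aa == aa]

forbidden_hits <- function(s, enzymes) {
  d <- dna(s, "linear")
  hits <- list()
  for (e in enzymes) {
    for (p in find_sites(d, e)) {
      hits[[length(hits) + 1L]] <- list(enzyme = e$name, pos = p,
                                        len = nchar(e$recognition))
    }
  }
  hits
}

#' Reverse-translate a tag + linker repeat unit avoiding forbidden sites
#'
#' Designs the DNA of one repeat unit (tag peptide followed by the flexible
#' linker, GSGG by default) by deterministic greedy codon choice -- the most
#' frequent codon per residue from the usage table -- with bounded
#' backtracking over synonymous swaps to eliminate any match to the forbidden
#' enzyme motifs.  Because tandem repeats create junction sites that a
#' single-unit scan misses, the unit concatenated with itself is scanned as
#' well (mandatory self-concatenation check).
#'
#' @param tag an [epitope_tag()].
#' @param linker_peptide linker residues appended after the tag
#'   (default `"GSGG"`, a 4-residue flexible linker, 12 nt per unit).
#' @param usage codon usage table from [load_codon_usage()].
#' @param forbidden list of `restriction_enzyme` objects whose motifs must not
#'   occur in the unit or across its self-junction.
#' @param max_iter backtracking budget.
#' @return repeat-unit DNA string of length `3 * (nchar(tag$peptide) +
#'   nchar(linker_peptide))`, with the chosen codons as attribute `codons`.
#' @export
reverse_translate_unit <- function(tag, linker_peptide = "GSGG",
                                   usage = load_codon_usage(),
                                   forbidden = default_enzymes(),
                                   max_iter = 200L) {
  stopifnot(inherits(tag, "epitope_tag"))
  peptide <- paste0(tag$peptide, toupper(linker_peptide))
  residues <- strsplit(peptide, "")[[1]]
  choices <- lapply(residues, codons_for, usage = usage)
  if (any(lengths(choices) == 0L)) {
    stop("codon table does not cover residue ",
         residues[which(lengths(choices) == 0L)[1]])
  }
  codons <- vapply(choices, `[`, character(1), 1L)
  ncod <- length(codons)

  for (iter in seq_len(max_iter)) {
    unit <- paste(codons, collapse = "")
    hits <- forbidden_hits(paste0(unit, unit), forbidden)
    if (!length(hits)) {
      return(structure(unit, codons = codons))
    }
    hit <- hits[[1]]
    # codon indices (in the single unit) overlapped by this hit
    span <- seq.int(hit$pos, hit$pos + hit$len - 1L)
    idx <- sort(unique((span %/% 3L) %% ncod)) + 1L
    swapped <- FALSE
    for (i in idx) {
      alts <- setdiff(choices[[i]], codons[i])
      for (alt in rev(alts)) {  # rarest-first: least disruptive to retry order
        trial <- codons
        trial[i] <- alt
        tu <- paste(trial, collapse = "")
        if (length(forbidden_hits(paste0(tu, tu), forbidden)) <
            length(hits)) {
          codons <- trial
          swapped <- TRUE
          break
        }
      }
      if (swapped) break
    }
    if (!swapped) {
      stop("no codon assignment avoids the forbidden motif ",
           hit$enzyme, " (irreducible at unit position ", hit$pos, ")")
    }
  }
  stop("codon search budget exhausted without a clean unit")
}

## Locate the AscI..NotI insert span: c(asc_start, notI_end), possibly
## wrapping.  Requires exactly one site each.
locate_span <- function(plasmid, enzymes) {
  a <- find_sites(plasmid, enzymes$AscI)
  n2 <- find_sites(plasmid, enzymes$NotI)
  if (length(a) != 1L || length(n2) != 1L) {
    stop("construct must carry exactly one AscI and one NotI site")
  }
  c(a, n2 + nchar(enzymes$NotI$recognition))
}

new_multimer_construct <- function(plasmid, repeat_unit, copy_number,
                                   insert_span, backbone_name, tag,
                                   linker_peptide, spacers, enzymes) {
  structure(list(plasmid = plasmid, repeat_unit = repeat_unit,
                 copy_number = copy_number, insert_span = insert_span,
                 backbone_name = backbone_name, tag = tag,
                 linker_peptide = linker_peptide, spacers = spacers,
                 enzymes = enzymes),
            class = "multimer_construct")
}

#' @export
print.multimer_construct <- function(x, ...) {
  cat(sprintf("<multimer_construct> %dX%s on %s (%d bp plasmid, insert span %d..%d)\n",
              x$copy_number, x$tag$name, x$backbone_name,
              dna_length(x$plasmid), x$insert_span[1], x$insert_span[2]))
  invisible(x)
}

## Canonicalize: rotate the circular plasmid so the insert span is interior
## and centred, then locate the span.  The rotation is an explicit
## construction step of the new plasmid, recorded in the returned span.
canonicalize_construct <- function(plasmid, enzymes) {
  n <- dna_length(plasmid)
  a <- find_sites(plasmid, enzymes$AscI)
  n2 <- find_sites(plasmid, enzymes$NotI)
  if (length(a) != 1L || length(n2) != 1L) {
    stop("construct must carry exactly one AscI and one NotI site")
  }
  span_len <- ((n2 + nchar(enzymes$NotI$recognition) - a) %% n + n) %% n
  target <- (n - span_len) %/% 2L
  plasmid <- rotate_dna(plasmid, (a - target) %% n)
  span <- locate_span(plasmid, enzymes)
  list(plasmid = plasmid, insert_span = span)
}

validate_construct <- function(c, check_count = TRUE) {
  census <- unique_site_census(c$plasmid, c$enzymes)
  if (!all(census == 1L)) {
    stop("restriction-site census violated: ",
         paste(names(census), census, sep = "=", collapse = ", "))
  }
  fr <- verify_frame(c)
  if (!fr$ok) {
    bad <- fr$clauses[!fr$clauses$pass, , drop = FALSE]
    stop("frame verification failed: ", paste(bad$clause, collapse = ", "))
  }
  if (check_count && count_repeats(c) != c$copy_number) {
    stop("protein-level repeat count (", count_repeats(c),
         ") disagrees with the recorded copy number (", c$copy_number, ")")
  }
  invisible(c)
}

#' Build a 5X seed construct
#'
#' Lays the synthesis-ready seed architecture into a site-free backbone:
#' `AscI | spacer1 | XhoI | spacer2 | n x repeat unit | spacer3 | SalI |
#' spacer4 | NotI`, with minimal in-frame spacers chosen so that the reading
#' frame anchored one nucleotide before the AscI motif runs without a stop
#' through the whole cassette, places the repeat block at a codon boundary,
#' and stays valid at every doubling round (spacer lengths 2, 1, 2, 1; see
#' the package vignette for the derivation).  The backbone must contain no
#' site for any of the four enzymes.
#'
#' @param tag an [epitope_tag()].
#' @param backbone circular site-free `dna_seq` (e.g. from
#'   [generate_backbone()]).
#' @param n number of tandem repeats in the seed (default 5).
#' @param linker_peptide inter-repeat linker (default `"GSGG"`).
#' @param unit optional precomputed repeat-unit DNA; designed with
#'   [reverse_translate_unit()] when `NULL`.
#' @param enzymes named list holding `AscI`, `XhoI`, `SalI`, `NotI`.
#' @param usage codon usage table for unit design.
#' @param spacers character vector of the four spacer sequences.
#' @param backbone_name label recorded in the construct.
#' @return a `multimer_construct`.
#' @export
build_seed <- function(tag, backbone, n = 5L, linker_peptide = "GSGG",
                       unit = NULL, enzymes = default_enzymes(),
                       usage = load_codon_usage(),
                       spacers = c("GA", "T", "GA", "A"),
                       backbone_name = "backbone") {
  stopifnot(inherits(tag, "epitope_tag"), inherits(backbone, "dna_seq"),
            n >= 1L)
  if (!is_circular(backbone)) stop("backbone must be circular")
  for (e in enzymes) {
    s <- find_sites(backbone, e)
    if (length(s)) {
      stop("backbone contains a ", e$name, " site at position ", s[1])
    }
  }
  if (is.null(unit)) {
    unit <- reverse_translate_unit(tag, linker_peptide, usage, enzymes)
  }
  unit <- as.character(unit)
  region <- paste0(enzymes$AscI$recognition, spacers[1],
                   enzymes$XhoI$recognition, spacers[2],
                   strrep(unit, n), spacers[3],
                   enzymes$SalI$recognition, spacers[4],
                   enzymes$NotI$recognition)
  b <- backbone$bases
  pos <- nchar(b) %/% 2L
  plasmid <- dna(paste0(substr(b, 1L, pos), region,
                        substr(b, pos + 1L, nchar(b))), "circular")
  canon <- canonicalize_construct(plasmid, enzymes)
  cons <- new_multimer_construct(canon$plasmid, unit, as.integer(n),
                                 canon$insert_span, backbone_name, tag,
                                 toupper(linker_peptide), spacers, enzymes)
  validate_construct(cons)
}

#' One doubling round: AscI/XhoI vector + AscI/SalI insert
#'
#' Implements the cloning cycle literally: the construct is digested with
#' AscI + XhoI and the large fragment kept as the vector; a second copy is
#' digested with AscI + SalI and the repeat-bearing fragment (the one carrying
#' the XhoI site) kept as the insert; the two are ligated via the compatible
#' TCGA cohesive ends of XhoI and SalI.  The product carries twice the tandem
#' copies, a hybrid XhoI/SalI junction between the two repeat blocks that
#' neither enzyme recognizes, and the original configuration of unique
#' AscI/XhoI/SalI/NotI sites.
#'
#' @param c a `multimer_construct`.
#' @return the doubled `multimer_construct`.
#' @export
double_round <- function(c) {
  stopifnot(inherits(c, "multimer_construct"))
  enz <- c$enzymes
  d1 <- digest(c$plasmid, list(enz$AscI, enz$XhoI))
  if (inherits(d1, "uncut_digest") || length(d1) != 2L) {
    stop("AscI/XhoI digest did not yield two fragments")
  }
  lens <- vapply(d1, fragment_length, integer(1))
  vec <- d1[[which.max(lens)]]
  d2 <- digest(c$plasmid, list(enz$AscI, enz$SalI))
  if (inherits(d2, "uncut_digest") || length(d2) != 2L) {
    stop("AscI/SalI digest did not yield two fragments")
  }
  has_xho <- vapply(d2, function(f) {
    grepl(enz$XhoI$recognition, fragment_top(f), fixed = TRUE)
  }, logical(1))
  if (sum(has_xho) != 1L) stop("could not identify the repeat-bearing insert")
  ins <- d2[[which(has_xho)]]
  lig <- ligate_circular(vec, ins, enz)
  canon <- canonicalize_construct(lig, enz)
  cons <- new_multimer_construct(canon$plasmid, c$repeat_unit,
                                 2L * c$copy_number, canon$insert_span,
                                 c$backbone_name, c$tag, c$linker_peptide,
                                 c$spacers, enz)
  validate_construct(cons)
}

#' Run the full doubling protocol
#'
#' Builds the seed and applies [double_round()] `rounds` times, returning the
#' whole series (copy numbers 5, 10, 20, 40, 80 for the default 4 rounds).
#'
#' @inheritParams build_seed
#' @param rounds number of doubling rounds (>= 0).
#' @param ... passed to [build_seed()].
#' @return list of `multimer_construct`, seed first.
#' @export
run_protocol <- function(tag, backbone, rounds = 4L, ...) {
  stopifnot(rounds >= 0L)
  out <- vector("list", rounds + 1L)
  out[[1L]] <- build_seed(tag, backbone, ...)
  for (r in seq_len(rounds)) out[[r + 1L]] <- double_round(out[[r]])
  out
}

#' Count tandem repeats in a construct
#'
#' Protein-level count is authoritative: the insert span is translated in the
#' frame anchored one nucleotide before the AscI motif and non-overlapping
#' occurrences of the tag + linker peptide are counted.  The DNA-level count
#' (occurrences of the exact repeat-unit DNA) is reported in the `dna_level`
#' attribute; the two differ when synonymous substitutions are present.
#'
#' @param c a `multimer_construct`.
#' @return integer protein-level count with attribute `dna_level`.
#' @export
count_repeats <- function(c) {
  stopifnot(inherits(c, "multimer_construct"))
  b <- c$plasmid$bases
  a <- c$insert_span[1]
  e <- c$insert_span[2]
  if (a < 1L || e + 1L > nchar(b)) stop("insert span touches the origin")
  if ((e - a + 2L) %% 3L != 0L) {
    stop("insert span frame broken: anchored length not a codon multiple")
  }
  region <- substr(b, a, e + 1L)  # anchor nt .. one nt past NotI
  pep <- translate_dna(region, 0L)
  target <- paste0(c$tag$peptide, c$linker_peptide)
  protein_n <- count_nonoverlap(pep, target)
  dna_n <- count_nonoverlap(substr(b, a + 1L, e), c$repeat_unit)
  structure(protein_n, dna_level = dna_n)
}

count_nonoverlap <- function(x, pattern) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(0L)
  # gregexpr returns overlap-free matches scanning left to right already
  length(m)
}

#' Verify the reading frame of a construct
#'
#' Checks the four frame clauses of the architecture: (a) the upstream
#' junction parses as codons (N,GG)(CGC)(GCC) with the frame anchored one
#' nucleotide before the AscI motif; (b) the NotI motif starts at a codon
#' boundary and parses as (GCG)(GCC)(GC,N); (c) no stop codon occurs anywhere
#' in the insert span in that frame; (d) the frame is open across NotI so a
#' downstream fusion is possible (carboxy-terminal fusions must supply their
#' own stop codon).
#'
#' @param c a `multimer_construct`.
#' @return list with `ok` (logical) and `clauses` (data frame with columns
#'   `clause`, `pass`, `detail`).
#' @export
verify_frame <- function(c) {
  stopifnot(inherits(c, "multimer_construct"))
  b <- c$plasmid$bases
  enz <- c$enzymes
  a <- c$insert_span[1]
  e <- c$insert_span[2]
  m_not <- nchar(enz$NotI$recognition)
  n2 <- e - m_not
  clause <- character(0); pass <- logical(0); detail <- character(0)
  add <- function(cl, p, d) {
    clause <<- c(clause, cl); pass <<- c(pass, p); detail <<- c(detail, d)
  }

  up_ok <- a >= 1L &&
    substr(b, a + 1L, a + 8L) == enz$AscI$recognition
  up_res <- if (up_ok) {
    paste0(translate_dna(substr(b, a, a + 8L), 0L), " (N,GG | CGC | GCC)")
  } else "AscI motif not at span start"
  add("ascI_junction", up_ok, up_res)

  down_frame <- ((n2 - a + 1L) %% 3L) == 0L
  down_motif <- substr(b, n2 + 1L, n2 + m_not) == enz$NotI$recognition
  down_ok <- down_frame && down_motif
  add("notI_junction", down_ok,
      if (!down_motif) "NotI motif not at span end"
      else if (!down_frame) sprintf("NotI start off-frame by %d nt",
                                    (n2 - a + 1L) %% 3L)
      else paste0(translate_dna(substr(b, n2 + 1L, n2 + 9L), 0L),
                  " (GCG | GCC | GCN)"))

  if (down_frame && a >= 1L && e + 1L <= nchar(b)) {
    pep <- translate_dna(substr(b, a, e + 1L), 0L)
    stop_at <- regexpr("*", pep, fixed = TRUE)
    ncod <- nchar(pep)
    internal <- substr(pep, 1L, ncod - 1L)
    int_stop <- regexpr("*", internal, fixed = TRUE)
    add("no_internal_stop", int_stop == -1L,
        if (int_stop == -1L) "no stop codon in the anchored frame"
        else sprintf("stop codon at codon %d (plasmid position %d)",
                     int_stop, a - 1L + 3L * (int_stop - 1L)))
    last <- substr(pep, ncod, ncod)
    add("open_downstream", last != "*",
        if (last != "*") "frame open across NotI (GCN codon)"
        else "junction codon is a stop")
  } else {
    add("no_internal_stop", FALSE, "frame broken; translation skipped")
    add("open_downstream", FALSE, "frame broken; translation skipped")
  }

  clauses <- data.frame(clause = clause, pass = pass, detail = detail,
                        stringsAsFactors = FALSE)
  list(ok = all(clauses$pass), clauses = clauses)
}

#' In-frame ORF cassette of a construct
#'
#' Returns the anchored, stop-free, codon-multiple DNA spanning from the
#' nucleotide before AscI through GCGGCC of the NotI site -- the piece whose
#' translation carries all tandem tag copies and whose frame matches a
#' carboxy-terminal fusion (see [fuse_cterminal_tag()]).
#'
#' @param c a `multimer_construct`.
#' @return DNA string, length a multiple of 3, no in-frame stop.
#' @export
multimer_orf <- function(c) {
  stopifnot(inherits(c, "multimer_construct"))
  b <- c$plasmid$bases
  a <- c$insert_span[1]
  e <- c$insert_span[2]
  substr(b, a, e - 2L)  # anchor .. NotI motif minus its last 2 nt
}

#' Positions of hybrid XhoI/SalI scars
#'
#' Scans the insert span for the doubling scar (spacer3 + SalI remainder +
#' TCGA + XhoI remainder + spacer2) and returns the 0-based start positions of
#' the 6-nt hybrid core.  The scar duplex reads GTCGAG/CTCGAC and is cut by
#' neither XhoI nor SalI.
#'
#' @param c a `multimer_construct`.
#' @return integer vector (empty for a seed).
#' @export
hybrid_junctions <- function(c) {
  stopifnot(inherits(c, "multimer_construct"))
  pat <- paste0(c$spacers[3], "G", "TCGA", "G", c$spacers[2])
  region <- substr(c$plasmid$bases, c$insert_span[1] + 1L, c$insert_span[2])
  m <- gregexpr(pat, region, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  c$insert_span[1] + (as.integer(m) - 1L) + nchar(c$spacers[3])
}

#' Enumerate the plasmid catalog
#'
#' One entry per (tag, copy-number) pair with copy numbers 5 x 2^r for
#' r = 0..rounds.  Pairs listed in `exclusions` are marked excluded with a
#' reason (the 80X HA multimer could not be generated, leaving 29 of the 30
#' combinations built for the shipped six tags and four rounds).
#'
#' @param tags list of [epitope_tag()] objects.
#' @param rounds number of doubling rounds enumerated.
#' @param exclusions list of `list(tag =, copy_number =, reason =)` entries
#'   (`reason` optional).
#' @param backbone optional circular site-free backbone; when supplied every
#'   built entry is actually constructed by [run_protocol()] and attached in
#'   the `constructs` attribute.
#' @param ... passed to [run_protocol()] when `backbone` is given.
#' @return data frame with columns `tag`, `copy_number`, `status`, `reason`;
#'   attribute `n_built` carries the built count.
#' @export
enumerate_catalog <- function(tags, rounds = 4L, exclusions = list(),
                              backbone = NULL, ...) {
  levels <- 5L * 2L^(0:rounds)
  tag_names <- vapply(tags, `[[`, character(1), "name")
  df <- expand.grid(tag = tag_names, copy_number = levels,
                    stringsAsFactors = FALSE)
  df <- df[order(match(df$tag, tag_names), df$copy_number), ]
  rownames(df) <- NULL
  df$status <- "built"
  df$reason <- ""
  for (ex in exclusions) {
    hit <- df$tag == ex$tag & df$copy_number == ex$copy_number
    df$status[hit] <- "excluded"
    df$reason[hit] <- if (!is.null(ex$reason)) ex$reason
    else "could not be generated (sequence-specific instability)"
  }
  if (!is.null(backbone)) {
    built <- list()
    for (tg in tags) {
      series <- run_protocol(tg, backbone, rounds = rounds, ...)
      for (cs in series) {
        key <- paste0(cs$copy_number, "X", cs$tag$name)
        if (df$status[df$tag == cs$tag$name &
                      df$copy_number == cs$copy_number] == "built") {
          built[[key]] <- cs
        }
      }
    }
    attr(df, "constructs") <- built
  }
  attr(df, "n_built") <- sum(df$status == "built")
  df
}

#' Heuristic stability warnings
#'
#' Flags constructs whose repeat load exceeds empirically motivated
#' boundaries: tandem multimers were generally stable up to 20X in a small
#' high-copy vector, 80X-scale repeats showed partial instability, and very
#' long repeat spans are flagged by length.  These are advisory heuristics,
#' never errors -- the tool does not predict biological repeat instability.
#'
#' @param c a `multimer_construct`.
#' @param stable_max copy-number boundary of the "generally stable" range
#'   (inclusive; default 20).
#' @param high_copy copy number at which the strong warning fires (default 80).
#' @param max_span_nt repeat-span length threshold in nucleotides.
#' @return character vector of warnings (length 0 when none apply), each
#'   citing its rule.
#' @export
stability_warnings <- function(c, stable_max = 20L, high_copy = 80L,
                               max_span_nt = 6000L) {
  stopifnot(inherits(c, "multimer_construct"))
  out <- character(0)
  if (c$copy_number > stable_max) {
    out <- c(out, sprintf(
      "copy number %d exceeds the %dX range observed to be generally stable in small high-copy vectors [rule: copy_gt_%d]",
      c$copy_number, stable_max, stable_max))
  }
  if (c$copy_number >= high_copy) {
    out <- c(out, sprintf(
      "%dX-scale repeats are prone to partial instability and some tag/level combinations may be unobtainable [rule: copy_ge_%d]",
      high_copy, high_copy))
  }
  span <- c$copy_number * nchar(c$repeat_unit)
  if (span > max_span_nt) {
    out <- c(out, sprintf(
      "repeat block spans %d nt, above the %d nt threshold [rule: span_gt_%d]",
      span, max_span_nt, max_span_nt))
  }
  out
}
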