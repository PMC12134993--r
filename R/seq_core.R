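#' DNA sequence with topology
#'
#' Construct a DNA sequence object over the alphabet A/C/G/T with an explicit
#' linear or circular topology flag.  Lowercase input is uppercased; degenerate
#' (IUPAC) letters are rejected here -- they are permitted only in restriction
#' enzyme recognition motifs.  All coordinate-reporting operations in the
#' package use 0-based, half-open positions on the stored linearization;
#' circular sequences are never silently rotated.
#'
#' @param bases single character string of A/C/G/T (case-insensitive).
#' @param topology `"linear"` or `"circular"`.
#' @return an object of class `dna_seq` with fields `bases` and `topology`.
#' @examples
#' dna("ggCGCGcc", "circular")
#' @export
dna <- function(bases, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  bases <- toupper(bases)
  if (!nzchar(bases)) stop("DNA sequence must be non-empty")
  if (grepl("[^ACGT]", bases)) {
    bad <- regmatches(bases, regexpr("[^ACGT]", bases))
    stop("invalid base '", bad, "': alphabet is restricted to A/C/G/T")
  }
  structure(list(bases = bases, topology = topology), class = "dna_seq")
}

#' @export
print.dna_seq <- function(x, ...) {
  n <- dna_length(x)
  head <- substr(x$bases, 1, 60)
  cat(sprintf("<dna_seq> %s, %d nt\n  %s%s\n",
              x$topology, n, head, if (n > 60) "..." else ""))
  invisible(x)
}

#' Length of a DNA sequence in nucleotides
#' @param x a `dna_seq`.
#' @return integer length.
#' @export
dna_length <- function(x) {
  stopifnot(inherits(x, "dna_seq"))
  nchar(x$bases)
}

#' @rdname dna
#' @param x object to test.
#' @export
is_circular <- function(x) {
  stopifnot(inherits(x, "dna_seq"))
  identical(x$topology, "circular")
}

## Circular-aware substring: 0-based start, wraps around the origin.
circ_substr <- function(bases, start, len) {
  n <- nchar(bases)
  if (len == 0L) return("")
  start <- ((start %% n) + n) %% n
  if (start + len <= n) return(substr(bases, start + 1L, start + len))
  paste0(substr(bases, start + 1L, n), substr(bases, 1L, start + len - n))
}

## Rotate a circular sequence so old position k becomes position 0.
rotate_dna <- function(seq, k) {
  stopifnot(inherits(seq, "dna_seq"), is_circular(seq))
  n <- dna_length(seq)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(seq)
  dna(paste0(substr(seq$bases, k + 1L, n), substr(seq$bases, 1L, k)),
      "circular")
}

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Restriction enzyme definition
#'
#' An enzyme is described by its recognition motif (IUPAC letters allowed) and
#' the top/bottom strand cut offsets measured in nucleotides from the motif
#' start.  The overhang length is `abs(cut_bottom - cut_top)`; the four
#' enzymes shipped with the package (AscI GG^CGCGCC, XhoI C^TCGAG,
#' SalI G^TCGAC, NotI GC^GGCCGC) all produce 4-nt 5' overhangs and have
#' palindromic motifs.
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition motif, length >= 4.
#' @param cut_top top-strand cut offset from motif start.
#' @param cut_bottom bottom-strand cut offset (top-strand coordinates).
#' @return an object of class `restriction_enzyme`.
#' @seealso [default_enzymes()]
#' @export
restriction_enzyme <- function(name, recognition, cut_top, cut_bottom) {
  recognition <- toupper(recognition)
  stopifnot(is.character(name), nzchar(name), nchar(recognition) >= 4L)
  letters <- strsplit(recognition, "")[[1]]
  if (!all(letters %in% IUPAC_DNA)) {
    stop("recognition motif of ", name, " contains a non-IUPAC letter")
  }
  structure(list(name = name, recognition = recognition,
                 cut_top = as.integer(cut_top),
                 cut_bottom = as.integer(cut_bottom)),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s %s cut %d/%d (%d-nt overhang)\n",
              x$name, x$recognition, x$cut_top, x$cut_bottom,
              overhang_length(x)))
  invisible(x)
}

#' @rdname restriction_enzyme
#' @param enzyme a `restriction_enzyme`.
#' @export
overhang_length <- function(enzyme) abs(enzyme$cut_bottom - enzyme$cut_top)

#' Load restriction enzyme definitions from a config file
#'
#' The file is tab-separated with columns `name`, `recognition`, `cut_top`,
#' `cut_bottom`.  The bundled default defines AscI, XhoI, SalI and NotI; the
#' definitions are data, not code, and can be overridden by pointing `path` at
#' a user file.
#'
#' @param path path to the enzyme table; defaults to the bundled file.
#' @return named list of `restriction_enzyme` objects.
#' @export
default_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                               package = "tandemtag")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  enz <- lapply(seq_len(nrow(tab)), function(i) {
    restriction_enzyme(tab$name[i], tab$recognition[i],
                       tab$cut_top[i], tab$cut_bottom[i])
  })
  stats::setNames(enz, tab$name)
}

#' Single-stranded end of a DNA fragment
#'
#' Ends are either blunt or 5' overhangs.  The overhang `seq` is recorded as
#' the top-strand text of the single-stranded gap between the top and bottom
#' cut positions, so two ends anneal exactly when their recorded sequences are
#' equal (for the shipped palindromic-overhang enzymes this is the plain 4-mer
#' comparison, e.g. XhoI and SalI both leave TCGA).
#'
#' @param kind `"five_prime"` or `"blunt"`.
#' @param seq overhang sequence (top-strand gap text); empty iff blunt.
#' @return an object of class `overhang`.
#' @export
overhang <- function(kind = c("five_prime", "blunt"), seq = "") {
  kind <- match.arg(kind)
  seq <- toupper(seq)
  if (kind == "blunt" && nzchar(seq)) stop("blunt ends carry no overhang")
  if (kind == "five_prime" && !nzchar(seq)) {
    stop("a five_prime overhang must have a non-empty sequence")
  }
  structure(list(kind = kind, seq = seq), class = "overhang")
}

#' Find restriction sites
#'
#' Scans a sequence for the enzyme's recognition motif and returns sorted
#' 0-based motif start positions on the stored linearization.  IUPAC letters
#' in the motif are honoured.  For circular sequences, matches spanning the
#' linearization origin are found and reported modulo the length.
#' Non-palindromic motifs are additionally scanned on the bottom strand, the
#' top-strand start of the match being reported; for the palindromic shipped
#' motifs one strand scan suffices.
#'
#' @param seq a `dna_seq`.
#' @param enzyme a `restriction_enzyme`.
#' @return sorted integer vector of 0-based motif start positions (empty when
#'   there is no match).
#' @examples
#' find_sites(dna("AAGGCGCGCCTT"), default_enzymes()$AscI)  # 2
#' @export
find_sites <- function(seq, enzyme) {
  stopifnot(inherits(seq, "dna_seq"), inherits(enzyme, "restriction_enzyme"))
  n <- dna_length(seq)
  m <- nchar(enzyme$recognition)
  if (n < m) return(integer(0))
  subject <- seq$bases
  if (is_circular(seq)) {
    subject <- paste0(subject, substr(subject, 1L, m - 1L))
  }
  motif <- Biostrings::DNAString(enzyme$recognition)
  rc_motif <- Biostrings::reverseComplement(motif)
  pats <- unique(c(as.character(motif), as.character(rc_motif)))
  subj <- Biostrings::DNAString(subject)
  hits <- integer(0)
  for (p in pats) {
    mp <- Biostrings::matchPattern(p, subj, fixed = FALSE)
    hits <- c(hits, BiocGenerics::start(mp) - 1L)
  }
  if (is_circular(seq)) hits <- hits %% n
  sort(unique(hits))
}

#' Translate DNA in a fixed frame
#'
#' Standard genetic code; stop codons are rendered `"*"`; trailing 1-2 nt are
#' ignored.
#'
#' @param seq a `dna_seq` or plain character DNA string.
#' @param offset reading-frame offset, 0, 1 or 2.
#' @return peptide string.
#' @examples
#' translate_dna("GGTTCTGGAGGA")  # "GSGG"
#' @export
translate_dna <- function(seq, offset = 0L) {
  x <- if (inherits(seq, "dna_seq")) seq$bases else toupper(seq)
  stopifnot(offset %in% 0:2)
  s <- substr(x, offset + 1L, nchar(x))
  nc <- nchar(s) - nchar(s) %% 3L
  if (nc < 3L) stop("translated span is shorter than one codon")
  codons <- substring(s, seq.int(1L, nc, 3L), seq.int(3L, nc, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) stop("untranslatable codon: ", codons[which(is.na(aa))[1]])
  paste(aa, collapse = "")
}

#' Reverse complement
#'
#' Applying it twice is the identity; topology is preserved for `dna_seq`
#' input.
#'
#' @param x a `dna_seq` or character string (IUPAC letters allowed).
#' @return object of the same type as the input.
#' @export
reverse_complement <- function(x) UseMethod("reverse_complement")

#' @export
reverse_complement.character <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @export
reverse_complement.dna_seq <- function(x) {
  dna(reverse_complement(x$bases), x$topology)
}
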