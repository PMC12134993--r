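#' DNA fragment with typed ends
#'
#' A linear double-stranded piece produced by digestion and consumed by
#' ligation.  `core` is the fully double-stranded region (top strand);
#' `left_end`/`right_end` are [overhang()] objects; `provenance` records the
#' (enzyme name, cut position) pair that created each end.  The fragment's
#' cut-to-cut length on the top strand is `fragment_length()`; summed over a
#' digest this reconstitutes the parent length exactly (each shared overhang
#' counted once).
#'
#' @param core top-strand sequence of the double-stranded region.
#' @param left_end,right_end [overhang()] objects.
#' @param provenance list with elements `left` and `right`, each either `NULL`
#'   (natural end) or `list(enzyme =, cut =)`.
#' @return an object of class `dna_fragment`.
#' @export
dna_fragment <- function(core, left_end, right_end, provenance = list()) {
  stopifnot(inherits(left_end, "overhang"), inherits(right_end, "overhang"))
  structure(list(core = toupper(core), left_end = left_end,
                 right_end = right_end, provenance = provenance),
            class = "dna_fragment")
}

#' @rdname dna_fragment
#' @param f a `dna_fragment`.
#' @export
fragment_length <- function(f) nchar(f$left_end$seq) + nchar(f$core)

#' @rdname dna_fragment
#' @export
fragment_top <- function(f) paste0(f$left_end$seq, f$core)

#' @export
print.dna_fragment <- function(x, ...) {
  fmt <- function(e) if (e$kind == "blunt") "blunt" else paste0("5'-", e$seq)
  cat(sprintf("<dna_fragment> %d nt [%s | %s]\n", fragment_length(x),
              fmt(x$left_end), fmt(x$right_end)))
  invisible(x)
}

#' @export
reverse_complement.dna_fragment <- function(x) {
  flip <- function(e) {
    if (e$kind == "blunt") e else overhang("five_prime",
                                           reverse_complement(e$seq))
  }
  dna_fragment(core = reverse_complement(x$core),
               left_end = flip(x$right_end),
               right_end = flip(x$left_end),
               provenance = list(left = x$provenance$right,
                                 right = x$provenance$left))
}

#' In-silico restriction digestion
#'
#' Cuts a linear or circular sequence with one or more enzymes.  A circular
#' input with k distinct cuts yields exactly k fragments; a linear input
#' yields k + 1.  Fragments are ordered by cut position and their cut-to-cut
#' lengths sum to the input length.  Zero cuts on a circular input return a
#' distinguished `uncut_digest` object rather than a fragment list; a linear
#' input with no sites is returned as a single blunt fragment.
#'
#' @param seq a `dna_seq`.
#' @param enzymes a `restriction_enzyme` or list of them.
#' @return a list of `dna_fragment` objects (class `digest_result`) or an
#'   `uncut_digest`.
#' @export
digest <- function(seq, enzymes) {
  stopifnot(inherits(seq, "dna_seq"))
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  n <- dna_length(seq)
  cuts <- list()
  for (e in enzymes) {
    for (s in find_sites(seq, e)) {
      if (!is_circular(seq) && s + max(e$cut_top, e$cut_bottom) > n) next
      pos <- s + e$cut_top
      if (is_circular(seq)) pos <- pos %% n
      cuts[[length(cuts) + 1L]] <-
        list(pos = pos, len = overhang_length(e), enzyme = e$name)
    }
  }
  if (length(cuts)) {
    pos <- vapply(cuts, `[[`, integer(1), "pos")
    cuts <- cuts[!duplicated(pos)]
    cuts <- cuts[order(vapply(cuts, `[[`, integer(1), "pos"))]
  }
  k <- length(cuts)
  b <- seq$bases

  if (k == 0L) {
    if (is_circular(seq)) {
      return(structure(list(uncut = TRUE, sequence = seq),
                       class = "uncut_digest"))
    }
    frag <- dna_fragment(b, overhang("blunt"), overhang("blunt"),
                         provenance = list(left = NULL, right = NULL))
    return(structure(list(frag), class = c("digest_result", "list")))
  }

  end_of <- function(cut) if (cut$len > 0L)
    overhang("five_prime", circ_substr(b, cut$pos, cut$len))
  else overhang("blunt")

  frags <- list()
  if (is_circular(seq)) {
    for (i in seq_len(k)) {
      a <- cuts[[i]]
      z <- cuts[[if (i == k) 1L else i + 1L]]
      core_len <- ((z$pos - a$pos - a$len) %% n + n) %% n
      frags[[i]] <- dna_fragment(
        core = circ_substr(b, a$pos + a$len, core_len),
        left_end = end_of(a), right_end = end_of(z),
        provenance = list(left = list(enzyme = a$enzyme, cut = a$pos),
                          right = list(enzyme = z$enzyme, cut = z$pos)))
    }
  } else {
    bounds <- c(list(NULL), cuts, list(NULL))
    for (i in seq_len(k + 1L)) {
      a <- bounds[[i]]
      z <- bounds[[i + 1L]]
      start <- if (is.null(a)) 0L else a$pos + a$len
      stop_ <- if (is.null(z)) n else z$pos
      frags[[i]] <- dna_fragment(
        core = substr(b, start + 1L, stop_),
        left_end = if (is.null(a)) overhang("blunt") else end_of(a),
        right_end = if (is.null(z)) overhang("blunt") else end_of(z),
        provenance = list(
          left = if (is.null(a)) NULL else list(enzyme = a$enzyme, cut = a$pos),
          right = if (is.null(z)) NULL else list(enzyme = z$enzyme,
                                                 cut = z$pos)))
    }
  }
  structure(frags, class = c("digest_result", "list"))
}

#' Cohesive-end compatibility
#'
#' Two ends ligate when both are blunt, or both are 5' overhangs whose
#' single-stranded sequences are reverse-complementary in the annealing
#' orientation.  With overhangs recorded as top-strand gap text (see
#' [overhang()]) this is sequence equality -- e.g. the XhoI and SalI ends both
#' read TCGA and are compatible, while an AscI end (CGCG) is not compatible
#' with either.
#'
#' @param a,b [overhang()] objects.
#' @return logical.
#' @export
ends_compatible <- function(a, b) {
  stopifnot(inherits(a, "overhang"), inherits(b, "overhang"))
  if (a$kind == "blunt" && b$kind == "blunt") return(TRUE)
  if (a$kind != b$kind) return(FALSE)
  identical(a$seq, b$seq)
}

fmt_end <- function(e) if (e$kind == "blunt") "blunt" else paste0("5'-", e$seq)

#' Circular ligation of a vector and an insert
#'
#' Joins one vector fragment and one insert fragment into a circular plasmid.
#' The insert orientation is resolved by end compatibility: it may anneal
#' flipped if its ends permit, but if both orientations are compatible the
#' ligation is rejected as ambiguous, and if neither is, the failing end pair
#' is named.  Each junction is re-scanned with the supplied enzymes and the
#' result notes which sites were regenerated and which were destroyed -- the
#' XhoI/SalI hybrid junction of the doubling protocol is recognized by
#' neither parent enzyme.  Fragments whose own two ends are self-compatible
#' trigger a self-circularization warning (the real-world failure mode of
#' re-ligation without insert).
#'
#' @param vector,insert `dna_fragment` objects.
#' @param enzymes enzymes used for the junction re-scan (defaults to the
#'   shipped four).
#' @return circular `dna_seq` with a `junctions` attribute (data frame with
#'   columns `position`, `text`, `regenerated`).
#' @export
ligate_circular <- function(vector, insert, enzymes = default_enzymes()) {
  stopifnot(inherits(vector, "dna_fragment"), inherits(insert, "dna_fragment"))
  for (nm in c("vector", "insert")) {
    f <- get(nm)
    if (ends_compatible(f$left_end, f$right_end)) {
      warning(nm, " fragment has self-compatible ends and can ",
              "self-circularize without a partner", call. = FALSE)
    }
  }
  fits <- function(ins) {
    ends_compatible(vector$right_end, ins$left_end) &&
      ends_compatible(ins$right_end, vector$left_end)
  }
  flipped <- reverse_complement(insert)
  ok1 <- fits(insert)
  ok2 <- fits(flipped)
  if (ok1 && ok2) {
    stop("ambiguous insert orientation: both orientations have compatible ends")
  }
  if (!ok1 && !ok2) {
    if (!ends_compatible(vector$right_end, insert$left_end)) {
      stop("incompatible ends: vector right (", fmt_end(vector$right_end),
           ") vs insert left (", fmt_end(insert$left_end), ")")
    }
    stop("incompatible ends: insert right (", fmt_end(insert$right_end),
         ") vs vector left (", fmt_end(vector$left_end), ")")
  }
  ins <- if (ok1) insert else flipped
  out_str <- paste0(fragment_top(vector), fragment_top(ins))
  out <- dna(out_str, "circular")
  n <- dna_length(out)

  scan_junction <- function(pos) {
    hits <- character(0)
    for (e in enzymes) {
      m <- nchar(e$recognition)
      window_start <- pos - (m - 1L)
      window <- circ_substr(out_str, window_start, 2L * (m - 1L) + 1L)
      w <- find_sites(dna(window, "linear"), e)
      if (length(w)) hits <- c(hits, e$name)
    }
    hits
  }
  j1 <- fragment_length(vector)  # start of insert (vector/insert junction)
  j2 <- 0L                       # wrap junction (insert/vector)
  jtext <- function(pos, k = 8L) circ_substr(out_str, pos - k, 2L * k)
  junctions <- data.frame(
    position = c(j1, j2),
    text = c(jtext(j1), jtext(j2)),
    regenerated = vapply(c(j1, j2),
                         function(p) paste(scan_junction(p), collapse = ","),
                         character(1)),
    stringsAsFactors = FALSE)
  attr(out, "junctions") <- junctions
  out
}

#' Restriction-site census
#'
#' Convenience wrapper counting [find_sites()] hits per enzyme; used to assert
#' that the doubling protocol regenerates the original configuration of unique
#' AscI/XhoI/SalI/NotI sites after every round.
#'
#' @param seq a `dna_seq`.
#' @param enzymes list of `restriction_enzyme` objects (possibly empty).
#' @return named integer vector of site counts.
#' @export
unique_site_census <- function(seq, enzymes) {
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  if (!length(enzymes)) return(stats::setNames(integer(0), character(0)))
  counts <- vapply(enzymes, function(e) length(find_sites(seq, e)), integer(1))
  names(counts) <- vapply(enzymes, `[[`, character(1), "name")
  counts
}

#' Write a digest report
#'
#' Tab-separated table of fragment index, cut-to-cut length and bounding
#' enzymes -- the machine-readable analog of a diagnostic gel lane.
#'
#' @param fragments result of [digest()].
#' @param path output file.
#' @return the report data frame, invisibly.
#' @export
write_digest_report <- function(fragments, path) {
  if (inherits(fragments, "uncut_digest")) {
    df <- data.frame(fragment = 1L, length = dna_length(fragments$sequence),
                     left_enzyme = "uncut", right_enzyme = "uncut")
  } else {
    df <- data.frame(
      fragment = seq_along(fragments),
      length = vapply(fragments, fragment_length, integer(1)),
      left_enzyme = vapply(fragments, function(f) {
        if (is.null(f$provenance$left)) NA_character_
        else f$provenance$left$enzyme
      }, character(1)),
      right_enzyme = vapply(fragments, function(f) {
        if (is.null(f$provenance$right)) NA_character_
        else f$provenance$right$enzyme
      }, character(1)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
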