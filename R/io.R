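#' Read sequences from a FASTA file
#'
#' @param path FASTA file (single- or multi-record).
#' @param topology topology assigned to every record (`"linear"` default);
#'   records whose description contains the word `circular` are read as
#'   circular regardless.
#' @return named list of `dna_seq` objects.
#' @export
read_fasta <- function(path, topology = "linear") {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    topo <- if (grepl("\\bcircular\\b", names(set)[i], ignore.case = TRUE)) {
      "circular"
    } else topology
    dna(as.character(set[[i]]), topo)
  })
  stats::setNames(out, sub("\\s.*$", "", names(set)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs a `dna_seq`, a named list of them, or a `multimer_construct`
#'   (written as its full plasmid).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "multimer_construct")) {
    seqs <- stats::setNames(
      list(seqs$plasmid),
      sprintf("%dX%s_%s circular", seqs$copy_number, seqs$tag$name,
              seqs$backbone_name))
  }
  if (inherits(seqs, "dna_seq")) seqs <- list(sequence = seqs)
  strs <- vapply(seqs, function(s) s$bases, character(1))
  nm <- names(strs)
  extra <- vapply(seqs, function(s) if (is_circular(s)) " circular" else "",
                  character(1))
  nm <- ifelse(grepl("circular", nm), nm, paste0(nm, extra))
  set <- Biostrings::DNAStringSet(strs)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

construct_features <- function(c) {
  b <- c$plasmid$bases
  feats <- data.frame(key = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
  add <- function(key, start, end, label) {
    rbind(feats, data.frame(key = key, start = start, end = end,
                            label = label, stringsAsFactors = FALSE))
  }
  for (e in c$enzymes) {
    for (s in find_sites(c$plasmid, e)) {
      feats <- add("misc_feature", s, s + nchar(e$recognition),
                   paste0(e$name, "_site"))
    }
  }
  a <- c$insert_span[1]
  region <- substr(b, a + 1L, c$insert_span[2])
  m <- gregexpr(c$repeat_unit, region, fixed = TRUE)[[1]]
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      s <- a + as.integer(m[i]) - 1L
      feats <- add("misc_feature", s, s + nchar(c$repeat_unit),
                   sprintf("%s_repeat_%d", c$tag$name, i))
    }
  }
  for (j in hybrid_junctions(c)) {
    feats <- add("misc_feature", j, j + 6L, "xhoI_salI_scar")
  }
  sp <- c$spacers
  asc_end <- a + 8L
  feats <- add("misc_feature", asc_end, asc_end + nchar(sp[1]), "spacer_1")
  xho_end <- asc_end + nchar(sp[1]) + 6L
  feats <- add("misc_feature", xho_end, xho_end + nchar(sp[2]), "spacer_2")
  not_start <- c$insert_span[2] - 8L
  sal_start <- not_start - nchar(sp[4]) - 6L
  feats <- add("misc_feature", sal_start - nchar(sp[3]), sal_start, "spacer_3")
  feats <- add("misc_feature", sal_start + 6L, not_start, "spacer_4")
  feats <- add("CDS", a - 1L, c$insert_span[2] - 2L,
               sprintf("%dX%s_orf", c$copy_number, c$tag$name))
  feats[order(feats$start, feats$end), ]
}

donor_features <- function(d) {
  feats <- data.frame(key = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
  add <- function(key, start, end, label) {
    rbind(feats, data.frame(key = key, start = start, end = end,
                            label = label, stringsAsFactors = FALSE))
  }
  ex <- d$gene$exons
  for (i in seq_len(nrow(ex))) {
    feats <- add("exon", ex[i, "start"], ex[i, "end"], sprintf("exon_%d", i))
  }
  feats <- add("CDS", d$gene$cds_start, d$gene$cds_end, "cds")
  for (i in seq_len(nrow(d$rt_sites))) {
    feats <- add("misc_feature", d$rt_sites[i, 1], d$rt_sites[i, 2],
                 sprintf("rt_site_%d", i))
  }
  if (!is.null(d$cassette_insert)) {
    feats <- add("misc_feature", d$cassette_insert[1], d$cassette_insert[2],
                 "stop_cassette")
  }
  if (!is.null(d$tag_insert)) {
    feats <- add("misc_feature", d$tag_insert[1], d$tag_insert[2],
                 "tag_multimer")
  }
  for (i in seq_len(nrow(d$homology_arms))) {
    feats <- add("misc_feature", d$homology_arms[i, 1],
                 d$homology_arms[i, 2], sprintf("homology_arm_%d", i))
  }
  for (i in seq_len(nrow(d$pam_edits))) {
    pe <- d$pam_edits[i, ]
    feats <- add("misc_feature", pe$position, pe$position + 1L,
                 sprintf("pam_edit_%s>%s", pe$old, pe$new))
  }
  feats[order(feats$start, feats$end), ]
}

#' Write a construct or donor design as GenBank
#'
#' Minimal flat-file GenBank dialect: a LOCUS line with circular/linear
#' topology, one feature per enzyme site, repeat unit, spacer and hybrid
#' junction (labelled `xhoI_salI_scar`), a CDS feature for the tag ORF, and a
#' standard ORIGIN block.  Features use `misc_feature` with `/label` for
#' maximal viewer compatibility.  The dialect round-trips through
#' [read_genbank()].
#'
#' @param x a `multimer_construct` or `donor_design`.
#' @param path output file.
#' @param name LOCUS name.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(x, path, name = NULL) {
  if (inherits(x, "multimer_construct")) {
    seq <- x$plasmid
    feats <- construct_features(x)
    if (is.null(name)) name <- sprintf("%dX%s", x$copy_number, x$tag$name)
  } else if (inherits(x, "donor_design")) {
    seq <- x$gene$sequence
    feats <- donor_features(x)
    if (is.null(name)) name <- "donor"
  } else {
    stop("write_genbank handles multimer_construct and donor_design objects")
  }
  n <- dna_length(seq)
  topo <- if (is_circular(seq)) "circular" else "linear"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s   SYN",
                     substr(name, 1, 16), n, topo), con)
  writeLines(sprintf("DEFINITION  %s.", name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (i in seq_len(nrow(feats))) {
    writeLines(sprintf("     %-15s %d..%d", feats$key[i],
                       feats$start[i] + 1L, feats$end[i]), con)
    writeLines(sprintf("                     /label=\"%s\"",
                       feats$label[i]), con)
  }
  writeLines("ORIGIN", con)
  b <- tolower(seq$bases)
  for (off in seq.int(1L, n, 60L)) {
    line <- substr(b, off, min(off + 59L, n))
    blocks <- substring(line, seq.int(1L, nchar(line), 10L),
                        pmin(seq.int(10L, nchar(line) + 9L, 10L),
                             nchar(line)))
    writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read the GenBank dialect written by [write_genbank()]
#'
#' @param path GenBank file.
#' @return list with `name`, `sequence` (a `dna_seq`) and `features`
#'   (data frame with 0-based half-open `start`/`end`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- strsplit(trimws(lines[grepl("^LOCUS", lines)][1]), "\\s+")[[1]]
  topo <- if ("circular" %in% locus) "circular" else "linear"
  name <- locus[2]
  feats <- data.frame(key = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
  in_feats <- FALSE
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^FEATURES", ln)) {
      in_feats <- TRUE
    } else if (grepl("^ORIGIN", ln)) {
      break
    } else if (in_feats && grepl("^     \\S", ln)) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      key <- parts[1]
      loc <- parts[2]
      label <- NA_character_
      if (i + 1L <= length(lines) && grepl("/label=", lines[i + 1L])) {
        label <- sub('.*?/label="([^"]*)".*', "\\1", lines[i + 1L])
        i <- i + 1L
      }
      if (key != "source") {
        se <- as.integer(strsplit(loc, "\\.\\.")[[1]])
        feats <- rbind(feats, data.frame(key = key, start = se[1] - 1L,
                                         end = se[2], label = label,
                                         stringsAsFactors = FALSE))
      }
    }
    i <- i + 1L
  }
  seq_lines <- lines[seq.int(i + 1L, length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  bases <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  list(name = name, sequence = dna(bases, topo), features = feats)
}

#' Reconstruct a multimer construct from its GenBank file
#'
#' Inverse of [write_genbank()] for `multimer_construct` objects: the copy
#' number and tag name are parsed from the CDS label, the repeat unit is read
#' from the first repeat feature, and the insert span from the AscI/NotI site
#' features.  The reconstructed construct passes the same validation as a
#' freshly built one.
#'
#' @param path GenBank file written by [write_genbank()].
#' @param enzymes,tags,linker_peptide,spacers design context used to
#'   reconstitute the object; defaults match [build_seed()].
#' @return a `multimer_construct`.
#' @export
read_construct_genbank <- function(path, enzymes = default_enzymes(),
                                   tags = default_tags(),
                                   linker_peptide = "GSGG",
                                   spacers = c("GA", "T", "GA", "A")) {
  gb <- read_genbank(path)
  f <- gb$features
  b <- gb$sequence$bases
  cds <- f[f$key == "CDS", , drop = FALSE]
  m <- regmatches(cds$label, regexec("^([0-9]+)X(.+)_orf$", cds$label))[[1]]
  if (length(m) != 3L) stop("CDS label does not encode <copies>X<tag>_orf")
  copies <- as.integer(m[2])
  tag <- tags[[m[3]]]
  if (is.null(tag)) stop("unknown tag '", m[3], "' in ", path)
  rep1 <- f[grepl("_repeat_1$", f$label), , drop = FALSE]
  if (nrow(rep1) != 1L) stop("repeat feature missing from ", path)
  unit <- substr(b, rep1$start + 1L, rep1$end)
  asc <- f[f$label == "AscI_site", , drop = FALSE]
  noti <- f[f$label == "NotI_site", , drop = FALSE]
  if (nrow(asc) != 1L || nrow(noti) != 1L) {
    stop("AscI/NotI site features missing from ", path)
  }
  cons <- new_multimer_construct(gb$sequence, unit, copies,
                                 c(asc$start, noti$end), gb$name, tag,
                                 toupper(linker_peptide), spacers, enzymes)
  validate_construct(cons)
}

#' Reconstruct a donor design from its GenBank file
#'
#' Inverse of [write_genbank()] for `donor_design` objects: the gene model is
#' rebuilt from the exon and CDS features, the RT sites, cassette, tag insert
#' and homology arms from their labelled features, and the RT sequence from
#' the first RT feature.  PAM edit features are read back with their position
#' and base change (the synonymous/fallback flags and guide are not stored in
#' GenBank and come back as `NA`).
#'
#' @param path GenBank file written by [write_genbank()].
#' @return a `donor_design`.
#' @export
read_donor_genbank <- function(path) {
  gb <- read_genbank(path)
  f <- gb$features
  b <- gb$sequence$bases
  ex <- f[f$key == "exon", , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  cds <- f[f$key == "CDS", , drop = FALSE]
  if (!nrow(ex) || nrow(cds) != 1L) {
    stop("donor GenBank must carry exon and CDS features")
  }
  gene <- gene_model(b, as.matrix(ex[, c("start", "end")]),
                     cds$start, cds$end)
  pick <- function(label) {
    row <- f[f$label == label, , drop = FALSE]
    if (nrow(row) != 1L) NULL else c(row$start, row$end)
  }
  rt1 <- pick("rt_site_1")
  if (is.null(rt1)) stop("rt_site_1 feature missing from ", path)
  rt2 <- pick("rt_site_2")
  rt_sites <- if (is.null(rt2)) rbind(rt1 = rt1) else rbind(rt1 = rt1,
                                                            rt2 = rt2)
  arms <- rbind(pick("homology_arm_1"), pick("homology_arm_2"))
  colnames(arms) <- c("start", "end")
  tag_iv <- pick("tag_multimer")
  if (!is.null(tag_iv)) attr(gene, "tag_insert") <- tag_iv
  pe <- f[grepl("^pam_edit_", f$label), , drop = FALSE]
  pam_edits <- data.frame(
    position = pe$start,
    old = sub("^pam_edit_(.)>(.)$", "\\1", pe$label),
    new = sub("^pam_edit_(.)>(.)$", "\\2", pe$label),
    synonymous = rep(NA, nrow(pe)), fallback = rep(NA, nrow(pe)),
    guide = rep(NA_character_, nrow(pe)), stringsAsFactors = FALSE)
  structure(list(gene = gene,
                 tag_insert = tag_iv,
                 cassette_insert = pick("stop_cassette"),
                 rt_sites = rt_sites,
                 rt_seq = substr(b, rt1[1] + 1L, rt1[2]),
                 pam_edits = pam_edits,
                 homology_arms = arms),
            class = "donor_design")
}

#' Read a gene model from FASTA + exon table or minimal GFF3
#'
#' The tab-separated table has columns `feature`, `start`, `end` with one
#' `exon` row per exon and one `CDS` row giving the CDS span; coordinates are
#' 0-based half-open.  Alternatively a minimal GFF3 file (gene/mRNA/exon/CDS
#' lines, 1-based closed coordinates) can be given; it is parsed with
#' rtracklayer.  Minus-strand GFF genes are reverse-complemented so the top
#' strand is the coding strand, with coordinates remapped.
#'
#' @param fasta FASTA file holding the genomic sequence (first record used).
#' @param exon_table path to the exon/CDS table (TSV), or `NULL`.
#' @param gff path to a GFF3 file, or `NULL`; exactly one of `exon_table` and
#'   `gff` must be given.
#' @return a [gene_model()].
#' @export
read_gene_model <- function(fasta, exon_table = NULL, gff = NULL) {
  seqs <- read_fasta(fasta)
  seq <- seqs[[1]]
  if (!is.null(exon_table)) {
    tab <- utils::read.delim(exon_table, stringsAsFactors = FALSE)
    ex <- tab[tolower(tab$feature) == "exon", c("start", "end")]
    cds <- tab[tolower(tab$feature) == "cds", c("start", "end")]
    if (nrow(cds) != 1L) stop("exon table must have exactly one CDS row")
    return(gene_model(seq, as.matrix(ex), cds$start[1], cds$end[1]))
  }
  if (is.null(gff)) stop("supply either exon_table or gff")
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(gff)
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  if (!length(ex) || !length(cds)) stop("GFF3 must contain exon and CDS lines")
  strand <- as.character(BiocGenerics::strand(ex))[1]
  exons <- cbind(start = BiocGenerics::start(ex) - 1L,
                 end = BiocGenerics::end(ex))
  cds_start <- min(BiocGenerics::start(cds)) - 1L
  cds_end <- max(BiocGenerics::end(cds))
  if (identical(strand, "-")) {
    n <- dna_length(seq)
    seq <- reverse_complement(seq)
    exons <- cbind(start = n - exons[, "end"], end = n - exons[, "start"])
    exons <- exons[order(exons[, "start"]), , drop = FALSE]
    tmp <- cds_start
    cds_start <- n - cds_end
    cds_end <- n - tmp
    message("minus-strand gene reverse-complemented; coordinates remapped")
  }
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  gene_model(seq, exons, cds_start, cds_end)
}

#' Read the tool configuration
#'
#' YAML file resolving enzyme, tag and codon-usage tables plus the design
#' defaults (linker, spacers, stability thresholds, RT site, splice distance,
#' seed).  Relative table paths are resolved against the config file's
#' directory, falling back to the bundled data.
#'
#' @param path YAML config; defaults to the bundled one.
#' @return list of class `tool_config` with resolved `enzymes`, `tags` and
#'   `codon_usage` plus the raw settings.
#' @export
read_config <- function(path = system.file("extdata", "config.yaml",
                                           package = "tandemtag")) {
  cfg <- yaml::read_yaml(path)
  resolve <- function(f) {
    cand <- file.path(dirname(path), f)
    if (file.exists(cand)) cand
    else system.file("extdata", f, package = "tandemtag")
  }
  cfg$enzymes <- default_enzymes(resolve(cfg$enzymes_file))
  cfg$tags <- default_tags(resolve(cfg$tags_file))
  cfg$codon_usage <- load_codon_usage(resolve(cfg$codon_usage_file))
  cfg$config_hash <- unname(tools::md5sum(path))
  structure(cfg, class = "tool_config")
}
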