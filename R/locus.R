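#' Merge two overlapping contigs into a locus assembly
#'
#' Finds the longest exact suffix(a)/prefix(b) match of at least
#' `min_overlap` nucleotides, trying `b` in both orientations, and
#' concatenates. Overlap detection is exact-match by design: the clones
#' being merged derive from a single genome, so mismatch-tolerant
#' merging is out of scope.
#'
#' @param a,b Contigs ([contig()], `DNAString`, or plain DNA strings).
#' @param min_overlap Minimum acceptable exact overlap in nt.
#' @return An object of class `locus_assembly`: `sequence`,
#'   `contig_offsets` (1-based placement of each input on the merge),
#'   `overlap_len`, `b_orientation` (`"forward"`/`"revcomp"`).
#' @export
merge_contigs <- function(a, b, min_overlap = 100L) {
  sa <- .contig_seq(a); sb0 <- .contig_seq(b)
  if (nchar(sa) == 0L || nchar(sb0) == 0L) stop("merge_contigs(): empty contig")
  ids <- c(.contig_id(a, "a"), .contig_id(b, "b"))
  best <- list(k = 0L, orient = NA_character_, sb = NA_character_)
  probe <- function(sb, orient, thr) {
    La <- nchar(sa); Lb <- nchar(sb)
    pl <- min(thr, Lb, La)
    if (pl < 1L) return(invisible())
    hits <- Biostrings::matchPattern(Biostrings::DNAString(substr(sb, 1L, pl)),
                                     Biostrings::DNAString(sa))
    for (p in BiocGenerics::start(hits)) {
      k <- La - p + 1L
      if (k > Lb || k < thr || k <= best$k) next
      if (substr(sa, p, La) == substr(sb, 1L, k))
        best <<- list(k = k, orient = orient, sb = sb)
    }
  }
  probe(sb0, "forward", min_overlap)
  probe(reverse_complement(sb0), "revcomp", min_overlap)
  if (best$k == 0L) {
    # name the best shorter candidate for the error message
    best$k <- 0L
    probe(sb0, "forward", 8L)
    probe(reverse_complement(sb0), "revcomp", 8L)
    stop("merge_contigs(): no exact overlap of >= ", min_overlap,
         " nt between suffix(", ids[1], ") and prefix(", ids[2],
         ") in either orientation; best candidate found: ", best$k, " nt")
  }
  k <- best$k; sb <- best$sb
  merged <- paste0(sa, substr(sb, k + 1L, nchar(sb)))
  offs <- c(1L, nchar(sa) - k + 1L)
  names(offs) <- ids
  structure(list(sequence = merged, contig_offsets = offs,
                 overlap_len = k, b_orientation = best$orient),
            class = "locus_assembly")
}

#' @export
print.locus_assembly <- function(x, ...) {
  cat("<locus assembly>", nchar(x$sequence), "nt; overlap", x$overlap_len,
      "nt; second contig", x$b_orientation, "\n")
  cat("  contig offsets:",
      paste(sprintf("%s@%d", names(x$contig_offsets), x$contig_offsets),
            collapse = ", "), "\n")
  invisible(x)
}

#' Validate/construct a gene feature table
#'
#' Feature tables are plain data frames with 1-based inclusive
#' coordinates (`start <= end`; orientation in `strand`), a `kind` in
#' `{pheromone, receptor, other}` and an optional free-text `note`.
#'
#' @param name,kind,start,end,strand,note Column vectors.
#' @return A validated `data.frame`.
#' @export
gene_features <- function(name, kind, start, end, strand = "+", note = "") {
  df <- data.frame(name = as.character(name), kind = as.character(kind),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), note = as.character(note),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$kind %in% c("pheromone", "receptor", "other")),
            all(df$start <= df$end), all(df$start >= 1L),
            all(df$strand %in% c("+", "-")))
  df
}

#' Span of the mating-type genes
#'
#' Inclusive nucleotide span over pheromone and receptor features only;
#' flanking homolog features do not contribute. Invariant under feature
#' order.
#'
#' @param features Feature `data.frame` (see [gene_features()]).
#' @return Integer span in nt.
#' @export
mating_span <- function(features) {
  mk <- features$kind %in% c("pheromone", "receptor")
  if (!any(mk)) stop("mating_span(): no pheromone/receptor features")
  max(features$end[mk]) - min(features$start[mk]) + 1L
}

#' In-silico PCR: locate an amplicon by exact primer matching
#'
#' The forward primer is matched on the plus strand and the reverse
#' complement of the reverse primer downstream of it (and the mirrored
#' orientation, where the reverse primer initiates on the plus strand).
#' Matching is exact; a single mismatch yields no product.
#'
#' @param primer_fwd,primer_rev Primer sequences (>= 15 nt).
#' @param assembly A `locus_assembly` or DNA string.
#' @return A `data.frame` of product intervals (`start`, `end`,
#'   `orientation`), with attribute `multiple = TRUE` when more than one
#'   product forms; `NULL` when there is no product.
#' @export
locate_amplicon <- function(primer_fwd, primer_rev, assembly) {
  stopifnot(nchar(primer_fwd) >= 15L, nchar(primer_rev) >= 15L)
  seq <- if (inherits(assembly, "locus_assembly")) assembly$sequence
         else .contig_seq(assembly)
  subj <- Biostrings::DNAString(seq)
  prods <- list()
  pair_up <- function(fwd, rev, orient) {
    f <- Biostrings::matchPattern(Biostrings::DNAString(toupper(fwd)), subj)
    r <- Biostrings::matchPattern(
      Biostrings::DNAString(reverse_complement(toupper(rev))), subj)
    for (fs in BiocGenerics::start(f)) for (re in BiocGenerics::end(r)) {
      rs <- re - nchar(rev) + 1L
      if (rs > fs + nchar(fwd) - 1L)
        prods[[length(prods) + 1L]] <<- data.frame(
          start = fs, end = re, orientation = orient, stringsAsFactors = FALSE)
    }
  }
  pair_up(primer_fwd, primer_rev, "fwd>rev")
  pair_up(primer_rev, primer_fwd, "rev>fwd")
  if (length(prods) == 0L) return(NULL)
  out <- unique(do.call(rbind, prods))
  rownames(out) <- NULL
  attr(out, "multiple") <- nrow(out) > 1L
  out
}

#' Locate a CDS on an assembly by exact match
#'
#' @param cds cDNA/CDS sequence (string or `DNAString`).
#' @param assembly `locus_assembly` or DNA string.
#' @return A one-row `data.frame` (`start`, `end`, `strand`) or `NULL`
#'   when absent; errors when the CDS matches more than once.
#' @export
locate_cds <- function(cds, assembly) {
  seq <- if (inherits(assembly, "locus_assembly")) assembly$sequence
         else .contig_seq(assembly)
  subj <- Biostrings::DNAString(seq)
  cds <- .contig_seq(cds)
  hits <- list()
  f <- Biostrings::matchPattern(Biostrings::DNAString(cds), subj)
  for (s in BiocGenerics::start(f))
    hits[[length(hits) + 1L]] <- data.frame(start = s, end = s + nchar(cds) - 1L,
                                            strand = "+", stringsAsFactors = FALSE)
  r <- Biostrings::matchPattern(Biostrings::DNAString(reverse_complement(cds)), subj)
  for (s in BiocGenerics::start(r))
    hits[[length(hits) + 1L]] <- data.frame(start = s, end = s + nchar(cds) - 1L,
                                            strand = "-", stringsAsFactors = FALSE)
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) stop("locate_cds(): multiple exact matches")
  hits[[1L]]
}

.features_to_granges <- function(features, seqname = "locus", seqlen = NA_integer_) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$Name <- features$name
  S4Vectors::mcols(gr)$type <- features$kind
  if (!is.null(features$note)) S4Vectors::mcols(gr)$note <- features$note
  if (!is.na(seqlen))
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(seqlen, seqname)
  gr
}

#' Write a feature annotation file
#'
#' GFF3 is written 1-based inclusive, BED 0-based half-open (both via
#' rtracklayer, so the conventions are bit-exact); CSV keeps the native
#' 1-based table. BED has no type column, so the feature kind is encoded
#' in the BED name as `name|kind` and recovered by [read_annotation()].
#'
#' @param features Feature `data.frame` (see [gene_features()]); may
#'   have zero rows (a valid header-only file is produced).
#' @param path Output path.
#' @param format `"gff3"`, `"bed"` or `"csv"`.
#' @param assembly_length When given, features outside `[1, length]` are
#'   refused.
#' @param seqname Sequence name used in GFF3/BED.
#' @export
write_annotation <- function(features, path, format = c("gff3", "bed", "csv"),
                             assembly_length = NULL, seqname = "locus") {
  format <- match.arg(format)
  if (nrow(features) > 0L && !is.null(assembly_length) &&
      (any(features$start < 1L) || any(features$end > assembly_length)))
    stop("write_annotation(): feature coordinates outside assembly [1, ",
         assembly_length, "]")
  if (format == "csv") {
    utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  if (nrow(features) == 0L) {
    writeLines(if (format == "gff3") "##gff-version 3" else character(), path)
    return(invisible(path))
  }
  if (format == "gff3") {
    gr <- .features_to_granges(features, seqname,
                               if (is.null(assembly_length)) NA_integer_
                               else assembly_length)
    rtracklayer::export(gr, path, format = "gff3")
    # drop the volatile ##date pragma so identical maps are byte-identical
    lines <- readLines(path)
    writeLines(lines[!startsWith(lines, "##date")], path)
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = seqname,
      ranges = IRanges::IRanges(start = features$start, end = features$end),
      strand = features$strand)
    S4Vectors::mcols(gr)$name <- paste(features$name, features$kind, sep = "|")
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read a feature annotation file
#'
#' Inverse of [write_annotation()] for GFF3, BED and CSV; the
#' GFF3 <-> BED <-> native table round trip is lossless for coordinates,
#' strand, name and kind.
#'
#' @param path Input path.
#' @param format `"gff3"`, `"bed"` or `"csv"`; guessed from the file
#'   extension when missing.
#' @return A feature `data.frame`.
#' @export
read_annotation <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(sub("^.*\\.", "", path))
    format <- switch(ext, gff = "gff3", gff3 = "gff3", bed = "bed", csv = "csv",
                     stop("cannot guess annotation format from extension: ", ext))
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(gene_features(df$name, df$kind, df$start, df$end, df$strand,
                         if (is.null(df$note)) "" else df$note))
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (length(gr) == 0L)
    return(gene_features(character(), character(), integer(), integer(),
                         character(), character()))
  if (format == "gff3") {
    nm <- as.character(S4Vectors::mcols(gr)$Name)
    kind <- as.character(S4Vectors::mcols(gr)$type)
    note <- if ("note" %in% names(S4Vectors::mcols(gr)))
      as.character(S4Vectors::mcols(gr)$note) else ""
    note[is.na(note)] <- ""
  } else {
    parts <- strsplit(as.character(S4Vectors::mcols(gr)$name), "|", fixed = TRUE)
    nm <- vapply(parts, `[`, "", 1L)
    kind <- vapply(parts, `[`, "", 2L)
    note <- ""
  }
  gene_features(nm, kind, BiocGenerics::start(gr), BiocGenerics::end(gr),
                as.character(BiocGenerics::strand(gr)), note)
}

#' Assemble a locus map
#'
#' @param features Feature `data.frame`.
#' @param assembly Optional `locus_assembly` (or assembly length).
#' @param scar_interval Optional `[start, end]` of the locus-specific
#'   marker amplicon, e.g. from [locate_amplicon()].
#' @return An object of class `locus_map` with the features ordered by
#'   start, the mating-gene span, and the amplicon interval.
#' @export
locus_map <- function(features, assembly = NULL, scar_interval = NULL) {
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  len <- if (inherits(assembly, "locus_assembly")) nchar(assembly$sequence)
         else if (is.numeric(assembly)) as.integer(assembly) else NA_integer_
  if (!is.na(len) && nrow(features) > 0L &&
      (any(features$start < 1L) || any(features$end > len)))
    stop("locus_map(): feature coordinates outside assembly")
  span <- if (any(features$kind %in% c("pheromone", "receptor")))
    mating_span(features) else NA_integer_
  structure(list(features = features, assembly_length = len,
                 mating_span_nt = span, scar_interval = scar_interval),
            class = "locus_map")
}

#' @export
print.locus_map <- function(x, ...) {
  cat("<locus map>", nrow(x$features), "feature(s)")
  if (!is.na(x$assembly_length)) cat(" on", x$assembly_length, "nt assembly")
  cat("\n")
  if (!is.na(x$mating_span_nt))
    cat("  mating-gene span:", x$mating_span_nt, "nt\n")
  if (!is.null(x$scar_interval))
    cat("  marker amplicon:", x$scar_interval[1], "-", x$scar_interval[2], "\n")
  kinds <- table(x$features$kind)
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read the packaged mating-locus coordinate fixture
#'
#' A CSV of the published gene coordinates on the 60-kb locus (mating
#' genes plus flanking homologs), usable as a feature table.
#'
#' @return A feature `data.frame`.
#' @export
locus_feature_fixture <- function() {
  read_annotation(system.file("extdata", "table2_features.csv",
                              package = "b3locus"), format = "csv")
}
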