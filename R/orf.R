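#' Construct a contig
#'
#' A contig is a named DNA sequence (alphabet `A,C,G,T,N`) with a free-text
#' source tag, e.g. a clone name or "synthetic".
#'
#' @param id Character label.
#' @param sequence DNA string.
#' @param source Free-text provenance tag.
#' @return An object of class `contig`.
#' @export
contig <- function(id, sequence, source = "unknown") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("contig '", id, "': sequence contains symbols outside {A,C,G,T,N}")
  structure(list(id = id, sequence = sequence, source = source),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat("<contig>", x$id, "-", nchar(x$sequence), "nt (source:", x$source, ")\n")
  invisible(x)
}

.contig_seq <- function(x) {
  if (inherits(x, "contig")) return(x$sequence)
  if (inherits(x, "DNAString")) return(as.character(x))
  if (inherits(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    return(as.character(x[[1L]]))
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

.contig_id <- function(x, default = "contig") {
  if (inherits(x, "contig")) return(x$id)
  if (inherits(x, "DNAStringSet") && !is.null(names(x))) return(names(x)[1L])
  default
}

#' Read contigs from a FASTA file
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @param source Source tag recorded on each contig.
#' @return A list of [contig()] objects.
#' @export
read_contigs <- function(path, source = path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  ids <- if (is.null(names(set))) paste0("contig_", seq_along(set)) else
    sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    contig(ids[i], as.character(set[[i]]), source = source))
}

## One reading frame worth of ORFs: `aa` is the frame translation, `f` the
## 0-based frame offset on the scanned strand, `L` the contig length.
.frame_orfs <- function(aa, f, L, strand, min_aa, max_aa) {
  v <- strsplit(aa, "", fixed = TRUE)[[1L]]
  m <- which(v == "M")
  s <- which(v == "*")
  if (length(m) == 0L || length(s) == 0L) return(NULL)
  nxt <- findInterval(m, s) + 1L           # first stop strictly after each M
  ok <- nxt <= length(s)
  m <- m[ok]
  if (length(m) == 0L) return(NULL)
  j <- s[nxt[ok]]
  len <- j - m
  keep <- len >= min_aa & len <= max_aa
  m <- m[keep]; j <- j[keep]; len <- len[keep]
  if (length(m) == 0L) return(NULL)
  local_start <- f + 3L * (m - 1L) + 1L
  local_end <- f + 3L * j                  # includes the stop codon
  if (strand == "+") {
    start <- local_start; end <- local_end
  } else {
    start <- L - local_end + 1L; end <- L - local_start + 1L
  }
  data.frame(start = start, end = end, strand = strand, frame = f,
             length_aa = len,
             peptide = substring(aa, m, j - 1L),
             stringsAsFactors = FALSE)
}

#' Six-frame ORF extraction
#'
#' Scans both strands and all three frames of a contig for ATG-initiated,
#' first-stop-terminated open reading frames whose translated peptide
#' (initiator Met included, stop excluded) has `min_aa` to `max_aa`
#' residues. All candidates are returned: nested and overlapping ORFs are
#' not suppressed, so downstream filters decide what is a gene.
#'
#' Coordinates are 1-based inclusive on the forward strand and span the
#' stop codon; for a minus-strand ORF, reverse-complementing
#' `[start, end]` reproduces the coding sequence.
#'
#' @param x A [contig()], `DNAString`, or plain DNA string.
#' @param min_aa,max_aa Peptide length bounds (default 10--100, the small
#'   peptide window used to mine pheromone precursor candidates).
#' @param id Contig id used when `x` carries none.
#' @return A `data.frame` of class `orf_table` with columns `contig_id`,
#'   `start`, `end`, `strand`, `frame`, `length_aa`, `peptide`.
#' @export
six_frame_orfs <- function(x, min_aa = 10L, max_aa = 100L, id = NULL) {
  stopifnot(min_aa >= 1L, min_aa <= max_aa)
  seq <- .contig_seq(x)
  cid <- if (is.null(id)) .contig_id(x) else id
  L <- nchar(seq)
  out <- list()
  if (L >= 3L * (min_aa + 1L)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else reverse_complement(seq)
      for (f in 0:2) {
        if (L - f < 3L) next
        aa <- translate_dna(substr(s, f + 1L, L))
        res <- .frame_orfs(aa, f, L, strand, min_aa, max_aa)
        if (!is.null(res)) out[[length(out) + 1L]] <- res
      }
    }
  }
  if (length(out) == 0L) {
    df <- data.frame(contig_id = character(), start = integer(),
                     end = integer(), strand = character(),
                     frame = integer(), length_aa = integer(),
                     peptide = character(), stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, out)
    df <- cbind(contig_id = cid, df, stringsAsFactors = FALSE)
    df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("orf_table", "data.frame")
  df
}

#' Write an ORF table as CSV
#'
#' @param orfs An `orf_table` from [six_frame_orfs()].
#' @param path Output CSV path.
#' @export
write_orf_table <- function(orfs, path) {
  utils::write.csv(as.data.frame(orfs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ORF peptides as protein FASTA
#'
#' @param orfs An `orf_table`.
#' @param path Output FASTA path.
#' @export
write_orf_fasta <- function(orfs, path) {
  ids <- sprintf("%s_%d_%d_%s", orfs$contig_id, orfs$start, orfs$end, orfs$strand)
  aa <- Biostrings::AAStringSet(orfs$peptide)
  names(aa) <- ids
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
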