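## Independent oracles used by the property tests. These deliberately use
## naive algorithms (position-by-position scans, exhaustive enumeration)
## that share no code with the package implementation.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_dna <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_peptide <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

## naive single-codon translation table (standard code), built from scratch
.oracle_code <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  cods <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(aas, cods)
})

oracle_translate_codon <- function(codon) {
  if (!grepl("N", codon)) return(unname(.oracle_code[codon]))
  expand <- function(c3) {
    idx <- which(strsplit(c3, "")[[1]] == "N")[1]
    if (is.na(idx)) return(c3)
    unlist(lapply(c("A", "C", "G", "T"), function(b) {
      s <- c3
      substr(s, idx, idx) <- b
      expand(s)
    }))
  }
  res <- unique(unname(.oracle_code[expand(codon)]))
  if (length(res) == 1L) res else "X"
}

## brute-force ORF scan: every position, both strands, walk codons
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_orfs <- function(seq, min_aa, max_aa) {
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (p in seq_len(L - 2L)) {
      if (substr(s, p, p + 2L) != "ATG") next
      q <- p
      pep <- character()
      found <- FALSE
      while (q + 2L <= L) {
        cod <- substr(s, q, q + 2L)
        aa <- oracle_translate_codon(cod)
        if (aa == "*") { found <- TRUE; break }
        pep <- c(pep, aa)
        q <- q + 3L
      }
      if (!found) next
      n <- length(pep)
      if (n < min_aa || n > max_aa) next
      le <- q + 2L
      st <- if (strand == "+") p else L - le + 1L
      en <- if (strand == "+") le else L - p + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        start = st, end = en, strand = strand,
        peptide = paste(pep, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), peptide = character()))
  df <- do.call(rbind, rows)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

## exhaustive global-alignment score: enumerate all alignments, charging
## a gap run of length L as open + extend * L
oracle_align_score <- function(a, b, submat, open = 10, extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= n)
      best <- max(best, -extend - (if (prev != "X") open else 0) +
                    rec(i + 1L, j, "X"))
    if (j <= m)
      best <- max(best, -extend - (if (prev != "Y") open else 0) +
                    rec(i, j + 1L, "Y"))
    best
  }
  rec(1L, 1L, "start")
}
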