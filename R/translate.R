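#' Translate a DNA string
#'
#' Codon-wise translation under a chosen genetic code. Stop codons are
#' rendered as `*`. Codons containing `N` translate to `X` unless every
#' resolution of the ambiguity gives the same amino acid (e.g. `GCN` is
#' always Ala). A trailing partial codon (1--2 nt) is silently dropped so
#' that frame scans can pass arbitrary suffixes.
#'
#' @param dna Single character string over `A,C,G,T,N` (case-insensitive).
#' @param code Genetic code identifier passed to
#'   [Biostrings::getGeneticCode()]; default `"1"` (the standard code).
#' @return A single amino-acid string, one symbol per complete codon;
#'   `""` for empty input.
#' @examples
#' translate_dna("ATGGCC")  # "MA"
#' translate_dna("ATGTAA")  # "M*"
#' translate_dna("ATGANG")  # "MX"
#' @export
translate_dna <- function(dna, code = "1") {
  stopifnot(is.character(dna), length(dna) == 1L, !is.na(dna))
  dna <- toupper(dna)
  if (nchar(dna) == 0L) return("")
  if (grepl("[^ACGTN]", dna)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", dna), "")[[1]])
    stop("non-DNA symbols in input (only A, C, G, T, N are accepted): ",
         paste(bad, collapse = ", "))
  }
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n == 0L) return("")
  gc <- Biostrings::getGeneticCode(code)
  cods <- substring(dna, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  aa <- unname(gc[cods])                  # NA for codons containing N
  if (anyNA(aa)) {
    for (u in unique(cods[is.na(aa)]))
      aa[is.na(aa) & cods == u] <- .solve_n_codon(u, gc)
  }
  paste(aa, collapse = "")
}

## Resolve a codon containing N: the consensus amino acid if every
## resolution agrees (e.g. GCN -> A), X otherwise.
.solve_n_codon <- function(codon, gc) {
  expanded <- codon
  for (k in which(strsplit(codon, "")[[1L]] == "N")) {
    expanded <- unlist(lapply(expanded, function(s) {
      vapply(c("A", "C", "G", "T"), function(b) {
        substr(s, k, k) <- b
        s
      }, "")
    }), use.names = FALSE)
  }
  res <- unique(unname(gc[expanded]))
  if (length(res) == 1L) res else "X"
}

#' Reverse complement of a DNA string
#'
#' @param dna Single character string over `A,C,G,T,N`.
#' @return The reverse complement as a character string.
#' @export
reverse_complement <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(dna))))
}
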