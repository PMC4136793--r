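#' Find a C-terminal CaaX motif
#'
#' Lipopeptide pheromone precursors end in a prenylation signal whose
#' defining feature is a cysteine at the 4th position from the C-terminus;
#' the two "a" positions are deliberately not constrained to aliphatic
#' residues, since characterized basidiomycete pheromones include looser
#' CXXX variants (CVCH, CVRG, CVVA).
#'
#' @param peptide Amino-acid string.
#' @return A list of class `caax_motif` with `motif` (the terminal four
#'   residues) and `cys_offset` (always 4), or `NULL` when absent or the
#'   peptide is shorter than 4 residues.
#' @export
find_caax <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  n <- nchar(peptide)
  if (n < 4L) return(NULL)
  if (substr(peptide, n - 3L, n - 3L) != "C") return(NULL)
  structure(list(motif = substr(peptide, n - 3L, n), cys_offset = 4L),
            class = "caax_motif")
}

#' Enumerate candidate pheromone cleavage sites
#'
#' Mature pheromones are excised between an ER or TR doublet and the
#' farnesylated Cys at position -4. This scans for E/T followed by R with
#' the R (the doublet's second residue, taken as the cut-site reference)
#' at a C-terminal offset inside `window`, and scores each site by its
#' consensus context: +1 for the doublet itself, +1 for Pro at cut-site
#' position -4, +1 for Asp/Asn at -2.
#'
#' Offsets count from the C-terminus with the terminal residue at 1, so a
#' doublet at offset `o` yields a mature peptide of `o - 4` residues
#' (doublet-adjacent through the Cys inclusive).
#'
#' @param peptide Amino-acid string (expected to carry a CaaX motif).
#' @param window Integer range of admissible `doublet_end_offset` values;
#'   the default `c(13, 19)` spans mature lengths 9--15.
#' @return A `data.frame` with one row per site: `doublet`,
#'   `doublet_end_offset`, `has_pro_minus4`, `has_dn_minus2`, `score`,
#'   sorted by descending score then ascending offset. Zero rows when no
#'   doublet falls in the window.
#' @export
enumerate_cleavage_sites <- function(peptide, window = c(13L, 19L)) {
  stopifnot(is.character(peptide), length(peptide) == 1L,
            length(window) == 2L, window[1] <= window[2], window[1] > 4L)
  v <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  n <- length(v)
  empty <- data.frame(doublet = character(), doublet_end_offset = integer(),
                      has_pro_minus4 = logical(), has_dn_minus2 = logical(),
                      score = integer(), stringsAsFactors = FALSE)
  # positions of the doublet's second residue (R) admissible by offset
  p2 <- seq_len(n)[n - seq_len(n) + 1L >= window[1] & n - seq_len(n) + 1L <= window[2]]
  p2 <- p2[p2 >= 2L]
  if (length(p2) == 0L) return(empty)
  is_site <- v[p2] == "R" & v[p2 - 1L] %in% c("E", "T")
  p2 <- p2[is_site]
  if (length(p2) == 0L) return(empty)
  pro <- ifelse(p2 - 4L >= 1L, v[pmax(p2 - 4L, 1L)] == "P", FALSE)
  dn <- ifelse(p2 - 2L >= 1L, v[pmax(p2 - 2L, 1L)] %in% c("D", "N"), FALSE)
  df <- data.frame(doublet = paste0(v[p2 - 1L], "R"),
                   doublet_end_offset = n - p2 + 1L,
                   has_pro_minus4 = pro, has_dn_minus2 = dn,
                   score = 1L + pro + dn, stringsAsFactors = FALSE)
  df[order(-df$score, df$doublet_end_offset), , drop = FALSE]
}

#' Predict the mature pheromone of a precursor
#'
#' Chooses a cleavage site and derives the mature peptide: the residues
#' strictly after the doublet through the CaaX cysteine inclusive (the
#' three terminal residues being removed during prenylation processing).
#' Site choice is by descending consensus score, then membership of the
#' preferred length band, then the smaller offset (shorter mature
#' peptide).
#'
#' @param precursor A `pheromone_precursor` (see [classify_pheromone()]).
#' @param accept_len Acceptable mature length range (default 9--15).
#' @param preferred_len Preferred length sub-range (default 12--13).
#' @return The completed `pheromone_precursor`; when no site yields an
#'   acceptable length, `chosen_site` and `mature_peptide` are `NULL`.
#' @export
predict_mature <- function(precursor, accept_len = c(9L, 15L),
                           preferred_len = c(12L, 13L)) {
  stopifnot(inherits(precursor, "pheromone_precursor"))
  sites <- precursor$sites
  precursor$chosen_site <- NULL
  precursor$mature_peptide <- NULL
  precursor$mature_length <- NULL
  if (is.null(sites) || nrow(sites) == 0L) return(precursor)
  len <- sites$doublet_end_offset - 4L
  ok <- len >= accept_len[1] & len <= accept_len[2]
  if (!any(ok)) return(precursor)
  cand <- sites[ok, , drop = FALSE]
  clen <- len[ok]
  pref <- clen >= preferred_len[1] & clen <= preferred_len[2]
  o <- order(-cand$score, -pref, cand$doublet_end_offset)
  chosen <- cand[o[1L], , drop = FALSE]
  n <- nchar(precursor$peptide)
  off <- chosen$doublet_end_offset
  mature <- substr(precursor$peptide, n - off + 2L, n - 3L)
  precursor$chosen_site <- chosen
  precursor$mature_peptide <- mature
  precursor$mature_length <- nchar(mature)
  precursor
}

#' Classify an ORF as a pheromone precursor
#'
#' Applies the full small-gene grammar: peptide length within
#' `[min_aa, max_aa]`, a C-terminal CaaX motif, and (in strict mode) an
#' ER/TR cleavage site producing an acceptable mature length. In
#' permissive mode, CaaX-only candidates are kept with a warning recorded
#' on the object.
#'
#' @param x Either a one-row `orf_table` slice or a plain peptide string.
#' @param min_aa,max_aa Precursor size filter (default 10--100 aa).
#' @param window Cleavage-site search window, see
#'   [enumerate_cleavage_sites()].
#' @param accept_len,preferred_len Mature-length ranges, see
#'   [predict_mature()].
#' @param mode `"strict"` (requires a scored site with acceptable mature
#'   length) or `"permissive"`.
#' @return A `pheromone_precursor` object, or `NULL` when rejected.
#' @export
classify_pheromone <- function(x, min_aa = 10L, max_aa = 100L,
                               window = c(13L, 19L),
                               accept_len = c(9L, 15L),
                               preferred_len = c(12L, 13L),
                               mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  if (is.character(x)) {
    peptide <- x
    orf <- NULL
  } else {
    stopifnot(is.data.frame(x), nrow(x) == 1L)
    peptide <- x$peptide
    orf <- as.data.frame(x)
  }
  n <- nchar(peptide)
  if (n < min_aa || n > max_aa) return(NULL)
  caax <- find_caax(peptide)
  if (is.null(caax)) return(NULL)
  prec <- structure(list(orf = orf, peptide = peptide, caax = caax,
                         sites = enumerate_cleavage_sites(peptide, window),
                         chosen_site = NULL, mature_peptide = NULL,
                         mature_length = NULL, mode = mode, warning = NULL),
                    class = "pheromone_precursor")
  prec <- predict_mature(prec, accept_len = accept_len,
                         preferred_len = preferred_len)
  if (is.null(prec$chosen_site)) {
    if (mode == "strict") return(NULL)
    prec$warning <- "CaaX-only candidate: no acceptable cleavage site"
  }
  prec
}

#' @export
print.pheromone_precursor <- function(x, ...) {
  cat("<pheromone precursor>", nchar(x$peptide), "aa, CaaX", x$caax$motif, "\n")
  if (!is.null(x$chosen_site)) {
    cat("  cleavage:", x$chosen_site$doublet, "at offset",
        x$chosen_site$doublet_end_offset, "(score", x$chosen_site$score, ")\n")
    cat("  mature:", x$mature_peptide, "(", x$mature_length, "aa )\n")
  } else {
    cat("  no acceptable cleavage site\n")
  }
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Scan an ORF table for pheromone precursors
#'
#' @param orfs An `orf_table` from [six_frame_orfs()].
#' @param ... Passed to [classify_pheromone()].
#' @return A list of `pheromone_precursor` objects (possibly empty).
#' @export
scan_pheromones <- function(orfs, ...) {
  out <- lapply(seq_len(nrow(orfs)), function(i)
    classify_pheromone(orfs[i, , drop = FALSE], ...))
  out[!vapply(out, is.null, logical(1L))]
}

#' Tabular report for classified precursors
#'
#' @param precursors List of `pheromone_precursor` objects.
#' @return A `data.frame` with ORF coordinates, motif, doublet, offset,
#'   mature peptide/length and consensus score.
#' @export
precursor_report <- function(precursors) {
  rows <- lapply(precursors, function(p) {
    orf <- p$orf
    data.frame(
      contig_id = if (is.null(orf)) NA_character_ else orf$contig_id,
      start = if (is.null(orf)) NA_integer_ else orf$start,
      end = if (is.null(orf)) NA_integer_ else orf$end,
      strand = if (is.null(orf)) NA_character_ else orf$strand,
      length_aa = nchar(p$peptide),
      caax = p$caax$motif,
      doublet = if (is.null(p$chosen_site)) NA_character_ else p$chosen_site$doublet,
      doublet_end_offset = if (is.null(p$chosen_site)) NA_integer_ else
        p$chosen_site$doublet_end_offset,
      score = if (is.null(p$chosen_site)) NA_integer_ else p$chosen_site$score,
      mature_peptide = if (is.null(p$mature_peptide)) NA_character_ else p$mature_peptide,
      mature_length = if (is.null(p$mature_length)) NA_integer_ else p$mature_length,
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      length_aa = integer(), caax = character(),
                      doublet = character(), doublet_end_offset = integer(),
                      score = integer(), mature_peptide = character(),
                      mature_length = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write mature pheromone peptides as FASTA
#'
#' @param precursors List of `pheromone_precursor` objects.
#' @param path Output FASTA path.
#' @param ids Optional sequence names.
#' @export
write_mature_fasta <- function(precursors, path, ids = NULL) {
  keep <- !vapply(precursors, function(p) is.null(p$mature_peptide), logical(1L))
  precursors <- precursors[keep]
  aa <- Biostrings::AAStringSet(vapply(precursors, `[[`, "", "mature_peptide"))
  names(aa) <- if (is.null(ids)) paste0("mature_", seq_along(precursors)) else ids[keep]
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' C-terminally anchored precursor alignment block
#'
#' A display aid (not a multiple-alignment method): precursors are padded
#' on the left so their C-termini share a column, with the predicted
#' mature segment and the cleavage doublet annotated underneath each row.
#'
#' @param precursors List of at least two `pheromone_precursor` objects.
#' @param ids Optional row labels.
#' @return An object of class `precursor_alignment` with a `print`
#'   method; carries `rows` (padded sequences), `doublet_cols`,
#'   `mature_cols` and `n_mismatch_cols` (columns holding more than one
#'   distinct residue).
#' @export
align_precursors <- function(precursors, ids = NULL) {
  if (length(precursors) < 2L)
    stop("align_precursors() needs at least two precursors")
  peps <- vapply(precursors, `[[`, "", "peptide")
  if (is.null(ids)) ids <- paste0("precursor_", seq_along(precursors))
  w <- max(nchar(peps))
  pad <- w - nchar(peps)
  rows <- paste0(strrep("-", pad), peps)
  ann <- character(length(peps))
  doublet_cols <- rep(NA_integer_, length(peps))
  mature_cols <- vector("list", length(peps))
  for (i in seq_along(precursors)) {
    p <- precursors[[i]]
    a <- rep(" ", w)
    if (!is.null(p$chosen_site)) {
      n <- nchar(p$peptide)
      off <- p$chosen_site$doublet_end_offset
      r_col <- w - off + 1L              # C-terminal anchoring
      a[c(r_col - 1L, r_col)] <- "^"
      mcols <- (w - off + 2L):(w - 3L)
      a[mcols] <- "="
      doublet_cols[i] <- r_col
      mature_cols[[i]] <- mcols
    }
    ann[i] <- paste(a, collapse = "")
  }
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  n_mis <- sum(apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    length(unique(col)) > 1L
  }))
  structure(list(ids = ids, rows = rows, annotations = ann,
                 doublet_cols = doublet_cols, mature_cols = mature_cols,
                 n_mismatch_cols = n_mis),
            class = "precursor_alignment")
}

#' @export
print.precursor_alignment <- function(x, ...) {
  wid <- max(nchar(x$ids))
  for (i in seq_along(x$rows)) {
    cat(formatC(x$ids[i], width = wid), x$rows[i], "\n")
    cat(strrep(" ", wid), x$annotations[i], "\n")
  }
  cat("mismatch columns:", x$n_mismatch_cols, "\n")
  invisible(x)
}
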