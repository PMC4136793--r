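## Kyte-Doolittle hydropathy scale
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

.kd_values <- function(peptide) {
  v <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  kd <- unname(.KD[v])
  if (anyNA(kd)) {
    warning("unknown residue symbol(s) treated as hydropathy 0: ",
            paste(unique(v[is.na(kd)]), collapse = ", "))
    kd[is.na(kd)] <- 0
  }
  kd
}

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Centered window mean of per-residue hydropathy; edge residues use
#' truncated windows. Unknown residue symbols contribute 0 with a
#' warning.
#'
#' @param peptide Amino-acid string.
#' @param window Odd window width, at most the peptide length.
#' @return Numeric vector, one value per residue.
#' @export
hydropathy_profile <- function(peptide, window = 19L) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  L <- nchar(peptide)
  stopifnot(window %% 2L == 1L, window >= 1L, window <= L)
  kd <- .kd_values(peptide)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, kd))
  i <- seq_len(L)
  lo <- pmax(1L, i - half)
  hi <- pmin(L, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Predict transmembrane segments from hydropathy
#'
#' Single-sequence TM caller: maximal runs of windowed hydropathy at or
#' above `threshold` are found, runs separated by fewer than `merge_gap`
#' residues are merged, segment boundaries are refined to the underlying
#' hydrophobic stretch (extended/trimmed by the sign of per-residue
#' hydropathy), and refined segments shorter than `min_len` are dropped.
#' Fully deterministic.
#'
#' @param peptide Amino-acid string of length at least `min_len`.
#' @param window Hydropathy window (odd; default 19).
#' @param threshold Windowed-hydropathy call threshold (default 1.6).
#' @param min_len Minimum segment length in residues (default 15).
#' @param merge_gap Runs closer than this many residues are merged
#'   (default 3).
#' @return A `data.frame` with `start`, `end`, `length`,
#'   `mean_hydropathy` (per-residue mean over the segment), ordered and
#'   non-overlapping.
#' @export
predict_tm_segments <- function(peptide, window = 19L, threshold = 1.6,
                                min_len = 15L, merge_gap = 3L) {
  L <- nchar(peptide)
  stopifnot(L >= min_len)
  prof <- hydropathy_profile(peptide, window = min(window, L - (1L - L %% 2L)))
  kd <- suppressWarnings(.kd_values(peptide))
  r <- rle(prof >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (nrow(seg) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), mean_hydropathy = numeric()))
  # merge runs separated by < merge_gap
  merged <- seg[1L, , drop = FALSE]
  if (nrow(seg) > 1L) for (i in 2:nrow(seg)) {
    gap <- seg[i, 1L] - merged[nrow(merged), 2L] - 1L
    if (gap < merge_gap) merged[nrow(merged), 2L] <- seg[i, 2L]
    else merged <- rbind(merged, seg[i, , drop = FALSE])
  }
  # refine each run to the underlying hydrophobic stretch
  for (i in seq_len(nrow(merged))) {
    s <- merged[i, 1L]; e <- merged[i, 2L]
    while (s > 1L && kd[s - 1L] > 0) s <- s - 1L
    while (e < L && kd[e + 1L] > 0) e <- e + 1L
    while (s < e && kd[s] <= 0) s <- s + 1L
    while (e > s && kd[e] <= 0) e <- e - 1L
    merged[i, ] <- c(s, e)
  }
  # refinement can make neighbours touch: merge overlaps
  out <- merged[1L, , drop = FALSE]
  if (nrow(merged) > 1L) for (i in 2:nrow(merged)) {
    if (merged[i, 1L] <= out[nrow(out), 2L] + 1L)
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], merged[i, 2L])
    else out <- rbind(out, merged[i, , drop = FALSE])
  }
  len <- out[, 2L] - out[, 1L] + 1L
  keep <- len >= min_len
  out <- out[keep, , drop = FALSE]
  data.frame(start = out[, 1L], end = out[, 2L],
             length = out[, 2L] - out[, 1L] + 1L,
             mean_hydropathy = vapply(seq_len(nrow(out)), function(i)
               mean(kd[out[i, 1L]:out[i, 2L]]), numeric(1L)))
}

#' Build a pheromone-receptor topology model
#'
#' Predicts TM segments, assigns topology alternating from an
#' extracellular N-terminus (the STE3-family convention, no
#' signal-peptide modelling), and measures the terminal tails. A protein
#' is flagged `receptor_like` when it has exactly seven TM segments and
#' a C-terminal cytoplasmic tail shorter than `tail_threshold` residues
#' (the configuration seen in unusually short-tailed receptors).
#'
#' @param protein_id Label.
#' @param peptide Amino-acid string.
#' @param tail_threshold Receptor-like C-tail cut-off in residues
#'   (default 50).
#' @param ... Passed to [predict_tm_segments()].
#' @return An object of class `receptor_model` with fields `protein_id`,
#'   `length_aa`, `segments`, `n_tail_len`, `c_tail_len`, `topology`,
#'   `seven_tm`, `receptor_like`.
#' @export
build_receptor_model <- function(protein_id, peptide, tail_threshold = 50L, ...) {
  segs <- predict_tm_segments(peptide, ...)
  L <- nchar(peptide)
  n <- nrow(segs)
  seven <- n == 7L
  if (!seven)
    warning("topology: ", protein_id, " has ", n,
            " predicted TM segments (7 expected for an STE3-class receptor)")
  topology <- if (n > 0L)
    ifelse(seq_len(n) %% 2L == 1L, "out->in", "in->out") else character()
  n_tail <- if (n > 0L) segs$start[1L] - 1L else L
  c_tail <- if (n > 0L) L - segs$end[n] else L
  structure(list(protein_id = protein_id, length_aa = L, segments = segs,
                 n_tail_len = n_tail, c_tail_len = c_tail,
                 topology = topology,
                 c_tail_location = if (seven) "cytoplasmic" else NA_character_,
                 seven_tm = seven,
                 receptor_like = seven && c_tail < tail_threshold),
            class = "receptor_model")
}

#' @export
print.receptor_model <- function(x, ...) {
  cat("<receptor model>", x$protein_id, "-", x$length_aa, "aa,",
      nrow(x$segments), "TM segment(s)\n")
  if (nrow(x$segments) > 0L) {
    cat("  segments:",
        paste(sprintf("%d-%d", x$segments$start, x$segments$end), collapse = " "),
        "\n")
    cat("  N-tail:", x$n_tail_len, "aa; C-tail:", x$c_tail_len, "aa",
        if (!is.na(x$c_tail_location)) paste0("(", x$c_tail_location, ")"), "\n")
  }
  cat("  receptor-like (7 TM, short C-tail):", x$receptor_like, "\n")
  invisible(x)
}

## Translate a cDNA/CDS: frame 1, trimmed at the first stop.
.cdna_to_protein <- function(dna) {
  aa <- translate_dna(.contig_seq(dna))
  sub("\\*.*$", "", aa)
}

#' Annotate a set of receptor proteins
#'
#' Builds a [build_receptor_model()] for every sequence and returns a
#' per-protein report. cDNA input is translated in frame 1 and trimmed
#' at the first stop codon.
#'
#' @param x An `AAStringSet`, `DNAStringSet` (cDNA), named character
#'   vector of sequences, or a FASTA path.
#' @param tail_threshold Receptor-like C-tail cut-off; see
#'   [build_receptor_model()].
#' @param ... Passed to [predict_tm_segments()].
#' @return A list with `models` (named list of `receptor_model`) and
#'   `report` (a `data.frame`: id, length_aa, n_tm, segments, n_tail_len,
#'   c_tail_len, receptor_like).
#' @export
analyze_receptors <- function(x, tail_threshold = 50L, ...) {
  peps <- .as_protein_set(x)
  models <- lapply(seq_along(peps), function(i)
    suppressWarnings(build_receptor_model(names(peps)[i], peps[[i]],
                                          tail_threshold = tail_threshold, ...)))
  names(models) <- names(peps)
  report <- do.call(rbind, lapply(models, function(m)
    data.frame(id = m$protein_id, length_aa = m$length_aa,
               n_tm = nrow(m$segments),
               segments = paste(sprintf("%d-%d", m$segments$start, m$segments$end),
                                collapse = ";"),
               n_tail_len = m$n_tail_len, c_tail_len = m$c_tail_len,
               seven_tm = m$seven_tm, receptor_like = m$receptor_like,
               stringsAsFactors = FALSE)))
  rownames(report) <- NULL
  list(models = models, report = report)
}

## Coerce protein input forms to a named character vector.
.as_protein_set <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- Biostrings::readBStringSet(x)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
    # heuristically detect nucleotide input
    if (all(grepl("^[ACGTNacgtn]+$", seqs))) seqs <- vapply(seqs, .cdna_to_protein, "")
    return(seqs)
  }
  if (inherits(x, "AAStringSet")) {
    seqs <- as.character(x)
    if (is.null(names(seqs))) names(seqs) <- paste0("protein_", seq_along(seqs))
    return(seqs)
  }
  if (inherits(x, "DNAStringSet")) {
    seqs <- vapply(as.character(x), .cdna_to_protein, "")
    names(seqs) <- if (is.null(names(x))) paste0("protein_", seq_along(x)) else names(x)
    return(seqs)
  }
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- paste0("protein_", seq_along(x))
  if (all(grepl("^[ACGTNacgtn]+$", x))) {
    nm <- names(x)
    x <- vapply(x, .cdna_to_protein, "")
    names(x) <- nm
  }
  toupper(x)
}

#' Write the receptor report as CSV
#'
#' @param ann Result of [analyze_receptors()].
#' @param path Output CSV path.
#' @export
write_receptor_report <- function(ann, path) {
  utils::write.csv(ann$report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
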