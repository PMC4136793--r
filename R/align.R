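.get_submat <- function(m) {
  if (is.matrix(m)) return(m)
  stopifnot(is.character(m), length(m) == 1L)
  e <- new.env()
  utils::data(list = m, package = "Biostrings", envir = e)
  get(m, envir = e)
}

## Global (Needleman-Wunsch) alignment with affine gaps, Gotoh's
## three-state recursion. A gap of length L costs gap_open + gap_extend*L
## (terminal gaps are penalized: true global alignment). Row-vectorized;
## the horizontal-gap state is closed over each row with a running-max
## identity.
.nw_align <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  go <- gap_open; ge <- gap_extend
  NEG <- -Inf
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  M[1L, 1L] <- 0
  if (m > 0L) Y[1L, 1L + seq_len(m)] <- -(go + ge * seq_len(m))
  ks <- 0:m
  for (i in seq_len(n)) {
    pm <- M[i, ]; px <- X[i, ]; py <- Y[i, ]
    sub <- submat[av[i], bv]
    best_prev <- pmax(pm, px, py)
    Mrow <- c(NEG, sub + best_prev[seq_len(m)])
    Xrow <- pmax(pm - go - ge, px - ge, py - go - ge)
    B <- pmax(Mrow, Xrow) + ge * ks
    cm <- cummax(B)
    Yrow <- c(NEG, cm[seq_len(m)] - go - ge * seq_len(m))
    M[i + 1L, ] <- Mrow; X[i + 1L, ] <- Xrow; Y[i + 1L, ] <- Yrow
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])

  # traceback
  eps <- 1e-9
  i <- n; j <- m
  st <- c("M", "X", "Y")[which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L],
                                     Y[n + 1L, m + 1L]))]
  al_a <- character(); al_b <- character()
  matches <- 0L; columns <- 0L
  while (i > 0L || j > 0L) {
    columns <- columns + 1L
    if (st == "M") {
      al_a <- c(al_a, av[i]); al_b <- c(al_b, bv[j])
      if (av[i] == bv[j]) matches <- matches + 1L
      v <- M[i + 1L, j + 1L] - submat[av[i], bv[j]]
      cand <- c(M[i, j], X[i, j], Y[i, j])
      st <- c("M", "X", "Y")[which(abs(cand - v) < eps)[1L]]
      i <- i - 1L; j <- j - 1L
    } else if (st == "X") {
      al_a <- c(al_a, av[i]); al_b <- c(al_b, "-")
      v <- X[i + 1L, j + 1L]
      if (abs(v - (M[i, j + 1L] - go - ge)) < eps) st <- "M"
      else if (abs(v - (X[i, j + 1L] - ge)) < eps) st <- "X"
      else st <- "Y"
      i <- i - 1L
    } else {
      al_a <- c(al_a, "-"); al_b <- c(al_b, bv[j])
      v <- Y[i + 1L, j + 1L]
      if (abs(v - (Y[i + 1L, j] - ge)) < eps) st <- "Y"
      else if (abs(v - (M[i + 1L, j] - go - ge)) < eps) st <- "M"
      else st <- "X"
      j <- j - 1L
    }
  }
  list(score = score,
       aligned_a = paste(rev(al_a), collapse = ""),
       aligned_b = paste(rev(al_b), collapse = ""),
       matches = matches, columns = columns)
}

#' Global alignment percent identity between two proteins
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a gap of
#' length L costs `gap_open + gap_extend * L`; terminal gaps are
#' penalized). Identity is `100 * matches / aligned_columns`, with
#' gapped columns included in the denominator ("full-length" identity).
#' `mode = "truncated"` first truncates the longer sequence to
#' `truncate_len` residues (default: the length of the shorter
#' sequence), mirroring comparisons against a receptor whose
#' non-corresponding C-terminal extension is removed.
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param id_a,id_b Labels.
#' @param mode `"full"` or `"truncated"`.
#' @param truncate_len Truncation length for `mode = "truncated"`.
#' @param substitution_matrix Matrix or the name of a matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters (default 10 / 0.5).
#' @return An object of class `alignment_result`: `id_a`, `id_b`,
#'   `matches`, `aligned_columns`, `identity_pct`, `score`, plus the
#'   aligned strings.
#' @export
global_identity <- function(a, b, id_a = "a", id_b = "b",
                            mode = c("full", "truncated"),
                            truncate_len = NULL,
                            substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  mode <- match.arg(mode)
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("global_identity(): empty sequence")
  a <- toupper(a); b <- toupper(b)
  if (mode == "truncated") {
    if (is.null(truncate_len)) truncate_len <- min(nchar(a), nchar(b))
    if (nchar(a) >= nchar(b)) a <- substr(a, 1L, truncate_len)
    else b <- substr(b, 1L, truncate_len)
  }
  submat <- .get_submat(substitution_matrix)
  res <- .nw_align(a, b, submat, gap_open = gap_open, gap_extend = gap_extend)
  structure(list(id_a = id_a, id_b = id_b, mode = mode,
                 matches = res$matches, aligned_columns = res$columns,
                 identity_pct = 100 * res$matches / res$columns,
                 score = res$score,
                 aligned_a = res$aligned_a, aligned_b = res$aligned_b),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> %s vs %s (%s): identity %.1f%% (%d/%d columns), score %.1f\n",
              x$id_a, x$id_b, x$mode, x$identity_pct, x$matches,
              x$aligned_columns, x$score))
  invisible(x)
}

#' Pairwise identity matrix for a protein set
#'
#' @param x Protein input accepted by [analyze_receptors()].
#' @param ... Passed to [global_identity()].
#' @return A symmetric numeric matrix of percent identities (diagonal
#'   100).
#' @export
identity_matrix <- function(x, ...) {
  peps <- .as_protein_set(x)
  k <- length(peps)
  out <- matrix(100, k, k, dimnames = list(names(peps), names(peps)))
  if (k > 1L) for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    r <- global_identity(peps[[i]], peps[[j]], names(peps)[i], names(peps)[j], ...)
    out[i, j] <- out[j, i] <- r$identity_pct
  }
  out
}
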