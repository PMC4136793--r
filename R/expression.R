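#' Read a qRT-PCR Ct table
#'
#' Expected columns: `gene`, `condition`, `replicate`, `ct_target`,
#' `ct_reference` (the duplexed internal-standard well). A table without
#' a `replicate` column (already-averaged values) is accepted and given
#' replicate index 1. `col_map` renames arbitrary source columns onto
#' the expected names.
#'
#' @param path CSV path.
#' @param col_map Optional named character vector, e.g.
#'   `c(ct_target = "Ct")`, mapping expected names to source names.
#' @return A validated `data.frame` of Ct records.
#' @export
read_ct_table <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map))
    for (nm in names(col_map)) names(df)[names(df) == col_map[[nm]]] <- nm
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  need <- c("gene", "condition", "replicate", "ct_target", "ct_reference")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  df[need]
}

#' Calibrated relative expression from Ct records
#'
#' Per replicate, the target Ct is normalized against the
#' internal-standard partner (dCt = ct_target - ct_reference); per
#' (gene, condition) the mean dCt is taken and expression relative to
#' the calibrator condition computed as
#' `efficiency^(dCt_calibrator - dCt_condition)`, so the calibrator is
#' exactly 1 for every gene by construction. The per-condition `sd` is
#' the spread of per-replicate fold values around the calibrator mean.
#' Adding a constant to every Ct (target and reference alike) leaves
#' all folds unchanged.
#'
#' @param records Ct `data.frame` (see [read_ct_table()]).
#' @param calibrator Calibrator condition (must be present for every
#'   gene); default `"monokaryon"`.
#' @param efficiency Amplification factor per cycle in (1, 2]; default 2
#'   (the delta-delta-Ct assumption).
#' @return A `data.frame` of class `rel_expression` (`gene`,
#'   `condition`, `fold`, `sd`, `n`), with attribute `"replicates"`
#'   carrying per-replicate folds for downstream group tests.
#' @export
relative_expression <- function(records, calibrator = "monokaryon",
                                efficiency = 2) {
  stopifnot(efficiency > 1, efficiency <= 2)
  need <- c("gene", "condition", "replicate", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(records)))
  bad <- !is.finite(records$ct_reference) | !is.finite(records$ct_target)
  if (any(bad)) {
    warning("dropping ", sum(bad), " record(s) with missing target/reference Ct")
    records <- records[!bad, , drop = FALSE]
  }
  stopifnot(all(records$ct_target > 0), all(records$ct_reference > 0))
  records$dct <- records$ct_target - records$ct_reference
  out <- list(); reps <- list()
  for (g in unique(records$gene)) {
    rg <- records[records$gene == g, , drop = FALSE]
    if (!calibrator %in% rg$condition)
      stop("gene ", g, ": calibrator condition '", calibrator, "' absent")
    cal_mean <- mean(rg$dct[rg$condition == calibrator])
    for (cond in unique(rg$condition)) {
      d <- rg$dct[rg$condition == cond]
      fold <- efficiency^(cal_mean - mean(d))
      rep_folds <- efficiency^(cal_mean - d)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, condition = cond, fold = fold,
        sd = if (length(d) >= 2L) stats::sd(rep_folds) else NA_real_,
        n = length(d), stringsAsFactors = FALSE)
      reps[[length(reps) + 1L]] <- data.frame(
        gene = g, condition = cond,
        replicate = rg$replicate[rg$condition == cond],
        fold = rep_folds, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "replicates") <- do.call(rbind, reps)
  attr(res, "calibrator") <- calibrator
  attr(res, "efficiency") <- efficiency
  class(res) <- c("rel_expression", "data.frame")
  res
}

#' Between-condition expression ratio
#'
#' Ratio of calibrated folds `numerator / denominator` per gene, e.g.
#' monokaryon-over-dikaryon fold differences.
#'
#' @param rel A `rel_expression` table.
#' @param numerator,denominator Condition names.
#' @return Named numeric vector (one ratio per gene).
#' @export
condition_ratio <- function(rel, numerator, denominator) {
  genes <- unique(rel$gene)
  vapply(genes, function(g) {
    num <- rel$fold[rel$gene == g & rel$condition == numerator]
    den <- rel$fold[rel$gene == g & rel$condition == denominator]
    if (length(num) != 1L || length(den) != 1L)
      stop("condition_ratio(): conditions missing for gene ", g)
    num / den
  }, numeric(1L))
}

#' One-way ANOVA with Tukey HSD grouping
#'
#' Standard one-way analysis of variance followed by Tukey's honest
#' significant difference test at `alpha`, with a compact letter display
#' assigning group labels. When every group has (numerically) zero
#' within-group variance the case is flagged degenerate and letters are
#' assigned directly from distinct group means.
#'
#' @param values Numeric response (e.g. per-replicate folds).
#' @param groups Grouping factor/character (>= 2 groups, >= 2 replicates
#'   each).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `group_test`: `F`, `p`, `tukey` (the
#'   [stats::TukeyHSD()] table), `letters` (named by group),
#'   `degenerate`.
#' @export
group_test <- function(values, groups, alpha = 0.05) {
  d <- data.frame(y = as.numeric(values), g = factor(groups))
  if (nlevels(d$g) < 2L) stop("group_test(): need at least 2 groups")
  if (any(table(d$g) < 2L)) stop("group_test(): need >= 2 replicates per group")
  wvar <- tapply(d$y, d$g, stats::var)
  if (all(wvar < 1e-12)) {
    mns <- tapply(d$y, d$g, mean)
    lev <- letters[match(round(mns, 9), sort(unique(round(mns, 9))))]
    names(lev) <- names(mns)
    return(structure(list(F = NA_real_, p = NA_real_, tukey = NULL,
                          letters = lev, degenerate = TRUE),
                     class = "group_test"))
  }
  fit <- stats::aov(y ~ g, data = d)
  an <- stats::anova(fit)
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  cld <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey")),
                       level = alpha)
  structure(list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
                 tukey = tuk, letters = cld$mcletters$Letters,
                 degenerate = FALSE),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  if (x$degenerate) {
    cat("<group test> degenerate (zero within-group variance)\n")
  } else {
    cat(sprintf("<group test> F = %.3f, p = %.4g\n", x$F, x$p))
  }
  cat("  groups:", paste(names(x$letters), x$letters, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Per-gene expression statistics
#'
#' Runs [group_test()] on the per-replicate folds of every gene in a
#' `rel_expression` table and attaches the Tukey group letter to each
#' (gene, condition) row.
#'
#' @param rel A `rel_expression` table from [relative_expression()].
#' @param alpha Significance level.
#' @return A list with `table` (the `rel_expression` rows plus `F`, `p`
#'   and `group_label`) and `tests` (named list of `group_test`
#'   objects).
#' @export
expression_stats <- function(rel, alpha = 0.05) {
  reps <- attr(rel, "replicates")
  stopifnot(!is.null(reps))
  tests <- list()
  tab <- as.data.frame(rel)
  tab$F <- NA_real_; tab$p <- NA_real_; tab$group_label <- NA_character_
  for (g in unique(rel$gene)) {
    rg <- reps[reps$gene == g, , drop = FALSE]
    gt <- group_test(rg$fold, rg$condition, alpha = alpha)
    tests[[g]] <- gt
    sel <- tab$gene == g
    tab$F[sel] <- gt$F
    tab$p[sel] <- gt$p
    tab$group_label[sel] <- unname(gt$letters[tab$condition[sel]])
  }
  list(table = tab, tests = tests)
}

#' Write a relative-expression table as CSV
#'
#' @param x `rel_expression` table or the `table` element of
#'   [expression_stats()].
#' @param path Output CSV path.
#' @export
write_expression <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
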