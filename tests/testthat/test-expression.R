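mk_ct <- function(genes, dct_by_cond, ref = 15, reps = 3, noise = 0) {
  rows <- list()
  for (g in genes) for (cond in names(dct_by_cond)) for (r in seq_len(reps)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, condition = cond, replicate = r,
      ct_target = ref + dct_by_cond[[cond]] + stats::rnorm(1, 0, noise),
      ct_reference = ref + stats::rnorm(1, 0, noise),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("the calibrator condition has fold exactly 1 for every gene", {
  set.seed(71)
  ct <- mk_ct(c("g1", "g2"), c(monokaryon = 7, dikaryon = 9), noise = 0.3)
  rel <- relative_expression(ct)
  expect_identical(rel$fold[rel$condition == "monokaryon"], c(1, 1))
})

test_that("a delta-delta-Ct of 2 at efficiency 2 gives fold 4 exactly", {
  ct <- mk_ct("g", c(monokaryon = 7, dikaryon = 9))
  rel <- relative_expression(ct, efficiency = 2)
  expect_identical(rel$fold[rel$condition == "dikaryon"], 0.25)
  expect_identical(unname(condition_ratio(rel, "monokaryon", "dikaryon")), 4)
})

test_that("folds are invariant to a constant shift of every Ct", {
  set.seed(72)
  ct <- mk_ct(c("g1", "g2"), c(monokaryon = 7, dikaryon = 8.3), noise = 0.2)
  rel0 <- relative_expression(ct)
  ct2 <- ct
  ct2$ct_target <- ct2$ct_target + 3.7
  ct2$ct_reference <- ct2$ct_reference + 3.7
  rel1 <- relative_expression(ct2)
  expect_equal(rel0$fold, rel1$fold)
})

test_that("records without a reference well are dropped with a warning", {
  ct <- mk_ct("g", c(monokaryon = 7, dikaryon = 9))
  ct$ct_reference[2] <- NA
  expect_warning(rel <- relative_expression(ct), "dropping")
  expect_identical(rel$n[rel$condition == "monokaryon"], 2L)
  # a lone replicate still yields a fold, with sd unavailable
  ct1 <- mk_ct("g", c(monokaryon = 7, dikaryon = 9), reps = 1)
  rel1 <- relative_expression(ct1)
  expect_identical(rel1$fold[rel1$condition == "dikaryon"], 0.25)
  expect_true(all(is.na(rel1$sd)))
})

test_that("missing calibrator or invalid efficiency are errors", {
  ct <- mk_ct("g", c(dikaryon = 9))
  expect_error(relative_expression(ct), "calibrator")
  ct2 <- mk_ct("g", c(monokaryon = 7, dikaryon = 9))
  expect_error(relative_expression(ct2, efficiency = 2.5))
})

test_that("ANOVA/Tukey separates distinct groups and not identical ones", {
  gt <- group_test(c(1, 1, 1, 10, 10.1, 9.9), rep(c("a", "b"), each = 3))
  expect_lt(gt$p, 0.001)
  expect_false(gt$letters[["a"]] == gt$letters[["b"]])

  set.seed(73)
  same <- rep(rnorm(3), 2)
  gt2 <- group_test(same, rep(c("a", "b"), each = 3))
  expect_gt(gt2$p, 0.9)
  expect_identical(unname(gt2$letters[["a"]]), unname(gt2$letters[["b"]]))

  gt3 <- group_test(c(1, 1, 1, 1, 1, 1), rep(c("a", "b"), each = 3))
  expect_true(gt3$degenerate)
  expect_identical(unname(gt3$letters[["a"]]), unname(gt3$letters[["b"]]))
  expect_error(group_test(1:3, c("a", "a", "b")), "replicates")
})

test_that("per-gene statistics separate real effects but not a null gene", {
  set.seed(74)
  folds <- c(r1 = 3.8, r3 = 12.2, null_gene = 1)
  null_flags <- 0L
  for (i in 1:10) {
    ct <- generate_ct_table(folds, noise_sd = 0.1)
    st <- expression_stats(relative_expression(ct))
    # genuine effects are separated in every draw
    expect_lt(st$tests[["r1"]]$p, 0.05)
    expect_lt(st$tests[["r3"]]$p, 0.05)
    if (st$tests[["null_gene"]]$p < 0.05) null_flags <- null_flags + 1L
  }
  # the null gene is a 5%-level false positive only occasionally
  expect_lte(null_flags, 2L)
  expect_true(all(!is.na(st$table$group_label)))
})

test_that("injected folds are recovered without bias across 200 simulations", {
  set.seed(75)
  f <- 6
  est <- replicate(200, {
    ct <- generate_ct_table(c(g = f), noise_sd = 0.1)
    unname(condition_ratio(relative_expression(ct), "monokaryon", "dikaryon"))
  })
  # log-scale sampling error of the mean over 200 draws
  se <- stats::sd(log(est)) / sqrt(200)
  expect_lt(abs(mean(log(est)) - log(f)), 3 * se)
})
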