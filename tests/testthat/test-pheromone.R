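test_that("CaaX detection tests only the cysteine at position -4", {
  expect_identical(find_caax("MDAFKKLNQCVIA")$motif, "CVIA")
  expect_identical(find_caax("MDAFKKLNQCVIA")$cys_offset, 4L)
  expect_null(find_caax("MDAFKKLNQAVIC"))  # Cys terminal, not at -4
  expect_null(find_caax("MAC"))            # too short
  for (tail in c("CVCH", "CVRG", "CVVA"))  # permissive CXXX variants
    expect_identical(find_caax(paste0("MDAFKKLNQ", tail))$motif, tail)
})

test_that("cleavage sites carry doublet, context flags and score", {
  # M + 10xA + P A D E R + 8 residues + CVIA: R at offset 13
  pep <- paste0("M", strrep("A", 10), "PADER", "GGGGGGGG", "CVIA")
  sites <- enumerate_cleavage_sites(pep)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$doublet, "ER")
  expect_identical(sites$doublet_end_offset, 13L)
  expect_true(sites$has_pro_minus4)
  expect_true(sites$has_dn_minus2)
  expect_identical(sites$score, 3L)

  expect_identical(nrow(enumerate_cleavage_sites(
    paste0("M", strrep("G", 20), "CVIA"))), 0L)
})

test_that("equal-score doublets are returned smaller offset first", {
  # two bare ER doublets (no P/D context) at offsets 13 and 17
  pep <- paste0("M", strrep("G", 6), "ER", "GG", "ER", "GGGGGGGG", "CVIA")
  sites <- enumerate_cleavage_sites(pep)
  expect_identical(nrow(sites), 2L)
  expect_identical(sites$score, c(1L, 1L))
  expect_identical(sites$doublet_end_offset, c(13L, 17L))
  # brute-force check: every T/E-R pair with R in the window is reported
  v <- strsplit(pep, "")[[1]]; n <- length(v)
  manual <- sum(vapply(2:n, function(p)
    v[p] == "R" && v[p - 1] %in% c("E", "T") &&
      (n - p + 1) >= 13 && (n - p + 1) <= 19, logical(1)))
  expect_identical(nrow(sites), manual)
})

test_that("mature peptide is the doublet-to-Cys segment ending in C", {
  mk <- function(off) {
    # doublet at offset `off`; mature length off - 4
    paste0("M", strrep("A", 30), "P", "G", "D", "ER",
           strrep("G", off - 8), "KLM", "CVIA")
  }
  for (off in c(16L, 17L)) {
    pep <- mk(off)
    p <- classify_pheromone(pep)
    expect_identical(p$chosen_site$doublet_end_offset, off)
    expect_identical(p$mature_length, off - 4L)
    expect_identical(substr(p$mature_peptide, p$mature_length,
                            p$mature_length), "C")
    # position arithmetic: residues strictly after the doublet through -4
    n <- nchar(pep)
    expect_identical(p$mature_peptide, substr(pep, n - off + 2, n - 3))
  }
})

test_that("size filter and strict mode gate classification", {
  long <- paste0("M", strrep("A", 145), "CVIA")  # 150 aa, CaaX present
  expect_identical(nchar(long), 150L)
  expect_null(classify_pheromone(long))
  # CaaX but no doublet: strict rejects, permissive keeps with warning
  bare <- paste0("M", strrep("G", 40), "CVIA")
  expect_null(classify_pheromone(bare, mode = "strict"))
  perm <- classify_pheromone(bare, mode = "permissive")
  expect_false(is.null(perm))
  expect_match(perm$warning, "CaaX-only")
})

test_that("the full grammar accepts strictly fewer random peptides than CaaX alone", {
  set.seed(515)
  peps <- vapply(1:1000, function(i) random_peptide(sample(10:100, 1)), "")
  caax_only <- vapply(peps, function(p) !is.null(find_caax(p)), logical(1))
  full <- vapply(peps, function(p)
    !is.null(classify_pheromone(p, mode = "strict")), logical(1))
  expect_true(all(which(full) %in% which(caax_only)))  # monotonicity
  expect_lt(sum(full), sum(caax_only))
  expect_lt(sum(full) / length(full), 0.02)  # measured FP rate is small
})

test_that("classification is deterministic", {
  set.seed(616)
  pep <- random_peptide(60)
  a <- classify_pheromone(pep)
  b <- classify_pheromone(pep)
  expect_identical(a, b)
})

test_that("C-terminally anchored alignment annotates matching doublet columns", {
  set.seed(717)
  prs <- lapply(1:4, function(i) {
    g <- generate_precursor_gene(mature_len_range = c(12L, 12L))
    classify_pheromone(g$peptide)
  })
  al <- align_precursors(prs)
  expect_identical(length(unique(al$doublet_cols)), 1L)  # columns align
  # two identical precursors: identical rows, no mismatch columns
  al2 <- align_precursors(list(prs[[1]], prs[[1]]))
  expect_identical(al2$rows[1], al2$rows[2])
  expect_identical(al2$n_mismatch_cols, 0L)
  expect_error(align_precursors(prs[1]), "at least two")
})
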