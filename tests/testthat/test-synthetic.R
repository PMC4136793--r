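test_that("generated precursors are recovered exactly by the classifier", {
  set.seed(81)
  for (i in 1:20) {
    g <- generate_precursor_gene()
    expect_true(g$length_aa >= 57 && g$length_aa <= 61)
    expect_identical(translate_dna(g$dna), paste0(g$peptide, "*"))
    p <- classify_pheromone(g$peptide)
    expect_false(is.null(p))
    expect_identical(p$mature_peptide, g$mature_peptide)
    expect_identical(p$chosen_site$score, 3L)
    expect_identical(substr(p$mature_peptide, p$mature_length,
                            p$mature_length), "C")
  }
  g12 <- replicate(10, generate_precursor_gene(mature_len_range = c(12L, 12L)),
                   simplify = FALSE)
  expect_true(all(vapply(g12, function(g) nchar(g$mature_peptide), 0L) == 12L))
  expect_error(generate_precursor_gene(precursor_len_range = c(15L, 15L)),
               "too short")
})

test_that("precursor lengths are uniform over the configured range", {
  set.seed(82)
  lens <- replicate(1000, generate_precursor_gene()$length_aa)
  tab <- table(factor(lens, levels = 57:61))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("shuffled precursor compositions are rarely accepted", {
  set.seed(83)
  kept <- vapply(1:200, function(i) {
    g <- generate_precursor_gene()
    shuf <- paste(sample(strsplit(g$peptide, "")[[1]]), collapse = "")
    !is.null(classify_pheromone(shuf))
  }, logical(1))
  expect_lt(mean(kept), 0.2)
})

test_that("receptor genes honour the requested tail and topology", {
  set.seed(84)
  r <- generate_receptor_gene(34)
  m <- build_receptor_model("r", r$peptide)
  expect_identical(m$c_tail_len, 34L)
  expect_true(m$receptor_like)
  expect_identical(m$segments$start, r$tm_segments$start)
  expect_identical(m$segments$end, r$tm_segments$end)
  r2 <- generate_receptor_gene(330)
  expect_false(build_receptor_model("r2", r2$peptide)$receptor_like)
})

test_that("zero-noise Ct tables reproduce injected folds in closed form", {
  ct <- generate_ct_table(c(g = 4), noise_sd = 0, efficiency = 2, seed = 85)
  rel <- relative_expression(ct)
  expect_identical(unname(condition_ratio(rel, "monokaryon", "dikaryon")), 4)
  ct1 <- generate_ct_table(c(g = 1), noise_sd = 0.05, seed = 86)
  est <- unname(condition_ratio(relative_expression(ct1),
                                "monokaryon", "dikaryon"))
  expect_equal(est, 1, tolerance = 0.3)
})

test_that("the default locus carries the configured geometry and truth", {
  sim <- generate_locus(locus_spec())
  expect_identical(nchar(sim$assembly), 60000L)
  expect_identical(nchar(sim$contigs[[1]]$sequence), 40400L)
  expect_identical(nchar(sim$contigs[[2]]$sequence), 32700L)
  expect_identical(nrow(sim$truth$features), 8L)
  expect_identical(sum(sim$truth$features$kind == "pheromone"), 4L)
  expect_identical(sum(sim$truth$features$kind == "receptor"), 4L)
  expect_identical(length(sim$truth$mature_peptides), 4L)
  expect_true(all(nchar(sim$truth$mature_peptides) %in% 12:13))

  # the emitted pair re-merges to exactly the configured overlap
  m <- merge_contigs(sim$contigs[[1]], sim$contigs[[2]], min_overlap = 1000)
  expect_identical(m$overlap_len, 13100L)
  expect_identical(m$sequence, sim$assembly)

  # receptor cDNAs sit at their annotated coordinates
  feats <- sim$truth$features
  for (nm in names(sim$truth$receptor_cdna)) {
    hit <- locate_cds(sim$truth$receptor_cdna[[nm]], sim$assembly)
    row <- feats[feats$name == nm, ]
    expect_identical(c(hit$start, hit$end, hit$strand),
                     c(row$start, row$end, row$strand))
  }

  # marker primers amplify exactly the truth interval
  amp <- locate_amplicon(sim$truth$primers["fwd"], sim$truth$primers["rev"],
                         sim$assembly)
  expect_identical(c(amp$start, amp$end), unname(sim$truth$amplicon))
  expect_identical(amp$end - amp$start + 1L, 2100L)
})

test_that("identical spec and seed give byte-identical output files", {
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  write_locus(generate_locus(locus_spec(seed = 7L)), td1)
  write_locus(generate_locus(locus_spec(seed = 7L)), td2)
  files <- list.files(td1)
  expect_true(length(files) >= 7)
  for (f in files)
    expect_identical(readLines(file.path(td1, f)),
                     readLines(file.path(td2, f)), info = f)
  # and a different seed changes the sequence
  sim3 <- generate_locus(locus_spec(seed = 8L))
  expect_false(identical(readLines(file.path(td1, "contigs.fasta"))[2],
                         Biostrings::toString(sim3$contigs[[1]]$sequence)))
})
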