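test_that("hydropathy profile matches the scale on homopolymers", {
  prof_i <- hydropathy_profile(strrep("I", 30), window = 19)
  expect_true(all(abs(prof_i[10:21] - 4.5) < 1e-12))
  prof_r <- hydropathy_profile(strrep("R", 30), window = 19)
  expect_true(all(abs(prof_r[10:21] + 4.5) < 1e-12))
  # alternating I/R: interior means close to 0 (odd window, one extra I or R)
  alt <- paste(rep(c("I", "R"), 20), collapse = "")
  prof_a <- hydropathy_profile(alt, window = 19)
  expect_true(all(abs(prof_a[10:31]) < 0.25))
  # unknown residues contribute 0 with a warning
  expect_warning(hydropathy_profile("IIIIIZIIIII", window = 3), "unknown")
})

test_that("an all-hydrophilic peptide has no TM segments", {
  expect_identical(nrow(predict_tm_segments(strrep("R", 100))), 0L)
})

test_that("threshold runs separated by less than merge_gap are merged", {
  pep <- paste0(strrep("I", 16), "D", strrep("I", 16))
  merged <- predict_tm_segments(pep, window = 1, threshold = 1.6,
                                min_len = 15, merge_gap = 3)
  expect_identical(nrow(merged), 1L)
  expect_identical(c(merged$start, merged$end), c(1L, 33L))
  split <- predict_tm_segments(pep, window = 1, threshold = 1.6,
                               min_len = 15, merge_gap = 1)
  expect_identical(nrow(split), 2L)
})

test_that("synthetic 7-TM receptors are recovered at the truth segments", {
  set.seed(808)
  hits <- 0L
  for (i in 1:100) {
    r <- generate_receptor_gene(tail_len = sample(30:300, 1))
    segs <- predict_tm_segments(r$peptide)
    if (nrow(segs) == 7L &&
        all(abs(segs$start - r$tm_segments$start) <= 2) &&
        all(abs(segs$end - r$tm_segments$end) <= 2))
      hits <- hits + 1L
  }
  expect_identical(hits, 100L)
})

test_that("TM calls are invariant to hydrophilic flanks and the C-tail grows with them", {
  set.seed(909)
  r <- generate_receptor_gene(tail_len = 40)
  m0 <- build_receptor_model("r", r$peptide)
  flank <- paste(sample(c("R", "K", "D", "E", "S", "T", "N", "Q", "G", "P"),
                        25, replace = TRUE), collapse = "")
  m1 <- build_receptor_model("r", paste0(r$peptide, flank))
  expect_identical(m1$segments, m0$segments)
  expect_identical(m1$c_tail_len, m0$c_tail_len + 25L)
})

test_that("receptor-like flag requires seven TMs and a short cytoplasmic tail", {
  set.seed(1010)
  short <- generate_receptor_gene(tail_len = 30)
  m <- build_receptor_model("short", short$peptide, tail_threshold = 50)
  expect_true(m$seven_tm)
  expect_identical(m$c_tail_len, 30L)
  expect_true(m$receptor_like)
  expect_identical(m$topology[1], "out->in")   # extracellular N-terminus
  expect_identical(m$c_tail_location, "cytoplasmic")

  long <- generate_receptor_gene(tail_len = 300)
  m2 <- build_receptor_model("long", long$peptide, tail_threshold = 50)
  expect_true(m2$seven_tm)
  expect_false(m2$receptor_like)

  five <- generate_receptor_gene(tail_len = 40, n_tm = 5)
  expect_warning(m3 <- build_receptor_model("five", five$peptide), "topology")
  expect_false(m3$receptor_like)
})

test_that("analyze_receptors reports the deposited-length geometry", {
  set.seed(1111)
  tails <- c(R1 = 34L, R2 = 126L, R3 = 264L, R4 = 176L)
  peps <- vapply(tails, function(t) generate_receptor_gene(t)$peptide, "")
  ann <- analyze_receptors(peps)
  expect_identical(ann$report$length_aa, c(328L, 420L, 558L, 470L))
  expect_identical(ann$report$n_tm, rep(7L, 4))
  expect_identical(ann$report$c_tail_len, unname(tails))
  expect_identical(ann$report$receptor_like, c(TRUE, FALSE, FALSE, FALSE))
})
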