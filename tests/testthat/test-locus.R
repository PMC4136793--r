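test_that("suffix/prefix overlap merging works in both orientations", {
  m <- merge_contigs("AAAATTTT", "TTTTGGGG", min_overlap = 4)
  expect_identical(m$sequence, "AAAATTTTGGGG")
  expect_identical(m$overlap_len, 4L)
  expect_identical(m$b_orientation, "forward")
  expect_identical(unname(m$contig_offsets), c(1L, 5L))

  ident <- merge_contigs("ACGTACGT", "ACGTACGT", min_overlap = 4)
  expect_identical(ident$sequence, "ACGTACGT")
  expect_identical(ident$overlap_len, 8L)

  rc <- merge_contigs("AAAATTTT", reverse_complement("TTTTGGGG"),
                      min_overlap = 4)
  expect_identical(rc$sequence, "AAAATTTTGGGG")
  expect_identical(rc$b_orientation, "revcomp")
})

test_that("merge length conservation holds on random overlapping contigs", {
  set.seed(61)
  for (i in 1:5) {
    core <- random_dna(3000)
    la <- sample(1000:2000, 1); ov <- sample(150:600, 1)
    a <- substr(core, 1, la)
    b <- substr(core, la - ov + 1, 3000)
    m <- merge_contigs(a, b, min_overlap = 100)
    expect_identical(nchar(m$sequence) + m$overlap_len, nchar(a) + nchar(b))
    expect_gte(m$overlap_len, ov)  # a longer chance overlap may exist
    expect_identical(m$sequence, core)
  }
})

test_that("absent overlap raises an error naming the best candidate", {
  set.seed(62)
  expect_error(merge_contigs(random_dna(500), random_dna(500),
                             min_overlap = 100), "no exact overlap")
})

test_that("mating span covers mating genes only and ignores order", {
  f <- gene_features(c("p1", "r1", "x"), c("pheromone", "receptor", "other"),
                     c(26325L, 36579L, 100L), c(26510L, 38224L, 50000L),
                     c("+", "+", "+"))
  expect_identical(mating_span(f), 11900L)
  set.seed(63)
  expect_identical(mating_span(f[sample(nrow(f)), ]), 11900L)
  single <- gene_features("p", "pheromone", 100L, 200L)
  expect_identical(mating_span(single), 101L)
  expect_error(mating_span(gene_features("x", "other", 1L, 10L)), "no pheromone")
})

test_that("in-silico PCR is exact and orientation-aware", {
  set.seed(64)
  seqx <- random_dna(5000)
  fwd <- substr(seqx, 1001, 1020)
  rev <- reverse_complement(substr(seqx, 2981, 3000))
  amp <- locate_amplicon(fwd, rev, seqx)
  expect_identical(c(amp$start, amp$end), c(1001L, 3000L))
  expect_false(attr(amp, "multiple"))
  # reverse site upstream of forward: no product (either orientation)
  fwd2 <- substr(seqx, 3001, 3020)
  rev2 <- substr(seqx, 1001, 1020)  # + strand sequence: its rc binds upstream
  expect_null(locate_amplicon(fwd2, rev2, seqx))
  # one mismatch kills the product
  fwd_mm <- fwd
  substr(fwd_mm, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                    substr(fwd, 10, 10))[1]
  expect_null(locate_amplicon(fwd_mm, rev, seqx))
  expect_error(locate_amplicon("ACGTACGT", rev, seqx))  # primer too short
})

test_that("annotation conventions are bit-exact and round-trip", {
  f <- gene_features("g1", "pheromone", 26325L, 26510L, "+")
  td <- withr::local_tempdir()
  bed <- file.path(td, "one.bed")
  write_annotation(f, bed, "bed")
  cols <- strsplit(readLines(bed)[1], "\t")[[1]]
  expect_identical(cols[2], "26324")  # 0-based half-open start
  expect_identical(cols[3], "26510")

  set.seed(65)
  n <- 1000
  feats <- gene_features(paste0("f", 1:n),
                         sample(c("pheromone", "receptor", "other"), n, TRUE),
                         st <- sample(1:50000, n),
                         st + sample(50:5000, n, TRUE),
                         sample(c("+", "-"), n, TRUE))
  for (fmt in c("gff3", "bed", "csv")) {
    path <- file.path(td, paste0("all.", fmt))
    write_annotation(feats, path, fmt, assembly_length = 60000)
    back <- read_annotation(path)
    back <- back[match(feats$name, back$name), ]
    rownames(back) <- NULL
    expect_identical(feats[c("name", "kind", "start", "end", "strand")],
                     back[c("name", "kind", "start", "end", "strand")],
                     info = fmt)
  }

  empty <- gene_features(character(), character(), integer(), integer(),
                         character(), character())
  epath <- file.path(td, "empty.gff3")
  write_annotation(empty, epath, "gff3")
  expect_identical(readLines(epath), "##gff-version 3")

  expect_error(write_annotation(f, file.path(td, "oob.gff3"), "gff3",
                                assembly_length = 1000), "outside assembly")
})

test_that("the packaged locus coordinate fixture spans under 12 kb", {
  fx <- locus_feature_fixture()
  expect_identical(nrow(fx), 22L)
  expect_identical(sum(fx$kind == "pheromone"), 4L)
  expect_identical(sum(fx$kind == "receptor"), 4L)
  expect_identical(mating_span(fx), 11900L)
  expect_lt(mating_span(fx), 12000L)
})
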