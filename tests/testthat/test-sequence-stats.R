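test_that("gc_content matches hand counts, excludes N, and rejects empty input", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ATGCN"), 0.5)
  expect_equal(gc_content(Biostrings::DNAString("acgt")), 0.5)
  expect_error(gc_content("NNNN"), "all-N")
  expect_error(gc_content("ABCZ"), "outside")
})

test_that("window and core counts reproduce enumerated examples", {
  expect_equal(unname(count_at_windows(strrep("A", 20))), c(1L, 1L))
  expect_equal(unname(count_at_windows(strrep("G", 100))), c(0L, 0L))
  # 21 windows in a 40-mer; starts 1-10 hold >= 11 A/T and all overlap
  expect_equal(
    unname(count_at_windows(paste0(strrep("A", 20), strrep("G", 20)))),
    c(10L, 1L)
  )
  expect_equal(unname(count_at_windows("ACGTACGT")), c(0L, 0L)) # shorter than window
  expect_equal(unname(count_at_cores("AAAAAA")), c(1L, 1L))
  expect_equal(unname(count_at_cores("GGGGGG")), c(0L, 0L))
  expect_equal(unname(count_at_cores("AAAAAGAAAAAG"))[2], 2L)
  # a window containing N can still qualify on its A/T count
  expect_equal(unname(count_at_cores("AAAAAN"))[1], 1L)
  expect_equal(unname(count_at_cores("AAAANN"))[1], 0L)
})

test_that("scan_config validates its thresholds", {
  expect_error(scan_config(core_min_at = 7), "core_min_at")
  expect_error(scan_config(window_min_at = 25), "window_min_at")
  expect_error(scan_config(window_len = 4), "core_len <= window_len")
})

test_that("counts agree with a naive enumeration oracle on random sequences", {
  cfg <- scan_config()
  set.seed(42)
  for (i in 1:300) {
    s <- random_dna(sample(1:150, 1), gc = runif(1, 0.2, 0.9), with_n = i %% 5 == 0)
    expect_identical(
      unname(count_at_windows(s, cfg)),
      unname(as.integer(naive_window_count(s, 20, 11)))
    )
    expect_identical(
      unname(count_at_cores(s, cfg)),
      unname(as.integer(naive_window_count(s, 6, 5)))
    )
  }
})

test_that("replacing one G/C by A/T never decreases any count", {
  cfg <- scan_config()
  set.seed(7)
  for (i in 1:40) {
    s <- strsplit(random_dna(80, gc = 0.6), "")[[1]]
    gcpos <- which(s %in% c("G", "C"))
    if (!length(gcpos)) next
    before_w <- count_at_windows(paste(s, collapse = ""), cfg)
    before_c <- count_at_cores(paste(s, collapse = ""), cfg)
    s[sample(gcpos, 1)] <- sample(c("A", "T"), 1)
    after_w <- count_at_windows(paste(s, collapse = ""), cfg)
    after_c <- count_at_cores(paste(s, collapse = ""), cfg)
    expect_true(all(after_w >= before_w))
    expect_true(all(after_c >= before_c))
  }
})

test_that("greedy disjoint count equals the exact maximum on short sequences", {
  cfg <- scan_config()
  set.seed(11)
  for (i in 1:150) {
    s <- random_dna(sample(6:60, 1), gc = runif(1, 0.1, 0.8))
    expect_identical(
      count_at_windows(s, cfg)[["disjoint"]],
      as.integer(naive_window_count(s, 20, 11)[["disjoint"]])
    )
    expect_identical(
      count_at_cores(s, cfg)[["disjoint"]],
      as.integer(naive_window_count(s, 6, 5)[["disjoint"]])
    )
  }
})

test_that("gc_content of a concatenation is the length-weighted mean of parts", {
  set.seed(3)
  for (i in 1:20) {
    a <- random_dna(sample(10:200, 1), gc = runif(1))
    b <- random_dna(sample(10:200, 1), gc = runif(1))
    expected <- (gc_content(a) * nchar(a) + gc_content(b) * nchar(b)) /
      (nchar(a) + nchar(b))
    expect_equal(gc_content(paste0(a, b)), expected)
  }
})

test_that("at_profile agrees with its component operations", {
  cfg <- scan_config()
  p <- at_profile(strrep("G", 50), cfg)
  expect_false(p$has_window)
  expect_false(p$has_core)
  expect_equal(p$gc_fraction, 1)
  p2 <- at_profile(strrep("A", 20), cfg)
  expect_true(p2$has_window)
  expect_true(p2$has_core)
  set.seed(5)
  s <- random_dna(120, gc = 0.5)
  p3 <- at_profile(s, cfg, id = "x")
  w <- count_at_windows(s, cfg)
  k <- count_at_cores(s, cfg)
  expect_equal(p3$window_hits_overlapping, unname(w["overlapping"]))
  expect_equal(p3$window_hits_disjoint, unname(w["disjoint"]))
  expect_equal(p3$core_hits_overlapping, unname(k["overlapping"]))
  expect_equal(p3$core_hits_disjoint, unname(k["disjoint"]))
  expect_equal(p3$gc_fraction, gc_content(s))
  expect_true(p3$window_hits_disjoint <= p3$window_hits_overlapping)
  expect_true(p3$core_hits_disjoint <= p3$core_hits_overlapping)
})

test_that("at_profile_set profiles every FASTA record", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", strrep("A", 20), ">s2", "GGGG", "CCCC"), tmp)
  prof <- at_profile_set(tmp)
  expect_equal(prof$id, c("s1", "s2"))
  expect_equal(prof$length, c(20L, 8L))
  expect_equal(prof$gc_fraction, c(0, 1))
  expect_equal(prof$has_window, c(TRUE, FALSE))
})

test_that("baseline segment sampling is seeded, in-bounds and faithful", {
  set.seed(99)
  chrom <- random_dna(10000, gc = 0.7)
  segs <- sample_baseline_segments(chrom, 15, c(500, 1000), seed = 4)
  expect_equal(nrow(segs), 30)
  expect_equal(as.vector(table(segs$length)), c(15L, 15L))
  expect_true(all(segs$start >= 1 & segs$end <= 10000))
  # recorded coordinates really address the returned subsequence
  expect_equal(segs$seq, substring(chrom, segs$start, segs$end))
  expect_identical(segs, sample_baseline_segments(chrom, 15, c(500, 1000), seed = 4))
  expect_false(identical(
    segs$start,
    sample_baseline_segments(chrom, 15, c(500, 1000), seed = 5)$start
  ))
  expect_equal(nrow(sample_baseline_segments(chrom, 0, c(500), seed = 1)), 0)
  expect_error(sample_baseline_segments(chrom, 2, 20000, seed = 1), "exceeds")
})
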