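test_that("site filtering is strict at the q threshold", {
  sites <- validate_sites(data.frame(
    start = c(10L, 20L, 30L, 40L),
    end = c(19L, 29L, 39L, 49L),
    q_value = c(0.005, 0.01, 0.5, 0.0099)
  ))
  kept <- filter_sites(sites)
  expect_equal(kept$start, c(10L, 40L)) # q = 0.01 excluded, order preserved
  # subset equals a brute-force filter
  expect_equal(kept$site_id, sites$site_id[sites$q_value < 0.01])
})

test_that("gene association applies the upstream/overlap rule", {
  genes <- divergent_gene_table()
  # site inside a gene body
  s1 <- validate_sites(data.frame(start = 1200L, end = 1300L, q_value = 0.001))
  a1 <- assign_site_to_genes(s1, genes)
  expect_equal(a1$locus_id, "TST_0001")
  expect_equal(a1$relation, "overlaps_cds")
  # site far from everything
  s2 <- validate_sites(data.frame(start = 5000L, end = 5100L, q_value = 0.001))
  expect_equal(nrow(assign_site_to_genes(s2, genes)), 0)
  # divergent promoters: TST_0001 is '-' (5' end at 2000, upstream 2001-2300),
  # TST_0002 is '+' (5' end at 2500, upstream 2200-2499)
  s3 <- validate_sites(data.frame(start = 2250L, end = 2290L, q_value = 0.001))
  a3 <- assign_site_to_genes(s3, genes)
  expect_setequal(a3$locus_id, c("TST_0001", "TST_0002"))
  expect_true(all(a3$relation == "upstream"))
  # both relations reported when a site spans a gene 5' end and its promoter
  s4 <- validate_sites(data.frame(start = 2400L, end = 2600L, q_value = 0.001))
  a4 <- assign_site_to_genes(s4, genes)
  a4_g2 <- a4[a4$locus_id == "TST_0002", ]
  expect_setequal(a4_g2$relation, c("overlaps_cds", "upstream"))
  # upstream window of zero disables promoter association
  expect_equal(nrow(assign_site_to_genes(s3, genes, upstream_window = 0)), 0)
})

test_that("gene association is symmetric under coordinate mirroring", {
  set.seed(21)
  L <- 50000L
  for (rep in 1:10) {
    starts <- sort(sample.int(L - 2000L, 8))
    genes <- validate_genes(data.frame(
      locus_id = sprintf("M_%04d", 1:8),
      start = starts,
      end = starts + sample(200:800, 8, replace = TRUE),
      strand = sample(c("+", "-"), 8, replace = TRUE),
      stringsAsFactors = FALSE
    ))
    ss <- sample.int(L - 500L, 6)
    sites <- validate_sites(data.frame(
      start = ss, end = ss + sample(50:400, 6, replace = TRUE), q_value = 0.001
    ))
    mirror_genes <- validate_genes(data.frame(
      locus_id = genes$locus_id,
      start = L + 1L - genes$end,
      end = L + 1L - genes$start,
      strand = ifelse(genes$strand == "+", "-", "+"),
      stringsAsFactors = FALSE
    ))
    mirror_sites <- validate_sites(data.frame(
      site_id = sites$site_id,
      start = L + 1L - sites$end,
      end = L + 1L - sites$start,
      q_value = sites$q_value
    ))
    a <- assign_site_to_genes(sites, genes, 300)
    b <- assign_site_to_genes(mirror_sites, mirror_genes, 300)
    key <- function(d) sort(paste(d$site_id, d$locus_id, d$relation))
    expect_identical(key(a), key(b))
  }
})

test_that("region classification matches brute-force containment and tie-breaks left", {
  regions <- partition_regions(1000, 4000, 5000)
  set.seed(31)
  ss <- sample.int(4800, 50)
  sites <- validate_sites(data.frame(
    start = ss, end = ss + sample(10:200, 50, replace = TRUE), q_value = 0.001
  ))
  sites$end <- pmin(sites$end, 5000L)
  labels <- classify_region(sites, regions)
  brute <- vapply(seq_len(nrow(sites)), function(i) {
    mid <- (sites$start[i] + sites$end[i]) %/% 2L
    regions$region[regions$start <= mid & regions$end >= mid]
  }, character(1))
  expect_identical(labels, brute)
  # even-width site straddling a boundary: midpoint floors leftward
  edge <- validate_sites(data.frame(start = 1000L, end = 1001L, q_value = 0.001))
  expect_equal(classify_region(edge, regions), "left_arm")
  out <- validate_sites(data.frame(start = 5800L, end = 6000L, q_value = 0.001))
  expect_error(classify_region(out, regions), "outside")
})

test_that("per-region summaries count every site and average widths by change status", {
  regions <- partition_regions(1000, 4000, 5000)
  sites <- validate_sites(data.frame(
    start = c(100L, 300L, 1500L, 1600L, 4500L),
    end = c(199L, 599L, 1700L, 1799L, 4599L),
    q_value = 0.001
  ))
  sites$region <- classify_region(sites, regions)
  sites$width <- sites$end - sites$start + 1L
  sites$transcription_change <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  s <- summarize_by_region(sites)
  expect_equal(sum(s$n_sites), nrow(sites))
  expect_equal(s$n_sites, c(2L, 2L, 1L))
  expect_equal(s$fraction_with_change, c(0.5, 0, 1))
  # widths {100, 300} in the left-arm groups
  expect_equal(s$mean_width_change[1], 100)
  expect_equal(s$mean_width_no_change[1], 300)
  # empty groups are NA, not zero
  expect_true(is.na(s$mean_width_change[2]))
  expect_true(is.na(s$mean_width_no_change[3]))
  all_changed <- sites
  all_changed$transcription_change <- TRUE
  expect_equal(
    summarize_by_region(all_changed)$fraction_with_change,
    c(1, 1, 1)
  )
})

test_that("site GC is computed on the spanned subsequence", {
  chrom <- paste0(strrep("G", 100), strrep("A", 100))
  sites <- validate_sites(data.frame(
    start = c(1L, 101L, 51L), end = c(100L, 200L, 150L), q_value = 0.001
  ))
  expect_equal(site_gc(sites, chrom), c(1, 0, 0.5))
  bad <- validate_sites(data.frame(start = 150L, end = 250L, q_value = 0.001))
  expect_error(site_gc(bad, chrom), "outside")
})

test_that("annotation joins DE flags and cluster labels onto sites", {
  genes <- divergent_gene_table()
  regions <- partition_regions(4000, 8000, 10000)
  chrom <- strrep("ACGT", 2500)
  sites <- validate_sites(data.frame(
    start = c(1200L, 9100L, 5000L),
    end = c(1300L, 9200L, 5100L),
    q_value = 0.001
  ))
  ann <- annotate_sites(sites, genes, regions, chrom,
    de_significant = "TST_0001"
  )
  expect_equal(ann$transcription_change, c(TRUE, FALSE, FALSE))
  expect_equal(ann$region, c("left_arm", "right_arm", "core"))
  expect_equal(ann$n_genes, c(1L, 1L, 0L))
  # re-joining with a different significant set updates the flag
  ann2 <- join_sites_expression(ann, c("TST_0003"))
  expect_equal(ann2$transcription_change, c(FALSE, TRUE, FALSE))
  cl <- cluster_genomic_span(
    validate_clusters(data.frame(
      name = "c1", first_locus = "TST_0001", last_locus = "TST_0002"
    )),
    genes
  )
  expect_equal(assign_site_to_clusters(ann, cl), c("c1", "", ""))
})
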