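test_that("simulated chromosomes hit the background GC and plant their islands", {
  for (s in 1:3) {
    chrom <- simulate_chromosome(10000, seed = s)
    expect_equal(nchar(chrom$sequence), 10000L)
    expect_lte(abs(gc_content(chrom$sequence) - 0.724), 0.02)
  }
  islands <- data.frame(
    start = c(1000L, 3000L, 5000L), length = 300L, at_fraction = 0.6
  )
  chrom <- simulate_chromosome(10000, islands = islands, seed = 1)
  expect_equal(nrow(chrom$truth$islands), 3)
  for (i in 1:3) {
    sub <- substring(
      chrom$sequence, chrom$truth$islands$start[i], chrom$truth$islands$end[i]
    )
    expect_true(at_profile(sub)$has_core) # guaranteed-core stamping
    expect_lte(gc_content(sub), 0.55) # AT-rich relative to background
  }
  expect_identical(
    simulate_chromosome(5000, islands = islands[1, ], seed = 9)$sequence,
    simulate_chromosome(5000, islands = islands[1, ], seed = 9)$sequence
  )
  expect_error(
    simulate_chromosome(10000,
      islands = data.frame(start = c(100L, 200L), length = 300L, at_fraction = 0.6),
      seed = 1
    ),
    "overlap"
  )
  expect_error(
    simulate_chromosome(1000,
      islands = data.frame(start = 900L, length = 300L, at_fraction = 0.6),
      seed = 1
    ),
    "outside"
  )
})

test_that("simulated annotations are packed, indexed and cluster-consistent", {
  ann <- simulate_annotation(
    n_genes = 100, n_clusters = 2, genes_per_cluster = 10, seed = 2
  )
  expect_equal(nrow(ann$genes), 100)
  # locus numbering strictly increasing with coordinate, genes non-overlapping
  expect_true(all(diff(ann$genes$locus_idx) == 1))
  expect_true(all(ann$genes$start[-1] > ann$genes$end[-100]))
  expect_equal(length(ann$truth$cluster_gene_ids), 20)
  # cluster span arithmetic matches the annotation module's member counting
  expect_equal(ann$clusters$n_span, c(10L, 10L))
  members <- cluster_members(ann$clusters[1, ], mode = "span")
  expect_true(all(members %in% ann$genes$locus_id))
  expect_identical(
    members,
    cluster_members(ann$clusters[1, ], genes = ann$genes, mode = "explicit")
  )
  # the region partition tiles the chromosome the genes live on
  expect_gte(ann$regions$end[3], max(ann$genes$end))
  expect_error(
    simulate_annotation(n_genes = 10, n_clusters = 3, genes_per_cluster = 5),
    "more cluster genes"
  )
})

test_that("planted DE genes are exactly the filter output", {
  ann <- simulate_annotation(
    n_genes = 500, n_clusters = 3, genes_per_cluster = 30, seed = 3
  )
  sim <- simulate_de(ann$genes, ann$clusters, seed = 4)
  sig <- filter_de(sim$de)
  expect_setequal(sig$locus_id, sim$truth$planted)
  expect_equal(
    sig$direction[match(sim$truth$planted, sig$locus_id)],
    sim$truth$planted_direction
  )
  # silent-in-wild-type emulation: planted upregulated genes have WT RPKM < 10
  up <- sim$truth$planted[sim$truth$planted_direction == "up"]
  expect_true(all(sim$de$wt_expr[sim$de$locus_id %in% up] < 10))
  # no planting at zero probabilities
  none <- simulate_de(ann$genes, ann$clusters,
    p_cluster = 0, p_background = 0, seed = 5
  )
  expect_equal(nrow(filter_de(none$de)), 0)
  expect_identical(
    simulate_de(ann$genes, ann$clusters, seed = 6)$de,
    simulate_de(ann$genes, ann$clusters, seed = 6)$de
  )
})

test_that("simulated sites anchor on their islands", {
  islands <- data.frame(
    start = seq(1000L, 9000L, by = 2000L), length = 300L, at_fraction = 0.6
  )
  chrom <- simulate_chromosome(10000, islands = islands, seed = 7)
  sites <- simulate_sites(chrom$truth$islands, 10000, n_noise_sites = 0, seed = 8)
  expect_equal(nrow(sites), nrow(islands))
  expect_true(all(sites$q_value < 0.01))
  # each site overlaps its island
  expect_true(all(
    sites$start <= chrom$truth$islands$end & sites$end >= chrom$truth$islands$start
  ))
  # island-site GC reflects the planted AT fraction
  gcs <- site_gc(sites, chrom$sequence)
  expect_true(all(abs(gcs - 0.4) < 0.12))
  with_noise <- simulate_sites(chrom$truth$islands, 10000,
    n_noise_sites = 7, seed = 8
  )
  expect_equal(nrow(with_noise), nrow(islands) + 7)
  expect_equal(sum(with_noise$origin == "noise"), 7)
})

test_that("volatile simulation is reproducible and shifts the right compounds", {
  a <- simulate_volatiles(n_compounds = 30, n_per_group = 4, seed = 9)
  b <- simulate_volatiles(n_compounds = 30, n_per_group = 4, seed = 9)
  expect_identical(a$matrix, b$matrix)
  expect_equal(dim(a$matrix), c(30L, 12L))
  expect_equal(as.integer(table(a$groups)[c("WT", "mutant", "medium")]), rep(4L, 3))
  expect_equal(length(a$truth$shifted), 10)
})

test_that("the default scene wires all components together", {
  scene <- simulate_scene(seed = 1, scale = 0.02)
  expect_true(all(c("chromosome", "genes", "clusters", "sites", "de") %in% names(scene)))
  expect_gte(nrow(scene$genes), 200)
  expect_true(all(scene$sites$end <= nchar(scene$chromosome$sequence)))
  sig <- filter_de(scene$de)
  expect_setequal(sig$locus_id, scene$de_truth$planted)
})
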