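# Seeded generators producing chromosomes, annotations, binding sites, DE
# tables and volatile matrices with recorded ground truth. Defaults emulate
# the study conditions of a high-GC Streptomyces chromosome: ~72.4% GC
# background carrying AT-rich islands, ~8000 loci of which ~1000 lie in
# specialized metabolic clusters, per-gene DE probability ~0.15 inside
# clusters versus ~0.04 outside, and a compounds-by-samples volatile matrix
# with a handful of planted group shifts.

#' Simulate a high-GC chromosome with planted AT-rich islands
#'
#' Background positions are i.i.d. with `P(G or C) = background_gc`; island
#' positions are i.i.d. with `P(A or T) = at_fraction`. Islands must not
#' overlap. When `guarantee_core` is set (the default), one 6-mer of A/T
#' symbols is stamped at each island's centre so every island carries at
#' least one AT-rich core by construction.
#'
#' @param length Chromosome length in nucleotides.
#' @param background_gc Background GC fraction (default 0.724, the
#'   chromosome-average GC of *S. venezuelae*).
#' @param islands Data frame with columns `start`, `length`, `at_fraction`
#'   (and optionally `guarantee_core`), or `NULL` for none.
#' @param seed Integer seed.
#' @return List with `sequence` (character string) and `truth` (list with
#'   element `islands`: data frame `start`, `end`, `length`, `at_fraction`,
#'   `guarantee_core`).
#' @export
simulate_chromosome <- function(length, background_gc = 0.724, islands = NULL,
                                seed = 1L) {
  length <- as.integer(length)
  if (is.null(islands) || nrow(islands) == 0L) {
    islands <- data.frame(
      start = integer(0), length = integer(0), at_fraction = numeric(0)
    )
  }
  islands$start <- as.integer(islands$start)
  islands$length <- as.integer(islands$length)
  islands$end <- islands$start + islands$length - 1L
  if (is.null(islands$guarantee_core)) {
    islands$guarantee_core <- rep(TRUE, nrow(islands))
  }
  if (nrow(islands)) {
    if (any(islands$start < 1L) || any(islands$end > length)) {
      stop("island outside chromosome", call. = FALSE)
    }
    o <- order(islands$start)
    if (any(islands$start[o][-1L] <= islands$end[o][-nrow(islands)])) {
      stop("islands overlap", call. = FALSE)
    }
  }
  x <- local_seed(seed, {
    gcp <- background_gc / 2
    atp <- (1 - background_gc) / 2
    x <- sample(c("G", "C", "A", "T"), length,
      replace = TRUE, prob = c(gcp, gcp, atp, atp)
    )
    for (i in seq_len(nrow(islands))) {
      idx <- islands$start[i]:islands$end[i]
      atp_i <- islands$at_fraction[i] / 2
      gcp_i <- (1 - islands$at_fraction[i]) / 2
      x[idx] <- sample(c("A", "T", "G", "C"), length(idx),
        replace = TRUE, prob = c(atp_i, atp_i, gcp_i, gcp_i)
      )
      if (isTRUE(islands$guarantee_core[i]) && islands$length[i] >= 6L) {
        mid <- islands$start[i] + (islands$length[i] - 6L) %/% 2L
        x[mid:(mid + 5L)] <- sample(c("A", "T"), 6L, replace = TRUE)
      }
    }
    x
  })
  list(
    sequence = paste(x, collapse = ""),
    truth = list(islands = islands)
  )
}

#' Simulate a clustered gene annotation with a chromosome-region partition
#'
#' Genes are packed left to right with jittered lengths and intergenic gaps,
#' locus numbering strictly increasing with coordinate (`SYN_0001`, ...).
#' Clusters are consecutive locus blocks placed at evenly spaced offsets.
#' The region partition puts the central half of the chromosome in the core
#' and a quarter in each arm.
#'
#' @param n_genes Number of genes.
#' @param mean_gene_len Mean gene length in nucleotides (default 900).
#' @param mean_gap Mean intergenic gap (default 100).
#' @param n_clusters Number of clusters.
#' @param genes_per_cluster Genes per cluster.
#' @param chrom_length Chromosome length; derived from the packing when
#'   `NULL`.
#' @param seed Integer seed.
#' @return List with `genes` (gene-model data frame), `clusters` (validated
#'   cluster table), `regions` ([partition_regions()] object), and `truth`
#'   (list with `cluster_gene_ids`).
#' @export
simulate_annotation <- function(n_genes = 8000L, mean_gene_len = 900L,
                                mean_gap = 100L, n_clusters = 25L,
                                genes_per_cluster = 40L, chrom_length = NULL,
                                seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (n_clusters * genes_per_cluster > n_genes) {
    stop("more cluster genes than genes", call. = FALSE)
  }
  res <- local_seed(seed, {
    lens <- pmax(90L, as.integer(round(
      mean_gene_len * exp(stats::rnorm(n_genes, 0, 0.3))
    )))
    gaps <- pmax(10L, as.integer(round(
      mean_gap * exp(stats::rnorm(n_genes, 0, 0.5))
    )))
    starts <- cumsum(c(1L, (lens + gaps)[-n_genes]))
    ends <- starts + lens - 1L
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    list(starts = starts, ends = ends, strand = strand)
  })
  footprint <- res$ends[n_genes] + 100L
  if (is.null(chrom_length)) {
    chrom_length <- footprint
  } else if (chrom_length < footprint) {
    stop("genes do not fit on the requested chromosome", call. = FALSE)
  }
  width <- max(4L, nchar(as.character(n_genes)))
  genes <- validate_genes(data.frame(
    locus_id = sprintf(paste0("SYN_%0", width, "d"), seq_len(n_genes)),
    start = res$starts,
    end = res$ends,
    strand = res$strand,
    stringsAsFactors = FALSE
  ))
  # evenly spaced consecutive-locus blocks
  cluster_first <- as.integer(round(seq(
    1L, n_genes - genes_per_cluster + 1L,
    length.out = n_clusters
  )))
  clusters <- validate_clusters(data.frame(
    name = sprintf("cluster_%02d", seq_len(n_clusters)),
    first_locus = genes$locus_id[cluster_first],
    last_locus = genes$locus_id[cluster_first + genes_per_cluster - 1L],
    stringsAsFactors = FALSE
  ))
  regions <- partition_regions(
    left_end = chrom_length %/% 4L,
    core_end = (3L * chrom_length) %/% 4L,
    chrom_length = chrom_length
  )
  cluster_gene_ids <- unique(unlist(lapply(
    seq_len(n_clusters),
    function(i) cluster_members(clusters[i, , drop = FALSE], mode = "span")
  )))
  list(
    genes = genes, clusters = clusters, regions = regions,
    truth = list(cluster_gene_ids = cluster_gene_ids)
  )
}

#' Simulate a differential-expression table with planted cluster enrichment
#'
#' Each gene is independently significant with probability `p_cluster` when
#' its locus lies in a cluster span and `p_background` otherwise. Planted
#' genes receive a fold change strictly above the significance threshold
#' (log-uniform between 4.5x and 900x; a small fraction are repressed, i.e.
#' fold change below 1/4.5) and q-value below 0.01; all other genes receive
#' sub-threshold fold changes and/or large q-values, so the planted set
#' equals the `filter_de()` output exactly. Wild-type expression for planted
#' upregulated genes emulates transcriptionally silent clusters (RPKM < 10).
#'
#' @param genes Gene-model data frame.
#' @param clusters Validated cluster table.
#' @param p_cluster Per-gene significance probability inside clusters
#'   (default 0.15).
#' @param p_background Probability outside clusters (default 0.04).
#' @param prop_down Fraction of planted genes that are repressed
#'   (default 0.1).
#' @param seed Integer seed.
#' @return List with `de` (DE data frame: `locus_id`, `wt_expr`, `mut_expr`,
#'   `fold_change`, `q_value`) and `truth` (list with `planted`: locus ids,
#'   and `planted_direction`).
#' @export
simulate_de <- function(genes, clusters, p_cluster = 0.15, p_background = 0.04,
                        prop_down = 0.1, seed = 1L) {
  n <- nrow(genes)
  idx <- genes$locus_idx
  in_cluster <- rep(FALSE, n)
  for (i in seq_len(nrow(clusters))) {
    in_cluster <- in_cluster |
      (!is.na(idx) & idx >= clusters$first_idx[i] & idx <= clusters$last_idx[i])
  }
  local_seed(seed, {
    p <- ifelse(in_cluster, p_cluster, p_background)
    planted <- runif(n) < p
    dir_down <- planted & runif(n) < prop_down
    fc <- numeric(n)
    q <- numeric(n)
    wt <- numeric(n)
    # non-planted: sub-threshold on both criteria
    fc[!planted] <- exp(runif(sum(!planted), log(0.5), log(3)))
    q[!planted] <- runif(sum(!planted), 0.02, 1)
    wt[!planted] <- exp(runif(sum(!planted), log(20), log(500)))
    n_up <- sum(planted & !dir_down)
    n_dn <- sum(planted & dir_down)
    fc[planted & !dir_down] <- exp(runif(n_up, log(4.5), log(900)))
    fc[planted & dir_down] <- 1 / exp(runif(n_dn, log(4.5), log(50)))
    q[planted] <- runif(sum(planted), 0, 0.009)
    wt[planted & !dir_down] <- exp(runif(n_up, log(0.5), log(9)))
    wt[planted & dir_down] <- exp(runif(n_dn, log(50), log(500)))
    de <- data.frame(
      locus_id = genes$locus_id,
      wt_expr = wt,
      mut_expr = wt * fc,
      fold_change = fc,
      q_value = q,
      stringsAsFactors = FALSE
    )
    list(
      de = de,
      truth = list(
        planted = genes$locus_id[planted],
        planted_direction = ifelse(dir_down[planted], "down", "up"),
        in_cluster = genes$locus_id[in_cluster]
      )
    )
  })
}

#' Simulate a binding-site table anchored on planted islands
#'
#' Emits one site per island (bounds jittered by up to `jitter` nucleotides)
#' with q-value below 0.01, plus uniformly placed noise sites with q-values
#' spread across `[0, 0.05)`.
#'
#' @param islands Island truth data frame (from [simulate_chromosome()]).
#' @param chrom_length Chromosome length.
#' @param n_noise_sites Number of noise sites (default 0).
#' @param noise_width_range Width range for noise sites.
#' @param jitter Maximum bound jitter for island sites (default 20).
#' @param seed Integer seed.
#' @return Binding-site data frame with an `origin` column
#'   (`"island"`/`"noise"`).
#' @export
simulate_sites <- function(islands, chrom_length, n_noise_sites = 0L,
                           noise_width_range = c(100L, 1000L), jitter = 20L,
                           seed = 1L) {
  chrom_length <- as.integer(chrom_length)
  local_seed(seed, {
    n_isl <- nrow(islands)
    isl <- data.frame(
      start = pmax(1L, islands$start +
        sample(seq(-jitter, jitter), n_isl, replace = TRUE)),
      end = pmin(chrom_length, islands$end +
        sample(seq(-jitter, jitter), n_isl, replace = TRUE)),
      q_value = runif(n_isl, 0, 0.009),
      origin = rep("island", n_isl),
      stringsAsFactors = FALSE
    )
    isl$end <- pmax(isl$end, isl$start)
    noise <- NULL
    if (n_noise_sites > 0L) {
      w <- sample(seq(noise_width_range[1L], noise_width_range[2L]),
        n_noise_sites,
        replace = TRUE
      )
      s <- vapply(w, function(wi) sample.int(chrom_length - wi + 1L, 1L), integer(1))
      noise <- data.frame(
        start = s, end = s + w - 1L,
        q_value = runif(n_noise_sites, 0, 0.05),
        origin = rep("noise", n_noise_sites),
        stringsAsFactors = FALSE
      )
    }
    validate_sites(rbind(isl, noise))
  })
}

#' Simulate a volatile-compound abundance matrix with planted shifts
#'
#' Per-compound baseline log10 intensities are drawn uniformly in `[4, 7]`
#' with a within-group standard deviation of `within_sd` log10 units;
#' samples are log-normal around the baseline. The first `n_shifted`
#' compounds are displaced by `shift_sd` within-group standard deviations in
#' the mutant group (alternating direction). A sterile-medium group at
#' 10-fold lower abundance is included for display.
#'
#' @param n_compounds Number of compounds (default 200).
#' @param n_per_group Samples per group (default 6).
#' @param n_shifted Number of shifted compounds (default 10).
#' @param shift_sd Shift magnitude in within-group standard deviations
#'   (default 3).
#' @param within_sd Within-group sd on the log10 scale (default 0.25).
#' @param seed Integer seed.
#' @return List with `matrix` (compounds x samples intensity matrix),
#'   `groups` (named label vector: WT, mutant, medium) and `truth` (list
#'   with `shifted` compound ids and `shift_direction`).
#' @export
simulate_volatiles <- function(n_compounds = 200L, n_per_group = 6L,
                               n_shifted = 10L, shift_sd = 3, within_sd = 0.25,
                               seed = 1L) {
  local_seed(seed, {
    groups <- rep(c("WT", "mutant", "medium"), each = n_per_group)
    names(groups) <- sprintf(
      "%s_%d", groups, rep(seq_len(n_per_group), times = 3)
    )
    base <- runif(n_compounds, 4, 7)
    shifted <- seq_len(min(n_shifted, n_compounds))
    direction <- rep(c("up_in_mutant", "down_in_mutant"), length.out = length(shifted))
    m <- matrix(0, n_compounds, length(groups))
    rownames(m) <- sprintf("compound_%03d", seq_len(n_compounds))
    colnames(m) <- names(groups)
    for (g in c("WT", "mutant", "medium")) {
      cols <- which(groups == g)
      mu <- base
      if (g == "medium") mu <- base - 1
      if (g == "mutant" && length(shifted)) {
        mu[shifted] <- mu[shifted] +
          ifelse(direction == "up_in_mutant", 1, -1) * shift_sd * within_sd
      }
      m[, cols] <- 10^(mu + matrix(
        stats::rnorm(n_compounds * length(cols), 0, within_sd),
        n_compounds, length(cols)
      ))
    }
    list(
      matrix = m,
      groups = groups,
      truth = list(
        shifted = rownames(m)[shifted],
        shift_direction = direction
      )
    )
  })
}

#' Simulate a complete synthetic scene
#'
#' Bundles chromosome, annotation, binding sites, DE table and volatile
#' matrix at a configurable scale. The default scale mirrors the magnitudes
#' of the reference study (8000 loci, ~1000 cluster loci, ~220 binding
#' sites); `scale` shrinks every count proportionally for fast tests.
#'
#' @param seed Integer seed.
#' @param scale Scene scale factor in (0, 1] (default 1).
#' @param island_at Island AT fraction (default 0.6, emulating the ~55-65%
#'   AT content of bound sites on a 72.4% GC background).
#' @return List with components `chromosome` (list: `sequence`, `truth`),
#'   `genes`, `clusters`, `regions`, `sites`, `de`, `de_truth`, `volatiles`.
#'   The chromosome is sized independently of the gene annotation (island
#'   scanning does not require gene coordinates).
#' @export
simulate_scene <- function(seed = 1L, scale = 1, island_at = 0.6) {
  n_genes <- max(200L, as.integer(round(8000L * scale)))
  n_clusters <- max(2L, as.integer(round(25L * scale)))
  ann <- simulate_annotation(
    n_genes = n_genes, n_clusters = n_clusters, genes_per_cluster = 40L,
    seed = seed
  )
  chrom_length <- max(50000L, as.integer(round(1e6 * scale)))
  n_islands <- max(5L, as.integer(round(220L * scale)))
  island_len <- 300L
  island_starts <- as.integer(round(seq(
    1000L, chrom_length - island_len - 1000L,
    length.out = n_islands
  )))
  islands <- data.frame(
    start = island_starts, length = island_len, at_fraction = island_at
  )
  chrom <- simulate_chromosome(chrom_length, islands = islands, seed = seed + 1L)
  sites <- simulate_sites(
    chrom$truth$islands, chrom_length,
    n_noise_sites = max(2L, as.integer(round(20L * scale))), seed = seed + 2L
  )
  de <- simulate_de(ann$genes, ann$clusters, seed = seed + 3L)
  vol <- simulate_volatiles(seed = seed + 4L)
  list(
    chromosome = chrom,
    genes = ann$genes, clusters = ann$clusters, regions = ann$regions,
    cluster_truth = ann$truth,
    sites = sites, de = de$de, de_truth = de$truth, volatiles = vol
  )
}

#' Write a chromosome to FASTA
#'
#' @param sequence Character string.
#' @param path Output path.
#' @param id Record id (default `"chr"`).
#' @return `path`, invisibly.
#' @export
write_chromosome_fasta <- function(sequence, path, id = "chr") {
  set <- Biostrings::DNAStringSet(sequence)
  names(set) <- id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
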