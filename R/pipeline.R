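# End-to-end pipeline: load inputs, run every analysis stage with shared
# thresholds, and write a reproducible report bundle of TSVs plus a
# machine-readable parameter manifest.

#' Pipeline configuration
#'
#' Collects input paths and analysis thresholds. All thresholds default to
#' the reference configuration: fold change 4, DE q 0.01, site q 0.01,
#' volatile alpha 0.05, upstream window 300 nt, and the standard
#' 20/11-window, 6/5-core scan.
#'
#' @param chromosome_fasta Path to the chromosome FASTA.
#' @param annotation Path to gene models (GFF3 or BED).
#' @param cluster_table Path to the cluster TSV.
#' @param sites Path to the binding-site table (TSV or BED).
#' @param de_table Path to the differential-expression TSV.
#' @param volatile_matrix,volatile_groups Optional paths to the volatile
#'   abundance matrix and sample-group map TSVs.
#' @param left_end,core_end Region boundaries (chromosome length is read
#'   from the FASTA).
#' @param fc_threshold,q_threshold,site_q_max,alpha,upstream_window,pseudocount
#'   Analysis thresholds.
#' @param total_loci Total locus count for the enrichment null; derived from
#'   the gene table when `NULL`.
#' @param scan [scan_config()] to use.
#' @param seed Integer seed (baseline segment sampling).
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `run_config`.
#' @export
run_config <- function(chromosome_fasta, annotation, cluster_table, sites,
                       de_table, volatile_matrix = NULL, volatile_groups = NULL,
                       left_end, core_end,
                       fc_threshold = 4, q_threshold = 0.01, site_q_max = 0.01,
                       alpha = 0.05, upstream_window = 300L, pseudocount = 1,
                       total_loci = NULL, scan = scan_config(), seed = 1L,
                       out_dir = "silencescan_report") {
  stopifnot(fc_threshold > 0, q_threshold > 0, site_q_max > 0, alpha > 0)
  paths <- c(
    chromosome_fasta = chromosome_fasta, annotation = annotation,
    cluster_table = cluster_table, sites = sites, de_table = de_table,
    volatile_matrix = volatile_matrix, volatile_groups = volatile_groups
  )
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(
      "config error: missing input file(s): ",
      paste(sprintf("%s (%s)", names(missing), missing), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      chromosome_fasta = chromosome_fasta, annotation = annotation,
      cluster_table = cluster_table, sites = sites, de_table = de_table,
      volatile_matrix = volatile_matrix, volatile_groups = volatile_groups,
      left_end = as.integer(left_end), core_end = as.integer(core_end),
      fc_threshold = fc_threshold, q_threshold = q_threshold,
      site_q_max = site_q_max, alpha = alpha,
      upstream_window = as.integer(upstream_window), pseudocount = pseudocount,
      total_loci = total_loci, scan = scan, seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full silencing-analysis pipeline
#'
#' Executes every stage against the configured inputs: site significance
#' filtering, composition profiling of sites, gene/region/cluster
#' annotation, DE filtering, per-cluster summaries, binomial cluster
#' enrichment, and (when volatile inputs are configured) the volatile
#' differential pipeline. Deterministic given the inputs and seed; no input
#' is mutated and every output lands under `config$out_dir`:
#' `annotated_sites.tsv`, `site_profiles.tsv`, `region_summary.tsv`,
#' `de_significant.tsv`, `cluster_summary.tsv`, `enrichment.tsv`,
#' `volatiles.tsv` (optional), `summary.tsv` and `manifest.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all computed tables (`sites`, `profiles`,
#'   `region_summary`, `de_sig`, `cluster_summary`, `enrichment`,
#'   `volatiles`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  chrom_set <- step("chromosome", Biostrings::readDNAStringSet(config$chromosome_fasta))
  chrom <- as.character(chrom_set[[1L]])
  genes <- step("annotation", read_annotation(config$annotation))
  clusters <- step("clusters", read_cluster_table(config$cluster_table))
  regions <- step("regions", partition_regions(
    config$left_end, config$core_end, nchar(chrom)
  ))
  sites <- step("sites", filter_sites(read_sites(config$sites), config$site_q_max))
  de <- step("expression", read_de_table(config$de_table))
  de_sig <- step("expression", filter_de(
    de, config$fc_threshold, config$q_threshold, config$pseudocount
  ))
  annotated <- step("site-annotation", annotate_sites(
    sites, genes, regions, chrom,
    de_significant = de_sig$locus_id,
    upstream_window = config$upstream_window
  ))
  clusters <- cluster_genomic_span(clusters, genes)
  annotated$clusters <- step(
    "site-annotation", assign_site_to_clusters(annotated, clusters)
  )
  profiles <- step("scan", do.call(rbind, lapply(
    seq_len(nrow(annotated)),
    function(i) {
      at_profile(
        substring(chrom, annotated$start[i], annotated$end[i]),
        config$scan,
        id = annotated$site_id[i]
      )
    }
  )))
  region_summary <- step("region-summary", summarize_by_region(annotated))
  cluster_summary <- step(
    "cluster-summary", cluster_de_summary_all(clusters, de_sig)
  )
  total_loci <- config$total_loci
  if (is.null(total_loci)) total_loci <- nrow(genes)
  p0 <- cluster_null_proportion(clusters, total_loci)
  didx <- locus_index(de_sig$locus_id)
  in_cluster <- vapply(didx, function(i) {
    !is.na(i) && any(i >= clusters$first_idx & i <= clusters$last_idx)
  }, logical(1))
  enr <- step("enrichment", enrichment_binomial(
    sum(in_cluster), nrow(de_sig), as.numeric(p0)
  ))
  volatiles <- NULL
  if (!is.null(config$volatile_matrix)) {
    volatiles <- step("volatiles", {
      m <- read_abundance_matrix(config$volatile_matrix)
      g <- read_sample_groups(config$volatile_groups)
      significant_compounds(m, g, alpha = config$alpha)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  .write_tsv(annotated, out("annotated_sites.tsv"))
  .write_tsv(profiles, out("site_profiles.tsv"))
  .write_tsv(region_summary, out("region_summary.tsv"))
  .write_tsv(de_sig, out("de_significant.tsv"))
  .write_tsv(cluster_summary, out("cluster_summary.tsv"))
  .write_tsv(
    data.frame(
      k = enr$k, n = enr$n, p0 = enr$p0, p_value = enr$p_value,
      n_union_loci = attr(p0, "n_union"), total_loci = total_loci
    ),
    out("enrichment.tsv")
  )
  if (!is.null(volatiles)) .write_tsv(volatiles, out("volatiles.tsv"))
  .write_tsv(
    data.frame(
      quantity = c(
        "n_sites_significant", "n_de_significant", "n_de_in_clusters",
        "enrichment_p", "n_volatiles_selected"
      ),
      value = c(
        nrow(annotated), nrow(de_sig), enr$k, enr$p_value,
        if (is.null(volatiles)) NA_real_ else nrow(volatiles)
      )
    ),
    out("summary.tsv")
  )
  manifest <- config[c(
    "fc_threshold", "q_threshold", "site_q_max", "alpha", "upstream_window",
    "pseudocount", "left_end", "core_end", "seed"
  )]
  manifest$scan <- unclass(config$scan)
  manifest$total_loci <- total_loci
  jsonlite::write_json(manifest, out("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(list(
    sites = annotated, profiles = profiles, region_summary = region_summary,
    de_sig = de_sig, cluster_summary = cluster_summary, enrichment = enr,
    volatiles = volatiles
  ))
}
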