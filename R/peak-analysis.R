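# Binding-site annotation: significance filtering, gene association by the
# upstream/overlap rule, chromosome-region classification, and composition
# summaries.

#' Read a binding-site table
#'
#' Accepts either a TSV with header columns `start`, `end`, `q_value`
#' (optionally `chrom`), or a BED file (0-based half-open; converted, with
#' the score column interpreted as the q-value).
#'
#' @param path Path to the site table.
#' @param format `"tsv"`, `"bed"` or `"auto"` (by extension).
#' @return Data frame with columns `site_id`, `start`, `end`, `width`,
#'   `q_value`.
#' @export
read_sites <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    sites <- data.frame(
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      q_value = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    lc <- tolower(names(tab))
    names(tab) <- lc
    qcol <- intersect(c("q_value", "q", "qvalue", "fdr"), lc)[1L]
    if (!all(c("start", "end") %in% lc) || is.na(qcol)) {
      stop("site TSV needs columns start, end and a q-value column", call. = FALSE)
    }
    sites <- data.frame(
      start = as.integer(tab$start),
      end = as.integer(tab$end),
      q_value = as.numeric(tab[[qcol]]),
      stringsAsFactors = FALSE
    )
  }
  validate_sites(sites)
}

#' Validate a binding-site data frame
#'
#' @param sites Data frame with columns `start`, `end`, `q_value`.
#' @return The data frame with `site_id` and `width` columns added.
#' @export
validate_sites <- function(sites) {
  if (any(sites$end < sites$start)) stop("site with end < start", call. = FALSE)
  if (any(!is.na(sites$q_value) & (sites$q_value < 0 | sites$q_value > 1))) {
    stop("q_value outside [0, 1]", call. = FALSE)
  }
  if (is.null(sites$site_id)) {
    sites$site_id <- sprintf("site_%04d", seq_len(nrow(sites)))
  }
  sites$width <- sites$end - sites$start + 1L
  rownames(sites) <- NULL
  sites[, union(c("site_id", "start", "end", "width", "q_value"), names(sites))]
}

#' Filter binding sites on adjusted significance
#'
#' Retains sites with `q_value` strictly below `q_max` (the reference
#' analysis kept differentially bound sites with an adjusted p-value less
#' than 0.01). Order is preserved.
#'
#' @param sites Binding-site data frame.
#' @param q_max Exclusive significance threshold (default 0.01).
#' @return The retained subset.
#' @export
filter_sites <- function(sites, q_max = 0.01) {
  sites[!is.na(sites$q_value) & sites$q_value < q_max, , drop = FALSE]
}

#' Associate binding sites with genes by the upstream/overlap rule
#'
#' A gene is associated with a site when the site interval intersects the
#' gene body (`overlaps_cds`) or the strand-aware upstream interval of
#' `upstream_window` nucleotides ending immediately 5' of the gene
#' (`upstream`). Both relations are reported when both hold; a site between
#' two divergently transcribed genes can associate with both.
#'
#' @param sites Binding-site data frame (columns `site_id`, `start`, `end`).
#' @param genes Gene-model data frame (see [validate_genes()]).
#' @param upstream_window Upstream extent in nucleotides (default 300);
#'   "immediately upstream" is not quantified by the reference analysis, so
#'   this is configurable.
#' @return Data frame with columns `site_id`, `locus_id`, `relation`.
#' @export
assign_site_to_genes <- function(sites, genes, upstream_window = 300L) {
  upstream_window <- as.integer(upstream_window)
  if (upstream_window < 0L) stop("upstream_window must be >= 0", call. = FALSE)
  site_r <- IRanges::IRanges(start = sites$start, end = sites$end)
  body_r <- IRanges::IRanges(start = genes$start, end = genes$end)
  hits_body <- IRanges::findOverlaps(site_r, body_r)
  out <- data.frame(
    site_id = sites$site_id[S4Vectors::queryHits(hits_body)],
    locus_id = genes$locus_id[S4Vectors::subjectHits(hits_body)],
    relation = rep("overlaps_cds", length(hits_body)),
    stringsAsFactors = FALSE
  )
  if (upstream_window > 0L) {
    up_start <- ifelse(genes$strand == "+",
      pmax(1L, genes$start - upstream_window), genes$end + 1L
    )
    up_end <- ifelse(genes$strand == "+",
      genes$start - 1L, genes$end + upstream_window
    )
    valid <- up_end >= up_start
    up_r <- IRanges::IRanges(
      start = up_start[valid], end = up_end[valid]
    )
    hits_up <- IRanges::findOverlaps(site_r, up_r)
    gene_idx <- which(valid)[S4Vectors::subjectHits(hits_up)]
    out <- rbind(out, data.frame(
      site_id = sites$site_id[S4Vectors::queryHits(hits_up)],
      locus_id = genes$locus_id[gene_idx],
      relation = rep("upstream", length(hits_up)),
      stringsAsFactors = FALSE
    ))
  }
  out <- out[order(match(out$site_id, sites$site_id), out$locus_id, out$relation), ,
    drop = FALSE
  ]
  rownames(out) <- NULL
  out
}

#' Classify binding sites into chromosome regions by midpoint
#'
#' Each site is assigned the region containing its midpoint
#' `floor((start + end) / 2)`; for even-width sites this rounds leftward, so
#' a site straddling a boundary is assigned to the leftward region.
#'
#' @param sites Binding-site data frame.
#' @param regions A [partition_regions()] object.
#' @return Character vector of region labels, one per site.
#' @export
classify_region <- function(sites, regions) {
  mid <- (sites$start + sites$end) %/% 2L
  if (any(mid < regions$start[1L] | mid > regions$end[3L])) {
    stop("site midpoint outside the chromosome partition", call. = FALSE)
  }
  idx <- findInterval(mid, regions$start)
  regions$region[idx]
}

#' GC fraction of binding-site subsequences
#'
#' @param sites Binding-site data frame.
#' @param chrom Chromosome sequence (character string or
#'   [Biostrings::DNAString]).
#' @return Numeric vector of per-site GC fractions. Summaries over sites are
#'   conventionally width-unweighted means of these values.
#' @export
site_gc <- function(sites, chrom) {
  if (methods::is(chrom, "DNAString")) chrom <- as.character(chrom)
  n <- nchar(chrom)
  if (any(sites$start < 1L | sites$end > n)) {
    stop("site outside chromosome bounds", call. = FALSE)
  }
  vapply(
    seq_len(nrow(sites)),
    function(i) gc_content(substring(chrom, sites$start[i], sites$end[i])),
    numeric(1)
  )
}

#' Annotate binding sites
#'
#' One-stop annotation: gene association by the upstream/overlap rule,
#' chromosome-region classification by midpoint, per-site GC fraction, and
#' (when a significant DE set is supplied) the transcription-change flag
#' (`TRUE` iff any associated gene is in the significant set).
#'
#' @param sites Binding-site data frame.
#' @param genes Gene-model data frame.
#' @param regions A [partition_regions()] object, or `NULL` to skip.
#' @param chrom Chromosome sequence, or `NULL` to skip GC.
#' @param de_significant Character vector of significant locus identifiers
#'   (e.g. `filter_de(...)$locus_id`), or `NULL` to skip the change flag.
#' @param upstream_window Passed to [assign_site_to_genes()].
#' @return The site data frame with columns `region`, `gc_fraction`,
#'   `associated_genes` (comma-separated), `n_genes`,
#'   `transcription_change` added; the full association table is attached as
#'   attribute `"associations"`.
#' @export
annotate_sites <- function(sites, genes, regions = NULL, chrom = NULL,
                           de_significant = NULL, upstream_window = 300L) {
  assoc <- assign_site_to_genes(sites, genes, upstream_window)
  per_site <- split(assoc$locus_id, factor(assoc$site_id, levels = sites$site_id))
  sites$associated_genes <- vapply(
    per_site, function(g) paste(unique(g), collapse = ","), character(1)
  )
  sites$n_genes <- vapply(per_site, function(g) length(unique(g)), integer(1))
  if (!is.null(regions)) sites$region <- classify_region(sites, regions)
  if (!is.null(chrom)) sites$gc_fraction <- site_gc(sites, chrom)
  if (!is.null(de_significant)) {
    sites$transcription_change <- vapply(
      per_site, function(g) any(g %in% de_significant), logical(1)
    )
  }
  attr(sites, "associations") <- assoc
  sites
}

#' Join a significant DE set onto annotated sites
#'
#' Sets `transcription_change` to `TRUE` for sites with at least one
#' associated gene in the significant set.
#'
#' @param annotated_sites Output of [annotate_sites()].
#' @param de_significant Character vector of significant locus identifiers,
#'   or a data frame with a `locus_id` column.
#' @return `annotated_sites` with `transcription_change` set.
#' @export
join_sites_expression <- function(annotated_sites, de_significant) {
  if (is.data.frame(de_significant)) de_significant <- de_significant$locus_id
  gene_lists <- strsplit(annotated_sites$associated_genes, ",", fixed = TRUE)
  annotated_sites$transcription_change <- vapply(
    gene_lists, function(g) any(g %in% de_significant), logical(1)
  )
  annotated_sites
}

#' Per-region binding-site summary
#'
#' Counts sites per chromosome region, the number and fraction associated
#' with a transcriptional change, and mean site widths split by change
#' status. Means over empty groups are `NA`, not zero.
#'
#' @param annotated_sites Annotated site data frame with `region`, `width`
#'   and `transcription_change` columns.
#' @return Data frame with one row per region: `region`, `n_sites`,
#'   `n_with_change`, `fraction_with_change`, `mean_width_change`,
#'   `mean_width_no_change`.
#' @export
summarize_by_region <- function(annotated_sites) {
  levels <- c("left_arm", "core", "right_arm")
  out <- do.call(rbind, lapply(levels, function(r) {
    sub <- annotated_sites[annotated_sites$region == r, , drop = FALSE]
    n <- nrow(sub)
    n_chg <- sum(sub$transcription_change)
    data.frame(
      region = r,
      n_sites = n,
      n_with_change = n_chg,
      fraction_with_change = if (n > 0L) n_chg / n else NA_real_,
      mean_width_change = if (n_chg > 0L) {
        mean(sub$width[sub$transcription_change])
      } else {
        NA_real_
      },
      mean_width_no_change = if (n - n_chg > 0L) {
        mean(sub$width[!sub$transcription_change])
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Associate binding sites with clusters
#'
#' A site is associated with every cluster whose genomic span (hull of its
#' member genes) it intersects.
#'
#' @param sites Binding-site data frame.
#' @param clusters Cluster table with `span_start`/`span_end` columns (see
#'   [cluster_genomic_span()]).
#' @return Character vector (comma-separated cluster names per site, `""`
#'   when none).
#' @export
assign_site_to_clusters <- function(sites, clusters) {
  has_span <- !is.na(clusters$span_start)
  cl <- clusters[has_span, , drop = FALSE]
  site_r <- IRanges::IRanges(start = sites$start, end = sites$end)
  cl_r <- IRanges::IRanges(start = cl$span_start, end = cl$span_end)
  hits <- IRanges::findOverlaps(site_r, cl_r)
  per_site <- split(
    cl$name[S4Vectors::subjectHits(hits)],
    factor(sites$site_id[S4Vectors::queryHits(hits)], levels = sites$site_id)
  )
  unname(vapply(per_site, function(x) paste(unique(x), collapse = ","), character(1)))
}
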