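# Annotation, cluster-table and region I/O.
#
# Internal coordinate convention is 1-based inclusive (GFF); BED input is
# converted at the boundary. Cluster membership follows the locus-index-range
# convention of published cluster tables (first gene through last gene).

#' Read gene models from GFF3 or BED
#'
#' Parses gene models into a data frame with 1-based inclusive coordinates.
#' BED input (0-based half-open) is converted on read. GFF3 features of type
#' `gene` are used when present (all features otherwise); the locus
#' identifier is taken from `locus_tag`, `ID` or `Name`, in that order of
#' preference. Genes are returned sorted by start coordinate; duplicated
#' locus identifiers are an error.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"`; guessed from the file extension when
#'   omitted.
#' @return Data frame with columns `locus_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `locus_idx` (integer index parsed from `PREFIX_digits`
#'   identifiers, `NA` otherwise).
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    types <- as.character(gr$type)
    if (any(types == "gene")) gr <- gr[types == "gene"]
    meta <- S4Vectors::mcols(gr)
    ids <- NULL
    for (col in c("locus_tag", "ID", "Name")) {
      if (col %in% colnames(meta) && !all(is.na(meta[[col]]))) {
        ids <- as.character(meta[[col]])
        break
      }
    }
    if (is.null(ids)) stop("no locus identifiers found in GFF3", call. = FALSE)
  } else {
    ids <- gr$name
    if (is.null(ids)) stop("BED file lacks a name column", call. = FALSE)
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  genes <- data.frame(
    locus_id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  validate_genes(genes)
}

#' Validate and normalise a gene-model data frame
#'
#' @param genes Data frame with columns `locus_id`, `start`, `end`, `strand`.
#' @return The data frame sorted by start, with a `locus_idx` column added.
#' @export
validate_genes <- function(genes) {
  need <- c("locus_id", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop("gene table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(genes$end < genes$start)) {
    bad <- which(genes$end < genes$start)[1L]
    stop(sprintf("gene %s has end < start", genes$locus_id[bad]), call. = FALSE)
  }
  if (anyDuplicated(genes$locus_id)) {
    stop(
      "duplicated locus identifiers: ",
      paste(unique(genes$locus_id[duplicated(genes$locus_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  genes$locus_idx <- locus_index(genes$locus_id)
  rownames(genes) <- NULL
  genes
}

#' Write gene models to GFF3 or BED
#'
#' Inverse of [read_annotation()]; coordinates and strands round-trip
#' exactly.
#'
#' @param genes Gene-model data frame (see [validate_genes()]).
#' @param path Output path.
#' @param format `"gff3"` or `"bed"`.
#' @param seqname Chromosome name to write (default `"chr"`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path, format = c("gff3", "bed"),
                             seqname = "chr") {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  if (format == "gff3") {
    gr$type <- "gene"
    gr$ID <- genes$locus_id
    gr$locus_tag <- genes$locus_id
    gr$source <- "silencescan"
    rtracklayer::export(gr, path, format = "GFF3")
  } else {
    gr$name <- genes$locus_id
    rtracklayer::export(gr, path, format = "BED")
  }
  invisible(path)
}

#' Read a specialized-metabolic-cluster table
#'
#' Reads a TSV with one row per cluster giving its name and first/last locus
#' identifiers (the locus-range convention of published cluster tables).
#' Member counts are computed as the inclusive locus-index span; extra
#' columns (e.g. a printed upregulated-gene count) are carried through.
#'
#' @param path Path to a tab-separated file with a header. Column names are
#'   matched case-insensitively to `name`/`cluster`, `first_locus`/`first_gene`,
#'   `last_locus`/`last_gene`.
#' @return Data frame with columns `name`, `first_locus`, `last_locus`,
#'   `first_idx`, `last_idx`, `n_span` plus any extra input columns.
#' @export
read_cluster_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lc <- tolower(names(tab))
  pick <- function(opts) {
    i <- which(lc %in% opts)[1L]
    if (is.na(i)) stop("cluster table lacks column: ", opts[1L], call. = FALSE)
    i
  }
  i_name <- pick(c("name", "cluster"))
  i_first <- pick(c("first_locus", "first_gene", "first"))
  i_last <- pick(c("last_locus", "last_gene", "last"))
  out <- data.frame(
    name = as.character(tab[[i_name]]),
    first_locus = as.character(tab[[i_first]]),
    last_locus = as.character(tab[[i_last]]),
    stringsAsFactors = FALSE
  )
  extra <- tab[, -c(i_name, i_first, i_last), drop = FALSE]
  if (ncol(extra)) out <- cbind(out, extra)
  validate_clusters(out)
}

#' Validate a cluster-definition data frame
#'
#' @param clusters Data frame with `name`, `first_locus`, `last_locus`.
#' @return The data frame with `first_idx`, `last_idx` and `n_span`
#'   (inclusive locus-index span) added.
#' @export
validate_clusters <- function(clusters) {
  fi <- locus_index(clusters$first_locus)
  li <- locus_index(clusters$last_locus)
  if (anyNA(fi) || anyNA(li)) {
    bad <- clusters$name[is.na(fi) | is.na(li)]
    stop(
      "cluster loci not of PREFIX_digits form: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  pf <- locus_prefix(clusters$first_locus)
  pl <- locus_prefix(clusters$last_locus)
  if (any(pf != pl)) {
    stop(
      "first/last locus prefixes differ for: ",
      paste(clusters$name[pf != pl], collapse = ", "),
      call. = FALSE
    )
  }
  if (any(fi > li)) {
    stop(
      "first locus index exceeds last for: ",
      paste(clusters$name[fi > li], collapse = ", "),
      call. = FALSE
    )
  }
  clusters$first_idx <- fi
  clusters$last_idx <- li
  clusters$n_span <- li - fi + 1L
  clusters
}

#' Cluster member loci
#'
#' Returns the locus identifiers belonging to one cluster, either as the
#' full inclusive locus-index span (`mode = "span"`, the convention of
#' first-gene/last-gene cluster tables) or restricted to loci present in a
#' supplied gene table (`mode = "explicit"`).
#'
#' @param cluster One row of a validated cluster table.
#' @param genes Optional gene-model data frame (required for
#'   `mode = "explicit"`).
#' @param mode `"span"` or `"explicit"`.
#' @return Character vector of locus identifiers.
#' @export
cluster_members <- function(cluster, genes = NULL, mode = c("span", "explicit")) {
  mode <- match.arg(mode)
  fi <- cluster$first_idx
  li <- cluster$last_idx
  prefix <- locus_prefix(cluster$first_locus)
  width <- nchar(sub("^.*_", "", cluster$first_locus))
  if (mode == "span") {
    sprintf(paste0(prefix, "_%0", width, "d"), fi:li)
  } else {
    if (is.null(genes)) stop("mode='explicit' requires a gene table", call. = FALSE)
    idx <- genes$locus_idx
    genes$locus_id[!is.na(idx) & idx >= fi & idx <= li]
  }
}

#' Genomic span of clusters over a gene table
#'
#' The hull interval covering all member genes of each cluster.
#'
#' @param clusters Validated cluster table.
#' @param genes Gene-model data frame.
#' @return `clusters` with `span_start`/`span_end` columns (`NA` when no
#'   member gene is present in `genes`).
#' @export
cluster_genomic_span <- function(clusters, genes) {
  idx <- genes$locus_idx
  clusters$span_start <- NA_integer_
  clusters$span_end <- NA_integer_
  for (i in seq_len(nrow(clusters))) {
    memb <- !is.na(idx) & idx >= clusters$first_idx[i] & idx <= clusters$last_idx[i]
    if (any(memb)) {
      clusters$span_start[i] <- min(genes$start[memb])
      clusters$span_end[i] <- max(genes$end[memb])
    }
  }
  clusters
}

#' Define a three-way chromosome partition (left arm, core, right arm)
#'
#' Linear *Streptomyces* chromosomes are conventionally divided into a
#' central core (enriched in essential genes) and two arms. Boundaries are
#' user-supplied; the partition must be contiguous, non-overlapping, ordered
#' and cover `[1, chrom_length]`.
#'
#' @param left_end Last coordinate of the left arm.
#' @param core_end Last coordinate of the core.
#' @param chrom_length Chromosome length.
#' @return Data frame with columns `region`, `start`, `end` and class
#'   `chrom_regions`.
#' @examples
#' partition_regions(100, 900, 1000)
#' @export
partition_regions <- function(left_end, core_end, chrom_length) {
  regions <- data.frame(
    region = c("left_arm", "core", "right_arm"),
    start = c(1L, as.integer(left_end) + 1L, as.integer(core_end) + 1L),
    end = c(as.integer(left_end), as.integer(core_end), as.integer(chrom_length)),
    stringsAsFactors = FALSE
  )
  validate_regions(regions, chrom_length)
}

#' Validate a chromosome-region partition
#'
#' @param regions Data frame with `region`, `start`, `end` rows in
#'   left-to-right order.
#' @param chrom_length Chromosome length the partition must cover.
#' @return `regions` with class `chrom_regions`.
#' @export
validate_regions <- function(regions, chrom_length) {
  if (nrow(regions) != 3L || !identical(regions$region, c("left_arm", "core", "right_arm"))) {
    stop("regions must be the three rows left_arm, core, right_arm", call. = FALSE)
  }
  if (any(regions$end < regions$start)) {
    stop("region with end < start", call. = FALSE)
  }
  if (regions$start[1L] != 1L || regions$end[3L] != as.integer(chrom_length)) {
    stop("regions must cover [1, chrom_length]", call. = FALSE)
  }
  if (any(regions$start[-1L] != regions$end[-3L] + 1L)) {
    stop("regions must be contiguous and non-overlapping", call. = FALSE)
  }
  class(regions) <- c("chrom_regions", "data.frame")
  regions
}
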