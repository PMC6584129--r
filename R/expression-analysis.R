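# Differential-expression filtering, RPKM, per-cluster summaries and the
# binomial cluster-enrichment test.

#' Reads per kilobase per million mapped reads
#'
#' @param read_count Mapped reads assigned to the gene.
#' @param gene_len_nt Gene length in nucleotides (> 0).
#' @param library_size Total mapped reads in the library (> 0).
#' @return RPKM value(s): `count / ((len/1e3) * (library_size/1e6))`.
#' @examples
#' rpkm(1000, 1000, 1e6) # 1000
#' rpkm(250, 500, 2e6) # 250
#' @export
rpkm <- function(read_count, gene_len_nt, library_size) {
  if (any(gene_len_nt <= 0)) stop("gene_len_nt must be > 0", call. = FALSE)
  if (any(library_size <= 0)) stop("library_size must be > 0", call. = FALSE)
  read_count / ((gene_len_nt / 1e3) * (library_size / 1e6))
}

#' Read a differential-expression table
#'
#' TSV with a header; requires a locus column and a q-value column, plus
#' either a fold-change column or wild-type/mutant expression columns.
#'
#' @param path Path to the TSV.
#' @return Data frame with normalised column names `locus_id`, `wt_expr`,
#'   `mut_expr`, `fold_change`, `q_value` (absent inputs become `NA`
#'   columns).
#' @export
read_de_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  lc <- tolower(names(tab))
  pick <- function(opts) {
    i <- which(lc %in% opts)[1L]
    if (is.na(i)) NULL else tab[[i]]
  }
  locus <- pick(c("locus_id", "locus", "gene", "gene_id"))
  q <- pick(c("q_value", "q", "qvalue"))
  if (is.null(locus) || is.null(q)) {
    stop("DE table needs locus and q_value columns", call. = FALSE)
  }
  wt <- pick(c("wt_expr", "wt_rpkm", "wt"))
  mut <- pick(c("mut_expr", "mut_rpkm", "mutant", "mut"))
  fc <- pick(c("fold_change", "fc"))
  n <- length(locus)
  data.frame(
    locus_id = as.character(locus),
    wt_expr = if (is.null(wt)) rep(NA_real_, n) else as.numeric(wt),
    mut_expr = if (is.null(mut)) rep(NA_real_, n) else as.numeric(mut),
    fold_change = if (is.null(fc)) rep(NA_real_, n) else as.numeric(fc),
    q_value = as.numeric(q),
    stringsAsFactors = FALSE
  )
}

#' Filter a DE table to significantly changed genes
#'
#' A gene is significant when `max(fc, 1/fc)` is strictly greater than
#' `fc_threshold` and its q-value is strictly below `q_threshold` (the
#' reference cut-off is "greater than four"-fold with q "less than 0.01", so
#' fc exactly 4 or q exactly 0.01 are excluded). Fold change is mutant over
#' wild type; when not supplied it is computed as
#' `(mut + pseudocount) / (wt + pseudocount)`, the pseudocount guarding
#' against division by zero for transcriptionally silent genes. Both
#' directions are retained and labelled.
#'
#' @param de DE data frame (see [read_de_table()]).
#' @param fc_threshold Exclusive fold-change threshold (default 4).
#' @param q_threshold Exclusive q-value threshold (default 0.01).
#' @param pseudocount Expression pseudocount used when computing fold change
#'   from `wt_expr`/`mut_expr` (default 1 RPKM).
#' @return The significant subset, with `fold_change` filled in and a
#'   `direction` column (`"up"` = higher in mutant, `"down"` = lower).
#'   Idempotent: re-filtering the output returns it unchanged.
#' @export
filter_de <- function(de, fc_threshold = 4, q_threshold = 0.01, pseudocount = 1) {
  fc <- de$fold_change
  if (is.null(fc)) fc <- rep(NA_real_, nrow(de))
  need_fc <- is.na(fc)
  if (any(need_fc)) {
    computable <- need_fc & !is.na(de$wt_expr) & !is.na(de$mut_expr)
    fc[computable] <- (de$mut_expr[computable] + pseudocount) /
      (de$wt_expr[computable] + pseudocount)
  }
  missing <- is.na(fc) | is.na(de$q_value)
  if (any(missing)) {
    warning(
      sum(missing), " record(s) lack both fold change and expression; skipped"
    )
  }
  effect <- pmax(fc, 1 / fc)
  keep <- !missing & effect > fc_threshold & de$q_value < q_threshold
  out <- de[keep, , drop = FALSE]
  out$fold_change <- fc[keep]
  out$direction <- ifelse(out$fold_change >= 1, "up", "down")
  rownames(out) <- NULL
  out
}

#' Per-cluster differential-expression summary
#'
#' Counts significantly up- and down-regulated genes among a cluster's
#' members and reports the percentage upregulated over the member count.
#' With `member_mode = "span"` the denominator is the inclusive locus-index
#' span (the first-gene/last-gene convention); with `"explicit"` it is the
#' number of member loci present in `genes`.
#'
#' @param cluster One row of a validated cluster table.
#' @param de_sig Significant DE subset (output of [filter_de()], with
#'   `locus_id` and `direction`).
#' @param member_mode `"span"` or `"explicit"`.
#' @param genes Gene table, required for `member_mode = "explicit"`.
#' @return One-row data frame: `name`, `n_members`, `n_up`, `n_down`,
#'   `pct_up` (percentage, rounded to 2 decimals).
#' @export
cluster_de_summary <- function(cluster, de_sig, member_mode = c("span", "explicit"),
                               genes = NULL) {
  member_mode <- match.arg(member_mode)
  members <- cluster_members(cluster, genes = genes, mode = member_mode)
  n_members <- length(members)
  if (n_members == 0L) stop("cluster has no members", call. = FALSE)
  midx <- locus_index(members)
  didx <- locus_index(de_sig$locus_id)
  same_prefix <- locus_prefix(de_sig$locus_id) == locus_prefix(members[1L])
  in_cluster <- !is.na(didx) & same_prefix &
    didx >= min(midx) & didx <= max(midx)
  if (member_mode == "explicit") {
    in_cluster <- in_cluster & de_sig$locus_id %in% members
  }
  n_up <- sum(in_cluster & de_sig$direction == "up")
  n_down <- sum(in_cluster & de_sig$direction == "down")
  data.frame(
    name = cluster$name,
    n_members = n_members,
    n_up = n_up,
    n_down = n_down,
    pct_up = round(100 * n_up / n_members, 2),
    stringsAsFactors = FALSE
  )
}

#' Summarise all clusters of a table
#'
#' @param clusters Validated cluster table.
#' @param de_sig Significant DE subset.
#' @inheritParams cluster_de_summary
#' @return Data frame with one [cluster_de_summary()] row per cluster.
#' @export
cluster_de_summary_all <- function(clusters, de_sig,
                                   member_mode = c("span", "explicit"),
                                   genes = NULL) {
  member_mode <- match.arg(member_mode)
  out <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
    cluster_de_summary(clusters[i, , drop = FALSE], de_sig, member_mode, genes)
  }))
  rownames(out) <- NULL
  out
}

#' Genome-wide null proportion of cluster genes
#'
#' The fraction of loci lying in any cluster's inclusive locus-index span,
#' with overlapping spans merged (unioned) so shared loci are counted once.
#' This is the null success probability for [enrichment_binomial()] when
#' cluster membership of differentially expressed genes is tested.
#'
#' @param clusters Validated cluster table.
#' @param total_loci Total number of loci on the chromosome.
#' @return Proportion in (0, 1); the union size is attached as attribute
#'   `"n_union"`.
#' @export
cluster_null_proportion <- function(clusters, total_loci) {
  spans <- IRanges::reduce(
    IRanges::IRanges(start = clusters$first_idx, end = clusters$last_idx)
  )
  n_union <- sum(IRanges::width(spans))
  structure(n_union / total_loci, n_union = n_union)
}

#' One-sided binomial enrichment test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`, computed
#' through the regularized incomplete beta function (numerically stable for
#' extreme tails). Used to test whether differentially expressed genes are
#' over-represented within specialized metabolic clusters.
#'
#' @param k Observed successes (e.g. DE genes inside clusters).
#' @param n Trials (e.g. total DE genes).
#' @param p0 Null success proportion, in (0, 1).
#' @return List of class `enrichment_result` with elements `k`, `n`, `p0`,
#'   `p_value`.
#' @examples
#' enrichment_binomial(2, 2, 0.5)$p_value # 0.25
#' @export
enrichment_binomial <- function(k, n, p0) {
  k <- as.integer(k)
  n <- as.integer(n)
  if (k < 0L || k > n) stop("need 0 <= k <= n", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)", call. = FALSE)
  p <- if (k == 0L) 1 else pbinom(k - 1L, n, p0, lower.tail = FALSE)
  structure(list(k = k, n = n, p0 = p0, p_value = p), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "binomial enrichment: %d / %d successes, null p0 = %.4g, one-sided p = %.4g\n",
    x$k, x$n, x$p0, x$p_value
  ))
  invisible(x)
}
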