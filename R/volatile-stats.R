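# Volatile-metabolome differential pipeline: transform/scale for display,
# rank-based testing with FDR control, and compound selection.

#' Read a compound-by-sample abundance matrix
#'
#' TSV whose first column holds compound identifiers and whose header row
#' holds sample identifiers; intensities are total-ion-chromatogram units.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix (compounds x samples) with dimnames.
#' @export
read_abundance_matrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  if (any(m < 0, na.rm = TRUE)) stop("negative intensities", call. = FALSE)
  m
}

#' Read a sample-to-group map
#'
#' Two-column TSV (`sample`, `group`); groups are typically `WT`, `mutant`
#' and `medium`.
#'
#' @param path Path to the TSV.
#' @return Named character vector of group labels, names = sample ids.
#' @export
read_sample_groups <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Transform and scale an abundance matrix for display
#'
#' Per compound (row): log10-transform, mean-center, and unit-scale across
#' samples. Unit scaling divides by the population (1/n) standard deviation
#' of the log values, so a row of log10 values `{1, 2, 3}` maps to
#' `{-1.2247, 0, 1.2247}`. Zero intensities are replaced by half the
#' smallest positive value of that compound before the log. Rows with fewer
#' than two finite values or zero variance after the log cannot be scaled;
#' they are dropped with a warning and listed in the `"excluded"` attribute.
#'
#' @param mat Compounds x samples matrix of non-negative intensities.
#' @return Row-standardised matrix (each kept row has mean 0, unit
#'   population sd), with attribute `"excluded"` naming dropped compounds.
#' @examples
#' m <- rbind(a = c(10, 100, 1000))
#' preprocess_abundance(m) # -1.2247, 0, 1.2247 on the log10 values 1,2,3
#' @export
preprocess_abundance <- function(mat) {
  if (any(mat < 0, na.rm = TRUE)) stop("negative intensities", call. = FALSE)
  lg <- t(apply(mat, 1L, function(x) {
    pos <- x[!is.na(x) & x > 0]
    if (length(pos)) x[!is.na(x) & x == 0] <- min(pos) / 2
    log10(x)
  }))
  dimnames(lg) <- dimnames(mat)
  sds <- apply(lg, 1L, function(x) sd(x[is.finite(x)]))
  n_fin <- rowSums(is.finite(lg))
  bad <- n_fin < 2L | !is.finite(sds) | sds == 0
  if (any(bad)) {
    warning(
      "excluded ", sum(bad), " compound(s) with <2 finite values or zero variance"
    )
  }
  kept <- lg[!bad, , drop = FALSE]
  out <- t(apply(kept, 1L, function(x) {
    fin <- is.finite(x)
    n <- sum(fin)
    mu <- mean(x[fin])
    s <- sqrt(sum((x[fin] - mu)^2) / n)
    (x - mu) / s
  }))
  dimnames(out) <- dimnames(kept)
  attr(out, "excluded") <- rownames(mat)[bad]
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. The exact null distribution
#' is used when the combined sample size is at most `exact_max` and there
#' are no ties; otherwise the normal approximation with continuity and tie
#' correction is used. The U statistic reported is that of `a`
#' (`U_a + U_b = n_a * n_b`).
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param exact_max Largest combined n for the exact branch (default 12).
#' @return List with `U`, `p_value` and `exact` (logical).
#' @examples
#' mwu_test(c(1, 2, 3), c(10, 11, 12))$p_value # 0.1 (2 / choose(6, 3))
#' @export
mwu_test <- function(a, b, exact_max = 12L) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && (length(a) + length(b)) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE, alternative = "two.sided")
  )
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = use_exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction: p-values are sorted ascending,
#' scaled by `m / rank`, made monotone from the largest rank down, capped at
#' one, and returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (always >= the raw values).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # 0.03 0.03 0.03
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Select differentially abundant compounds
#'
#' Runs a per-compound Mann-Whitney U test between two sample groups,
#' applies Benjamini-Hochberg correction, and selects compounds with
#' adjusted p strictly below `alpha`. Testing uses the raw intensities (the
#' test is rank-based, so the monotone log/center/scale display transform
#' cannot change its p-values); samples outside the two tested groups
#' (typically sterile-medium controls) are excluded from testing. Direction
#' compares group medians. Compounds with zero variance across the tested
#' samples are excluded from testing.
#'
#' @param mat Compounds x samples intensity matrix.
#' @param groups Group label per sample (named vector or vector aligned to
#'   columns).
#' @param group_a,group_b The two group labels to compare (defaults `"WT"`
#'   and `"mutant"`).
#' @param alpha Exclusive adjusted-significance threshold (default 0.05).
#' @return Data frame of selected compounds (`compound`, `U`, `p_value`,
#'   `p_adjusted`, `direction` = `"higher_in_a"`/`"higher_in_b"`); the full
#'   per-compound table is attached as attribute `"all"`.
#' @export
significant_compounds <- function(mat, groups, group_a = "WT", group_b = "mutant",
                                  alpha = 0.05) {
  if (!is.null(names(groups))) {
    groups <- groups[colnames(mat)]
  }
  if (length(groups) != ncol(mat)) {
    stop("groups must label every sample column", call. = FALSE)
  }
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("each tested group needs >= 2 samples", call. = FALSE)
  }
  sub <- mat[, c(ia, ib), drop = FALSE]
  testable <- apply(sub, 1L, function(x) sd(x) > 0)
  res <- do.call(rbind, lapply(which(testable), function(i) {
    t <- mwu_test(mat[i, ia], mat[i, ib])
    data.frame(
      compound = rownames(mat)[i],
      U = t$U,
      p_value = t$p_value,
      direction = if (median(mat[i, ia]) >= median(mat[i, ib])) {
        "higher_in_a"
      } else {
        "higher_in_b"
      },
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(res)) {
    res <- data.frame(
      compound = character(0), U = numeric(0), p_value = numeric(0),
      direction = character(0), stringsAsFactors = FALSE
    )
  }
  res$p_adjusted <- bh_adjust(res$p_value)
  res <- res[, c("compound", "U", "p_value", "p_adjusted", "direction")]
  rownames(res) <- NULL
  selected <- res[res$p_adjusted < alpha, , drop = FALSE]
  rownames(selected) <- NULL
  attr(selected, "all") <- res
  attr(selected, "untested") <- rownames(mat)[!testable]
  selected
}
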