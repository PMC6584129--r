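# -- internal sequence helpers ------------------------------------------------

#' Normalise a nucleotide sequence to an uppercase character vector of symbols
#'
#' Accepts a single character string, a character vector of single symbols, or
#' a [Biostrings::DNAString]. Case-folded; only A/C/G/T/N permitted.
#' @noRd
.as_nuc_vector <- function(seq) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "DNAStringSet")) {
    seq <- as.character(seq)
  }
  if (!is.character(seq)) {
    stop("sequence must be a character string or DNAString", call. = FALSE)
  }
  if (length(seq) == 1L) {
    x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  } else {
    x <- toupper(seq)
  }
  bad <- !(x %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    stop(
      "sequence contains symbols outside {A,C,G,T,N}: ",
      paste(unique(x[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  x
}

#' Scan parameters for AT-rich window and core detection
#'
#' Bundles the thresholds used to call a subsequence "AT-rich". The defaults
#' reproduce the reference definitions for Lsr2-bound DNA: an AT-rich segment
#' is a 20-nt window with strictly more than 50% A/T (i.e. at least 11 of 20),
#' and an AT-rich core is any 6 consecutive nucleotides of which at least 5
#' are A or T. `N` symbols count as neither A/T nor G/C (`n_policy` is fixed
#' at `"n_is_not_at"`): a window containing `N` can still qualify provided its
#' A/T count meets the threshold.
#'
#' @param window_len Window length in nucleotides (default 20).
#' @param window_min_at Minimum A/T count for a window to qualify
#'   (default 11, the strict majority of 20).
#' @param core_len Core length in nucleotides (default 6).
#' @param core_min_at Minimum A/T count for a core to qualify (default 5).
#' @return An object of class `scan_config`.
#' @examples
#' scan_config()
#' scan_config(window_len = 10, window_min_at = 6)
#' @export
scan_config <- function(window_len = 20L, window_min_at = 11L,
                        core_len = 6L, core_min_at = 5L) {
  window_len <- as.integer(window_len)
  window_min_at <- as.integer(window_min_at)
  core_len <- as.integer(core_len)
  core_min_at <- as.integer(core_min_at)
  if (core_min_at <= 0L || core_min_at > core_len || core_len > window_len) {
    stop("need 0 < core_min_at <= core_len <= window_len", call. = FALSE)
  }
  if (window_min_at > window_len || window_min_at <= 0L) {
    stop("need 0 < window_min_at <= window_len", call. = FALSE)
  }
  structure(
    list(
      window_len = window_len, window_min_at = window_min_at,
      core_len = core_len, core_min_at = core_min_at,
      n_policy = "n_is_not_at"
    ),
    class = "scan_config"
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat(
    sprintf(
      "scan_config: window >=%d A/T of %d nt; core >=%d A/T of %d nt (N is not A/T)\n",
      x$window_min_at, x$window_len, x$core_min_at, x$core_len
    )
  )
  invisible(x)
}

#' GC fraction of a nucleotide sequence
#'
#' Fraction of G+C among determinate (non-`N`) symbols. `N` symbols are
#' excluded from both numerator and denominator.
#'
#' @param seq Character string, character vector of symbols, or
#'   [Biostrings::DNAString].
#' @return Proportion in `[0, 1]`.
#' @examples
#' gc_content("GGCC") # 1
#' gc_content("ATGCN") # 0.5
#' @export
gc_content <- function(seq) {
  x <- .as_nuc_vector(seq)
  n_gc <- sum(x == "G" | x == "C")
  n_det <- sum(x != "N")
  if (n_det == 0L) {
    stop("gc_content undefined: sequence empty or all-N", call. = FALSE)
  }
  n_gc / n_det
}

# qualifying window start positions: sliding sum of the A/T indicator
.at_window_starts <- function(is_at, len, min_at) {
  n <- length(is_at)
  if (n < len) {
    return(integer(0))
  }
  cs <- c(0L, cumsum(as.integer(is_at)))
  sums <- cs[(len + 1L):(n + 1L)] - cs[1L:(n - len + 1L)]
  which(sums >= min_at)
}

# maximum set of pairwise non-overlapping fixed-length windows from a sorted
# vector of qualifying starts; earliest-end greedy (optimal for interval
# scheduling; with equal lengths, earliest end = earliest start)
.greedy_disjoint <- function(starts, len) {
  k <- 0L
  next_free <- -Inf
  for (s in starts) {
    if (s >= next_free) {
      k <- k + 1L
      next_free <- s + len
    }
  }
  k
}

.count_at_runs <- function(seq, len, min_at) {
  x <- .as_nuc_vector(seq)
  is_at <- x == "A" | x == "T"
  starts <- .at_window_starts(is_at, len, min_at)
  c(
    overlapping = length(starts),
    disjoint = .greedy_disjoint(starts, len)
  )
}

#' Count AT-rich windows in a sequence
#'
#' Slides a window of `cfg$window_len` nucleotides across the sequence and
#' counts start positions with at least `cfg$window_min_at` A/T symbols.
#' Two counts are returned: every qualifying start (`overlapping`), and the
#' size of a maximum set of pairwise non-overlapping qualifying windows
#' (`disjoint`), selected by the earliest-end greedy rule. Sequences shorter
#' than the window yield `(0, 0)`.
#'
#' @inheritParams gc_content
#' @param cfg A [scan_config()].
#' @return Named integer vector `c(overlapping =, disjoint =)`.
#' @examples
#' count_at_windows(strrep("A", 20)) # 1, 1
#' count_at_windows(paste0(strrep("A", 20), strrep("G", 20))) # 10, 1
#' @export
count_at_windows <- function(seq, cfg = scan_config()) {
  stopifnot(inherits(cfg, "scan_config"))
  .count_at_runs(seq, cfg$window_len, cfg$window_min_at)
}

#' Count AT-rich cores in a sequence
#'
#' As [count_at_windows()] but with the core parameters (`cfg$core_len`,
#' `cfg$core_min_at`): by default any 6 consecutive nucleotides of which at
#' least 5 are A/T.
#'
#' @inheritParams count_at_windows
#' @return Named integer vector `c(overlapping =, disjoint =)`.
#' @examples
#' count_at_cores("AAAAAGAAAAAG") # disjoint count 2
#' @export
count_at_cores <- function(seq, cfg = scan_config()) {
  stopifnot(inherits(cfg, "scan_config"))
  .count_at_runs(seq, cfg$core_len, cfg$core_min_at)
}

#' Composition profile of a sequence
#'
#' Aggregates [gc_content()], [count_at_windows()] and [count_at_cores()]
#' into a one-row data frame, the per-sequence record used when profiling
#' binding sites against a genome baseline.
#'
#' @inheritParams count_at_windows
#' @param id Optional sequence label.
#' @return One-row data frame with columns `id`, `length`, `gc_fraction`,
#'   `window_hits_overlapping`, `window_hits_disjoint`,
#'   `core_hits_overlapping`, `core_hits_disjoint`, `has_window`, `has_core`.
#' @examples
#' at_profile(strrep("A", 20))
#' @export
at_profile <- function(seq, cfg = scan_config(), id = NA_character_) {
  x <- .as_nuc_vector(seq)
  w <- count_at_windows(x, cfg)
  k <- count_at_cores(x, cfg)
  gc <- if (sum(x != "N") > 0L) gc_content(x) else NA_real_
  data.frame(
    id = id,
    length = length(x),
    gc_fraction = gc,
    window_hits_overlapping = unname(w["overlapping"]),
    window_hits_disjoint = unname(w["disjoint"]),
    core_hits_overlapping = unname(k["overlapping"]),
    core_hits_disjoint = unname(k["disjoint"]),
    has_window = unname(w["overlapping"]) >= 1L,
    has_core = unname(k["overlapping"]) >= 1L,
    stringsAsFactors = FALSE
  )
}

#' Profile every sequence of a FASTA file or DNAStringSet
#'
#' @param x Path to a FASTA file (multi-record, wrapped lines allowed) or a
#'   [Biostrings::DNAStringSet].
#' @inheritParams count_at_windows
#' @return Data frame with one [at_profile()] row per record.
#' @export
at_profile_set <- function(x, cfg = scan_config()) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (!methods::is(x, "DNAStringSet")) {
    stop("x must be a FASTA path or a DNAStringSet", call. = FALSE)
  }
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  out <- do.call(
    rbind,
    lapply(seq_along(x), function(i) {
      at_profile(as.character(x[[i]]), cfg, id = ids[i])
    })
  )
  rownames(out) <- NULL
  out
}

#' Sample random baseline segments from a chromosome
#'
#' Draws segments of stated lengths uniformly from the chromosome (any
#' coordinate eligible, without regard to annotation), reproducibly under a
#' seed. This is the genome-baseline procedure used to calibrate AT-window
#' and AT-core counts of binding sites: the reference design draws 15
#' segments of 500 bp and 15 of 1000 bp.
#'
#' @param chrom Chromosome sequence (character string or
#'   [Biostrings::DNAString]).
#' @param n_per_len Number of segments per length.
#' @param lengths Integer vector of segment lengths in nucleotides.
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `start`, `end`, `length`, `seq`
#'   (1-based inclusive source coordinates).
#' @examples
#' chrom <- strrep("ACGT", 2500)
#' segs <- sample_baseline_segments(chrom, 15, c(500, 1000), seed = 1)
#' table(segs$length)
#' @export
sample_baseline_segments <- function(chrom, n_per_len = 15L,
                                     lengths = c(500L, 1000L), seed = 1L) {
  x <- .as_nuc_vector(chrom)
  n <- length(x)
  lengths <- as.integer(lengths)
  if (any(lengths > n)) {
    stop("segment length exceeds chromosome length", call. = FALSE)
  }
  if (any(lengths <= 0L)) stop("segment lengths must be positive", call. = FALSE)
  n_per_len <- as.integer(n_per_len)
  if (n_per_len == 0L || length(lengths) == 0L) {
    return(data.frame(
      id = character(0), start = integer(0), end = integer(0),
      length = integer(0), seq = character(0), stringsAsFactors = FALSE
    ))
  }
  chrom_str <- paste(x, collapse = "")
  out <- local_seed(seed, {
    do.call(rbind, lapply(lengths, function(len) {
      starts <- sample.int(n - len + 1L, n_per_len, replace = TRUE)
      data.frame(
        id = sprintf("seg%d_%02d", len, seq_len(n_per_len)),
        start = starts,
        end = starts + len - 1L,
        length = len,
        seq = substring(chrom_str, starts, starts + len - 1L),
        stringsAsFactors = FALSE
      )
    }))
  })
  rownames(out) <- NULL
  out
}
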