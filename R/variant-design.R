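# GC-raising variant design for AT-rich binding sites. Emulates the probe
# engineering used to test AT-content dependence of nucleoid-associated
# protein binding: a wild-type site is raised to a target GC either by
# preferentially destroying its AT-rich cores (disrupt_cores) or by changing
# overall AT content while leaving every core intact (spare_cores).

#' Raise the GC content of a sequence
#'
#' Performs only A/T to G/C substitutions until the sequence's GC fraction
#' is as close as an integer count allows to `target_gc` (always within
#' plus/minus 0.5 percentage points, else an error is raised). Two modes:
#'
#' * `"disrupt_cores"` - substitutions preferentially target positions
#'   inside detected AT-rich cores (greedily, by the number of qualifying
#'   core windows covering the position; ties broken leftmost) until no core
#'   remains or the substitution budget is exhausted; any remaining budget
#'   is spent on randomly chosen A/T positions.
#' * `"spare_cores"` - substitutions are drawn only from A/T positions not
#'   covered by any qualifying core window, so every core survives.
#'
#' The replacement letter (G or C) is chosen by a seeded coin flip, and the
#' whole procedure is deterministic under `seed`. Lowering GC is not
#' supported.
#'
#' @param seq Input sequence (character string or [Biostrings::DNAString]);
#'   A/C/G/T only.
#' @param target_gc Target GC fraction, at least the current GC.
#' @param mode `"disrupt_cores"` or `"spare_cores"`.
#' @param protected Optional integer positions excluded from mutation, or a
#'   two-column matrix/data frame of `start`,`end` intervals.
#' @param seed Integer seed.
#' @param cfg [scan_config()] supplying the core definition.
#' @return List with elements `sequence` (the variant, as a string) and
#'   `report`: a list with the change table (`position`, `from`, `to`),
#'   `gc_before`, `gc_after`, `cores_before`, `cores_after`, `n_changes`.
#' @examples
#' v <- raise_gc(strrep("A", 100), 1, mode = "disrupt_cores", seed = 1)
#' v$report$cores_after # 0
#' @export
raise_gc <- function(seq, target_gc, mode = c("disrupt_cores", "spare_cores"),
                     protected = NULL, seed = 1L, cfg = scan_config()) {
  mode <- match.arg(mode)
  x <- .as_nuc_vector(seq)
  if (any(x == "N")) stop("variant design requires an N-free sequence", call. = FALSE)
  n <- length(x)
  prot <- rep(FALSE, n)
  if (!is.null(protected)) {
    if (is.matrix(protected) || is.data.frame(protected)) {
      for (i in seq_len(nrow(protected))) {
        prot[protected[i, 1L]:protected[i, 2L]] <- TRUE
      }
    } else {
      prot[as.integer(protected)] <- TRUE
    }
  }
  gc_before <- gc_content(x)
  cores_before <- unname(count_at_cores(x, cfg)["overlapping"])
  if (target_gc < gc_before - 1e-12) {
    stop("target_gc below current GC; lowering GC is not supported", call. = FALSE)
  }
  needed <- round(target_gc * n)
  if (abs(needed / n - target_gc) > 0.005) {
    stop(sprintf(
      "target GC %.4f not achievable within 0.5 points on a %d-mer", target_gc, n
    ), call. = FALSE)
  }
  budget <- as.integer(needed - sum(x == "G" | x == "C"))
  is_at <- function(v) v == "A" | v == "T"
  mutable <- is_at(x) & !prot
  if (budget > sum(mutable)) {
    stop(sprintf(
      "target requires %d substitutions but only %d unprotected A/T positions exist",
      budget, sum(mutable)
    ), call. = FALSE)
  }
  changed <- integer(0)
  x_new <- x
  local_seed(seed, {
    flips <- sample(c("G", "C"), max(budget, 1L), replace = TRUE)
    remaining <- budget
    if (mode == "disrupt_cores") {
      while (remaining > 0L) {
        at_now <- is_at(x_new)
        starts <- .at_window_starts(at_now, cfg$core_len, cfg$core_min_at)
        if (!length(starts)) break
        coverage <- tabulate(
          unlist(lapply(starts, function(s) s:(s + cfg$core_len - 1L))),
          nbins = n
        )
        cand <- which(coverage > 0L & at_now & !prot)
        if (!length(cand)) break
        pos <- cand[order(-coverage[cand], cand)][1L]
        x_new[pos] <- flips[budget - remaining + 1L]
        changed <- c(changed, pos)
        remaining <- remaining - 1L
      }
    } else {
      at_now <- is_at(x_new)
      starts <- .at_window_starts(at_now, cfg$core_len, cfg$core_min_at)
      covered <- rep(FALSE, n)
      if (length(starts)) {
        covered[unique(unlist(lapply(starts, function(s) s:(s + cfg$core_len - 1L))))] <- TRUE
      }
      eligible <- which(at_now & !prot & !covered)
      if (remaining > length(eligible)) {
        stop(sprintf(
          "spare_cores: target requires %d substitutions but only %d A/T positions lie outside cores",
          remaining, length(eligible)
        ), call. = FALSE)
      }
      if (remaining > 0L) {
        picks <- if (length(eligible) == 1L) eligible else sample(eligible, remaining)
        for (j in seq_len(remaining)) {
          x_new[picks[j]] <- flips[j]
        }
        changed <- picks
        remaining <- 0L
      }
    }
    # leftover budget in disrupt mode (all cores destroyed): any A/T position
    if (remaining > 0L) {
      eligible <- which(is_at(x_new) & !prot)
      picks <- if (length(eligible) == 1L) eligible else sample(eligible, remaining)
      for (j in seq_len(remaining)) {
        x_new[picks[j]] <- flips[budget - remaining + j]
      }
      changed <- c(changed, picks)
    }
  })
  report <- list(
    changes = data.frame(
      position = as.integer(changed),
      from = x[changed],
      to = x_new[changed],
      stringsAsFactors = FALSE
    ),
    gc_before = gc_before,
    gc_after = gc_content(x_new),
    cores_before = cores_before,
    cores_after = unname(count_at_cores(x_new, cfg)["overlapping"]),
    n_changes = length(changed)
  )
  list(sequence = paste(x_new, collapse = ""), report = report)
}

#' Write a variant change report as TSV
#'
#' @param variant Output of [raise_gc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_report <- function(variant, path) {
  write.table(
    variant$report$changes, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
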