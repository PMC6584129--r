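#' @keywords internal
#' @importFrom methods is
#' @importFrom stats median p.adjust pbinom runif rbinom sd setNames wilcox.test
#' @importFrom utils read.delim write.table
"_PACKAGE"

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state so
#' that seeded generators do not perturb the session's random stream.
#' @noRd
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Parse the numeric index from locus identifiers of the form PREFIX_digits
#'
#' @param locus_id Character vector, e.g. `"SVEN_0223"`.
#' @return Integer vector; `NA` where the identifier does not follow the
#'   `prefix_digits` form.
#' @examples
#' locus_index(c("SVEN_0223", "SVEN_7455", "oddball"))
#' @export
locus_index <- function(locus_id) {
  m <- regmatches(locus_id, regexpr("_([0-9]+)$", locus_id))
  idx <- rep(NA_integer_, length(locus_id))
  ok <- lengths(regmatches(locus_id, gregexpr("_[0-9]+$", locus_id))) > 0
  idx[ok] <- as.integer(sub("^_", "", m))
  idx
}

#' Locus prefix of identifiers of the form PREFIX_digits
#' @noRd
locus_prefix <- function(locus_id) {
  ifelse(grepl("_[0-9]+$", locus_id), sub("_[0-9]+$", "", locus_id), NA_character_)
}
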