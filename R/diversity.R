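#' Hill-number diversity of order q
#'
#' The diversity profile of a frequency vector over species equivalents
#' (OTUs or HMMs) is \eqn{D_q = (\sum_s f_s^q)^{1/(1-q)}}.  At `q = 0` this is
#' richness -- species equivalents are counted without regard to frequency,
#' the definition of alpha diversity used throughout the package; at `q = 1`
#' the analytic limit \eqn{\exp(-\sum f \ln f)} (exponential Shannon) is
#' used; larger `q` weights abundant species equivalents more.  Zero
#' frequencies contribute nothing at any order.
#'
#' @param freqs Nonnegative weights (raw counts or scores are accepted and
#'   normalized to frequencies internally).
#' @param q Diversity order, a single number `>= 0`.
#' @return A single number `>= 1`, or 0 for empty/all-zero input.
#' @export
#' @examples
#' hill_number(c(0.25, 0.25, 0.25, 0.25), q = 2)  # 4
#' hill_number(c(0.5, 0.3, 0.2, 0), q = 0)        # 3
hill_number <- function(freqs, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("q must be a single nonnegative number")
  if (length(freqs) == 0L) return(0)
  if (any(freqs < 0)) stop("frequencies must be nonnegative")
  f <- freqs[freqs > 0]
  if (length(f) == 0L) return(0)
  if (q == 0) return(length(f))
  p <- f / sum(f)
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Diversity profile over a grid of orders
#'
#' @param freqs Nonnegative weights, as in [hill_number()].
#' @param q_grid Ascending vector of diversity orders.
#' @return A data frame with columns `q` and `d` (`d` non-increasing in `q`).
#' @export
diversity_profile <- function(freqs, q_grid = seq(0, 3, by = 0.1)) {
  if (is.unsorted(q_grid)) stop("q_grid must be sorted ascending")
  d <- vapply(q_grid, function(q) hill_number(freqs, q), numeric(1))
  data.frame(q = q_grid, d = d)
}

#' Rarefy a count vector to a fixed depth
#'
#' Subsamples reads (or any counted units) without replacement to a common
#' depth, i.e. a multivariate hypergeometric draw.  The output total equals
#' `depth` exactly and no category exceeds its input count.  Deterministic
#' under `seed`.
#'
#' @param raw_counts Named or unnamed nonnegative integer vector.
#' @param depth Number of units to keep; at most `sum(raw_counts)`.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return Integer vector of the same length and names as `raw_counts`.
#' @export
rarefy_counts <- function(raw_counts, depth, seed = NULL) {
  if (any(raw_counts < 0)) stop("counts must be nonnegative")
  total <- sum(raw_counts)
  if (depth > total)
    stop("depth (", depth, ") exceeds total count (", total, ")")
  if (!is.null(seed)) set.seed(seed)
  out <- integer(length(raw_counts))
  remaining_total <- total
  remaining_depth <- as.integer(depth)
  for (i in seq_along(raw_counts)) {
    if (remaining_depth == 0L) break
    m <- raw_counts[[i]]
    # draw category i against the pool of everything after it
    x <- rhyper(1L, m, remaining_total - m, remaining_depth)
    out[i] <- x
    remaining_total <- remaining_total - m
    remaining_depth <- remaining_depth - x
  }
  names(out) <- names(raw_counts)
  out
}

#' Rarefaction (saturation) curve of distinct features
#'
#' Mean number of distinct nonzero features observed when the counts are
#' rarefied to each depth, averaged over `reps` independent subsamples --
#' the standard saturation diagnostic for sequencing depth.
#'
#' @param raw_counts Nonnegative integer vector.
#' @param depths Ascending vector of depths; depths at or above the total
#'   return the exact richness.
#' @param reps Number of random subsamples averaged per depth (default 10).
#' @param seed Integer RNG seed.
#' @return A data frame with columns `depth` and `mean_features`.
#' @export
rarefaction_curve <- function(raw_counts, depths, reps = 10L, seed = 1L) {
  if (is.unsorted(depths)) stop("depths must be ascending")
  if (reps < 1L) stop("reps must be >= 1")
  total <- sum(raw_counts)
  set.seed(seed)
  mean_features <- vapply(depths, function(d) {
    if (d >= total) return(sum(raw_counts > 0))
    mean(vapply(seq_len(reps), function(r) {
      sum(rarefy_counts(raw_counts, d, seed = NULL) > 0L)
    }, numeric(1)))
  }, numeric(1))
  data.frame(depth = depths, mean_features = mean_features)
}

#' Percent change between two values
#'
#' `100 * (after - before) / before`, reported to one decimal place -- the
#' arithmetic behind statements like an alpha-diversity "10.9% increase".
#'
#' @param before Baseline value, must be positive.
#' @param after New value.
#' @return Percent change rounded to one decimal.
#' @export
#' @examples
#' percent_change(226.3, 251.0)  # 10.9
percent_change <- function(before, after) {
  if (any(before <= 0)) stop("'before' must be positive")
  round(100 * (after - before) / before, 1)
}
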