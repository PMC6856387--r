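#' Per-HMM DFPMAA_250 scores
#'
#' For each HMM, the score is the sum of HMM-coverage fractions of its
#' accepted hits, normalized per million amino acids of predicted protein:
#' \deqn{\mathrm{DFPMAA}_{250}(h) = 10^6 \times
#'   \frac{\sum_{i \in \mathrm{hits}(h)} \mathrm{cov}(i)}{\mathrm{total\_aa}}}
#' The subscript 250 records the reference read length (in nucleotides) at
#' which the score is calibrated; the ratio itself is read-length-neutral
#' once alignments clear the 0.3-coverage acceptance threshold, so no
#' additional length divisor is applied by default (see
#' `rescale_to_reference` for the opt-in alternative).
#'
#' @param accepted_hits Domain-hit data frame that already passed
#'   [apply_dbcan_filter()].
#' @param total_aa Total residues of all protein fragments submitted to
#'   scanning (see [total_amino_acids()]); must be positive.
#' @param mean_read_len_nt Mean merged-read length in nucleotides (metadata;
#'   required if `rescale_to_reference = TRUE`).
#' @param rescale_to_reference If `TRUE`, multiply every score by
#'   `reference_len_nt / mean_read_len_nt`, making the normalizer an explicit
#'   per-250-nt rescale rather than a calibration annotation.  Default
#'   `FALSE`.
#' @param reference_len_nt Reference read length, 250 nt.
#' @return Named numeric vector mapping HMM name to score.  HMMs without
#'   accepted hits are absent (treated as 0 downstream).
#' @seealso [score_table()], [sum_dfpmaa()]
#' @export
dfpmaa_per_hmm <- function(accepted_hits, total_aa,
                           mean_read_len_nt = NA_real_,
                           rescale_to_reference = FALSE,
                           reference_len_nt = 250) {
  if (!is.numeric(total_aa) || length(total_aa) != 1L || total_aa <= 0)
    stop("total_aa must be a single positive number")
  if (nrow(accepted_hits) == 0L) return(stats::setNames(numeric(0), character(0)))
  cov <- coverage_fraction(accepted_hits)
  sums <- tapply(cov, accepted_hits$hmm_name, sum)
  scores <- 1e6 * as.numeric(sums) / total_aa
  names(scores) <- names(sums)
  if (rescale_to_reference) {
    if (!is.finite(mean_read_len_nt) || mean_read_len_nt <= 0)
      stop("rescale_to_reference requires a positive mean_read_len_nt")
    scores <- scores * reference_len_nt / mean_read_len_nt
  }
  scores[order(names(scores))]
}

#' Per-sample score table
#'
#' Container for one sample's DFPMAA_250 scores plus the normalization
#' metadata (amino-acid denominator, read-length and read-count bookkeeping)
#' needed to audit and compare runs.
#'
#' @param scores Named numeric vector of nonnegative per-HMM scores.
#' @param sample_id Sample identifier.
#' @param total_aa Amino-acid denominator used for normalization.
#' @param mean_read_len_nt Mean merged-read length (nt).
#' @param n_reads Number of merged reads scanned.
#' @return An object of class `dfpmaa_score_table`.
#' @export
score_table <- function(scores, sample_id = "sample", total_aa = NA_integer_,
                        mean_read_len_nt = NA_real_, n_reads = NA_integer_) {
  scores <- unlist(scores)
  if (length(scores) == 0L) scores <- stats::setNames(numeric(0), character(0))
  if (any(scores < 0)) stop("scores must be nonnegative")
  if (any(scores > 0) && (!is.finite(total_aa) || total_aa <= 0))
    stop("total_aa must be positive when any score is positive")
  structure(
    list(sample_id = sample_id, scores = scores,
         total_aa = total_aa, mean_read_len_nt = mean_read_len_nt,
         n_reads = n_reads),
    class = "dfpmaa_score_table"
  )
}

#' @export
print.dfpmaa_score_table <- function(x, ...) {
  cat(sprintf("DFPMAA_250 score table: sample '%s'\n", x$sample_id))
  cat(sprintf("  %d scored HMMs, sum DFPMAA_250 = %.4f\n",
              length(x$scores), sum(x$scores)))
  cat(sprintf("  total_aa = %s, mean read length = %s nt, n_reads = %s\n",
              format(x$total_aa), format(x$mean_read_len_nt),
              format(x$n_reads)))
  invisible(x)
}

#' Integrated score over all HMMs
#'
#' The sample-level readout of overall carbohydrate-processing capability:
#' the sum of DFPMAA_250 over all HMMs.
#'
#' @param table A `dfpmaa_score_table` or a named numeric score vector.
#' @return A single number.
#' @export
sum_dfpmaa <- function(table) {
  scores <- if (inherits(table, "dfpmaa_score_table")) table$scores else table
  if (length(scores) == 0L) return(0)
  sum(scores)
}

#' CAZy class of an HMM name
#'
#' Classifies by the maximal leading alphabetic prefix of the name: `GH`
#' (glycoside hydrolases), `GT` (glycosyltransferases), `PL` (polysaccharide
#' lyases), `CE` (carbohydrate esterases), `CBM` (carbohydrate-binding
#' modules), `AA` (auxiliary activities); any other prefix (dockerin,
#' cohesin, SLH, ...) is `OTHER`.  Numeric/subfamily suffixes (`13`, `_2`,
#' `.hmm`) are ignored.
#'
#' @param hmm_name Character vector of HMM names.
#' @return Character vector over
#'   `c("AA","CBM","CE","GH","GT","PL","OTHER")`.
#' @export
#' @examples
#' cazy_class_of(c("GH13_2", "CBM50", "dockerin"))
cazy_class_of <- function(hmm_name) {
  if (length(hmm_name) == 0L) return(character(0))
  if (any(!nzchar(hmm_name))) stop("HMM names must be nonempty")
  prefix <- sub("^([A-Za-z]+).*$", "\\1", hmm_name)
  known <- c("AA", "CBM", "CE", "GH", "GT", "PL")
  ifelse(toupper(prefix) %in% known, toupper(prefix), "OTHER")
}

#' Proportion of the integrated score by CAZy class
#'
#' @param table A `dfpmaa_score_table` or named numeric score vector with a
#'   positive sum.
#' @return Named numeric vector of proportions (summing to 1) over the
#'   classes present.
#' @export
class_proportions <- function(table) {
  scores <- if (inherits(table, "dfpmaa_score_table")) table$scores else table
  total <- sum(scores)
  if (length(scores) == 0L || total <= 0)
    stop("class proportions undefined for an all-zero score table")
  cls <- cazy_class_of(names(scores))
  p <- tapply(scores, cls, sum) / total
  out <- as.numeric(p)
  names(out) <- names(p)
  out
}

#' Randomly trim reads to a target mean length
#'
#' Emulates shorter sequencing chemistry from full-length merged reads: each
#' read longer than the target loses `length - target` nucleotides, split
#' uniformly at random between its 5' and 3' ends.  Deterministic under
#' `seed`.
#'
#' @param reads Data frame with columns `id` and `seq`.
#' @param target_mean_len_nt Target mean read length; must not exceed the
#'   current mean.
#' @param seed Integer RNG seed.
#' @return The trimmed reads (same columns, same order).
#' @export
trim_reads <- function(reads, target_mean_len_nt, seed = 1L) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  lens <- nchar(reads$seq)
  if (nrow(reads) == 0L) return(reads)
  if (target_mean_len_nt > mean(lens))
    stop("target mean length (", target_mean_len_nt,
         ") exceeds current mean (", round(mean(lens), 2), ")")
  set.seed(seed)
  trim_total <- pmax(0L, as.integer(round(lens - target_mean_len_nt)))
  trim5 <- as.integer(floor(runif(length(lens)) * (trim_total + 1L)))
  trim3 <- trim_total - trim5
  out <- reads
  out$seq <- substr(reads$seq, trim5 + 1L, lens - trim3)
  out
}

#' Read-length comparability gate
#'
#' Below a mean merged-read length of about 187.6 bp the 0.3-coverage
#' acceptance criterion starts discarding genuine domain alignments, which
#' artificially depresses DFPMAA_250.  Samples are flagged comparable only
#' when their mean read length reaches that threshold; scores remain
#' computable either way.
#'
#' @param mean_read_len_nt Mean merged-read length(s) in nucleotides.
#' @param threshold_nt The comparability threshold (default 187.6).
#' @return Logical: `TRUE` when the mean length reaches the threshold
#'   (boundary inclusive).
#' @export
length_gate <- function(mean_read_len_nt, threshold_nt = 187.6) {
  if (any(mean_read_len_nt <= 0)) stop("mean read length must be positive")
  mean_read_len_nt >= threshold_nt
}
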