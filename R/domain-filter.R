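#' dbCAN-style acceptance thresholds for per-domain hits
#'
#' Bundles the acceptance criteria of the dbCAN hmmscan parser: a two-tier
#' independent-E-value cutoff (stricter for alignments longer than `long_aa`
#' residues), a same-sequence overlap-resolution rule, and the minimum
#' HMM-coverage fraction of 0.3.  The tier constants (1e-5 above 80 aa, else
#' 1e-3) and the >50%-of-shorter-alignment overlap rule are the parser's
#' published defaults; all are exposed here so none is hard-wired.
#'
#' @param evalue_long i-Evalue cutoff for alignments longer than `long_aa`
#'   residues (default `1e-5`).
#' @param evalue_short i-Evalue cutoff for alignments of at most `long_aa`
#'   residues (default `1e-3`).
#' @param long_aa Alignment-length boundary between the two tiers, in
#'   residues (default 80).
#' @param min_cov Minimum fraction of the HMM's match states that the
#'   alignment must span (default 0.3).
#' @param overlap_frac Two same-sequence hits conflict when their overlap
#'   exceeds this fraction of the shorter alignment (default 0.5).
#' @return A list of class `dbcan_filter_config`.
#' @export
filter_config <- function(evalue_long = 1e-5, evalue_short = 1e-3,
                          long_aa = 80L, min_cov = 0.3, overlap_frac = 0.5) {
  if (!(min_cov > 0 && min_cov <= 1)) stop("min_cov must be in (0, 1]")
  if (!(overlap_frac > 0 && overlap_frac <= 1))
    stop("overlap_frac must be in (0, 1]")
  if (evalue_long <= 0 || evalue_short <= 0)
    stop("E-value thresholds must be > 0")
  if (long_aa < 1) stop("long_aa must be >= 1")
  structure(
    list(evalue_long = evalue_long, evalue_short = evalue_short,
         long_aa = as.integer(long_aa), min_cov = min_cov,
         overlap_frac = overlap_frac),
    class = "dbcan_filter_config"
  )
}

#' Fraction of an HMM covered by a hit
#'
#' The "domain fraction" of a hit: the proportion of the HMM's match states
#' spanned by the alignment, `(hmm_to - hmm_from + 1) / hmm_len`.  Coordinates
#' are 1-based inclusive, hence the `+ 1`.
#'
#' @param hits Domain-hit data frame (see [read_domtblout()]).
#' @return Numeric vector in `(0, 1]`, one value per hit.
#' @export
#' @examples
#' h <- data.frame(seq_id = "r", seq_len = 100L, hmm_name = "GH13",
#'                 hmm_len = 100L, full_evalue = 1e-9, i_evalue = 1e-9,
#'                 bit_score = 50, hmm_from = 10L, hmm_to = 39L,
#'                 ali_from = 1L, ali_to = 30L)
#' coverage_fraction(h)  # 0.30
coverage_fraction <- function(hits) {
  if (nrow(hits) == 0L) return(numeric(0))
  if (any(hits$hmm_len <= 0)) stop("hmm_len must be > 0")
  (hits$hmm_to - hits$hmm_from + 1) / hits$hmm_len
}

#' Two-tier i-Evalue test
#'
#' A hit passes when its alignment is longer than `cfg$long_aa` residues and
#' its i-Evalue is below `cfg$evalue_long`, or its alignment is at most
#' `cfg$long_aa` residues and its i-Evalue is below `cfg$evalue_short`.  The
#' per-domain (independent) E-value is the filtering statistic, not the
#' full-sequence E-value, because per-domain decisions need the per-domain
#' statistic.
#'
#' @param hits Domain-hit data frame.
#' @param cfg A [filter_config()].
#' @return Logical vector, one value per hit.
#' @export
passes_evalue <- function(hits, cfg = filter_config()) {
  if (nrow(hits) == 0L) return(logical(0))
  ali_len <- hits$ali_to - hits$ali_from + 1
  ifelse(ali_len > cfg$long_aa,
         hits$i_evalue < cfg$evalue_long,
         hits$i_evalue < cfg$evalue_short)
}

#' Resolve overlapping hits on one sequence
#'
#' Greedy elimination in the style of the dbCAN parser: hits on the same
#' sequence are considered in order of ascending i-Evalue (ties broken by
#' higher bit score, then smaller `ali_from`); a hit is kept only if its
#' sequence-coordinate overlap with every already-kept hit is at most
#' `cfg$overlap_frac` times the shorter of the two alignment lengths.  The
#' kept set is therefore pairwise non-conflicting.
#'
#' @param hits Domain-hit data frame, all rows sharing one `seq_id`.
#' @param cfg A [filter_config()].
#' @return The kept hits, sorted by `ali_from`.
#' @export
resolve_overlaps <- function(hits, cfg = filter_config()) {
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$seq_id)) > 1L)
    stop("resolve_overlaps expects hits on a single sequence; got ",
         length(unique(hits$seq_id)), " seq_ids")
  if (nrow(hits) == 1L) return(hits)
  ord <- order(hits$i_evalue, -hits$bit_score, hits$ali_from)
  h <- hits[ord, , drop = FALSE]
  len <- h$ali_to - h$ali_from + 1
  kept <- integer(0)
  for (i in seq_len(nrow(h))) {
    conflict <- FALSE
    for (j in kept) {
      ov <- min(h$ali_to[i], h$ali_to[j]) - max(h$ali_from[i], h$ali_from[j]) + 1
      if (ov > cfg$overlap_frac * min(len[i], len[j])) { conflict <- TRUE; break }
    }
    if (!conflict) kept <- c(kept, i)
  }
  out <- h[kept, , drop = FALSE]
  out[order(out$ali_from), , drop = FALSE]
}

#' Apply the full dbCAN-style filter
#'
#' Composition of the three acceptance rules, in the dbCAN parser's pass
#' order: per-sequence overlap resolution first, then the two-tier i-Evalue
#' test, then the minimum HMM-coverage fraction (`cfg$min_cov`, default 0.3).
#' Output order is stable by `(seq_id, ali_from)`.
#'
#' @param hits Domain-hit data frame (any mix of sequences).
#' @param cfg A [filter_config()].
#' @return The accepted hits.
#' @export
apply_dbcan_filter <- function(hits, cfg = filter_config()) {
  if (nrow(hits) == 0L) return(hits)
  validate_domain_hits(hits)
  counts <- table(hits$seq_id)
  multi <- names(counts)[counts > 1L]
  if (length(multi)) {
    is_multi <- hits$seq_id %in% multi
    resolved <- lapply(split(hits[is_multi, , drop = FALSE],
                             hits$seq_id[is_multi]),
                       resolve_overlaps, cfg = cfg)
    hits <- rbind(hits[!is_multi, , drop = FALSE], do.call(rbind, resolved))
  }
  keep <- passes_evalue(hits, cfg) & coverage_fraction(hits) >= cfg$min_cov
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$seq_id, out$ali_from), , drop = FALSE]
  rownames(out) <- NULL
  out
}
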