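#' End-to-end synthetic scoring pipeline
#'
#' Convenience composition of the full desk-scale pipeline on simulated
#' merged reads: six-frame fragment prediction ([six_frame_fragments()]),
#' naive domain scanning against a toy registry ([naive_domain_scan()]),
#' dbCAN-style filtering ([apply_dbcan_filter()]), and DFPMAA_250 scoring
#' ([dfpmaa_per_hmm()]).  On real data the first two stages are replaced by
#' FragGeneScan and `hmmsearch` (run externally; see [read_domtblout()]), and
#' human-read depletion, where applicable, happens upstream of this function.
#'
#' @param reads Data frame with columns `id` and `seq`.
#' @param registry Registry from [make_registry()].
#' @param cfg A [filter_config()].
#' @param min_aa Minimum fragment length for [six_frame_fragments()].
#' @param min_overlap_aa Minimum scan window for [naive_domain_scan()].
#' @param sample_id Sample identifier for the resulting table.
#' @param details If `TRUE`, also return the intermediate fragments and hit
#'   tables.
#' @return A [score_table()]; with `details = TRUE`, a list with elements
#'   `table`, `fragments`, `hits_raw`, `hits_accepted`.
#' @export
dfpmaa_pipeline <- function(reads, registry, cfg = filter_config(),
                            min_aa = 20L, min_overlap_aa = 10L,
                            sample_id = "sample", details = FALSE) {
  frags <- six_frame_fragments(reads, min_aa = min_aa)
  total_aa <- total_amino_acids(frags)
  hits <- naive_domain_scan(frags, registry, min_overlap_aa = min_overlap_aa)
  accepted <- apply_dbcan_filter(hits, cfg)
  scores <- if (total_aa > 0) dfpmaa_per_hmm(accepted, total_aa)
            else stats::setNames(numeric(0), character(0))
  tab <- score_table(
    scores, sample_id = sample_id, total_aa = total_aa,
    mean_read_len_nt = if (nrow(reads)) mean(nchar(reads$seq)) else NA_real_,
    n_reads = nrow(reads)
  )
  if (!details) return(tab)
  list(table = tab, fragments = frags, hits_raw = hits,
       hits_accepted = accepted)
}
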