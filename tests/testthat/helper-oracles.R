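# Independent oracles used across the suite.  These deliberately re-derive
# results by direct enumeration or via an unrelated implementation, so they
# share no code path with the package functions they check.

# Elimination-style re-statement of the dbCAN acceptance rules: repeatedly
# take the globally best remaining hit per sequence (smallest i-Evalue, then
# highest bit score, then smallest ali_from), discard everything conflicting
# with it, then apply the E-value tier and coverage tests hit by hit.
oracle_dbcan_filter <- function(hits, cfg) {
  keep_rows <- integer(0)
  for (sid in unique(hits$seq_id)) {
    rows <- which(hits$seq_id == sid)
    remaining <- rows
    while (length(remaining)) {
      h <- hits[remaining, , drop = FALSE]
      best <- remaining[order(h$i_evalue, -h$bit_score, h$ali_from)[1L]]
      keep_rows <- c(keep_rows, best)
      remaining <- setdiff(remaining, best)
      if (length(remaining)) {
        conflict <- vapply(remaining, function(r) {
          ov <- min(hits$ali_to[best], hits$ali_to[r]) -
            max(hits$ali_from[best], hits$ali_from[r]) + 1
          shorter <- min(hits$ali_to[best] - hits$ali_from[best] + 1,
                         hits$ali_to[r] - hits$ali_from[r] + 1)
          ov > cfg$overlap_frac * shorter
        }, logical(1))
        remaining <- remaining[!conflict]
      }
    }
  }
  kept <- hits[sort(keep_rows), , drop = FALSE]
  ali_len <- kept$ali_to - kept$ali_from + 1
  ev_ok <- ifelse(ali_len > cfg$long_aa,
                  kept$i_evalue < cfg$evalue_long,
                  kept$i_evalue < cfg$evalue_short)
  cov_ok <- (kept$hmm_to - kept$hmm_from + 1) / kept$hmm_len >= cfg$min_cov
  out <- kept[ev_ok & cov_ok, , drop = FALSE]
  out <- out[order(out$seq_id, out$ali_from), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random but valid domain-hit tables for property tests.
random_hits <- function(n, n_seqs = 3L, n_hmms = 4L) {
  rand_between <- function(lo, hi) lo + vapply(
    hi - lo + 1L, function(w) sample.int(w, 1L), integer(1)) - 1L
  hmm_len <- sample(50:200, n, replace = TRUE)
  hmm_from <- rand_between(rep(1L, n), hmm_len)
  hmm_to <- rand_between(hmm_from, hmm_len)
  seq_len <- sample(80:250, n, replace = TRUE)
  ali_from <- rand_between(rep(1L, n), seq_len)
  ali_to <- rand_between(ali_from, seq_len)
  data.frame(
    seq_id = paste0("s", sample.int(n_seqs, n, replace = TRUE)),
    seq_len = as.integer(seq_len),
    hmm_name = paste0("GH", sample.int(n_hmms, n, replace = TRUE)),
    hmm_len = as.integer(hmm_len),
    full_evalue = 10^runif(n, -30, -1),
    i_evalue = 10^runif(n, -30, -1),
    bit_score = round(runif(n, 10, 300), 1),
    hmm_from = as.integer(hmm_from), hmm_to = as.integer(hmm_to),
    ali_from = as.integer(ali_from), ali_to = as.integer(ali_to),
    description = "",
    stringsAsFactors = FALSE
  )
}

# Brute-force six-frame translation via seqinr (independent codon handling).
oracle_six_frame_aa <- function(nt, min_aa) {
  stopifnot(requireNamespace("seqinr", quietly = TRUE))
  revcomp <- function(s) paste(rev(chartr("ACGT", "TGCA",
                                          strsplit(s, "")[[1]])), collapse = "")
  out <- character(0)
  for (s in c(nt, revcomp(nt))) {
    chars <- strsplit(s, "")[[1]]
    for (off in 0:2) {
      usable <- length(chars) - off
      n_codon <- usable %/% 3
      if (n_codon < 1) next
      aa <- seqinr::translate(chars[(off + 1):(off + 3 * n_codon)],
                              numcode = 11, ambiguous = FALSE)
      aa[aa == "X" | is.na(aa)] <- "X"
      pieces <- strsplit(paste(aa, collapse = ""), "*", fixed = TRUE)[[1]]
      out <- c(out, pieces[nchar(pieces) >= min_aa])
    }
  }
  sort(out)
}

hit_row <- function(seq_id = "s1", seq_len = 200L, hmm_name = "GH1",
                    hmm_len = 100L, i_evalue = 1e-10, bit_score = 50,
                    hmm_from = 1L, hmm_to = 50L, ali_from = 1L,
                    ali_to = 50L) {
  data.frame(seq_id = seq_id, seq_len = seq_len, hmm_name = hmm_name,
             hmm_len = hmm_len, full_evalue = i_evalue, i_evalue = i_evalue,
             bit_score = bit_score, hmm_from = hmm_from, hmm_to = hmm_to,
             ali_from = ali_from, ali_to = ali_to, description = "",
             stringsAsFactors = FALSE)
}

empty_hits_df <- function() hit_row()[0L, ]

# Small helper: a registry/genome/reads trio shared by pipeline tests.
toy_pipeline_inputs <- function(seed = 1L, n_hmms = 6L,
                                len_range = c(40L, 90L),
                                n_segments = 2L, spacer_len = 250L,
                                n_reads = 1500L, read_len = 250L) {
  registry <- make_registry(n_hmms, c(GH = 0.5, CBM = 0.3, GT = 0.2),
                            seed = seed, len_range = len_range)
  genome <- make_toy_genome(registry, n_segments_per_hmm = n_segments,
                            spacer_len = spacer_len, seed = seed + 100L)
  reads <- simulate_reads(genome, n_reads, read_len, seed = seed + 200L)
  list(registry = registry, genome = genome, reads = reads)
}
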