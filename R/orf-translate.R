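#' Six-frame translation into stop-free protein fragments
#'
#' A deliberately simple gene-fragment predictor for synthetic pipelines: each
#' read is translated in all six frames with the bacterial genetic code
#' (translation table 11), split at stop codons, and the maximal stop-free
#' fragments of at least `min_aa` residues are kept.  Fragments are not
#' required to start with methionine, because shotgun reads are random genome
#' fragments.  Codons containing `N` translate to `X`.  This is a declared
#' naive stand-in for a real fragment-aware gene caller such as FragGeneScan,
#' adequate for error-free simulated reads.
#'
#' @param reads Data frame with columns `id` and `seq` (nucleotides over
#'   `A,C,G,T,N`), e.g. from [read_fasta()] or [simulate_reads()].
#' @param min_aa Minimum fragment length in residues (default 20, well below
#'   the smallest scorable domain overlap).
#' @return A data frame of protein fragments with columns `frag_id`
#'   (`readid_frame_start`), `read_id`, `frame` (+1,+2,+3,-1,-2,-3), `aa_seq`,
#'   and `nt_start`/`nt_end` (0-based half-open on the read's forward strand;
#'   `nt_end - nt_start == 3 * nchar(aa_seq)`).
#' @seealso [total_amino_acids()], [naive_domain_scan()]
#' @export
#' @examples
#' six_frame_fragments(data.frame(id = "r1", seq = "ATGAAATAA"), min_aa = 2)
six_frame_fragments <- function(reads, min_aa = 20L) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)),
            min_aa >= 1L)
  if (nrow(reads) == 0L) return(empty_fragments())
  if (any(grepl("[^ACGTNacgtn]", reads$seq)))
    stop("reads must be over the alphabet {A,C,G,T,N}")

  fwd <- Biostrings::DNAStringSet(toupper(reads$seq))
  rev <- Biostrings::reverseComplement(fwd)
  widths <- Biostrings::width(fwd)
  code <- Biostrings::getGeneticCode("11")

  out <- vector("list", 6L)
  k <- 0L
  for (strand in c(1L, -1L)) {
    seqs <- if (strand == 1L) fwd else rev
    for (off in 0:2) {
      k <- k + 1L
      n_codon <- pmax((widths - off) %/% 3L, 0L)
      translatable <- which(n_codon >= 1L)
      if (length(translatable) == 0L) next
      sub <- Biostrings::subseq(seqs[translatable],
                                start = off + 1L,
                                width = 3L * n_codon[translatable])
      aa <- as.character(Biostrings::translate(sub, genetic.code = code,
                                               no.init.codon = TRUE,
                                               if.fuzzy.codon = "X"))
      out[[k]] <- split_stop_free(aa, reads$id[translatable],
                                  widths[translatable],
                                  frame = strand * (off + 1L),
                                  min_aa = min_aa)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L) return(empty_fragments())
  rownames(res) <- NULL
  res
}

empty_fragments <- function() {
  data.frame(frag_id = character(0), read_id = character(0),
             frame = integer(0), aa_seq = character(0),
             nt_start = integer(0), nt_end = integer(0),
             stringsAsFactors = FALSE)
}

# Split whole-frame translations at '*' and map fragment amino-acid offsets
# back to forward-strand nucleotide coordinates (vectorized across reads).
split_stop_free <- function(aa, read_ids, read_lens, frame, min_aa) {
  pieces <- strsplit(aa, "*", fixed = TRUE)
  npieces <- lengths(pieces)
  if (sum(npieces) == 0L) return(NULL)
  grp <- rep.int(seq_along(pieces), npieces)
  frag <- unlist(pieces, use.names = FALSE)
  # 0-based aa offset of each piece within its frame translation:
  # cumulative lengths of (piece + one stop) within each read
  step <- nchar(frag) + 1L
  cs <- cumsum(step)
  start_excl <- c(0L, cs[-length(cs)])
  first_idx <- which(!duplicated(grp))
  base <- start_excl[first_idx][match(grp, grp[first_idx])]
  aa_off0 <- start_excl - base

  keep <- nchar(frag) >= min_aa
  if (!any(keep)) return(NULL)
  frag <- frag[keep]; grp <- grp[keep]; aa_off0 <- aa_off0[keep]
  len_aa <- nchar(frag)
  off <- abs(frame) - 1L
  read_len <- read_lens[grp]
  if (frame > 0L) {
    nt_start <- off + 3L * aa_off0
    nt_end <- nt_start + 3L * len_aa
  } else {
    # coordinates on the reverse complement, mapped back to forward strand
    rc_start <- off + 3L * aa_off0
    rc_end <- rc_start + 3L * len_aa
    nt_start <- read_len - rc_end
    nt_end <- read_len - rc_start
  }
  ids <- read_ids[grp]
  data.frame(
    frag_id = paste(ids, frame, nt_start, sep = "_"),
    read_id = ids,
    frame = rep.int(frame, length(frag)),
    aa_seq = frag,
    nt_start = as.integer(nt_start),
    nt_end = as.integer(nt_end),
    stringsAsFactors = FALSE
  )
}

#' Total predicted amino acids in a fragment set
#'
#' The denominator of the DFPMAA_250 score counts the residues of all protein
#' fragments actually submitted to domain scanning.
#'
#' @param fragments Fragment data frame from [six_frame_fragments()].
#' @return Integer total residue count.
#' @export
total_amino_acids <- function(fragments) {
  if (is.null(fragments) || nrow(fragments) == 0L) return(0L)
  sum(nchar(fragments$aa_seq))
}
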