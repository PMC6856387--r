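# Synthetic communities with planted carbohydrate-active domain segments.
# Everything here is deterministic under a seed and designed so that ground
# truth is exactly recoverable: reverse translation uses one fixed codon per
# amino acid, reads are error-free by default, and the scanner is
# identity-based.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# one fixed codon per amino acid (translation table 11 compatible)
CODON_OF <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCG", Q = "CAG", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

reverse_translate <- function(aa_seq) {
  paste(CODON_OF[strsplit(aa_seq, "")[[1]]], collapse = "")
}

#' Build a toy HMM registry
#'
#' A synthetic catalog of carbohydrate-active domain models standing in for a
#' dbCAN-style HMM collection: each entry has a CAZy-style name (`GH1`,
#' `CBM3`, ...; `OTHER` entries are named `dockerin1`, ...), a length in
#' match states, a CAZy class, and a random amino-acid "signature" -- the
#' consensus that the naive scanner detects.
#'
#' @param n_hmms Number of models (`>= 1`).
#' @param class_mix Named proportions over
#'   `c("AA","CBM","CE","GH","GT","PL","OTHER")`, summing to 1.
#' @param seed Integer RNG seed.
#' @param len_range Inclusive range of signature lengths in residues.
#' @return A data frame with columns `name`, `length`, `cazy_class`,
#'   `signature`; names are unique and class-consistent.
#' @export
#' @examples
#' make_registry(4, c(GH = 0.5, CBM = 0.5), seed = 1)[, 1:3]
make_registry <- function(n_hmms,
                          class_mix = c(GH = 0.4, GT = 0.2, CBM = 0.2,
                                        CE = 0.1, PL = 0.05, AA = 0.05),
                          seed = 1L, len_range = c(30L, 300L)) {
  if (n_hmms < 1L) stop("n_hmms must be >= 1")
  valid_classes <- c("AA", "CBM", "CE", "GH", "GT", "PL", "OTHER")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% valid_classes) ||
      any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must be named proportions over CAZy classes summing to 1")
  set.seed(seed)
  # largest-remainder apportionment of n_hmms across classes
  raw <- class_mix * n_hmms
  counts <- floor(raw)
  short <- n_hmms - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  classes <- rep(names(counts), counts)
  idx_within <- stats::ave(seq_along(classes), classes, FUN = seq_along)
  name_stub <- ifelse(classes == "OTHER", "dockerin", classes)
  names_ <- paste0(name_stub, idx_within)
  lens <- len_range[1] - 1L +
    sample.int(len_range[2] - len_range[1] + 1L, n_hmms, replace = TRUE)
  sigs <- vapply(lens, function(l)
    paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""), character(1))
  data.frame(name = names_, length = as.integer(lens), cazy_class = classes,
             signature = sigs, stringsAsFactors = FALSE)
}

#' Build a toy genome with planted domain-encoding segments
#'
#' Interleaves random-nucleotide spacers with reverse-translated HMM
#' signatures (one fixed codon per residue, translation table 11), planting
#' each model `n_segments_per_hmm` times on a random strand in shuffled
#' order.  The annotation records every planted segment in 0-based half-open
#' coordinates, so parameter-recovery tests have exact ground truth.
#' Spacers are uniform random nucleotides: like intergenic or
#' non-carbohydrate coding sequence, they still yield open reading frames and
#' therefore contribute realistically to the amino-acid denominator.
#'
#' @param registry Registry from [make_registry()].
#' @param n_segments_per_hmm Copies of each model to plant.
#' @param spacer_len Spacer length (nt) between consecutive segments.
#' @param seed Integer RNG seed.
#' @param genome_id Identifier recorded in the annotation.
#' @return A list with `genome_id`, `seq`, `genome_len`, and `annotation`
#'   (data frame `start`, `end`, `strand`, `hmm_name`; each segment spans
#'   `3 * nchar(signature)` nt).
#' @export
make_toy_genome <- function(registry, n_segments_per_hmm = 1L,
                            spacer_len = 300L, seed = 1L,
                            genome_id = "toy_genome") {
  stopifnot(n_segments_per_hmm >= 1L, spacer_len >= 1L)
  set.seed(seed)
  plan <- rep(seq_len(nrow(registry)), each = n_segments_per_hmm)
  plan <- sample(plan)
  segments <- vapply(registry$signature[plan], reverse_translate, character(1))
  strands <- sample(c("+", "-"), length(plan), replace = TRUE)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  placed <- ifelse(strands == "-", vapply(segments, rc, character(1)), segments)
  spacer <- function() paste(sample(c("A", "C", "G", "T"), spacer_len,
                                    replace = TRUE), collapse = "")
  parts <- character(2L * length(plan) + 1L)
  ann_start <- integer(length(plan))
  pos <- 0L
  for (i in seq_along(plan)) {
    sp <- spacer()
    parts[2L * i - 1L] <- sp
    pos <- pos + nchar(sp)
    ann_start[i] <- pos
    parts[2L * i] <- placed[i]
    pos <- pos + nchar(placed[i])
  }
  parts[length(parts)] <- spacer()
  genome <- paste(parts, collapse = "")
  annotation <- data.frame(
    start = ann_start,
    end = ann_start + nchar(placed),
    strand = strands,
    hmm_name = registry$name[plan],
    stringsAsFactors = FALSE
  )
  list(genome_id = genome_id, seq = genome, genome_len = nchar(genome),
       annotation = annotation)
}

#' Simulate error-free merged shotgun reads
#'
#' Uniform random start positions and random strand, emulating merged
#' (overlap-assembled) shotgun reads.  Error-free by default; an optional
#' uniform substitution rate is available but the package's calibration
#' properties assume 0, because the scanner stand-in is identity-based.
#'
#' @param genome A [make_toy_genome()] result, or a nucleotide string.
#' @param n_reads Number of reads.
#' @param read_len Read length in nt; at most the genome length.
#' @param seed Integer RNG seed.
#' @param sub_rate Per-base substitution probability (default 0).
#' @return Data frame with columns `id` and `seq`.
#' @export
simulate_reads <- function(genome, n_reads, read_len, seed = 1L,
                           sub_rate = 0) {
  seq <- if (is.list(genome)) genome$seq else genome
  glen <- nchar(seq)
  if (read_len > glen)
    stop("read_len (", read_len, ") exceeds genome length (", glen, ")")
  if (n_reads == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  set.seed(seed)
  starts <- sample.int(glen - read_len + 1L, n_reads, replace = TRUE)
  reads <- substring(seq, starts, starts + read_len - 1L)
  minus <- runif(n_reads) < 0.5
  if (any(minus)) {
    reads[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[minus])))
  }
  if (sub_rate > 0) {
    chars <- strsplit(reads, "")
    reads <- vapply(chars, function(cc) {
      hit <- runif(length(cc)) < sub_rate
      if (any(hit))
        cc[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      paste(cc, collapse = "")
    }, character(1))
  }
  data.frame(
    id = sprintf("read%07d", seq_len(n_reads)),
    seq = reads, stringsAsFactors = FALSE
  )
}

#' Naive exact-match domain scanner
#'
#' A desk-scale stand-in for profile-HMM scanning, usable because the
#' synthetic generator plants literal signature copies: fragments are scanned
#' for maximal ungapped near-exact (identity `>= min_identity`) overlaps with
#' any registry signature, via exact k-mer seeding followed by greedy
#' extension that may bridge isolated substitutions while the window identity
#' stays above the threshold.  Each accepted window is emitted as one domain
#' hit with HMM coordinates on the signature, alignment coordinates on the
#' fragment, a monotone pseudo-statistic `i_evalue = 10^(-matched_aa / 2)`,
#' and `bit_score = matched_aa`.
#'
#' @param fragments Fragment data frame from [six_frame_fragments()].
#' @param registry Registry from [make_registry()].
#' @param min_overlap_aa Minimum window length in residues (default 10); the
#'   seed length is chosen so every qualifying window is guaranteed to be
#'   found.
#' @param min_identity Minimum fraction of identical residues in the reported
#'   window (default 0.9).
#' @return A domain-hit data frame (see [read_domtblout()] for columns).
#' @export
naive_domain_scan <- function(fragments, registry, min_overlap_aa = 10L,
                              min_identity = 0.9) {
  if (is.null(fragments) || nrow(fragments) == 0L) return(empty_domain_hits())
  stopifnot(min_overlap_aa >= 2L, min_identity > 0, min_identity <= 1)
  k <- max(3L, min(12L, (min_overlap_aa + 1L) %/% 2L))

  # dense k-mer index over all signatures
  sig_len <- nchar(registry$signature)
  n_kmer <- pmax(sig_len - k + 1L, 0L)
  sig_rep <- rep.int(seq_len(nrow(registry)), n_kmer)
  sig_pos <- sequence(n_kmer)
  keys <- substring(registry$signature[sig_rep], sig_pos, sig_pos + k - 1L)
  uniq_keys <- unique(keys)
  key_id <- match(keys, uniq_keys)
  entries_by_key <- split(seq_along(keys), key_id)

  # grid k-mers over fragments: step k guarantees every common substring of
  # length >= 2k - 1 (hence >= min_overlap_aa) contains one grid k-mer
  fl <- nchar(fragments$aa_seq)
  n_grid <- ifelse(fl >= k, (fl - k) %/% k + 1L, 0L)
  frag_rep <- rep.int(seq_len(nrow(fragments)), n_grid)
  grid_pos <- (sequence(n_grid) - 1L) * k + 1L
  gk <- substring(fragments$aa_seq[frag_rep], grid_pos, grid_pos + k - 1L)
  mid <- match(gk, uniq_keys)
  cand <- which(!is.na(mid))
  if (length(cand) == 0L) return(empty_domain_hits())

  ent <- entries_by_key[as.character(mid[cand])]
  n_ent <- lengths(ent)
  c_frag <- rep.int(frag_rep[cand], n_ent)
  c_fpos <- rep.int(grid_pos[cand], n_ent)
  e <- unlist(ent, use.names = FALSE)
  c_sig <- sig_rep[e]
  c_spos <- sig_pos[e]
  diag <- c_fpos - c_spos
  dup <- duplicated(paste(c_frag, c_sig, diag, sep = ":"))
  c_frag <- c_frag[!dup]; c_fpos <- c_fpos[!dup]
  c_sig <- c_sig[!dup]; c_spos <- c_spos[!dup]; diag <- diag[!dup]

  frag_int <- new.env(parent = emptyenv())
  get_frag <- function(i) {
    key <- as.character(i)
    v <- frag_int[[key]]
    if (is.null(v)) {
      v <- utf8ToInt(fragments$aa_seq[i])
      frag_int[[key]] <- v
    }
    v
  }
  sig_int <- lapply(registry$signature, utf8ToInt)

  rows <- vector("list", length(c_frag))
  for (ci in seq_along(c_frag)) {
    fi <- c_frag[ci]; si <- c_sig[ci]; d <- diag[ci]
    f <- get_frag(fi); s <- sig_int[[si]]
    j_lo <- max(1L, 1L - d)
    j_hi <- min(length(s), length(f) - d)
    if (j_hi - j_lo + 1L < min_overlap_aa) next
    m <- f[(j_lo + d):(j_hi + d)] == s[j_lo:j_hi]
    seed_l <- c_spos[ci] - j_lo + 1L
    win <- extend_identity_window(m, seed_l, seed_l + k - 1L, min_identity)
    wlen <- win[2L] - win[1L] + 1L
    matched <- win[3L]
    if (wlen < min_overlap_aa || matched / wlen < min_identity) next
    hmm_from <- j_lo + win[1L] - 1L
    hmm_to <- j_lo + win[2L] - 1L
    rows[[ci]] <- c(fi, si, hmm_from, hmm_to, matched, d)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_domain_hits())
  rm <- do.call(rbind, rows)
  # distinct windows only: one row per fragment/model/window
  key <- paste(rm[, 1], rm[, 2], rm[, 3], rm[, 4], sep = ":")
  rm <- rm[!duplicated(key), , drop = FALSE]
  fi <- rm[, 1]; si <- rm[, 2]
  matched <- rm[, 5]
  hits <- data.frame(
    seq_id = fragments$frag_id[fi],
    seq_len = nchar(fragments$aa_seq[fi]),
    hmm_name = registry$name[si],
    hmm_len = as.integer(nchar(registry$signature[si])),
    full_evalue = 10^(-matched / 2),
    i_evalue = 10^(-matched / 2),
    bit_score = as.numeric(matched),
    hmm_from = as.integer(rm[, 3]),
    hmm_to = as.integer(rm[, 4]),
    # fragment coordinates sit on the seed diagonal: ali = hmm + diag
    ali_from = as.integer(rm[, 3] + rm[, 6]),
    ali_to = as.integer(rm[, 4] + rm[, 6]),
    description = "",
    stringsAsFactors = FALSE
  )
  hits <- hits[order(hits$seq_id, hits$ali_from), , drop = FALSE]
  rownames(hits) <- NULL
  validate_domain_hits(hits)
  hits
}

# Greedy growth of a high-identity window around an exact seed.
# m: logical match vector; [l, r]: seed interval (all TRUE).
# Returns c(l, r, n_matched).
extend_identity_window <- function(m, l, r, min_identity) {
  n <- length(m)
  # exact extension
  while (l > 1L && m[l - 1L]) l <- l - 1L
  while (r < n && m[r + 1L]) r <- r + 1L
  matched <- r - l + 1L
  repeat {
    best <- NULL
    # candidate extension on the left: cross the mismatch block, absorb the
    # next run of matches
    if (l > 1L) {
      i <- l - 1L
      while (i >= 1L && !m[i]) i <- i - 1L
      if (i >= 1L) {
        j <- i
        while (j > 1L && m[j - 1L]) j <- j - 1L
        gain <- i - j + 1L
        z <- (l - 1L) - i
        new_matched <- matched + gain
        new_len <- (r - j + 1L)
        if (new_matched / new_len >= min_identity)
          best <- list(side = "L", l = j, r = r, matched = new_matched,
                       ident = new_matched / new_len)
      }
    }
    if (r < n) {
      i <- r + 1L
      while (i <= n && !m[i]) i <- i + 1L
      if (i <= n) {
        j <- i
        while (j < n && m[j + 1L]) j <- j + 1L
        gain <- j - i + 1L
        new_matched <- matched + gain
        new_len <- (j - l + 1L)
        if (new_matched / new_len >= min_identity) {
          cand <- list(side = "R", l = l, r = j, matched = new_matched,
                       ident = new_matched / new_len)
          if (is.null(best) || cand$ident > best$ident) best <- cand
        }
      }
    }
    if (is.null(best)) break
    l <- best$l; r <- best$r; matched <- best$matched
  }
  c(l, r, matched)
}

#' Write domain hits as HMMER3 domtblout text
#'
#' Emits a 22+-column per-domain table parseable by [read_domtblout()] with
#' identical scored fields (floats are serialized at full double precision,
#' unlike HMMER's rounded output, so round-trips are exact).
#'
#' @param hits Domain-hit data frame.
#' @param path Output path.
#' @param orientation `"search"` (HMM = query) or `"scan"` (HMM = target);
#'   must match the `orientation` later passed to [read_domtblout()].
#' @return `path`, invisibly.
#' @export
emit_domtblout <- function(hits, path, orientation = c("search", "scan")) {
  orientation <- match.arg(orientation)
  if (nrow(hits)) validate_domain_hits(hits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# synthetic per-domain hits table (domtblout layout)",
    sprintf("# orientation: %s", orientation),
    "#"), con)
  if (nrow(hits)) {
    desc <- if ("description" %in% names(hits)) hits$description else ""
    desc <- ifelse(nzchar(desc), desc, "-")
    if (orientation == "search") {
      tname <- hits$seq_id;  tlen <- hits$seq_len
      qname <- hits$hmm_name; qlen <- hits$hmm_len
    } else {
      tname <- hits$hmm_name; tlen <- hits$hmm_len
      qname <- hits$seq_id;  qlen <- hits$seq_len
    }
    writeLines(sprintf(
      "%s - %d %s - %d %.17g %.17g 0.0 1 1 %.17g %.17g %.17g 0.0 %d %d %d %d %d %d 0.99 %s",
      tname, tlen, qname, qlen,
      hits$full_evalue, hits$bit_score,
      hits$i_evalue, hits$i_evalue, hits$bit_score,
      hits$hmm_from, hits$hmm_to, hits$ali_from, hits$ali_to,
      hits$ali_from, hits$ali_to, desc), con)
  }
  invisible(path)
}
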