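#' Read a HMMER3 per-domain tabular file (domtblout)
#'
#' Parses the `--domtblout` output of `hmmsearch` or `hmmscan` into one row
#' per domain alignment.  The two programs swap the roles of query and target:
#' with `hmmsearch` the HMM is the query (its length is the `qlen` column) and
#' the sequence is the target, with `hmmscan` the roles are reversed.  Pass
#' `orientation` accordingly; the returned table is identical either way, so
#' downstream filtering and scoring never need to know which program ran.
#'
#' Coordinates are kept 1-based inclusive (the HMMER convention); all length
#' arithmetic downstream uses `to - from + 1`.  The free-text description
#' field (columns 23+) is preserved verbatim but never consumed.
#'
#' @param path Path to a domtblout file.  Lines starting with `#` are
#'   comments.
#' @param orientation `"search"` if the file came from `hmmsearch` (HMM =
#'   query), `"scan"` if from `hmmscan` (HMM = target).
#' @return A data frame of domain hits with columns `seq_id`, `seq_len`,
#'   `hmm_name`, `hmm_len`, `full_evalue`, `i_evalue`, `bit_score`,
#'   `hmm_from`, `hmm_to`, `ali_from`, `ali_to`, `description`.
#' @seealso [apply_dbcan_filter()], [emit_domtblout()]
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines("# comment only", tf)
#' nrow(read_domtblout(tf, "search"))  # 0
read_domtblout <- function(path, orientation = c("search", "scan")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("domtblout file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  data_lines <- lines[keep]
  line_no <- seq_along(lines)[keep]
  if (length(data_lines) == 0L) return(empty_domain_hits())

  parts <- strsplit(trimws(data_lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 22L)) {
    bad <- which(nf < 22L)[1L]
    stop("domtblout parse error at line ", line_no[bad], ": expected >= 22 ",
         "whitespace-separated fields, found ", nf[bad])
  }
  field <- function(i) vapply(parts, `[[`, character(1), i)
  num_field <- function(i, what) {
    v <- suppressWarnings(as.numeric(field(i)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("domtblout parse error at line ", line_no[bad], ": non-numeric ",
           what, " field")
    }
    v
  }
  desc <- vapply(parts, function(p) {
    if (length(p) > 22L) paste(p[23:length(p)], collapse = " ") else ""
  }, character(1))

  # fixed 22-column prefix:
  #  1 target  3 tlen  4 query  6 qlen  7 full E-value  13 i-Evalue
  # 14 domain bit score  16-17 hmm coords  18-19 ali coords
  target_name <- field(1); tlen <- num_field(3, "target length")
  query_name  <- field(4); qlen <- num_field(6, "query length")
  hits <- data.frame(
    seq_id      = if (orientation == "search") target_name else query_name,
    seq_len     = as.integer(if (orientation == "search") tlen else qlen),
    hmm_name    = if (orientation == "search") query_name else target_name,
    hmm_len     = as.integer(if (orientation == "search") qlen else tlen),
    full_evalue = num_field(7, "full-sequence E-value"),
    i_evalue    = num_field(13, "i-Evalue"),
    bit_score   = num_field(14, "bit score"),
    hmm_from    = as.integer(num_field(16, "hmm-from coordinate")),
    hmm_to      = as.integer(num_field(17, "hmm-to coordinate")),
    ali_from    = as.integer(num_field(18, "ali-from coordinate")),
    ali_to      = as.integer(num_field(19, "ali-to coordinate")),
    description = desc,
    stringsAsFactors = FALSE
  )
  validate_domain_hits(hits)
  hits
}

empty_domain_hits <- function() {
  data.frame(
    seq_id = character(0), seq_len = integer(0),
    hmm_name = character(0), hmm_len = integer(0),
    full_evalue = numeric(0), i_evalue = numeric(0), bit_score = numeric(0),
    hmm_from = integer(0), hmm_to = integer(0),
    ali_from = integer(0), ali_to = integer(0),
    description = character(0), stringsAsFactors = FALSE
  )
}

validate_domain_hits <- function(hits) {
  required <- c("seq_id", "seq_len", "hmm_name", "hmm_len", "full_evalue",
                "i_evalue", "bit_score", "hmm_from", "hmm_to",
                "ali_from", "ali_to")
  missing <- setdiff(required, names(hits))
  if (length(missing))
    stop("domain-hit table missing columns: ", paste(missing, collapse = ", "))
  if (nrow(hits) == 0L) return(invisible(hits))
  with(hits, {
    if (any(hmm_len <= 0L)) stop("invalid hit: hmm_len must be > 0")
    if (any(hmm_from < 1L | hmm_from > hmm_to | hmm_to > hmm_len))
      stop("invalid hit: need 1 <= hmm_from <= hmm_to <= hmm_len")
    if (any(ali_from < 1L | ali_from > ali_to | ali_to > seq_len))
      stop("invalid hit: need 1 <= ali_from <= ali_to <= seq_len")
    if (any(i_evalue < 0)) stop("invalid hit: i_evalue must be >= 0")
  })
  invisible(hits)
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrappers over [Biostrings::readBStringSet()] returning a plain data
#' frame, the carrier used throughout the package.  The id is the header token
#' before the first whitespace, matching the id convention of HMMER tabular
#' output so hits join back to sequences.
#'
#' @param path Path to the sequence file.
#' @return A data frame with columns `id` and `seq` (and `qual` for FASTQ).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  set <- Biostrings::readBStringSet(path, format = "fasta")
  data.frame(
    id = sub("\\s.*$", "", names(set)),
    seq = as.character(set),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  parsed <- tryCatch({
    set <- Biostrings::readBStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    quals <- S4Vectors::mcols(set)$qualities
    # compare raw widths before any character conversion: the reader pads
    # short quality strings with nul bytes, which must be treated as a
    # format violation, and nul-containing strings break as.character
    padded <- vapply(seq_along(quals), function(i)
      any(as.integer(quals[[i]]) == 0L), logical(1))
    if (any(Biostrings::width(quals) != Biostrings::width(set)) ||
        any(padded))
      stop("quality string length differs from sequence length")
    list(ids = names(set), seqs = as.character(set),
         qual = as.character(quals))
  }, error = function(e) stop("FASTQ format error in ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  qual <- parsed$qual
  seqs <- parsed$seqs
  data.frame(
    id = sub("\\s.*$", "", parsed$ids),
    seq = seqs, qual = qual,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write sequences as FASTA
#'
#' @param records Data frame with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records))
    writeLines(paste0(">", records$id, "\n", records$seq), con)
  invisible(path)
}

#' Read and write per-HMM score tables as TSV
#'
#' The on-disk format is a two-column TSV (`hmm`, `dfpmaa_250`) preceded by
#' `#`-prefixed metadata lines (sample id, total amino acids, mean read
#' length, read count) when the input is a full [score_table()].  Scores are
#' serialized with 17 significant digits so that write-then-read is the
#' identity to well below 1e-9.
#'
#' @param table A [score_table()] object, or a named numeric vector mapping
#'   HMM name to a nonnegative score.
#' @param path File path.
#' @return `write_score_table()` returns `path` invisibly;
#'   `read_score_table()` returns a named numeric vector of scores with any
#'   stored metadata in `attr(, "meta")`.
#' @export
write_score_table <- function(table, path) {
  meta <- NULL
  if (inherits(table, "dfpmaa_score_table")) {
    meta <- table[c("sample_id", "total_aa", "mean_read_len_nt", "n_reads")]
    scores <- table$scores
  } else {
    scores <- table
  }
  if (length(scores) && (is.null(names(scores)) || any(!nzchar(names(scores)))))
    stop("score table must be named by HMM")
  if (any(scores < 0)) stop("score table contains a negative score")
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(sprintf("# %s\t%s", key, format(meta[[key]], digits = 17)), con)
  writeLines("hmm\tdfpmaa_250", con)
  if (length(scores))
    writeLines(sprintf("%s\t%.17g", names(scores), unname(scores)), con)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L || body[1L] != "hmm\tdfpmaa_250")
    stop("not a score table (missing 'hmm\\tdfpmaa_250' header): ", path)
  body <- body[-1L]
  body <- body[nzchar(body)]
  scores <- numeric(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    scores <- as.numeric(vapply(parts, `[[`, character(1), 2L))
    names(scores) <- vapply(parts, `[[`, character(1), 1L)
    if (any(scores < 0)) stop("score table contains a negative score")
  }
  if (length(meta_lines)) {
    mp <- strsplit(sub("^#\\s*", "", meta_lines), "\t", fixed = TRUE)
    meta <- lapply(mp, `[[`, 2L)
    names(meta) <- vapply(mp, `[[`, character(1), 1L)
    attr(scores, "meta") <- meta
  }
  scores
}
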