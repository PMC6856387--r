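test_that("registries are deterministic, unique, and class-consistent", {
  one <- make_registry(1, c(GH = 1.0), seed = 2)
  expect_identical(nrow(one), 1L)
  expect_identical(cazy_class_of(one$name), "GH")

  big <- make_registry(585, seed = 3)
  expect_identical(length(unique(big$name)), 585L)
  expect_identical(nchar(big$signature), big$length)
  expect_identical(cazy_class_of(big$name), big$cazy_class)

  expect_identical(make_registry(20, seed = 9), make_registry(20, seed = 9))
  expect_error(make_registry(5, c(GH = 0.7)), "summing to 1")
  expect_error(make_registry(5, c(XX = 1.0)), "class_mix")
})

test_that("toy genomes plant segments that translate back to their signatures", {
  reg <- make_registry(4, c(GH = 0.5, CBM = 0.5), seed = 5,
                       len_range = c(30L, 60L))
  g1 <- make_toy_genome(reg, n_segments_per_hmm = 1L, spacer_len = 100L,
                        seed = 6)
  expect_identical(nrow(g1$annotation), 4L)
  expect_identical(g1$annotation$end - g1$annotation$start,
                   3L * reg$length[match(g1$annotation$hmm_name, reg$name)])

  g2 <- make_toy_genome(reg, n_segments_per_hmm = 2L, spacer_len = 100L,
                        seed = 6)
  expect_identical(nrow(g2$annotation), 8L)

  code <- Biostrings::getGeneticCode("11")
  for (i in seq_len(nrow(g1$annotation))) {
    seg <- substring(g1$seq, g1$annotation$start[i] + 1L, g1$annotation$end[i])
    if (g1$annotation$strand[i] == "-")
      seg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seg)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(seg),
                                             genetic.code = code,
                                             no.init.codon = TRUE))
    expect_identical(aa, reg$signature[reg$name == g1$annotation$hmm_name[i]])
  }
})

test_that("simulated reads have the requested length and coverage", {
  reg <- make_registry(3, c(GH = 1.0), seed = 7, len_range = c(40L, 60L))
  g <- make_toy_genome(reg, 2L, spacer_len = 2000L, seed = 8)

  expect_identical(nrow(simulate_reads(g, 0L, 100L, seed = 1)), 0L)
  reads <- simulate_reads(g, 500L, 150L, seed = 1)
  expect_true(all(nchar(reads$seq) == 150L))
  expect_identical(simulate_reads(g, 500L, 150L, seed = 1), reads)

  # 50x expected coverage: mean per-base depth within 10%
  n50 <- round(50 * g$genome_len / 250)
  reads50 <- simulate_reads(g, n50, 250L, seed = 2)
  expect_equal(n50 * 250 / g$genome_len, 50, tolerance = 0.01)
  expect_error(simulate_reads(g, 10L, g$genome_len + 1L, seed = 1),
               "exceeds")
})

test_that("the naive scanner finds planted overlaps and rejects random sequence", {
  reg <- make_registry(2, c(GH = 0.5, CBM = 0.5), seed = 10,
                       len_range = c(100L, 100L))
  sig <- reg$signature[1]

  full <- data.frame(frag_id = "f", read_id = "r", frame = 1L, aa_seq = sig,
                     nt_start = 0L, nt_end = 300L)
  h <- naive_domain_scan(full, reg)
  expect_identical(nrow(h), 1L)
  expect_equal(coverage_fraction(h), 1.0)
  expect_identical(h$hmm_name, reg$name[1])
  expect_equal(h$bit_score, 100)
  expect_equal(h$i_evalue, 1e-50)

  # a fragment overlapping only 25% of a 100-state signature: found by the
  # scanner but rejected by the 0.3-coverage rule
  part <- data.frame(frag_id = "p", read_id = "r", frame = 1L,
                     aa_seq = substring(sig, 1, 25),
                     nt_start = 0L, nt_end = 75L)
  hp <- naive_domain_scan(part, reg)
  expect_identical(nrow(hp), 1L)
  expect_equal(coverage_fraction(hp), 0.25)
  expect_identical(nrow(apply_dbcan_filter(hp)), 0L)

  # random fragments essentially never reach 90% identity over >= 10 aa
  set.seed(11)
  rand <- data.frame(
    frag_id = paste0("x", 1:1000), read_id = paste0("x", 1:1000),
    frame = 1L,
    aa_seq = replicate(1000, paste(
      sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, TRUE),
      collapse = "")),
    nt_start = 0L, nt_end = 180L)
  expect_identical(nrow(naive_domain_scan(rand, reg)), 0L)
})

test_that("the scanner tolerates isolated substitutions below 10% divergence", {
  reg <- make_registry(1, c(GH = 1.0), seed = 12, len_range = c(80L, 80L))
  sig <- strsplit(reg$signature, "")[[1]]
  mutated <- sig
  mutated[40] <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         sig[40])[1]
  frag <- data.frame(frag_id = "m", read_id = "r", frame = 1L,
                     aa_seq = paste(mutated, collapse = ""),
                     nt_start = 0L, nt_end = 240L)
  h <- naive_domain_scan(frag, reg)
  expect_identical(nrow(h), 1L)
  expect_equal(coverage_fraction(h), 1.0)  # window spans the full signature
  expect_equal(h$bit_score, 79)            # one mismatched residue
})

test_that("emitted domtblout files round-trip ground-truth hits exactly", {
  tf <- withr::local_tempfile()
  emit_domtblout(empty_hits_df(), tf, "search")
  expect_identical(nrow(read_domtblout(tf, "search")), 0L)

  set.seed(13)
  hits <- random_hits(2000)
  emit_domtblout(hits, tf, "search")
  back <- read_domtblout(tf, "search")
  scored <- c("seq_id", "seq_len", "hmm_name", "hmm_len", "full_evalue",
              "i_evalue", "bit_score", "hmm_from", "hmm_to",
              "ali_from", "ali_to")
  expect_equal(back[scored], hits[scored], ignore_attr = TRUE)
})

test_that("the pipeline scores planted communities and ignores barren genomes", {
  inp <- toy_pipeline_inputs(seed = 17, n_reads = 800L)
  tab <- dfpmaa_pipeline(inp$reads, inp$registry)
  expect_gt(sum_dfpmaa(tab), 0)
  expect_identical(tab$n_reads, 800L)

  set.seed(18)
  barren <- paste(sample(c("A", "C", "G", "T"), 20000L, TRUE), collapse = "")
  reads0 <- simulate_reads(barren, 400L, 250L, seed = 19)
  expect_identical(sum_dfpmaa(dfpmaa_pipeline(reads0, inp$registry)), 0)

  # duplicating every read (under fresh ids) leaves the ratio-normalized
  # score unchanged
  dup <- inp$reads
  dup$id <- paste0(dup$id, "_copy")
  tab2 <- dfpmaa_pipeline(rbind(inp$reads, dup), inp$registry)
  expect_equal(sum_dfpmaa(tab2), sum_dfpmaa(tab), tolerance = 1e-12)
})
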