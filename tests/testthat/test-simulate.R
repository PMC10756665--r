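test_that("synthetic references carry the terminal stem and are seeded", {
  ref <- generate_reference_set(
    lengths = c(112L, 101L, 93L, 83L),
    stem_len = 10L, seed = 1L
  )
  expect_equal(nrow(ref), 4L)
  expect_equal(ref$length, c(112L, 101L, 93L, 83L))
  for (i in seq_len(4)) {
    s <- ref$seq[i]
    stem5 <- substr(s, 1, 10)
    stem3 <- substr(s, nchar(s) - 9, nchar(s))
    expect_identical(
      stem3,
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(stem5)))
    )
  }
  ref2 <- generate_reference_set(
    lengths = c(112L, 101L, 93L, 83L),
    stem_len = 10L, seed = 1L
  )
  expect_identical(ref, ref2)
  expect_error(
    generate_reference_set(lengths = 83L, stem_len = 60L),
    "twice the stem"
  )
})

test_that("fragment_class validates its distributions", {
  expect_error(
    simple_class("hY1", lengths = c("36" = 1)),
    "\\[25, 35\\]"
  )
  expect_error(
    simple_class("hY1", lengths = c("24" = 1)),
    "\\[25, 35\\]"
  )
  expect_error(
    fragment_class("hY1", 0.5,
      start_prob = c("0" = 0.6, "1" = 0.6),
      length_prob = c("30" = 1),
      states = data.frame(five = "P", three = "OMe", prob = 1)
    ),
    "sum to 1"
  )
  expect_error(
    fragment_class("hY1", 0.5,
      start_prob = c("0" = 1), length_prob = c("30" = 1),
      states = data.frame(five = "PP", three = "OMe", prob = 1)
    ),
    "state"
  )
})

test_that("generated reads copy parent sequence at the recorded offset", {
  ref <- test_reference()
  reads <- generate_library(
    ref, list(simple_class("hY3", 0.9, start = c("0" = 0.5, "1" = 0.5),
      lengths = peaked_length_prob(31)
    )),
    background_fraction = 0.1, n_reads = 5000, seed = 3
  )
  ys <- reads[reads$parent != "background", ]
  pseq <- ref$seq[ref$id == "hY3"]
  expect_identical(
    ys$seq,
    substring(pseq, ys$start + 1L, ys$start + nchar(ys$seq))
  )
  expect_true(all(nchar(ys$seq) >= 25 & nchar(ys$seq) <= 35))
  expect_true(all(ys$start %in% c(0L, 1L)))

  # degenerate distributions give a single read sequence
  mono <- generate_library(ref, list(simple_class("hY1", 1)),
    background_fraction = 0, n_reads = 200, seed = 4
  )
  expect_identical(unique(mono$seq), substr(ref$seq[1], 1, 30))

  expect_equal(nrow(generate_library(ref, list(), 1, 0, seed = 1)), 0L)
})

test_that("class abundance follows the binomial draw and background avoids the halves", {
  ref <- test_reference()
  n <- 100000
  frac <- 0.6
  reads <- generate_library(
    ref, list(simple_class("hY1", frac, lengths = peaked_length_prob(30))),
    background_fraction = 1 - frac, n_reads = n, seed = 1
  )
  k <- sum(reads$parent == "hY1")
  expect_lt(abs(k - n * frac), 4 * sqrt(n * frac * (1 - frac)))

  bg <- reads$seq[reads$parent == "background"]
  idx <- build_match_index(ref, min_len = 20L)
  expect_false(any(bg %in% idx$table$seq))
  # and none matches any half outright
  some <- sample(bg, 50)
  for (s in some) expect_equal(nrow(naive_match(s, idx$halves)), 0L)
})

test_that("same seed and config give byte-identical libraries", {
  ref <- test_reference()
  cfg <- sperm_head_config()
  a <- generate_library(ref, cfg$classes, cfg$background_fraction, 2000, seed = 9)
  b <- generate_library(ref, cfg$classes, cfg$background_fraction, 2000, seed = 9)
  expect_identical(a, b)
  fq1 <- tempfile(fileext = ".fastq")
  fq2 <- tempfile(fileext = ".fastq")
  t1 <- tempfile(fileext = ".tsv")
  t2 <- tempfile(fileext = ".tsv")
  write_library(ligate_and_select(a), fq1, t1)
  write_library(ligate_and_select(b), fq2, t2)
  expect_identical(readLines(fq1), readLines(fq2))
  expect_identical(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))
})

test_that("oxidation/beta-elimination removes one 3' base from diol ends only", {
  reads <- make_reads(
    seqs = c("ACGTACGTACGTACGTACGTACGTACGTACG", # 31 nt
             "ACGTACGTACGTACGTACGTACGTACGTAC",
             "ACGTACGTACGTACGTACGTACGTACGTACG",
             "ACGTACGTACGTACGTACGTACGTACGTACG"),
    five = c("P", "P", "P", "PPP"),
    three = c("OH", "OMe", "P", "cP")
  )
  ox <- apply_treatment(reads, "OXIDATION_BETA_ELIM")
  expect_equal(nchar(ox$seq[1]), 30L)
  expect_equal(ox$three_prime[1], "P")
  expect_identical(ox$seq[2:4], reads$seq[2:4])
  expect_identical(ox$three_prime[2:4], reads$three_prime[2:4])
  # truth channel untouched
  expect_identical(ox$parent, reads$parent)
  expect_identical(ox$start, reads$start)
})

test_that("RppH converts 5' triphosphate to monophosphate and nothing else", {
  reads <- make_reads(
    seqs = rep(strrep("ACGT", 8), 3),
    five = c("PPP", "P", "OH"), three = "OH"
  )
  out <- apply_treatment(reads, "RPPH")
  expect_equal(out$five_prime, c("P", "P", "OH"))
  expect_identical(out$seq, reads$seq)
  expect_identical(out$three_prime, reads$three_prime)
})

test_that("PNK heals 3' phosphates and cycles the 5' end probabilistically", {
  reads <- make_reads(
    seqs = rep(strrep("ACGT", 8), 4),
    five = c("OH", "P", "P", "PPP"),
    three = c("P", "cP", "OMe", "OH")
  )
  all_dephos <- apply_treatment(reads, "PNK", p_pnk_5p_dephos = 1, seed = 1)
  expect_equal(all_dephos$three_prime, c("OH", "OH", "OMe", "OH"))
  expect_equal(all_dephos$five_prime, c("P", "OH", "OH", "PPP"))

  none_dephos <- apply_treatment(reads, "PNK", p_pnk_5p_dephos = 0, seed = 1)
  expect_equal(none_dephos$five_prime, c("P", "P", "P", "PPP"))

  # dephosphorylation rate approaches its parameter
  many <- make_reads(rep(strrep("ACGT", 8), 4000), five = "P", three = "OH")
  out <- apply_treatment(many, "PNK", p_pnk_5p_dephos = 0.8, seed = 2)
  rate <- mean(out$five_prime == "OH")
  expect_lt(abs(rate - 0.8), 4 * sqrt(0.8 * 0.2 / 4000))
})

test_that("combined PNK+RppH applies PNK first, then RppH", {
  reads <- make_reads(
    seqs = rep(strrep("ACGT", 8), 2),
    five = c("PPP", "OH"), three = c("P", "cP")
  )
  out <- apply_treatment(reads, "PNK_RPPH", p_pnk_5p_dephos = 1, seed = 1)
  # PPP passes PNK untouched, then RppH leaves monophosphate; the OH read
  # is phosphorylated by PNK and untouched by RppH
  expect_equal(out$five_prime, c("P", "P"))
  expect_equal(out$three_prime, c("OH", "OH"))
})

test_that("deterministic treatment operators are idempotent", {
  set.seed(7)
  states <- expand.grid(
    five = FIVE_PRIME_STATES, three = THREE_PRIME_STATES,
    stringsAsFactors = FALSE
  )
  reads <- make_reads(random_seqs <- replicate(nrow(states),
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  ), five = states$five, three = states$three)
  for (trt in c("OXIDATION_BETA_ELIM", "RPPH")) {
    once <- apply_treatment(reads, trt)
    twice <- apply_treatment(once, trt)
    expect_identical(once, twice)
  }
  # PNK 3'-phosphatase action is idempotent; the competing 5'
  # kinase/exchange activities cycle OH <-> P, so strict idempotence holds
  # only when the dephosphorylation probability is 0
  once <- apply_treatment(reads, "PNK", p_pnk_5p_dephos = 0)
  twice <- apply_treatment(once, "PNK", p_pnk_5p_dephos = 0)
  expect_identical(once, twice)
  once_full <- apply_treatment(reads, "PNK", p_pnk_5p_dephos = 1, seed = 1)
  expect_true(all(!once_full$three_prime %in% c("P", "cP")))
  again <- apply_treatment(once_full, "PNK", p_pnk_5p_dephos = 1, seed = 1)
  expect_identical(again$three_prime, once_full$three_prime)
})

test_that("ligation gate keeps 5'-P reads with free 3'-OH under the size cut-off", {
  reads <- make_reads(
    seqs = c(
      strrep("A", 30), strrep("C", 30), strrep("G", 30),
      strrep("T", 30), strrep("AC", 30)
    ),
    five = c("P", "PPP", "P", "OH", "P"),
    three = c("OMe", "OH", "P", "OH", "OH")
  )
  kept <- ligate_and_select(reads, max_len = 50)
  expect_identical(kept$read_id, reads$read_id[c(1)])
  # the 60-nt read fails size selection despite ligatable ends
  expect_false("t005" %in% kept$read_id)
  # subset + no-op on reapplication
  expect_identical(ligate_and_select(kept), kept)
  expect_true(all(kept$read_id %in% reads$read_id))
})

test_that("FASTQ output is standard 4-line records and round-trips", {
  ref <- test_reference()
  reads <- ligate_and_select(generate_library(
    ref, sperm_head_config()$classes, 0.2, 500,
    seed = 5
  ))
  fq <- tempfile(fileext = ".fastq")
  tr <- tempfile(fileext = ".tsv")
  write_library(reads, fq, tr)
  lines <- readLines(fq)
  expect_equal(length(lines), 4L * nrow(reads))
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))
  back <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  expect_identical(unname(back), reads$seq)
  truth <- read_truth(tr)
  expect_identical(truth$read_id, reads$read_id)
  expect_identical(truth$length, nchar(reads$seq))

  # empty library still produces valid (empty) outputs
  empty <- reads[0, ]
  write_library(empty, fq, tr)
  expect_equal(file.size(fq), 0)
  expect_equal(nrow(read_truth(tr)), 0L)

  # optional adapter suffix is appended verbatim
  write_library(reads[1:3, ], fq, tr, adapter = "AGATCGGAAG")
  withad <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  expect_identical(unname(withad), paste0(reads$seq[1:3], "AGATCGGAAG"))
})
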