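# Shared fixtures: all built in code at test time.

# Write a FASTA file from named sequences; returns the path.
write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".fa"),
                                wrap = NULL) {
  lines <- character()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    if (!is.null(wrap)) {
      starts <- seq(1L, nchar(s), by = wrap)
      s <- substring(s, starts, pmin(starts + wrap - 1L, nchar(s)))
    }
    lines <- c(lines, paste0(">", id), s)
  }
  writeLines(lines, path)
  path
}

# Independent matcher oracle: scan every start position of every half and
# compare the substring directly. Handles overlapping occurrences, which
# regex-based scans would miss.
naive_match <- function(seq, halves) {
  out <- list()
  L <- nchar(seq)
  for (i in seq_len(nrow(halves))) {
    h <- halves$seq[i]
    if (L > nchar(h) || L < 1L) next
    offs <- 0:(nchar(h) - L)
    ok <- substring(h, offs + 1L, offs + L) == seq
    for (o in offs[ok]) {
      out[[length(out) + 1L]] <- data.frame(
        parent_id = halves$parent_id[i], side = halves$side[i],
        offset = halves$start[i] + o, length = L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      parent_id = character(), side = character(),
      offset = integer(), length = integer(), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$parent_id, match(res$side, c("5p", "3p")), res$offset), ]
  rownames(res) <- NULL
  res
}

# A small deterministic synthetic reference shared across tests.
test_reference <- function(seed = 11L) {
  generate_reference_set(
    lengths = c(112L, 101L, 93L, 83L), stem_len = 10L,
    seed = seed, ids = c("hY1", "hY3", "hY4", "hY5")
  )
}

# One fragment class with degenerate or simple distributions.
simple_class <- function(parent_id, fraction = 0.8, start = c("0" = 1),
                         lengths = c("30" = 1),
                         five = "P", three = "OMe") {
  fragment_class(parent_id, fraction,
    start_prob = start, length_prob = lengths,
    states = data.frame(five = five, three = three, prob = 1)
  )
}

# Reads data.frame with explicit terminal states, for operator tests.
make_reads <- function(seqs, five, three, parent = "hY1", start = 0L) {
  df <- data.frame(
    read_id = sprintf("t%03d", seq_along(seqs)), seq = seqs,
    parent = parent, start = start, five_prime = five, three_prime = three,
    stringsAsFactors = FALSE
  )
  class(df) <- c("ysrna_reads", "data.frame")
  df
}
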