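#' Trim a 3' sequencing adapter from reads
#'
#' A read is truncated at the first occurrence of the full adapter; if the
#' full adapter is absent, the longest adapter prefix of at least
#' `min_overlap` nt found at the read's 3' end is removed. Reads without
#' any qualifying match are returned unchanged.
#'
#' @param seqs Character vector of read sequences.
#' @param adapter Adapter sequence (at least `min_overlap` nt).
#' @param min_overlap Minimum adapter prefix length recognised at the 3'
#'   end (nt).
#' @return Character vector of trimmed sequences.
#' @export
trim_adapter <- function(seqs, adapter, min_overlap = 6L) {
  stopifnot(
    is.character(adapter), length(adapter) == 1L,
    nchar(adapter) >= min_overlap
  )
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  hit <- pos > 0L
  seqs[hit] <- substr(seqs[hit], 1L, pos[hit] - 1L)
  # Partial adapter prefix flush with the 3' end, longest overlap first.
  k_max <- min(nchar(adapter) - 1L, max(nchar(seqs), 0L))
  if (k_max >= min_overlap) {
    for (k in k_max:min_overlap) {
      pref <- substr(adapter, 1L, k)
      part <- !hit & endsWith(seqs, pref)
      seqs[part] <- substr(seqs[part], 1L, nchar(seqs[part]) - k)
      hit <- hit | part
    }
  }
  seqs
}

#' Quantify an in-memory set of reads against the split-half index
#'
#' The core counting engine behind [quantify_library()]. Reads are length
#' filtered to `[min_len, max_len]`; each exact full-read containment of a
#' read in a reference half increments the (parent, side, length, offset)
#' cell it occurs at, so a read matching several halves increments every
#' matching cell. Counts are normalised to reads per million (RPM) of the
#' supplied alignable-read denominator.
#'
#' @param seqs Character vector of (already trimmed) read sequences.
#' @param index A `ysrna_index` from [build_match_index()].
#' @param denominator Alignable-read count of the library (> 0); for real
#'   data the external genome-alignment count, for simulations typically
#'   the number of generated reads.
#' @param sample_id,treatment Metadata carried on the result.
#' @param min_len,max_len Read-length window (nt); `min_len` may not be
#'   below the index's `min_len`.
#' @return A data.frame of class `ysrna_counts` with columns `parent_id`,
#'   `side`, `length`, `offset` (0-based in the full parent), `raw`,
#'   `rpm`, plus attributes `sample_id`, `treatment`, `denominator`,
#'   `min_len`, `max_len`, `parents`, `n_reads`, `n_in_window`,
#'   `n_matched`.
#' @export
quantify_reads <- function(seqs, index, denominator, sample_id = "sample",
                           treatment = "NONE", min_len = 20L, max_len = 50L) {
  stopifnot(inherits(index, "ysrna_index"))
  if (!is.numeric(denominator) || length(denominator) != 1L || denominator <= 0) {
    stop("denominator must be a single positive number")
  }
  treatment <- match.arg(treatment, TREATMENTS)
  if (min_len < index$min_len) {
    stop(
      "min_len (", min_len, ") below the index minimum (", index$min_len,
      "); rebuild the index"
    )
  }
  len <- nchar(seqs)
  inwin <- len >= min_len & len <= max_len
  kept <- seqs[inwin]

  tab <- index$table
  if (length(kept)) {
    mi <- match(kept, index$useq)
    per_useq <- tabulate(mi[!is.na(mi)], nbins = length(index$useq))
    hit_u <- which(per_useq > 0L)
    rows <- as.integer(unlist(index$groups[hit_u], use.names = FALSE))
    cells <- tab[rows, c("parent_id", "side", "offset", "length")]
    cells$raw <- rep(per_useq[hit_u], lengths(index$groups[hit_u]))
    cells <- cells[order(rows), , drop = FALSE] # restore index-table order
    n_matched <- sum(per_useq)
  } else {
    cells <- tab[0L, c("parent_id", "side", "offset", "length")]
    cells$raw <- integer()
    n_matched <- 0L
  }
  cells$rpm <- cells$raw * 1e6 / denominator
  rownames(cells) <- NULL
  structure(
    cells,
    class = c("ysrna_counts", "data.frame"),
    sample_id = sample_id, treatment = treatment,
    denominator = denominator,
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    parents = index$parents,
    n_reads = length(seqs), n_in_window = sum(inwin),
    n_matched = as.integer(n_matched)
  )
}

#' Quantify a FASTQ library against the split-half reference
#'
#' Reads the FASTQ, optionally trims a 3' adapter, then counts exact
#' full-read hits with [quantify_reads()]. Filter-gate counts (reads in,
#' in the length window, matched) are reported via `message()` and stored
#' as attributes on the result.
#'
#' @inheritParams quantify_reads
#' @param fastq_path Path to a (4-line-record) FASTQ file.
#' @param adapter Optional 3' adapter to trim before matching.
#' @param verbose Emit the filter-gate summary message.
#' @return A `ysrna_counts` table (see [quantify_reads()]).
#' @export
quantify_library <- function(fastq_path, index, denominator,
                             sample_id = sub("\\.f(ast)?q$", "", basename(fastq_path)),
                             treatment = "NONE", min_len = 20L, max_len = 50L,
                             adapter = NULL, verbose = FALSE) {
  if (!file.exists(fastq_path)) {
    stop("FASTQ not found: ", fastq_path)
  }
  seqs <- read_fastq_seqs(fastq_path)
  if (!is.null(adapter)) {
    seqs <- trim_adapter(seqs, adapter)
  }
  counts <- quantify_reads(seqs, index, denominator,
    sample_id = sample_id,
    treatment = treatment, min_len = min_len, max_len = max_len
  )
  if (verbose) {
    message(sprintf(
      "%s [%s]: %d reads in, %d in [%d,%d] nt, %d matched (%d cells)",
      sample_id, treatment, attr(counts, "n_reads"),
      attr(counts, "n_in_window"), min_len, max_len,
      attr(counts, "n_matched"), nrow(counts)
    ))
  }
  counts
}

read_fastq_seqs <- function(fastq_path) {
  if (file.size(fastq_path) == 0L) {
    return(character())
  }
  set <- Biostrings::readDNAStringSet(fastq_path, format = "fastq")
  as.character(set)
}

#' Aggregate a count table per (parent, side)
#'
#' @param counts A `ysrna_counts` table.
#' @return data.frame `parent_id`, `side`, `rpm` over the full
#'   parent-by-side grid of the reference (zeros filled in).
#' @export
aggregate_rpm <- function(counts) {
  stopifnot(inherits(counts, "ysrna_counts"))
  grid <- expand.grid(
    parent_id = attr(counts, "parents"), side = SIDES,
    stringsAsFactors = FALSE
  )
  if (nrow(counts)) {
    ag <- stats::aggregate(rpm ~ parent_id + side, data = counts, FUN = sum)
    grid <- merge(grid, ag, by = c("parent_id", "side"), all.x = TRUE)
    grid$rpm[is.na(grid$rpm)] <- 0
  } else {
    grid$rpm <- 0
  }
  grid <- grid[order(match(grid$parent_id, attr(counts, "parents")),
    match(grid$side, SIDES)), ]
  rownames(grid) <- NULL
  grid
}

#' Length profile of one (parent, side) fragment class
#'
#' RPM summed over start offsets per read length; lengths in the
#' quantification window with no hits map to 0.
#'
#' @param counts A `ysrna_counts` table.
#' @param parent_id,side The fragment class (side `"5p"` or `"3p"`).
#' @return Named numeric vector over `min_len:max_len` (names are lengths
#'   in nt).
#' @export
length_profile <- function(counts, parent_id, side) {
  stopifnot(inherits(counts, "ysrna_counts"))
  if (!parent_id %in% attr(counts, "parents")) {
    stop("unknown parent_id: ", parent_id)
  }
  side <- match.arg(side, SIDES)
  lens <- attr(counts, "min_len"):attr(counts, "max_len")
  prof <- stats::setNames(numeric(length(lens)), lens)
  sel <- counts$parent_id == parent_id & counts$side == side
  if (any(sel)) {
    sums <- tapply(counts$rpm[sel], counts$length[sel], sum)
    prof[names(sums)] <- sums
  }
  prof
}

#' @export
print.ysrna_counts <- function(x, ...) {
  cat(sprintf(
    "YsRNA count table '%s' (treatment %s)\n",
    attr(x, "sample_id"), attr(x, "treatment")
  ))
  cat(sprintf(
    "  %d reads in, %d in window, %d matched; denominator %g\n",
    attr(x, "n_reads"), attr(x, "n_in_window"), attr(x, "n_matched"),
    attr(x, "denominator")
  ))
  ag <- aggregate_rpm(x)
  cat("  aggregate RPM per (parent, side):\n")
  for (i in seq_len(nrow(ag))) {
    cat(sprintf("    %-8s %-3s %10.2f\n", ag$parent_id[i], ag$side[i], ag$rpm[i]))
  }
  invisible(x)
}

#' Write / read a count table as TSV
#'
#' The TSV has columns `sample`, `treatment`, `parent`, `side`, `length`,
#' `offset`, `raw`, `rpm`; library metadata (sample id, treatment,
#' denominator, length window, reference parents) is stored in `#`
#' comment header lines so an empty table round-trips losslessly.
#'
#' @param counts A `ysrna_counts` table.
#' @param path TSV path.
#' @return `write_counts()`: `path` invisibly; `read_counts()`: the
#'   restored `ysrna_counts`.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "ysrna_counts"))
  hdr <- c(
    sprintf(
      "# sample_id=%s treatment=%s denominator=%.10g min_len=%d max_len=%d",
      attr(counts, "sample_id"), attr(counts, "treatment"),
      attr(counts, "denominator"), attr(counts, "min_len"),
      attr(counts, "max_len")
    ),
    sprintf("# parents=%s", paste(attr(counts, "parents"), collapse = ","))
  )
  n <- nrow(counts)
  out <- data.frame(
    sample = rep(attr(counts, "sample_id"), n),
    treatment = rep(attr(counts, "treatment"), n),
    parent = counts$parent_id, side = counts$side, length = counts$length,
    offset = counts$offset, raw = counts$raw, rpm = counts$rpm,
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- regmatches(hdr[1], gregexpr("[a-z_]+=[^ ]+", hdr[1]))[[1]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, `[`, character(1), 2L),
    vapply(kv, `[`, character(1), 1L)
  )
  parents <- strsplit(sub("^# parents=", "", hdr[2]), ",", fixed = TRUE)[[1]]
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  cells <- data.frame(
    parent_id = as.character(df$parent), side = as.character(df$side),
    offset = as.integer(df$offset), length = as.integer(df$length),
    raw = as.integer(df$raw), rpm = as.numeric(df$rpm),
    stringsAsFactors = FALSE
  )[, c("parent_id", "side", "offset", "length", "raw", "rpm")]
  structure(
    cells,
    class = c("ysrna_counts", "data.frame"),
    sample_id = unname(vals["sample_id"]),
    treatment = unname(vals["treatment"]),
    denominator = as.numeric(vals["denominator"]),
    min_len = as.integer(vals["min_len"]),
    max_len = as.integer(vals["max_len"]),
    parents = parents,
    n_reads = NA_integer_, n_in_window = NA_integer_,
    n_matched = as.integer(if (nrow(cells)) NA else 0L)
  )
}
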