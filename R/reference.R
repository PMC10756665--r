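#' Load a YRNA homolog reference from FASTA
#'
#' Reads one sequence per FASTA record, uppercases it, and converts U to T
#' so references retrieved as RNA match the DNA alphabet of sequencing
#' reads. Record ids are taken as the first whitespace-delimited token of
#' each header.
#'
#' @param fasta_path Path to a (multi-record, wrapped or unwrapped) FASTA
#'   file.
#' @return A data.frame of class `ysrna_reference` with columns `id`,
#'   `seq`, `length`.
#' @examples
#' ref <- load_reference(ysrna_synthetic_fasta())
#' ref$length
#' @export
load_reference <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("reference FASTA not found: ", fasta_path)
  }
  # BStringSet first: RNA records and lowercase are normalised here rather
  # than rejected by the DNA alphabet check of the parser.
  set <- Biostrings::readBStringSet(fasta_path, format = "fasta")
  if (length(set) == 0L) {
    stop("reference FASTA contains no records: ", fasta_path)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(
      "duplicate reference ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop(
      "non-nucleotide characters in reference record(s): ",
      paste(ids[bad], collapse = ", ")
    )
  }
  if (any(nchar(seqs) < 2L)) {
    stop("reference sequences must be at least 2 nt")
  }
  ref <- data.frame(
    id = ids, seq = unname(seqs), length = nchar(seqs),
    stringsAsFactors = FALSE
  )
  class(ref) <- c("ysrna_reference", "data.frame")
  ref
}

#' Path to the packaged synthetic YRNA stand-in reference
#'
#' Four synthetic sequences named hY1/hY3/hY4/hY5 with the lengths of the
#' human homologs (112, 101, 93 and 83 nt) and a 10-nt terminal stem
#' (the last 10 bases are the reverse complement of the first 10). They are
#' SYNTHETIC stand-ins, not the NCBI sequences: use them for simulation and
#' testing, and supply real homolog FASTA for real data.
#'
#' @return File path of `yrna_synthetic.fa` inside the installed package.
#' @export
ysrna_synthetic_fasta <- function() {
  system.file("extdata", "yrna_synthetic.fa", package = "ysrna", mustWork = TRUE)
}

#' Split a reference sequence into its 5' and 3' halves
#'
#' The split point is `ceiling(length / 2)`, so the 5' half is never
#' shorter than the 3' half and the two halves tile the source exactly.
#' Splitting each homolog before matching prevents the terminal stem
#' complementarity of full-length YRNA from producing redundant hits.
#'
#' @param ref A `ysrna_reference` (or any data.frame with `id`, `seq`).
#' @return A data.frame of class `ysrna_halves` with one row per half:
#'   `parent_id`, `side` (`"5p"`/`"3p"`), `start`, `end` (0-based,
#'   half-open in the parent), `seq`.
#' @examples
#' halves <- split_halves(load_reference(ysrna_synthetic_fasta()))
#' subset(halves, parent_id == "hY3")[, c("side", "start", "end")]
#' @export
split_halves <- function(ref) {
  stopifnot(is.data.frame(ref), all(c("id", "seq") %in% names(ref)))
  len <- nchar(ref$seq)
  if (any(len < 2L)) {
    stop("cannot split sequences shorter than 2 nt")
  }
  s <- ceiling(len / 2)
  halves <- data.frame(
    parent_id = rep(ref$id, each = 2L),
    side = rep(SIDES, times = nrow(ref)),
    start = as.vector(rbind(0L, s)),
    end = as.vector(rbind(s, len)),
    stringsAsFactors = FALSE
  )
  parent_seq <- rep(ref$seq, each = 2L)
  halves$seq <- substr(parent_seq, halves$start + 1L, halves$end)
  class(halves) <- c("ysrna_halves", "data.frame")
  halves
}

#' Build an exact-match index over the split halves
#'
#' Enumerates every substring of every half with length between `min_len`
#' and the half length, keyed by sequence, so that a read is matched by a
#' single hash lookup. Matching is strand-specific (forward only) and
#' requires the full read to be contained in a half; this emulates a
#' 100%-identity search restricted to full-read hits.
#'
#' @param ref A `ysrna_reference` as returned by [load_reference()] or
#'   [generate_reference_set()].
#' @param min_len Smallest query length the index answers (nt).
#' @return An object of class `ysrna_index` with elements `halves` (the
#'   [split_halves()] table), `table` (one row per (substring, position)
#'   occurrence with columns `seq`, `parent_id`, `side`, `offset` in
#'   full-parent 0-based coordinates, `length`), `parents`, `min_len`.
#' @export
build_match_index <- function(ref, min_len = 20L) {
  stopifnot(is.data.frame(ref), nrow(ref) >= 1L, min_len >= 1L)
  halves <- split_halves(ref)
  pieces <- vector("list", nrow(halves))
  for (i in seq_len(nrow(halves))) {
    hseq <- halves$seq[i]
    hlen <- nchar(hseq)
    if (hlen < min_len) next
    lens <- min_len:hlen
    n_per <- hlen - lens + 1L
    length_col <- rep(lens, n_per)
    off_in_half <- unlist(lapply(n_per, function(n) 0L:(n - 1L)), use.names = FALSE)
    pieces[[i]] <- data.frame(
      seq = substring(hseq, off_in_half + 1L, off_in_half + length_col),
      parent_id = halves$parent_id[i],
      side = halves$side[i],
      offset = halves$start[i] + off_in_half,
      length = length_col,
      stringsAsFactors = FALSE
    )
  }
  table <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  ord <- order(table$parent_id, match(table$side, SIDES), table$offset, table$length)
  table <- table[ord, , drop = FALSE]
  rownames(table) <- NULL
  # Group occurrence rows by substring so bulk queries are one hash lookup
  # per read (a substring shared between halves owns several rows).
  groups <- split(seq_len(nrow(table)), table$seq)
  structure(
    list(
      halves = halves, table = table,
      useq = names(groups), groups = unname(groups),
      parents = ref$id, min_len = as.integer(min_len)
    ),
    class = "ysrna_index"
  )
}

#' Find all exact full-read hits of a sequence in the reference halves
#'
#' @param seq A single read sequence (character).
#' @param index A `ysrna_index`.
#' @return A data.frame with one row per occurrence (`parent_id`, `side`,
#'   `offset` in full-parent 0-based coordinates, `length`), sorted by
#'   (parent, side, offset). Zero rows if the read hits nothing or is
#'   shorter than the index `min_len`.
#' @examples
#' ref <- load_reference(ysrna_synthetic_fasta())
#' idx <- build_match_index(ref)
#' match_read(substr(ref$seq[1], 1, 30), idx)
#' @export
match_read <- function(seq, index) {
  stopifnot(inherits(index, "ysrna_index"), is.character(seq), length(seq) == 1L)
  hits <- index$table[index$table$seq == seq, c("parent_id", "side", "offset", "length")]
  rownames(hits) <- NULL
  hits
}

#' @export
print.ysrna_reference <- function(x, ...) {
  cat("YRNA reference:", nrow(x), "homolog(s)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-6s %4d nt\n", x$id[i], x$length[i]))
  }
  invisible(x)
}

#' @export
print.ysrna_index <- function(x, ...) {
  cat(
    "Exact-match index:", length(x$parents), "parent(s),",
    nrow(x$halves), "halves,", nrow(x$table), "indexed substrings",
    sprintf("(min length %d nt)\n", x$min_len)
  )
  invisible(x)
}

#' Export the split-half table as TSV
#'
#' @param halves A `ysrna_halves` table (or a `ysrna_index`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_halves <- function(halves, path) {
  if (inherits(halves, "ysrna_index")) halves <- halves$halves
  utils::write.table(
    halves[, c("parent_id", "side", "start", "end", "seq")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
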