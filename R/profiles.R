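#' Assemble a multi-sample profile matrix
#'
#' One row per sample, one column per (parent, side) class, entries are
#' aggregate RPM. This is the tabulation behind tissue-contrast bar
#' charts (sperm head vs oocyte, sperm head vs exosome, epididymis
#' regions).
#'
#' @param tables List of `ysrna_counts` tables sharing a reference.
#' @param labels Optional character vector of tissue labels, recycled to
#'   the number of samples; stored as attribute `tissue`.
#' @return Numeric matrix of class `ysrna_profile` with rownames = sample
#'   ids and colnames `"<parent>_<side>"`.
#' @export
build_profile_matrix <- function(tables, labels = NULL) {
  stopifnot(length(tables) >= 1L)
  parents <- attr(tables[[1]], "parents")
  for (t in tables) {
    stopifnot(inherits(t, "ysrna_counts"))
    if (!identical(attr(t, "parents"), parents)) {
      stop("count tables quantified against different references")
    }
  }
  rows <- lapply(tables, function(t) {
    ag <- aggregate_rpm(t)
    stats::setNames(ag$rpm, paste(ag$parent_id, ag$side, sep = "_"))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(tables, attr, character(1), "sample_id")
  if (!is.null(labels)) {
    labels <- rep_len(labels, nrow(mat))
  }
  structure(mat, class = c("ysrna_profile", class(mat)), tissue = labels)
}

#' Ratio between two homologs' abundances in one profile row
#'
#' @param row Named numeric vector (one row of a [build_profile_matrix()]
#'   result, or any named RPM vector with `"<parent>_<side>"` names).
#' @param numerator_parent,denominator_parent Parent ids.
#' @param side `"5p"` or `"3p"`.
#' @return The RPM ratio, or `NA` (insufficient data) when the denominator
#'   RPM is zero.
#' @export
homolog_ratio <- function(row, numerator_parent, denominator_parent,
                          side = "5p") {
  side <- match.arg(side, SIDES)
  nm_num <- paste(numerator_parent, side, sep = "_")
  nm_den <- paste(denominator_parent, side, sep = "_")
  if (!all(c(nm_num, nm_den) %in% names(row))) {
    stop("unknown parent/side column")
  }
  num <- row[[nm_num]]
  den <- row[[nm_den]]
  if (den <= 0) {
    return(NA_real_)
  }
  num / den
}

#' Compare two profile rows
#'
#' Cosine similarity (in \[0, 1\] for non-negative profiles; 1 for
#' proportional profiles, 0 for disjoint support) and Spearman rank
#' correlation, as scale-free summaries of profile shape.
#'
#' @param row_a,row_b Numeric vectors of equal length; neither may be
#'   all-zero.
#' @return List with elements `cosine` and `spearman`.
#' @export
compare_profiles <- function(row_a, row_b) {
  row_a <- as.numeric(row_a)
  row_b <- as.numeric(row_b)
  if (length(row_a) != length(row_b)) {
    stop("profiles must have the same length")
  }
  na <- sqrt(sum(row_a^2))
  nb <- sqrt(sum(row_b^2))
  if (na == 0 || nb == 0) {
    stop("cannot compare an all-zero profile")
  }
  list(
    cosine = sum(row_a * row_b) / (na * nb),
    spearman = suppressWarnings(stats::cor(row_a, row_b, method = "spearman"))
  )
}

#' @export
print.ysrna_profile <- function(x, ...) {
  cat("YsRNA profile matrix:", nrow(x), "sample(s) x", ncol(x), "class(es)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Barplot of a profile matrix
#'
#' Grouped bars per (parent, side) class, one bar colour per sample,
#' mirroring the layout of per-tissue YsRNA bar charts.
#'
#' @param x A `ysrna_profile` matrix.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.ysrna_profile <- function(x, ...) {
  mids <- graphics::barplot(unclass(x),
    beside = TRUE, las = 2,
    legend.text = rownames(x), ylab = "RPM of alignable reads", ...
  )
  invisible(mids)
}

#' Export a profile matrix as long-format TSV
#'
#' Columns `sample`, `tissue`, `parent`, `side`, `rpm` - one row per
#' (sample, class) cell, ready for any downstream statistics package.
#'
#' @param mat A `ysrna_profile` matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_long <- function(mat, path) {
  stopifnot(inherits(mat, "ysrna_profile"))
  tissue <- attr(mat, "tissue")
  if (is.null(tissue)) tissue <- rep(NA_character_, nrow(mat))
  ps <- strsplit(colnames(mat), "_(?=[53]p$)", perl = TRUE)
  long <- data.frame(
    sample = rep(rownames(mat), times = ncol(mat)),
    tissue = rep(tissue, times = ncol(mat)),
    parent = rep(vapply(ps, `[`, character(1), 1L), each = nrow(mat)),
    side = rep(vapply(ps, `[`, character(1), 2L), each = nrow(mat)),
    rpm = as.vector(mat),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
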