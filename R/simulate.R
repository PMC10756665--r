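#' Generate a synthetic YRNA-like reference set
#'
#' Random sequences whose last `stem_len` bases are the reverse complement
#' of their first `stem_len` bases, reproducing the terminal stem of real
#' YRNA. The stem is what makes split-half matching necessary in the first
#' place: without the split, a 5'-end fragment could also hit the reverse
#' complement embedded at the 3' end.
#'
#' @param lengths Integer vector of source lengths (nt); defaults to the
#'   human homolog lengths 112/101/93/83.
#' @param stem_len Length of the complementary terminal stem (nt).
#' @param seed Optional integer seed; identical seeds give identical sets.
#' @param ids Sequence names; defaults to `synY1`, `synY2`, ...
#' @return A `ysrna_reference` data.frame (`id`, `seq`, `length`).
#' @export
generate_reference_set <- function(lengths = c(112L, 101L, 93L, 83L),
                                   stem_len = 10L, seed = NULL,
                                   ids = paste0("synY", seq_along(lengths))) {
  stopifnot(length(ids) == length(lengths), stem_len >= 0L)
  if (any(lengths <= 2L * stem_len)) {
    stop("each source length must exceed twice the stem length")
  }
  seqs <- with_seed(seed, {
    vapply(lengths, function(L) {
      body <- paste(sample(c("A", "C", "G", "T"), L - stem_len, replace = TRUE),
        collapse = ""
      )
      if (stem_len == 0L) {
        return(body)
      }
      stem5 <- substr(body, 1L, stem_len)
      paste0(body, revcomp(stem5))
    }, character(1))
  })
  ref <- data.frame(
    id = ids, seq = seqs, length = nchar(seqs),
    stringsAsFactors = FALSE
  )
  class(ref) <- c("ysrna_reference", "data.frame")
  ref
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Describe one simulated fragment class
#'
#' A fragment class is a population of reads cut from one reference parent
#' with a start-offset distribution, a length distribution supported on
#' 25-35 nt (the YsRNA size class), a distribution over terminal-chemistry
#' states, and an abundance fraction of the library.
#'
#' @param parent_id Reference sequence the fragments derive from.
#' @param fraction Proportion of the library drawn from this class.
#' @param start_prob Named numeric: probability per 0-based start offset,
#'   e.g. `c("0" = 0.8, "1" = 0.2)` (fragments begin at the first or
#'   second base of the source).
#' @param length_prob Named numeric: probability per fragment length (nt);
#'   all lengths must lie in 25-35.
#' @param states data.frame with columns `five` (one of
#'   [FIVE_PRIME_STATES]), `three` (one of [THREE_PRIME_STATES]) and
#'   `prob`.
#' @return An object of class `ysrna_class`.
#' @export
fragment_class <- function(parent_id, fraction, start_prob, length_prob, states) {
  stopifnot(
    is.character(parent_id), length(parent_id) == 1L,
    fraction >= 0, fraction <= 1,
    is.numeric(start_prob), !is.null(names(start_prob)),
    is.numeric(length_prob), !is.null(names(length_prob)),
    is.data.frame(states), all(c("five", "three", "prob") %in% names(states))
  )
  check_dist <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(what, " probabilities must be non-negative and sum to 1")
    }
  }
  check_dist(start_prob, "start")
  check_dist(length_prob, "length")
  check_dist(states$prob, "state")
  lens <- as.integer(names(length_prob))
  if (any(is.na(lens)) || any(lens < 25L) || any(lens > 35L)) {
    stop("fragment lengths must lie in [25, 35] nt")
  }
  if (!all(states$five %in% FIVE_PRIME_STATES) ||
    !all(states$three %in% THREE_PRIME_STATES)) {
    stop("unknown terminal state code")
  }
  structure(
    list(
      parent_id = parent_id, fraction = fraction,
      start_prob = start_prob, length_prob = length_prob,
      states = states
    ),
    class = "ysrna_class"
  )
}

#' Peaked discrete length distribution on the YsRNA size range
#'
#' Probabilities proportional to a Gaussian density at integer lengths,
#' truncated to the support; a convenient way to model the unimodal length
#' profiles of YsRNA classes.
#'
#' @param mode Modal length (nt).
#' @param sd Spread of the peak (nt).
#' @param support Integer lengths carrying mass.
#' @return Named probability vector.
#' @export
peaked_length_prob <- function(mode, sd = 1.5, support = 25:35) {
  p <- stats::dnorm(support, mean = mode, sd = sd)
  stats::setNames(p / sum(p), support)
}

#' Default truth configurations
#'
#' `sperm_head_config()` encodes the qualitative sperm-head picture: Ys1
#' fragments start mostly at the first base with modal length 30 nt, Ys3
#' mostly at the second base with modal length 31 nt, both carrying a
#' canonical 5' monophosphate and a 2'-O-methylated (periodate-protected)
#' 3' end; Ys4 is a mixture of that piRNA-like state and a 5'-triphosphate
#' species; Ys5 is purely 5'-triphosphorylated with an unprotected 3' end,
#' so it only becomes visible after RppH. `oocyte_config()` has all classes
#' with unprotected 3' ends (they vanish after oxidation/beta-elimination),
#' Ys3 dominant and Ys1 nearly absent, with modal lengths 31-32 nt.
#'
#' @param parents Parent ids used by the four classes, in homolog order
#'   (Ys1, Ys3, Ys4, Ys5).
#' @return A list with elements `classes` (list of [fragment_class()]) and
#'   `background_fraction`.
#' @export
sperm_head_config <- function(parents = c("hY1", "hY3", "hY4", "hY5")) {
  stopifnot(length(parents) == 4L)
  pi_like <- data.frame(five = "P", three = "OMe", prob = 1)
  list(
    classes = list(
      fragment_class(parents[1], 0.35, c("0" = 0.8, "1" = 0.2),
        peaked_length_prob(30),
        states = pi_like
      ),
      fragment_class(parents[2], 0.20, c("0" = 0.2, "1" = 0.8),
        peaked_length_prob(31),
        states = pi_like
      ),
      fragment_class(parents[3], 0.15, c("0" = 0.7, "1" = 0.3),
        peaked_length_prob(30),
        states = data.frame(
          five = c("P", "PPP"), three = c("OMe", "OH"),
          prob = c(0.4, 0.6)
        )
      ),
      fragment_class(parents[4], 0.10, c("0" = 0.7, "1" = 0.3),
        peaked_length_prob(30),
        states = data.frame(five = "PPP", three = "OH", prob = 1)
      )
    ),
    background_fraction = 0.20
  )
}

#' @rdname sperm_head_config
#' @export
oocyte_config <- function(parents = c("hY1", "hY3", "hY4", "hY5")) {
  stopifnot(length(parents) == 4L)
  unprotected <- data.frame(five = "P", three = "OH", prob = 1)
  list(
    classes = list(
      fragment_class(parents[1], 0.01, c("0" = 0.8, "1" = 0.2),
        peaked_length_prob(31),
        states = unprotected
      ),
      fragment_class(parents[2], 0.40, c("0" = 0.2, "1" = 0.8),
        peaked_length_prob(31),
        states = unprotected
      ),
      fragment_class(parents[3], 0.15, c("0" = 0.7, "1" = 0.3),
        peaked_length_prob(32),
        states = unprotected
      ),
      fragment_class(parents[4], 0.04, c("0" = 0.7, "1" = 0.3),
        peaked_length_prob(31),
        states = unprotected
      )
    ),
    background_fraction = 0.40
  )
}

#' Simulate a pre-treatment small-RNA library with ground truth
#'
#' Each read is drawn by class (by abundance fraction), then start offset,
#' length, and terminal-chemistry state; its sequence is copied verbatim
#' from the parent. Background reads are random sequences rejection-checked
#' against every substring of every reference half, so their truth label
#' (`parent == "background"`) is clean. The output represents the RNA pool
#' BEFORE treatment and library preparation; apply [apply_treatment()] and
#' [ligate_and_select()] to model a sequencing readout.
#'
#' @param ref A `ysrna_reference`.
#' @param classes List of [fragment_class()] objects.
#' @param background_fraction Proportion of non-YRNA reads; class fractions
#'   plus this must sum to 1.
#' @param n_reads Number of reads to draw.
#' @param seed Optional integer seed (identical seeds give identical
#'   libraries).
#' @param bg_len_range Length range of background reads (nt).
#' @param bg_states data.frame(`five`, `three`, `prob`) for background
#'   terminal chemistry; defaults to ligatable 5'-P / 3'-OH degradation
#'   products.
#' @return A data.frame of class `ysrna_reads` with columns `read_id`,
#'   `seq`, `parent` (`"background"` for background reads), `start`
#'   (0-based offset in the parent, `NA` for background), `five_prime`,
#'   `three_prime`.
#' @export
generate_library <- function(ref, classes, background_fraction, n_reads,
                             seed = NULL, bg_len_range = c(20L, 45L),
                             bg_states = data.frame(
                               five = "P", three = "OH",
                               prob = 1
                             )) {
  stopifnot(
    is.data.frame(ref), n_reads >= 0,
    background_fraction >= 0, background_fraction <= 1
  )
  for (cl in classes) {
    if (!inherits(cl, "ysrna_class")) stop("classes must be ysrna_class objects")
    if (!cl$parent_id %in% ref$id) stop("unknown class parent: ", cl$parent_id)
  }
  fractions <- vapply(classes, `[[`, numeric(1), "fraction")
  if (abs(sum(fractions) + background_fraction - 1) > 1e-8) {
    stop("class fractions plus background_fraction must sum to 1")
  }
  empty <- data.frame(
    read_id = character(), seq = character(), parent = character(),
    start = integer(), five_prime = character(), three_prime = character(),
    stringsAsFactors = FALSE
  )
  class(empty) <- c("ysrna_reads", "data.frame")
  if (n_reads == 0L) {
    return(empty)
  }

  # Substring pool of the halves, used to rejection-check background reads.
  bg_min <- max(1L, as.integer(bg_len_range[1]))
  idx <- build_match_index(ref, min_len = bg_min)

  with_seed(seed, {
    k <- length(classes)
    assign_id <- sample.int(k + 1L, n_reads,
      replace = TRUE,
      prob = c(fractions, background_fraction)
    )
    out <- empty[rep(1L, 0L), ]
    parent <- character(n_reads)
    start <- rep(NA_integer_, n_reads)
    seqv <- character(n_reads)
    five <- character(n_reads)
    three <- character(n_reads)

    for (ci in seq_len(k)) {
      cl <- classes[[ci]]
      sel <- which(assign_id == ci)
      if (!length(sel)) next
      pseq <- ref$seq[ref$id == cl$parent_id]
      plen <- nchar(pseq)
      st <- as.integer(sample(names(cl$start_prob), length(sel),
        replace = TRUE, prob = cl$start_prob
      ))
      ln <- as.integer(sample(names(cl$length_prob), length(sel),
        replace = TRUE, prob = cl$length_prob
      ))
      if (any(st + ln > plen)) {
        stop("fragment class for ", cl$parent_id, " extends past the parent end")
      }
      si <- sample.int(nrow(cl$states), length(sel),
        replace = TRUE,
        prob = cl$states$prob
      )
      parent[sel] <- cl$parent_id
      start[sel] <- st
      seqv[sel] <- substring(pseq, st + 1L, st + ln)
      five[sel] <- cl$states$five[si]
      three[sel] <- cl$states$three[si]
    }

    bg <- which(assign_id == k + 1L)
    if (length(bg)) {
      lens <- sample(seq.int(bg_len_range[1], bg_len_range[2]),
        length(bg),
        replace = TRUE
      )
      bseq <- random_seqs(lens)
      # Reject background reads that are exact substrings of any half.
      for (tries in 1:20) {
        clash <- bseq %in% idx$table$seq
        if (!any(clash)) break
        bseq[clash] <- random_seqs(lens[clash])
      }
      if (any(bseq %in% idx$table$seq)) {
        stop("failed to draw background reads distinct from the reference halves")
      }
      bsi <- sample.int(nrow(bg_states), length(bg),
        replace = TRUE,
        prob = bg_states$prob
      )
      parent[bg] <- "background"
      seqv[bg] <- bseq
      five[bg] <- bg_states$five[bsi]
      three[bg] <- bg_states$three[bsi]
    }

    reads <- data.frame(
      read_id = paste0("r", seq_len(n_reads)),
      seq = seqv, parent = parent, start = start,
      five_prime = five, three_prime = three,
      stringsAsFactors = FALSE
    )
    class(reads) <- c("ysrna_reads", "data.frame")
    reads
  })
}

random_seqs <- function(lens) {
  if (!length(lens)) {
    return(character())
  }
  pool <- paste(sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE),
    collapse = ""
  )
  ends <- cumsum(lens)
  substring(pool, ends - lens + 1L, ends)
}

#' Apply a treatment operator to a simulated RNA pool
#'
#' Models the terminal-chemistry consequences of each treatment:
#'
#' * `OXIDATION_BETA_ELIM`: any read with a free 2',3'-diol (3' state `OH`)
#'   loses its 3'-terminal nucleotide and is left with a 3' monophosphate;
#'   2'-O-methylated (`OMe`), monophosphate (`P`) and cyclic-phosphate
#'   (`cP`) ends lack the vicinal diol and are untouched.
#' * `RPPH`: 5' triphosphate (`PPP`) becomes monophosphate (`P`); other 5'
#'   states unchanged.
#' * `PNK`: 3' `P` and `cP` become `OH` (3' phosphatase); 5' `OH` becomes
#'   `P` (kinase); 5' `P` becomes `OH` with probability `p_pnk_5p_dephos`
#'   (net phosphatase/exchange activity), else unchanged.
#' * `PNK_RPPH`: PNK followed by RppH.
#' * `NONE`: identity.
#'
#' Truth fields (`parent`, `start`) are never altered; only oxidation
#' changes a sequence, and only by removing exactly one 3' base.
#'
#' @param reads A `ysrna_reads` data.frame.
#' @param treatment One of [TREATMENTS].
#' @param p_pnk_5p_dephos Per-read probability that PNK removes a 5'
#'   monophosphate.
#' @param seed Optional seed for the PNK dephosphorylation draw.
#' @return The treated `ysrna_reads`.
#' @export
apply_treatment <- function(reads, treatment, p_pnk_5p_dephos = 0.8,
                            seed = NULL) {
  treatment <- match.arg(treatment, TREATMENTS)
  stopifnot(p_pnk_5p_dephos >= 0, p_pnk_5p_dephos <= 1)
  if (treatment == "NONE" || nrow(reads) == 0L) {
    return(reads)
  }
  if (treatment == "OXIDATION_BETA_ELIM") {
    hit <- reads$three_prime == "OH"
    reads$seq[hit] <- substr(reads$seq[hit], 1L, nchar(reads$seq[hit]) - 1L)
    reads$three_prime[hit] <- "P"
    return(reads)
  }
  if (treatment == "RPPH") {
    reads$five_prime[reads$five_prime == "PPP"] <- "P"
    return(reads)
  }
  if (treatment == "PNK") {
    reads$three_prime[reads$three_prime %in% c("P", "cP")] <- "OH"
    was_oh <- reads$five_prime == "OH"
    was_p <- reads$five_prime == "P"
    dephos <- with_seed(seed, stats::runif(nrow(reads)) < p_pnk_5p_dephos)
    reads$five_prime[was_oh] <- "P"
    reads$five_prime[was_p & dephos] <- "OH"
    return(reads)
  }
  # PNK_RPPH: PNK first, then RppH.
  reads <- apply_treatment(reads, "PNK",
    p_pnk_5p_dephos = p_pnk_5p_dephos,
    seed = seed
  )
  apply_treatment(reads, "RPPH")
}

#' Adapter-ligation eligibility and size selection
#'
#' Two-adapter small-RNA library chemistry: a read is sequenced only if it
#' carries a 5' monophosphate (required for 5'-adapter ligation) and a free
#' 3'-OH (3' states `OH` or `OMe`; phosphorylated 3' ends block the 3'
#' adapter), and passes the size-selection cut-off.
#'
#' @param reads A `ysrna_reads` data.frame.
#' @param max_len Size-selection cut-off (nt).
#' @return The retained subset, order preserved.
#' @export
ligate_and_select <- function(reads, max_len = 50L) {
  keep <- reads$five_prime == "P" &
    reads$three_prime %in% c("OH", "OMe") &
    nchar(reads$seq) <= max_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a simulated library as FASTQ plus a truth table
#'
#' FASTQ records carry a constant maximum quality symbol (`I`); qualities
#' are not modeled. The truth TSV records the generator's ground truth per
#' read.
#'
#' @param reads A `ysrna_reads` data.frame (normally after
#'   [ligate_and_select()]).
#' @param fastq_path Output FASTQ path.
#' @param truth_path Output TSV path (columns `read_id`, `parent`, `start`,
#'   `length`, `five_prime`, `three_prime`).
#' @param adapter Optional adapter sequence appended to every read's 3'
#'   end, for exercising adapter trimming; by default reads are emitted
#'   pre-trimmed.
#' @return Invisibly, `c(fastq_path, truth_path)`.
#' @export
write_library <- function(reads, fastq_path, truth_path, adapter = NULL) {
  seqs <- reads$seq
  if (!is.null(adapter)) {
    stopifnot(is.character(adapter), nchar(adapter) > 0L)
    seqs <- paste0(seqs, adapter)
  }
  if (nrow(reads) == 0L) {
    lines <- character()
  } else {
    lines <- as.vector(rbind(
      paste0("@", reads$read_id),
      seqs,
      "+",
      strrep("I", nchar(seqs))
    ))
  }
  writeLines(lines, fastq_path)
  truth <- data.frame(
    read_id = reads$read_id, parent = reads$parent, start = reads$start,
    length = nchar(reads$seq), five_prime = reads$five_prime,
    three_prime = reads$three_prime, stringsAsFactors = FALSE
  )
  utils::write.table(truth, truth_path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(c(fastq_path, truth_path))
}

#' Read a truth table written by [write_library()]
#'
#' @param path Truth TSV path.
#' @return data.frame with the truth columns.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    read_id = "character", parent = "character", start = "integer",
    length = "integer", five_prime = "character", three_prime = "character"
  ))
}
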