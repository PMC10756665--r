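#' Thresholds for terminal-modification calling
#'
#' None of these are measured constants; they are declared working points
#' chosen to separate the qualitative treatment responses ("slightly
#' decreasing" after oxidation vs "completely disappearing"; "markedly
#' reduced" after PNK; a clear RppH gain) with wide margins, and every call
#' records the thresholds it used.
#'
#' @param protected 3' call: oxidation ratio at or above this is
#'   `protected_2OMe`, below is `unprotected`.
#' @param gain 5' call: RppH ratio at or above this calls `triP`.
#' @param loss 5' call: PNK ratio at or below this (with no RppH gain)
#'   calls `monoP`.
#' @param floor Minimum RPM for a ratio denominator (or, for the RppH
#'   gain, the treated RPM) to be considered informative.
#' @return A named list of class `ysrna_thresholds`.
#' @export
ysrna_thresholds <- function(protected = 0.5, gain = 2.0, loss = 0.5,
                             floor = 1.0) {
  stopifnot(protected > 0, gain > 0, loss > 0, floor > 0)
  structure(
    list(protected = protected, gain = gain, loss = loss, floor = floor),
    class = "ysrna_thresholds"
  )
}

#' Ratio of treated to untreated abundance
#'
#' Returns `rpm_treated / rpm_untreated` when the untreated abundance is
#' informative (at least `floor` RPM); otherwise `NA`, the
#' insufficient-data sentinel used throughout the caller.
#'
#' @param rpm_treated,rpm_untreated Aggregate RPM values (vectorised).
#' @param floor Minimum untreated RPM for the ratio to be informative.
#' @return Numeric vector; `NA` where data are insufficient.
#' @export
protection_ratio <- function(rpm_treated, rpm_untreated, floor = 1.0) {
  if (any(rpm_treated < 0, na.rm = TRUE) || any(rpm_untreated < 0, na.rm = TRUE)) {
    stop("RPM values must be non-negative")
  }
  ifelse(!is.na(rpm_treated) & !is.na(rpm_untreated) & rpm_untreated >= floor,
    rpm_treated / rpm_untreated, NA_real_
  )
}

# RppH gain ratio: a genuine 5'-PPP population is invisible untreated, so
# the informative quantity when the untreated RPM is below the floor is the
# treated RPM itself; an appearance from nothing is an infinite gain.
gain_ratio <- function(rpm_rpph, rpm_untreated, floor = 1.0) {
  if (any(rpm_rpph < 0, na.rm = TRUE) || any(rpm_untreated < 0, na.rm = TRUE)) {
    stop("RPM values must be non-negative")
  }
  ifelse(is.na(rpm_rpph) | is.na(rpm_untreated), NA_real_,
    ifelse(rpm_untreated >= floor, rpm_rpph / rpm_untreated,
      ifelse(rpm_rpph >= floor, Inf, NA_real_)
    )
  )
}

#' Call the 3'-terminal state from the oxidation ratio
#'
#' Fragments that persist through periodate oxidation / beta-elimination
#' are protected by a 3' 2'-O-methyl group; fragments with a free
#' 2',3'-diol are destroyed and vanish from the library.
#'
#' @param ox_ratio Oxidised / untreated RPM ratio ([protection_ratio()]);
#'   `NA` means insufficient data.
#' @param protected_threshold Ratio at or above which the class is called
#'   protected.
#' @return Character vector over `"protected_2OMe"`, `"unprotected"`,
#'   `"insufficient_data"`.
#' @export
call_three_prime <- function(ox_ratio, protected_threshold = 0.5) {
  ifelse(is.na(ox_ratio), "insufficient_data",
    ifelse(ox_ratio >= protected_threshold, "protected_2OMe", "unprotected")
  )
}

#' Call the 5'-terminal state from the PNK and RppH ratios
#'
#' An RppH gain at or above `gain_threshold` calls a 5' triphosphate (the
#' gain rule wins when both fire, because a genuine 5'-PPP population is
#' invisible untreated, making the gain the stronger signal). Otherwise a
#' PNK loss at or below `loss_threshold` calls a canonical 5'
#' monophosphate. Anything else - including a missing PNK or RppH library -
#' is insufficient data.
#'
#' @param pnk_ratio PNK-treated / untreated RPM ratio (`NA` = missing).
#' @param rpph_ratio RppH-treated / untreated RPM ratio; may be `Inf` when
#'   the class appears only after RppH.
#' @param gain_threshold,loss_threshold Decision thresholds.
#' @return Character vector over `"monoP"`, `"triP"`,
#'   `"insufficient_data"`.
#' @export
call_five_prime <- function(pnk_ratio, rpph_ratio, gain_threshold = 2.0,
                            loss_threshold = 0.5) {
  ifelse(!is.na(rpph_ratio) & rpph_ratio >= gain_threshold, "triP",
    ifelse(
      !is.na(pnk_ratio) & !is.na(rpph_ratio) &
        pnk_ratio <= loss_threshold & rpph_ratio < gain_threshold,
      "monoP", "insufficient_data"
    )
  )
}

#' Assemble per-class treatment panels from count tables
#'
#' @param tables List of `ysrna_counts` tables, each tagged with its
#'   treatment (attribute set by [quantify_reads()]); the untreated
#'   (`NONE`) table is mandatory and all tables must share a reference.
#' @return data.frame of class `ysrna_panel`: one row per (parent, side)
#'   class with one aggregate-RPM column per treatment present (`NONE`,
#'   and any of `OXIDATION_BETA_ELIM`, `PNK`, `RPPH`, `PNK_RPPH`).
#' @export
build_treatment_panels <- function(tables) {
  stopifnot(length(tables) >= 1L)
  trts <- vapply(tables, attr, character(1), "treatment")
  if (anyDuplicated(trts)) {
    stop("multiple tables share a treatment label: ", trts[duplicated(trts)][1])
  }
  if (!"NONE" %in% trts) {
    stop("an untreated (NONE) library is required")
  }
  parents <- attr(tables[[1]], "parents")
  for (t in tables) {
    if (!identical(attr(t, "parents"), parents)) {
      stop("count tables quantified against different references")
    }
  }
  panel <- aggregate_rpm(tables[[1]])[, c("parent_id", "side")]
  for (i in order(match(trts, TREATMENTS))) {
    panel[[trts[i]]] <- aggregate_rpm(tables[[i]])$rpm
  }
  class(panel) <- c("ysrna_panel", "data.frame")
  panel
}

#' Infer terminal modifications per fragment class
#'
#' Converts a treatment panel (aggregate RPM per (parent, side) class for
#' untreated and treated aliquots of the same RNA) into categorical 5' and
#' 3' terminal calls with the supporting ratios.
#'
#' @param panel A `ysrna_panel` from [build_treatment_panels()], or a list
#'   of `ysrna_counts` tables which is passed through it.
#' @param thresholds A [ysrna_thresholds()] object.
#' @return data.frame of class `ysrna_calls`: `parent_id`, `side`,
#'   `rpm_none`, `ox_ratio`, `pnk_ratio`, `rpph_ratio`,
#'   `three_prime_call`, `five_prime_call`; the thresholds used are
#'   attached as attribute `thresholds`.
#' @examples
#' panel <- data.frame(
#'   parent_id = "hY1", side = "5p",
#'   NONE = 100, OXIDATION_BETA_ELIM = 90, PNK = 30, RPPH = 100
#' )
#' class(panel) <- c("ysrna_panel", "data.frame")
#' run_inference(panel)
#' @export
run_inference <- function(panel, thresholds = ysrna_thresholds()) {
  if (is.list(panel) && !is.data.frame(panel)) {
    panel <- build_treatment_panels(panel)
  }
  stopifnot(inherits(panel, "ysrna_panel") || is.data.frame(panel))
  if (!"NONE" %in% names(panel)) {
    stop("an untreated (NONE) column is required")
  }
  th <- thresholds
  get_col <- function(nm) {
    if (nm %in% names(panel)) panel[[nm]] else rep(NA_real_, nrow(panel))
  }
  none <- panel$NONE
  ox <- protection_ratio(get_col("OXIDATION_BETA_ELIM"), none, floor = th$floor)
  pnk <- protection_ratio(get_col("PNK"), none, floor = th$floor)
  rpph <- gain_ratio(get_col("RPPH"), none, floor = th$floor)
  calls <- data.frame(
    parent_id = panel$parent_id, side = panel$side,
    rpm_none = none, ox_ratio = ox, pnk_ratio = pnk, rpph_ratio = rpph,
    three_prime_call = call_three_prime(ox, th$protected),
    five_prime_call = call_five_prime(pnk, rpph,
      gain_threshold = th$gain,
      loss_threshold = th$loss
    ),
    stringsAsFactors = FALSE
  )
  structure(calls,
    class = c("ysrna_calls", "data.frame"),
    thresholds = th
  )
}

#' @export
print.ysrna_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("Terminal-modification calls per fragment class\n")
  cat(sprintf(
    "  thresholds: protected>=%.2g, RppH gain>=%.2g, PNK loss<=%.2g, floor %.2g RPM\n",
    th$protected, th$gain, th$loss, th$floor
  ))
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.3g", v))
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %-8s %-3s  3': %-16s 5': %-16s (ox %s, pnk %s, rpph %s)\n",
      x$parent_id[i], x$side[i], x$three_prime_call[i],
      x$five_prime_call[i], fmt(x$ox_ratio[i]), fmt(x$pnk_ratio[i]),
      fmt(x$rpph_ratio[i])
    ))
  }
  invisible(x)
}

#' Write modification calls as TSV
#'
#' @param calls A `ysrna_calls` table.
#' @param path Output TSV path; thresholds are recorded in a `#` comment
#'   header.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  th <- attr(calls, "thresholds")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# thresholds: protected=%g gain=%g loss=%g floor=%g",
    th$protected, th$gain, th$loss, th$floor
  ), con)
  utils::write.table(as.data.frame(calls), con,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Simulate a full treatment panel and quantify it in memory
#'
#' Generates one pre-treatment read pool (aliquots of the same RNA), applies
#' each requested treatment to a copy, models adapter ligation and size
#' selection, and quantifies each resulting library against the split-half
#' index. The denominator is the pool size (every generated read counts as
#' sequenced/alignable input), so RPM values are comparable across
#' treatments of the same pool.
#'
#' @inheritParams generate_library
#' @param treatments Subset of [TREATMENTS] to simulate; `NONE` is always
#'   informative to include.
#' @param p_pnk_5p_dephos PNK 5'-dephosphorylation probability (see
#'   [apply_treatment()]).
#' @param max_len Size-selection cut-off (nt).
#' @param index Optional prebuilt `ysrna_index` for `ref`.
#' @return A `ysrna_panel` (see [build_treatment_panels()]).
#' @export
simulate_panel <- function(ref, classes, background_fraction, n_reads,
                           seed = NULL, treatments = TREATMENTS,
                           p_pnk_5p_dephos = 0.8, max_len = 50L,
                           index = NULL) {
  treatments <- match.arg(treatments, TREATMENTS, several.ok = TRUE)
  if (is.null(index)) {
    index <- build_match_index(ref)
  }
  pool <- generate_library(ref, classes, background_fraction, n_reads,
    seed = seed
  )
  tables <- lapply(seq_along(treatments), function(i) {
    treated <- apply_treatment(pool, treatments[i],
      p_pnk_5p_dephos = p_pnk_5p_dephos, seed = derive_seed(seed, i)
    )
    kept <- ligate_and_select(treated, max_len = max_len)
    quantify_reads(kept$seq, index,
      denominator = max(n_reads, 1),
      sample_id = paste0("sim_", treatments[i]), treatment = treatments[i]
    )
  })
  build_treatment_panels(tables)
}
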