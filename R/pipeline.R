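#' Read and validate a pipeline run configuration
#'
#' The YAML schema mirrors the pipeline stages:
#'
#' ```yaml
#' reference:
#'   fasta: path/to/yrna.fa        # or:
#'   synthetic: {lengths: [112, 101, 93, 83], stem_len: 10,
#'               ids: [hY1, hY3, hY4, hY5], seed: 7}
#' simulate:
#'   preset: sperm_head            # sperm_head | oocyte, or explicit:
#'   classes:
#'     - {parent: hY1, fraction: 0.35, start: {"0": 0.8, "1": 0.2},
#'        length_mode: 30, length_sd: 1.5,
#'        states: [{five: P, three: OMe, prob: 1}]}
#'   background_fraction: 0.2
#'   n_reads: 100000
#'   seed: 1
#'   treatments: [NONE, OXIDATION_BETA_ELIM, PNK, RPPH]
#'   p_pnk_5p_dephos: 0.8
#' quantify:
#'   min_len: 20
#'   max_len: 50
#'   adapter: ~                    # optional 3' adapter to trim
#'   denominators: {}              # per-sample overrides; default n_reads
#' infer:
#'   thresholds: {protected: 0.5, gain: 2.0, loss: 0.5, floor: 1.0}
#' ```
#'
#' @param path YAML file path, or an already-parsed list.
#' @return The validated config list (class `ysrna_config`), with the
#'   source path (if any) in attribute `path`.
#' @export
read_run_config <- function(path) {
  if (is.character(path)) {
    if (!file.exists(path)) stop("config not found: ", path)
    config <- yaml::read_yaml(path)
    attr(config, "path") <- path
  } else {
    config <- path
    if (inherits(config, "ysrna_config")) {
      return(config)
    }
  }
  if (is.null(config$reference)) stop("config lacks a 'reference' block")
  if (!is.null(config$reference$fasta) && !file.exists(config$reference$fasta)) {
    stop("reference FASTA not found: ", config$reference$fasta)
  }
  sim <- config$simulate
  if (!is.null(sim)) {
    if (!is.null(sim$seed) && sim$seed != as.integer(sim$seed)) {
      stop("simulation seed must be an integer")
    }
    bad <- setdiff(sim$treatments, TREATMENTS)
    if (length(bad)) stop("unknown treatment(s): ", paste(bad, collapse = ", "))
  }
  th <- config$infer$thresholds
  if (!is.null(th) && any(unlist(th) <= 0)) {
    stop("inference thresholds must be positive")
  }
  class(config) <- c("ysrna_config", class(config))
  config
}

config_reference <- function(config) {
  rf <- config$reference
  if (!is.null(rf$fasta)) {
    return(load_reference(rf$fasta))
  }
  syn <- rf$synthetic
  if (is.null(syn)) stop("reference block needs 'fasta' or 'synthetic'")
  generate_reference_set(
    lengths = as.integer(syn$lengths %||% c(112L, 101L, 93L, 83L)),
    stem_len = as.integer(syn$stem_len %||% 10L),
    seed = syn$seed,
    ids = syn$ids %||% paste0("synY", seq_along(syn$lengths %||% 1:4))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_classes <- function(config, ref) {
  sim <- config$simulate
  if (!is.null(sim$classes)) {
    classes <- lapply(sim$classes, function(cl) {
      states <- do.call(rbind, lapply(cl$states, as.data.frame))
      fragment_class(
        parent_id = cl$parent, fraction = cl$fraction,
        start_prob = unlist(cl$start),
        length_prob = if (!is.null(cl$length_mode)) {
          peaked_length_prob(cl$length_mode, cl$length_sd %||% 1.5)
        } else {
          unlist(cl$lengths)
        },
        states = states
      )
    })
    return(list(
      classes = classes,
      background_fraction = sim$background_fraction %||%
        (1 - sum(vapply(classes, `[[`, numeric(1), "fraction")))
    ))
  }
  preset <- sim$preset %||% "sperm_head"
  switch(preset,
    sperm_head = sperm_head_config(parents = ref$id),
    oocyte = oocyte_config(parents = ref$id),
    stop("unknown simulate preset: ", preset)
  )
}

#' Pipeline stage commands
#'
#' `cmd_simulate()` draws one pre-treatment read pool and writes, per
#' requested treatment, a FASTQ plus truth TSV (the paper's design:
#' aliquots of the same RNA, treated separately). `cmd_quantify()` counts
#' each written library against the split-half reference and writes one
#' count TSV per library. `cmd_profile()` tabulates aggregate RPM across
#' the quantified libraries. `cmd_infer()` turns the count tables into
#' terminal-modification calls. [run_pipeline()] chains all four.
#'
#' @param config A config list or YAML path (see [read_run_config()]).
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of the config's simulation seed.
#' @param verbose Log filter-gate counts to stderr.
#' @return Each command returns the paths of the files it wrote,
#'   invisibly; `cmd_infer()` returns the `ysrna_calls` table.
#' @export
cmd_simulate <- function(config, outdir, seed = NULL, verbose = FALSE) {
  config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- config_reference(config)
  sim <- config$simulate %||% stop("config lacks a 'simulate' block")
  cc <- config_classes(config, ref)
  seed <- seed %||% sim$seed
  pool <- generate_library(ref, cc$classes, cc$background_fraction,
    n_reads = sim$n_reads %||% 100000L, seed = seed
  )
  treatments <- sim$treatments %||% "NONE"
  paths <- character()
  for (trt in treatments) {
    treated <- apply_treatment(pool, trt,
      p_pnk_5p_dephos = sim$p_pnk_5p_dephos %||% 0.8,
      seed = derive_seed(seed, match(trt, TREATMENTS))
    )
    kept <- ligate_and_select(treated, max_len = config$quantify$max_len %||% 50L)
    fq <- file.path(outdir, paste0("sim_", trt, ".fastq"))
    tr <- file.path(outdir, paste0("sim_", trt, ".truth.tsv"))
    write_library(kept, fq, tr, adapter = sim$adapter)
    if (verbose) {
      message(sprintf(
        "simulate %s: %d / %d reads ligatable and <= %d nt",
        trt, nrow(kept), nrow(pool), config$quantify$max_len %||% 50L
      ))
    }
    paths <- c(paths, fq, tr)
  }
  write_manifest(config, outdir, seed)
  invisible(paths)
}

#' @rdname cmd_simulate
#' @export
cmd_quantify <- function(config, outdir, verbose = FALSE) {
  config <- read_run_config(config)
  q <- config$quantify %||% list()
  ref <- config_reference(config)
  index <- build_match_index(ref, min_len = q$min_len %||% 20L)
  fastqs <- sort(list.files(outdir, pattern = "\\.fastq$", full.names = TRUE))
  if (!length(fastqs)) stop("no FASTQ files in ", outdir, "; run cmd_simulate first")
  paths <- character()
  for (fq in fastqs) {
    sample_id <- sub("\\.fastq$", "", basename(fq))
    trt <- sub("^sim_", "", sample_id)
    if (!trt %in% TREATMENTS) trt <- "NONE"
    denom <- q$denominators[[sample_id]] %||%
      config$simulate$n_reads %||%
      stop("no denominator for ", sample_id)
    counts <- quantify_library(fq, index,
      denominator = denom,
      sample_id = sample_id, treatment = trt,
      min_len = q$min_len %||% 20L, max_len = q$max_len %||% 50L,
      adapter = q$adapter, verbose = verbose
    )
    out <- file.path(outdir, paste0(sample_id, ".counts.tsv"))
    write_counts(counts, out)
    paths <- c(paths, out)
  }
  invisible(paths)
}

#' @rdname cmd_simulate
#' @export
cmd_profile <- function(config, outdir) {
  config <- read_run_config(config)
  tables <- lapply(
    sort(list.files(outdir, pattern = "\\.counts\\.tsv$", full.names = TRUE)),
    read_counts
  )
  if (!length(tables)) stop("no count tables in ", outdir)
  mat <- build_profile_matrix(tables)
  long <- file.path(outdir, "profile_long.tsv")
  write_profile_long(mat, long)
  wide <- file.path(outdir, "profile_matrix.tsv")
  utils::write.table(
    data.frame(sample = rownames(mat), unclass(mat), check.names = FALSE),
    wide,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(long, wide))
}

#' @rdname cmd_simulate
#' @export
cmd_infer <- function(config, outdir) {
  config <- read_run_config(config)
  tables <- lapply(
    sort(list.files(outdir, pattern = "\\.counts\\.tsv$", full.names = TRUE)),
    read_counts
  )
  if (!length(tables)) stop("no count tables in ", outdir)
  th <- config$infer$thresholds
  thresholds <- if (is.null(th)) {
    ysrna_thresholds()
  } else {
    do.call(ysrna_thresholds, th)
  }
  calls <- run_inference(tables, thresholds = thresholds)
  write_calls(calls, file.path(outdir, "calls.tsv"))
  calls
}

#' Run simulate, quantify, profile and infer in one pass
#'
#' @inheritParams cmd_simulate
#' @return The `ysrna_calls` table, invisibly.
#' @export
run_pipeline <- function(config, outdir, seed = NULL, verbose = FALSE) {
  config <- read_run_config(config)
  cmd_simulate(config, outdir, seed = seed, verbose = verbose)
  cmd_quantify(config, outdir, verbose = verbose)
  cmd_profile(config, outdir)
  invisible(cmd_infer(config, outdir))
}

# Provenance record: config hash (md5 of the YAML file when available,
# else of the serialised config), seed, package version.
write_manifest <- function(config, outdir, seed) {
  src <- attr(config, "path")
  if (is.null(src)) {
    src <- tempfile(fileext = ".yaml")
    yaml::write_yaml(unclass(config), src)
    on.exit(unlink(src))
  }
  md5 <- unname(tools::md5sum(src))
  utils::write.table(
    data.frame(
      config_md5 = md5, seed = seed %||% NA_integer_,
      ysrna_version = as.character(utils::packageVersion("ysrna"))
    ),
    file.path(outdir, "run_manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(NULL)
}
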