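#' Build a validated pipeline run configuration
#'
#' Defaults carry the conventional analysis constants: subsample presets
#' of 100K small-RNA and 200K mRNA reads, barcode tolerance 1 mismatch,
#' one-mismatch UMI collapse with fractional multimapper weighting,
#' log-normalization scale 10000, top 200 miRNAs and top 2500 mRNAs for
#' co-inertia, target consensus across at least 3 prediction algorithms,
#' and Bonferroni multiple-testing correction.
#'
#' @param ... overrides for any default key (unknown keys are an error).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # demux
    max_mismatch = 1L,
    trim_min_overlap = 5L,
    trim_max_err = 1L,
    subsample_smallrna = 100000L,
    subsample_mrna = 200000L,
    # quantification
    feature_max_mismatch = 1L,
    collapse_max_dist = 1L,
    weighting = "fractional",
    lognorm_scale = 1e4,
    # coinertia
    coinertia_k = 2L,
    coinertia_preprocessing = "center",
    top_n_mirna = 200L,
    top_n_mrna = 2500L,
    consensus_min_algorithms = 3L,
    # group comparison
    p_adjust_method = "bonferroni",
    min_cells_per_group = 3L,
    # inputs (either a scenario for synthetic runs, or file paths)
    scenario = NULL,
    smallrna_fastq = NULL,
    mrna_fastq = NULL,
    whitelist = NULL,
    mirna_reference = NULL,
    alignments = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a configuration list to validate.
#' @export
validate_run_config <- function(config) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(config$max_mismatch %in% 0:1, "max_mismatch: must be 0 or 1")
  chk(config$top_n_mirna >= 1, "top_n_mirna: must be >= 1")
  chk(config$top_n_mrna >= 1, "top_n_mrna: must be >= 1")
  chk(config$consensus_min_algorithms >= 1,
      "consensus_min_algorithms: must be >= 1")
  chk(config$weighting %in% c("fractional", "multiply"),
      "weighting: must be 'fractional' or 'multiply'")
  chk(config$p_adjust_method %in% stats::p.adjust.methods,
      "p_adjust_method: unknown method")
  chk(config$collapse_max_dist %in% 0:1, "collapse_max_dist: must be 0 or 1")
  synthetic <- !is.null(config$scenario)
  if (!synthetic) {
    for (key in c("smallrna_fastq", "mrna_fastq", "whitelist",
                  "mirna_reference", "alignments"))
      chk(!is.null(config[[key]]), paste0(key, ": required for file input"))
  }
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Write / read a run configuration as YAML
#'
#' The `scenario` entry, if any, is not serialized (it is reconstructable
#' from its own parameters); all scalar keys round-trip.
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  cfg <- config[!vapply(config, is.null, logical(1))]
  cfg$scenario <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the pipeline end to end into a run directory
#'
#' Executes demultiplexing, quantification, normalization, aggregation and
#' (for synthetic scenarios) co-inertia against truth labels, writing each
#' stage's outputs plus a manifest (`manifest.json` with stage list, file
#' md5 hashes and the effective configuration) under `outdir`. Completed
#' stage outputs stay on disk if a later stage fails.
#'
#' @param config a [run_config()]. Synthetic runs set `config$scenario`;
#'   file-based runs set the input path keys.
#' @param outdir run directory (created).
#' @return Invisibly, a list with the manifest and key in-memory results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), config = unclass(config["scenario" !=
                                                             names(config)]))
  files <- character()
  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, completed = TRUE)
    res
  }

  if (!is.null(config$scenario)) {
    scenario <- config$scenario
    truth <- stage("simulate", simulate_expression(scenario))
    sim <- stage("simulate_reads",
                 simulate_reads(truth, scenario, dir = file.path(outdir, "reads")))
    reads_s <- read_fastq(sim$paths$smallrna_fastq)
    reads_m <- read_fastq(sim$paths$mrna_fastq)
    whitelist <- scenario$whitelist
    layout_s <- scenario$layout_smallrna
    layout_m <- scenario$layout_mrna
    reference <- scenario$reference
    alignments <- sim$alignments
    files <- c(files, unlist(sim$paths))
  } else {
    reads_s <- read_fastq(config$smallrna_fastq)
    reads_m <- read_fastq(config$mrna_fastq)
    whitelist <- read_barcode_whitelist(config$whitelist)
    layout_s <- read_layout(adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            library_kind = "smallRNA")
    layout_m <- read_layout(library_kind = "mRNA")
    reference <- read_mirna_reference(config$mirna_reference)
    alignments <- read_alignment_table(config$alignments)
  }

  if (nrow(reads_s) > config$subsample_smallrna)
    reads_s <- downsample_reads(reads_s, config$subsample_smallrna,
                                seed = config$seed)
  if (nrow(reads_m) > config$subsample_mrna) {
    reads_m <- downsample_reads(reads_m, config$subsample_mrna,
                                seed = config$seed)
    # alignments describe the full library; keep only the sampled reads
    alignments <- alignments[alignments$read_id %in% reads_m$read_id, ,
                             drop = FALSE]
  }

  tagged_s <- stage("demux_smallrna",
                    demux_reads(reads_s, layout_s, whitelist,
                                max_mismatch = config$max_mismatch,
                                trim_min_overlap = config$trim_min_overlap,
                                trim_max_err = config$trim_max_err))
  tagged_m <- stage("demux_mrna",
                    demux_reads(reads_m, layout_m, whitelist,
                                max_mismatch = config$max_mismatch))
  p1 <- file.path(outdir, "tagged_smallrna.tsv")
  p2 <- file.path(outdir, "tagged_mrna.tsv")
  write_tagged_reads(tagged_s, p1)
  write_tagged_reads(tagged_m, p2)
  files <- c(files, p1, p2)

  em_s <- stage("quant_smallrna", {
    asg <- assign_smallrna_features(tagged_s, reference,
                                    max_mismatch = config$feature_max_mismatch)
    count_expression(asg, library_kind = "smallRNA",
                     weighting = config$weighting,
                     collapse_max_dist = config$collapse_max_dist)
  })
  em_m <- stage("quant_mrna", {
    asg <- ingest_alignments(alignments, tagged_m)
    count_expression(asg, library_kind = "mRNA",
                     weighting = config$weighting,
                     collapse_max_dist = config$collapse_max_dist)
  })
  write_expression_matrix(em_s, file.path(outdir, "matrix_smallrna"))
  write_expression_matrix(em_m, file.path(outdir, "matrix_mrna"))
  files <- c(files, list.files(file.path(outdir, "matrix_smallrna"),
                               full.names = TRUE),
             list.files(file.path(outdir, "matrix_mrna"), full.names = TRUE))

  norm_s <- stage("normalize", suppressWarnings(
    normalize_lognorm(em_s, scale_factor = config$lognorm_scale)))
  norm_m <- suppressWarnings(
    normalize_lognorm(em_m, scale_factor = config$lognorm_scale))

  coia <- NULL
  if (!is.null(config$scenario)) {
    coia <- stage("coinertia", {
      labels <- stats::setNames(config$scenario$cells$type,
                                config$scenario$cells$cell)
      X <- select_top_expressed(aggregate_by_group(norm_s, labels),
                                config$top_n_mirna)
      Y <- select_top_expressed(aggregate_by_group(norm_m, labels),
                                config$top_n_mrna)
      fit <- coinertia_fit(X, Y, k = config$coinertia_k,
                           preprocessing = config$coinertia_preprocessing)
      p <- file.path(outdir, "coinertia.json")
      jsonlite::write_json(list(rv = fit$rv,
                                eigenvalues = fit$eigenvalues),
                           p, auto_unbox = TRUE, digits = NA)
      fit
    })
    files <- c(files, file.path(outdir, "coinertia.json"))
  }

  cfg_path <- file.path(outdir, "config.yaml")
  write_run_config(config, cfg_path)
  files <- c(files, cfg_path)
  manifest$files <- lapply(unname(files), function(f)
    list(path = f, md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(manifest = manifest,
                 matrices = list(smallrna = em_s, mrna = em_m),
                 normalized = list(smallrna = norm_s, mrna = norm_m),
                 coinertia = coia,
                 tagged = list(smallrna = tagged_s, mrna = tagged_m)))
}
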