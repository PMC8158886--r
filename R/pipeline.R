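#' Configuration for a full pipeline run
#'
#' Bundles every tunable of the end-to-end analysis. Data come either from
#' the synthetic generator (`generator` set, the default) or from files
#' (`cohort_dir` + `cohort_names` + `gmt_path`).
#'
#' @param seed Integer master seed; recorded in every output header.
#' @param out_dir Output directory.
#' @param generator A [generator_config()], or `NULL` to read cohorts from
#'   files.
#' @param cohort_dir,cohort_names,gmt_path File inputs, used when
#'   `generator` is `NULL` (see [read_cohort()], [read_gmt()]).
#' @param outlier_k SD multiplier for the outcome-outlier exclusion;
#'   default 5.
#' @param homa_convention HOMA-IR unit convention for phenotype
#'   preparation; default `"mgdl"`.
#' @param missingness_threshold Strict pooled-missingness bound; default
#'   0.25.
#' @param n_perm,min_size,weight_exponent Enrichment options (see
#'   [run_enrichment()]).
#' @param modes Enrichment ranking modes to run; default both
#'   `"signed_z"` (on the univariate-model meta-analysis) and `"q_stat"`
#'   (on the covariate-adjusted full-model meta-analysis).
#' @param write_cohorts Also write the (simulated) cohort tables; default
#'   FALSE.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "metabometa_out",
                       generator = generator_config(seed = seed),
                       cohort_dir = NULL, cohort_names = NULL,
                       gmt_path = NULL, outlier_k = 5,
                       homa_convention = "mgdl",
                       missingness_threshold = 0.25,
                       n_perm = 10000, min_size = 5, weight_exponent = 1,
                       modes = c("signed_z", "q_stat"),
                       write_cohorts = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(generator)) {
    if (is.null(cohort_dir) || is.null(cohort_names))
      stop("either a generator config or cohort_dir + cohort_names is ",
           "required", call. = FALSE)
    if (!dir.exists(cohort_dir))
      stop("cohort_dir does not exist: ", cohort_dir, call. = FALSE)
    if (length(modes) && is.null(gmt_path))
      stop("enrichment requested but no set-definition (GMT) file given",
           call. = FALSE)
    if (!is.null(gmt_path) && !file.exists(gmt_path))
      stop("GMT file does not exist: ", gmt_path, call. = FALSE)
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 generator = generator, cohort_dir = cohort_dir,
                 cohort_names = cohort_names, gmt_path = gmt_path,
                 outlier_k = outlier_k, homa_convention = homa_convention,
                 missingness_threshold = missingness_threshold,
                 n_perm = n_perm, min_size = min_size,
                 weight_exponent = weight_exponent, modes = modes,
                 write_cohorts = write_cohorts),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar fields override [run_config()] defaults; a `generator` block (if
#' present) is passed to [generator_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  gen <- NULL
  if (!is.null(raw$generator)) {
    gargs <- raw$generator
    if (!is.null(gargs$subclass_composition))
      gargs$subclass_composition <- unlist(gargs$subclass_composition)
    gen <- do.call(generator_config, gargs)
  }
  raw$generator <- NULL
  do.call(run_config, c(raw, list(generator = gen)))
}

# Deterministic hash of the configuration (paths excluded so reruns into
# different directories compare equal).
.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                           force = TRUE, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or file
#' loading), per-cohort outcome-outlier exclusion, univariate and
#' covariate-adjusted regressions of percent change in HOMA-IR on every
#' metabolite, pooled missingness/known-identity filtering, fixed- and
#' random-effects meta-analysis of each model form with heterogeneity
#' statistics and FDR control, and metabolite-set enrichment (z-ranked on
#' the univariate meta-analysis, Q-ranked on the full-model meta-analysis).
#' All tables are written as TSV with provenance headers; a JSON manifest
#' records the seed, configuration hash and row counts. Two runs with the
#' same configuration produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg) message(sprintf("[metabometa %7.1fs] %s",
                                         proc.time()[["elapsed"]] - t0, msg))
  hash <- .config_hash(config)
  version <- as.character(utils::packageVersion("metabometa"))
  hdr <- c(paste0("metabometa ", version),
           paste0("seed=", config$seed),
           paste0("config_hash=", hash))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$generator)) {
    stage("simulating study")
    study <- generate_study(config$generator)
    cohorts <- study$cohorts
    annotation <- study$annotation
    sets <- study$sets
    if (config$write_cohorts) {
      for (co in cohorts) write_cohort(co, config$out_dir, hdr)
      write_gmt(sets, file.path(config$out_dir, "sets.gmt"))
      jsonlite::write_json(
        lapply(study$truth, unclass),
        file.path(config$out_dir, "truth.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  } else {
    stage("loading cohorts")
    cohorts <- lapply(config$cohort_names, function(nm)
      read_cohort(config$cohort_dir, nm))
    names(cohorts) <- config$cohort_names
    annotation <- cohorts[[1]]$annotation
    sets <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
  }

  stage("excluding outcome outliers")
  excluded <- list()
  for (nm in names(cohorts)) {
    cohorts[[nm]] <- apply_outlier_exclusion(cohorts[[nm]],
                                             k = config$outlier_k)
    excluded[[nm]] <- attr(cohorts[[nm]], "excluded_ids")
  }

  stage("fitting per-cohort regressions")
  reg <- list()
  for (form in c("univariate", "full")) {
    reg[[form]] <- lapply(cohorts, fit_cohort, model_form = form)
    for (nm in names(cohorts))
      .write_tsv(reg[[form]][[nm]],
                 file.path(config$out_dir,
                           sprintf("regression_%s_%s.tsv", nm, form)), hdr)
  }

  stage("applying missingness filter")
  filt <- missingness_filter(cohorts, annotation,
                             threshold = config$missingness_threshold)

  stage("meta-analyzing")
  meta <- lapply(reg, function(tables)
    run_meta(tables, annotation = annotation, retain = filt$retained,
             missingness = filt$missingness, zeroness = filt$zeroness))
  .write_tsv(meta$univariate,
             file.path(config$out_dir, "meta_univariate.tsv"), hdr)
  .write_tsv(meta$full, file.path(config$out_dir, "meta_full.tsv"), hdr)
  .write_tsv(volcano_data(meta$univariate),
             file.path(config$out_dir, "volcano_association.tsv"), hdr)
  .write_tsv(volcano_data(meta$full, p_column = "Q_Pvalue"),
             file.path(config$out_dir, "volcano_heterogeneity.tsv"), hdr)

  enr <- list()
  if (!is.null(sets) && length(config$modes)) {
    for (mode in config$modes) {
      stage(paste0("set enrichment (", mode, ")"))
      src <- if (mode == "signed_z") meta$univariate else meta$full
      label <- if (mode == "signed_z") "association" else "heterogeneity"
      enr[[label]] <- run_enrichment(
        src, sets, mode = mode, n_perm = config$n_perm,
        min_size = config$min_size,
        weight_exponent = config$weight_exponent,
        seed = config$seed + 101L)
      .write_tsv(enr[[label]],
                 file.path(config$out_dir,
                           sprintf("enrichment_%s.tsv", label)), hdr)
    }
  }

  manifest <- list(
    tool = "metabometa", version = version, seed = config$seed,
    config_hash = hash,
    n_cohorts = length(cohorts),
    excluded_outliers = excluded,
    n_metabolites_removed_by_filter = filt$n_removed,
    n_metabolites_retained = length(filt$retained),
    rows = c(lapply(meta, nrow), lapply(enr, nrow)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("done")
  invisible(manifest)
}
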