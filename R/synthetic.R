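#' Specification of one synthetic cohort
#'
#' Phenotype-scale parameters for one simulated weight-loss cohort. The
#' shipped defaults ([default_cohort_specs()]) mirror the structure of three
#' published intervention arms: a large behavioral cohort, a mid-size
#' exercise cohort and a smaller surgical cohort with much larger weight
#' loss and a tighter, strongly negative HOMA-IR response.
#'
#' @param name Cohort label.
#' @param n_subjects Number of subjects (>= 10).
#' @param homa_ir_baseline_mean_sd Mean and SD of baseline HOMA-IR
#'   (unitless); simulated log-normal so baselines stay positive.
#' @param pct_change_mean_sd Mean and residual SD of the percent-change
#'   outcome (%); the SD is the noise left after planted metabolite and
#'   covariate effects.
#' @param weight_baseline_mean_sd Mean/SD of baseline weight (kg).
#' @param weight_change_mean_sd Mean/SD of weight change over the
#'   intervention (kg); negative mean = weight loss.
#' @param age_mean_sd Mean/SD of age (years).
#' @param prop_female Proportion of female subjects, in \[0, 1\].
#' @param prop_race Named proportions for race categories (e.g.
#'   `c(AA = .37, EA = .62)`); must sum to <= 1, remainder is "other".
#' @param triglycerides_mean_sd Mean/SD of baseline clinical triglycerides
#'   (mg/dL).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_subjects,
                        homa_ir_baseline_mean_sd = c(2.4, 1.6),
                        pct_change_mean_sd = c(-16, 105),
                        weight_baseline_mean_sd = c(96, 16),
                        weight_change_mean_sd = c(-8.5, 3.8),
                        age_mean_sd = c(56, 8.7),
                        prop_female = 0.62,
                        prop_race = c(AA = 0.37, EA = 0.62),
                        triglycerides_mean_sd = c(127, 71)) {
  stopifnot(n_subjects >= 10,
            homa_ir_baseline_mean_sd[2] > 0, pct_change_mean_sd[2] > 0,
            weight_baseline_mean_sd[2] > 0, weight_change_mean_sd[2] > 0,
            age_mean_sd[2] > 0, triglycerides_mean_sd[2] > 0,
            prop_female >= 0, prop_female <= 1,
            all(prop_race >= 0), sum(prop_race) <= 1)
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 homa_ir_baseline_mean_sd = homa_ir_baseline_mean_sd,
                 pct_change_mean_sd = pct_change_mean_sd,
                 weight_baseline_mean_sd = weight_baseline_mean_sd,
                 weight_change_mean_sd = weight_change_mean_sd,
                 age_mean_sd = age_mean_sd, prop_female = prop_female,
                 prop_race = prop_race,
                 triglycerides_mean_sd = triglycerides_mean_sd),
            class = "cohort_spec")
}

#' Default three-cohort specification
#'
#' Cohort sizes 443 / 163 / 125 with percent-change HOMA-IR outcomes of
#' about -16 +/- 105, -16 +/- 42 and -71 +/- 21 respectively, plus matching
#' covariate distributions (age, sex, race, weight, triglycerides).
#'
#' @return List of three [cohort_spec()] objects named `behavioral`,
#'   `exercise`, `surgical`.
#' @export
default_cohort_specs <- function() {
  list(
    behavioral = cohort_spec(
      "behavioral", 443,
      homa_ir_baseline_mean_sd = c(2.4, 1.6),
      pct_change_mean_sd = c(-16, 105),
      weight_baseline_mean_sd = c(96, 16),
      weight_change_mean_sd = c(-8.5, 3.8),
      age_mean_sd = c(56, 8.7), prop_female = 0.62,
      prop_race = c(AA = 0.37, EA = 0.62),
      triglycerides_mean_sd = c(127, 71)),
    exercise = cohort_spec(
      "exercise", 163,
      homa_ir_baseline_mean_sd = c(2.0, 1.5),
      pct_change_mean_sd = c(-16, 42),
      weight_baseline_mean_sd = c(86, 12),
      weight_change_mean_sd = c(-2.7, 4.0),
      age_mean_sd = c(59, 7.5), prop_female = 0.63,
      prop_race = c(AA = 0.18, EA = 0.78),
      triglycerides_mean_sd = c(123, 64)),
    surgical = cohort_spec(
      "surgical", 125,
      homa_ir_baseline_mean_sd = c(9.6, 5.8),
      pct_change_mean_sd = c(-71, 21),
      weight_baseline_mean_sd = c(121, 22),
      weight_change_mean_sd = c(-35, 16),
      age_mean_sd = c(42, 10), prop_female = 0.82,
      prop_race = c(AA = 0.50, EA = 0.49),
      triglycerides_mean_sd = c(158, 108))
  )
}

#' Planted metabolite effect
#'
#' Ground-truth effect of a block of metabolites on the percent-change
#' outcome, in % change of HOMA-IR per natural-log unit of the metabolite.
#' An effect is homogeneous when every cohort gets the same beta; a
#' cohort-varying map plants heterogeneity for the Cochran-Q analyses.
#'
#' @param set_name Label of the metabolite block (usually an HMDB subclass).
#' @param members Character vector of member metabolite ids.
#' @param beta_per_cohort Named numeric: cohort name -> beta.
#' @return An object of class `effect_spec` with a `homogeneous` flag
#'   (TRUE iff all betas are equal).
#' @export
effect_spec <- function(set_name, members, beta_per_cohort) {
  stopifnot(length(members) >= 1, length(beta_per_cohort) >= 1,
            !is.null(names(beta_per_cohort)))
  structure(list(set_name = set_name, members = members,
                 beta_per_cohort = beta_per_cohort,
                 homogeneous = length(unique(beta_per_cohort)) == 1L),
            class = "effect_spec")
}

#' Default 22-subclass composition for a 765-metabolite panel
#'
#' An HMDB-subclass-style composition in which roughly half the panel is
#' lipid or lipid-like (triacylglycerol, diacylglycerol, phospholipid and
#' fatty-acyl blocks), the largest single polar block is amino acids,
#' peptides and analogues, and the remainder spreads over small organic-
#' compound subclasses. Counts sum to 765 over 22 subclasses.
#'
#' @return Named integer vector (subclass -> metabolite count).
#' @export
default_subclass_composition <- function() {
  c("Triradylcglycerols" = 130,
    "Diradylglycerols" = 30,
    "Glycerophosphocholines" = 80,
    "Glycerophosphoethanolamines" = 35,
    "Phosphosphingolipids" = 35,
    "Fatty acid esters" = 30,
    "Fatty acids and conjugates" = 45,
    "Cholesteryl esters" = 12,
    "Lysophospholipids" = 25,
    "Amino acids, peptides, and analogues" = 110,
    "Carbohydrates and carbohydrate conjugates" = 30,
    "Benzoic acids and derivatives" = 15,
    "Indolyl carboxylic acids and derivatives" = 10,
    "Purines and purine derivatives" = 20,
    "Pyrimidines and pyrimidine derivatives" = 15,
    "Bile acids, alcohols and derivatives" = 20,
    "Carnitines" = 30,
    "Organic dicarboxylic acids" = 20,
    "Hydroxy acids and derivatives" = 18,
    "Steroids and steroid derivatives" = 25,
    "Cinnamic acids and derivatives" = 10,
    "Azoles" = 20)
}

# Subclasses whose log-levels load on clinical triglycerides (neutral
# lipids and their precursors).
.lipid_like <- c("Triradylcglycerols", "Diradylglycerols",
                 "Cholesteryl esters", "Fatty acid esters")

#' Generator configuration for a synthetic multi-cohort study
#'
#' @param seed Integer seed; fully determines every generated value.
#' @param subclass_composition Named counts per subclass (sums to the panel
#'   size); default [default_subclass_composition()].
#' @param cohort_specs List of [cohort_spec()]; default
#'   [default_cohort_specs()].
#' @param effects List of [effect_spec()]; default none (global null).
#' @param within_subclass_correlation Exchangeable correlation of log-levels
#'   within a subclass, in \[0, 1); default 0.5.
#' @param tg_correlation Loading of lipid-like subclass common factors on
#'   standardized log clinical triglycerides, in \[0, 1\]; default 0.6.
#' @param missingness_rate MCAR missingness proportion for abundance cells;
#'   default 0.02.
#' @param n_outcome_outliers Subjects per cohort whose outcome is displaced
#'   beyond the 5-SD exclusion threshold; default 0.
#' @param covariate_betas Named list of outcome coefficients for
#'   `age` (%/year), `female` (%), `triglycerides` (%/(mg/dL)) and
#'   `pct_change_weight` (% per % weight change); small non-zero defaults
#'   so the full model has covariates worth adjusting for.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             subclass_composition = default_subclass_composition(),
                             cohort_specs = default_cohort_specs(),
                             effects = list(),
                             within_subclass_correlation = 0.5,
                             tg_correlation = 0.6,
                             missingness_rate = 0.02,
                             n_outcome_outliers = 0L,
                             covariate_betas = list(age = 0.2, female = 2,
                                                    triglycerides = 0.02,
                                                    pct_change_weight = 1)) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            all(subclass_composition >= 1),
            within_subclass_correlation >= 0, within_subclass_correlation < 1,
            tg_correlation >= 0, tg_correlation <= 1,
            missingness_rate >= 0, missingness_rate < 1,
            n_outcome_outliers >= 0)
  structure(list(seed = as.integer(seed),
                 n_metabolites = sum(subclass_composition),
                 subclass_composition = subclass_composition,
                 cohort_specs = cohort_specs, effects = effects,
                 within_subclass_correlation = within_subclass_correlation,
                 tg_correlation = tg_correlation,
                 missingness_rate = missingness_rate,
                 n_outcome_outliers = as.integer(n_outcome_outliers),
                 covariate_betas = covariate_betas),
            class = "generator_config")
}

#' Generate the shared metabolite annotation table
#'
#' One row per metabolite: a unique id, subclass label from the configured
#' composition, an LC-MS method label (lipid-like subclasses on C8-pos,
#' polar subclasses spread over C18-neg / HILIC-pos / HILIC-neg), a
#' coefficient of variation drawn in (0, 0.5], an HMDB-style accession, and
#' the per-metabolite log-scale location/scale used by [generate_cohort()].
#'
#' @param config A [generator_config()].
#' @return Data frame with columns `metabolite`, `hmdb_id`, `sub_class`,
#'   `class`, `super_class`, `method`, `cv`, `log_mean`, `log_sd`, `known`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  comp <- config$subclass_composition
  if (sum(comp) != config$n_metabolites)
    stop("subclass composition does not sum to n_metabolites", call. = FALSE)
  set.seed(config$seed)
  sub_class <- rep(names(comp), comp)
  abbrev <- toupper(substr(gsub("[^A-Za-z]", "", names(comp)), 1, 4))
  abbrev <- sprintf("%s%02d", abbrev, seq_along(comp))  # collision-proof
  ids <- unlist(lapply(seq_along(comp), function(i)
    sprintf("%s_%03d", abbrev[i], seq_len(comp[i]))), use.names = FALSE)
  stopifnot(!anyDuplicated(ids))
  lipid <- sub_class %in% .lipid_like |
    grepl("phospho|sphingo|fatty|steroid", sub_class, ignore.case = TRUE)
  method <- ifelse(lipid, "C8-pos",
                   sample(c("C18-neg", "HILIC-pos", "HILIC-neg"),
                          length(ids), replace = TRUE))
  n <- length(ids)
  data.frame(
    metabolite = ids,
    hmdb_id = sprintf("HMDB%07d", sample.int(9999999, n)),
    sub_class = sub_class,
    class = ifelse(lipid, "Lipids", "Organic compounds"),
    super_class = ifelse(lipid, "Lipids and lipid-like molecules",
                         "Organic acids and derivatives"),
    method = method,
    cv = round(runif(n, 0.01, 0.5), 3),
    log_mean = round(rnorm(n, 12, 3), 3),
    log_sd = round(runif(n, 0.4, 1.6), 3),
    known = TRUE,
    stringsAsFactors = FALSE
  )
}

# Displacement multiplier that guarantees the k-SD rule flags exactly the
# injected outliers after they themselves inflate the cohort SD.
.outlier_multiplier <- function(n, n_out, k = 5) {
  if (n - 1 - k^2 * n_out <= 0)
    stop("too many outcome outliers for cohort size", call. = FALSE)
  max(k + 1, 1.1 * sqrt(k^2 * (n - n_out) / (n - 1 - k^2 * n_out)))
}

#' Generate one synthetic cohort
#'
#' Draws covariates from the cohort spec, builds a log-abundance matrix
#' with exchangeable within-subclass correlation (lipid-like blocks load on
#' standardized log triglycerides), and constructs the percent-change
#' HOMA-IR outcome additively: cohort mean + planted metabolite effects on
#' centred log-abundances + covariate terms (centred) + Gaussian noise at
#' the spec's residual SD. Follow-up HOMA-IR is back-computed from the
#' simulated baseline and the percent change. Outcome outliers (if
#' requested) are displaced far enough from the cohort mean that the 5-SD
#' exclusion rule flags exactly them; missing abundance cells are injected
#' completely at random.
#'
#' @param spec A [cohort_spec()].
#' @param annotation Annotation table from [generate_annotation()].
#' @param effects List of [effect_spec()]; every member metabolite must
#'   exist in the annotation and every beta map must name this cohort.
#' @param seed Integer seed for this cohort.
#' @param within_subclass_correlation,tg_correlation,missingness_rate,n_outcome_outliers,covariate_betas
#'   See [generator_config()].
#' @return A [cohort_dataset()] whose phenotypes carry `subject_id`,
#'   glucose/insulin, HOMA-IR at both timepoints, the percent-change
#'   outcome and covariates.
#' @export
generate_cohort <- function(spec, annotation, effects = list(), seed = 1L,
                            within_subclass_correlation = 0.5,
                            tg_correlation = 0.6,
                            missingness_rate = 0.02,
                            n_outcome_outliers = 0L,
                            covariate_betas = list(age = 0.2, female = 2,
                                                   triglycerides = 0.02,
                                                   pct_change_weight = 1)) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (ef in effects) {
    unknown <- setdiff(ef$members, annotation$metabolite)
    if (length(unknown))
      stop("effect '", ef$set_name, "' references unknown metabolites: ",
           paste(head(unknown, 3), collapse = ", "), call. = FALSE)
    if (!spec$name %in% names(ef$beta_per_cohort))
      stop("effect '", ef$set_name, "' has no beta for cohort '",
           spec$name, "'", call. = FALSE)
  }
  set.seed(seed)
  n <- spec$n_subjects
  ids <- sprintf("%s_%04d", spec$name, seq_len(n))

  age <- rnorm(n, spec$age_mean_sd[1], spec$age_mean_sd[2])
  sex <- ifelse(runif(n) < spec$prop_female, "F", "M")
  race_levels <- c(names(spec$prop_race), "other")
  race_prob <- c(spec$prop_race, other = 1 - sum(spec$prop_race))
  race <- sample(race_levels, n, replace = TRUE, prob = race_prob)
  tg <- pmax(20, rnorm(n, spec$triglycerides_mean_sd[1],
                       spec$triglycerides_mean_sd[2]))
  weight0 <- pmax(40, rnorm(n, spec$weight_baseline_mean_sd[1],
                            spec$weight_baseline_mean_sd[2]))
  dweight <- rnorm(n, spec$weight_change_mean_sd[1],
                   spec$weight_change_mean_sd[2])
  pct_dweight <- 100 * dweight / weight0

  # log-abundances: subclass common factor (lipid blocks tied to log TG)
  # plus independent noise, scaled to each metabolite's location/scale
  rho <- within_subclass_correlation
  z_tg <- as.numeric(scale(log(tg)))
  p <- nrow(annotation)
  X <- matrix(NA_real_, n, p, dimnames = list(ids, annotation$metabolite))
  for (sc in unique(annotation$sub_class)) {
    j <- which(annotation$sub_class == sc)
    lam <- if (sc %in% .lipid_like) tg_correlation else 0
    f <- lam * z_tg + sqrt(1 - lam^2) * rnorm(n)
    E <- matrix(rnorm(n * length(j)), n, length(j))
    Zs <- sqrt(rho) * f + sqrt(1 - rho) * E
    X[, j] <- sweep(sweep(Zs, 2, annotation$log_sd[j], `*`),
                    2, annotation$log_mean[j], `+`)
  }

  y <- spec$pct_change_mean_sd[1] +
    rnorm(n, 0, spec$pct_change_mean_sd[2])
  for (ef in effects) {
    b <- ef$beta_per_cohort[[spec$name]]
    if (b != 0) {
      Xm <- X[, ef$members, drop = FALSE]
      y <- y + rowSums(sweep(Xm, 2, colMeans(Xm), `-`)) * b
    }
  }
  cb <- covariate_betas
  y <- y + cb$age * (age - mean(age)) +
    cb$female * ((sex == "F") - mean(sex == "F")) +
    cb$triglycerides * (tg - mean(tg)) +
    cb$pct_change_weight * (pct_dweight - mean(pct_dweight))

  outlier_ids <- character(0)
  if (n_outcome_outliers > 0) {
    d <- .outlier_multiplier(n, n_outcome_outliers, k = 5)
    idx <- sample.int(n, n_outcome_outliers)
    signs <- rep_len(c(1, -1), n_outcome_outliers)
    repeat {
      y2 <- y
      y2[idx] <- mean(y) + signs * d * sd(y)
      flag <- abs(y2 - mean(y2)) > 5 * sd(y2)
      if (all(flag[idx]) && sum(flag) == n_outcome_outliers) break
      d <- d * 1.2
    }
    y <- y2
    outlier_ids <- ids[idx]
  }

  # baseline HOMA-IR log-normal at the spec's mean/SD; glucose/insulin
  # back-filled consistently; follow-up from the percent change
  mu <- spec$homa_ir_baseline_mean_sd[1]
  s2 <- spec$homa_ir_baseline_mean_sd[2]^2
  sdlog <- sqrt(log(1 + s2 / mu^2))
  meanlog <- log(mu) - sdlog^2 / 2
  homa0 <- exp(rnorm(n, meanlog, sdlog))
  glucose0 <- pmax(60, rnorm(n, 100, 12))
  insulin0 <- homa0 * 405 / glucose0
  homa1 <- homa0 * (1 + y / 100)

  if (missingness_rate > 0) {
    nmiss <- rbinom(1, n * p, missingness_rate)
    X[sample.int(n * p, nmiss)] <- NA_real_
  }

  ph <- data.frame(subject_id = ids,
                   glucose_baseline = glucose0, insulin_baseline = insulin0,
                   homa_ir_baseline = homa0, homa_ir_followup = homa1,
                   pct_change_homa_ir = y,
                   weight_baseline = weight0, pct_change_weight = pct_dweight,
                   age = age, sex = sex, race = race, triglycerides = tg,
                   stringsAsFactors = FALSE)
  out <- cohort_dataset(spec$name, ph, X, annotation = annotation,
                        scale = "log")
  attr(out, "planted_outlier_ids") <- outlier_ids
  out
}

#' Default planted effects for the demonstration study
#'
#' Builds the two canonical ground-truth effects used throughout the
#' package's examples and validation: a homogeneous negative association in
#' a triacylglycerol-like block (higher baseline levels, larger drop in
#' HOMA-IR, same beta in every cohort) and a cohort-heterogeneous,
#' sign-flipping effect in an amino-acid-like block (positive in the
#' surgical cohort, negative in the other two), the pattern the
#' heterogeneity analysis is designed to detect.
#'
#' @param annotation Annotation from [generate_annotation()]; members are
#'   the first metabolites of each subclass, so the choice is
#'   deterministic.
#' @param n_assoc Members in the association block; default 30.
#' @param beta_assoc Homogeneous beta (% change HOMA-IR per log-unit);
#'   default -16, about 0.15 pooled outcome SD per typical metabolite
#'   log-SD at the default cohort scales.
#' @param n_het Members in the heterogeneous block; default 14.
#' @param beta_het Named per-cohort betas for the heterogeneous block.
#' @return List of two [effect_spec()] objects.
#' @export
default_planted_effects <- function(annotation, n_assoc = 30,
                                    beta_assoc = -16, n_het = 14,
                                    beta_het = c(behavioral = -4,
                                                 exercise = -8,
                                                 surgical = 12)) {
  pick <- function(sub, n) {
    m <- annotation$metabolite[annotation$sub_class == sub]
    if (length(m) < n) stop("subclass '", sub, "' has fewer than ", n,
                            " metabolites", call. = FALSE)
    m[seq_len(n)]
  }
  cohorts <- names(beta_het)
  list(
    effect_spec("Triradylcglycerols", pick("Triradylcglycerols", n_assoc),
                setNames(rep(beta_assoc, length(cohorts)), cohorts)),
    effect_spec("Amino acids, peptides, and analogues",
                pick("Amino acids, peptides, and analogues", n_het),
                beta_het)
  )
}

#' Generate a complete synthetic multi-cohort study
#'
#' Generates one [cohort_dataset()] per cohort spec (all sharing the
#' annotation produced by [generate_annotation()]), derives the metabolite
#' set database from the subclass labels (one set per subclass), and echoes
#' the planted-effect ledger for recovery tests.
#'
#' @param config A [generator_config()].
#' @return List with `cohorts` (named list of `cohort_dataset`),
#'   `annotation`, `sets` (named list: subclass -> member ids) and `truth`
#'   (the configured [effect_spec()] list).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"),
            length(config$cohort_specs) >= 1)
  annotation <- generate_annotation(config)
  cohorts <- list()
  for (i in seq_along(config$cohort_specs)) {
    spec <- config$cohort_specs[[i]]
    cohorts[[spec$name]] <- generate_cohort(
      spec, annotation, effects = config$effects,
      seed = config$seed + i,
      within_subclass_correlation = config$within_subclass_correlation,
      tg_correlation = config$tg_correlation,
      missingness_rate = config$missingness_rate,
      n_outcome_outliers = config$n_outcome_outliers,
      covariate_betas = config$covariate_betas)
  }
  sets <- split(annotation$metabolite, annotation$sub_class)
  list(cohorts = cohorts, annotation = annotation, sets = sets,
       truth = config$effects)
}
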