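#' Homeostatic Model Assessment of Insulin Resistance (HOMA-IR)
#'
#' Computes the HOMA-IR index from fasting glucose and insulin. Two unit
#' conventions are supported: `"mgdl"` (glucose in mg/dL, insulin in uU/mL,
#' divisor 405) and `"mmol"` (glucose in mmol/L, divisor 22.5). Both give
#' identical values for the same physical measurements.
#'
#' @param glucose Fasting blood glucose, mg/dL (or mmol/L for
#'   `convention = "mmol"`). Must be positive.
#' @param insulin Fasting insulin, uU/mL. Must be positive.
#' @param convention Unit convention, `"mgdl"` (default) or `"mmol"`.
#' @return Numeric vector of unitless HOMA-IR values.
#' @examples
#' compute_homa_ir(405, 1)   # 1
#' compute_homa_ir(100, 10)  # 2.469...
#' @export
compute_homa_ir <- function(glucose, insulin, convention = c("mgdl", "mmol")) {
  convention <- match.arg(convention)
  if (any(!is.na(glucose) & glucose <= 0))
    stop("glucose must be positive", call. = FALSE)
  if (any(!is.na(insulin) & insulin <= 0))
    stop("insulin must be positive", call. = FALSE)
  divisor <- if (convention == "mgdl") 405 else 22.5
  glucose * insulin / divisor
}

#' Percent change between two timepoints
#'
#' @param baseline Baseline value(s); must be non-zero.
#' @param followup Follow-up value(s).
#' @return `100 * (followup - baseline) / baseline`.
#' @examples
#' percent_change(4, 1)  # -75
#' percent_change(2, 3)  # +50
#' @export
percent_change <- function(baseline, followup) {
  if (any(!is.na(baseline) & baseline == 0))
    stop("baseline must be non-zero for percent change", call. = FALSE)
  100 * (followup - baseline) / baseline
}

#' Exclude extreme-outcome subjects
#'
#' Removes subjects whose outcome lies more than `k` standard deviations
#' from the cohort mean. Mean and SD are computed once, over all finite
#' values, before any exclusion; the rule is applied in a single pass (no
#' re-iteration after removal). With zero SD (all values equal) nothing is
#' excluded.
#'
#' @param values Numeric outcome vector (e.g. percent change in HOMA-IR).
#' @param k SD multiplier; default 5.
#' @param ids Optional identifiers parallel to `values`; defaults to
#'   indices.
#' @return List with `kept` (logical vector, TRUE = retained),
#'   `excluded_ids`, `mean` and `sd` used by the rule.
#' @export
exclude_outliers <- function(values, k = 5, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(values)
  finite <- is.finite(values)
  if (sum(finite) < 3)
    stop("need at least 3 finite outcome values", call. = FALSE)
  m <- mean(values[finite])
  s <- sd(values[finite])
  out <- finite & s > 0 & abs(values - m) > k * s
  list(kept = !out, excluded_ids = ids[out], mean = m, sd = s)
}

#' Natural-log transform an abundance matrix
#'
#' LC-MS peak areas are analyzed as the natural log of the area under the
#' curve to reduce skew. Zero abundances cannot be logged and are mapped to
#' missing, but are tracked separately from true missingness: the per-
#' metabolite zero rate ("zeroness") and the pre-existing missing rate are
#' attached as attributes. A matrix already on the log scale
#' (`scale = "log"`) passes through unchanged.
#'
#' @param x Numeric matrix, samples x metabolites. Raw abundances must be
#'   non-negative where present.
#' @param scale `"raw"` (default) to transform, `"log"` for identity
#'   pass-through.
#' @return The log-scale matrix with attributes `scale = "log"`,
#'   `zeroness` and `missingness` (named per-metabolite fractions).
#' @export
log_transform <- function(x, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  if (scale == "log") {
    attr(x, "scale") <- "log"
    return(x)
  }
  if (any(x < 0, na.rm = TRUE))
    stop("negative abundances are not valid on the raw scale", call. = FALSE)
  miss <- colMeans(is.na(x))
  zero <- colMeans(x == 0, na.rm = TRUE) * (1 - miss)
  is_zero <- !is.na(x) & x == 0
  x[is_zero] <- NA_real_
  out <- log(x)
  attr(out, "scale") <- "log"
  attr(out, "zeroness") <- zero
  attr(out, "missingness") <- miss
  out
}

#' Assemble a cohort dataset
#'
#' Bundles one cohort's phenotype table, log-abundance matrix and metabolite
#' annotation into the container consumed by the regression and
#' meta-analysis stages.
#'
#' @param name Cohort label.
#' @param phenotypes Data frame with one row per subject. Required columns:
#'   `subject_id`, `pct_change_homa_ir`, `age`, `sex`, `race`,
#'   `triglycerides`, `pct_change_weight`. If `pct_change_homa_ir` is
#'   absent it is derived from `homa_ir_baseline`/`homa_ir_followup`, which
#'   in turn are derived from glucose and insulin columns when present.
#' @param abundance Numeric matrix, samples x metabolites, rownames =
#'   subject ids. Interpreted per `scale`.
#' @param annotation Metabolite annotation data frame (column `metabolite`
#'   at minimum); may be `NULL`.
#' @param scale `"log"` (default) or `"raw"`; raw matrices are
#'   log-transformed on construction.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(name, phenotypes, abundance, annotation = NULL,
                           scale = c("log", "raw")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(phenotypes))
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    stop("abundance matrix must have subject ids as rownames", call. = FALSE)
  if (anyDuplicated(phenotypes$subject_id))
    stop("duplicate subject ids in phenotype table", call. = FALSE)
  missing_ids <- setdiff(rownames(abundance), phenotypes$subject_id)
  if (length(missing_ids))
    stop("abundance samples absent from phenotypes: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  if (!"pct_change_homa_ir" %in% names(phenotypes)) {
    if (!all(c("homa_ir_baseline", "homa_ir_followup") %in% names(phenotypes)) &&
        all(c("glucose_baseline", "insulin_baseline") %in% names(phenotypes)))
      phenotypes$homa_ir_baseline <-
        compute_homa_ir(phenotypes$glucose_baseline, phenotypes$insulin_baseline)
    if (all(c("homa_ir_baseline", "homa_ir_followup") %in% names(phenotypes)))
      phenotypes$pct_change_homa_ir <-
        percent_change(phenotypes$homa_ir_baseline, phenotypes$homa_ir_followup)
    else
      stop("phenotypes lack pct_change_homa_ir and the columns to derive it",
           call. = FALSE)
  }
  req <- c("subject_id", "age", "sex", "race", "triglycerides",
           "pct_change_weight")
  absent <- setdiff(req, names(phenotypes))
  if (length(absent))
    stop("phenotype table missing required columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  abundance <- log_transform(abundance, scale = scale)
  phenotypes <- phenotypes[match(rownames(abundance), phenotypes$subject_id), ,
                           drop = FALSE]
  rownames(phenotypes) <- NULL
  structure(
    list(name = name, phenotypes = phenotypes, abundance = abundance,
         annotation = annotation),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", x$name, ": ", nrow(x$abundance), " subjects x ",
      ncol(x$abundance), " metabolites\n", sep = "")
  invisible(x)
}

#' Apply the outcome-outlier exclusion to a cohort
#'
#' Single pre-analysis pass of the `k`-SD rule on percent change in HOMA-IR;
#' excluded subjects are dropped from both phenotypes and abundances.
#'
#' @param cohort A [cohort_dataset()].
#' @param k SD multiplier, default 5.
#' @return The filtered `cohort_dataset`, with attribute `excluded_ids`.
#' @export
apply_outlier_exclusion <- function(cohort, k = 5) {
  res <- exclude_outliers(cohort$phenotypes$pct_change_homa_ir, k = k,
                          ids = cohort$phenotypes$subject_id)
  cohort$phenotypes <- cohort$phenotypes[res$kept, , drop = FALSE]
  cohort$abundance <- cohort$abundance[res$kept, , drop = FALSE]
  attr(cohort, "excluded_ids") <- res$excluded_ids
  cohort
}

# Closed-form simple OLS of y on (1, x), vectorized over the columns of X.
# Complete cases per column; classical (homoscedastic) SEs, t inference.
.ols_simple <- function(X, y) {
  ok <- !is.na(X) & !is.na(y)
  n <- colSums(ok)
  X0 <- ifelse(ok, X, 0)
  y0 <- ifelse(ok, y, 0)
  sumx <- colSums(X0)
  sumy <- colSums(y0)
  sumxx <- colSums(X0 * X0)
  sumyy <- colSums(y0 * y0)
  sumxy <- colSums(X0 * y0)
  sxx <- sumxx - sumx^2 / n
  syy <- sumyy - sumy^2 / n
  sxy <- sumxy - sumx * sumy / n
  bad <- n < 3 | sxx <= .Machine$double.eps * pmax(1, sumxx)
  sxx[bad] <- NA_real_
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  df <- pmax(n - 2, 1)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  beta[bad] <- se[bad] <- p[bad] <- NA_real_
  data.frame(metabolite = colnames(X), beta = beta, se = se, n = as.integer(n),
             p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate regression of outcome change on one metabolite
#'
#' Ordinary least squares of percent change in HOMA-IR on an intercept and
#' the log metabolite abundance, on complete cases. Metabolites with fewer
#' than 3 complete cases or zero variance are reported as absent (all-`NA`
#' estimate), mirroring how undetected metabolites are carried through the
#' meta-analysis.
#'
#' @param cohort A [cohort_dataset()] (outliers already excluded).
#' @param metabolite Metabolite id (column of the abundance matrix).
#' @return One-row data frame: `metabolite`, `cohort`, `model_form`,
#'   `beta`, `se`, `n`, `p`.
#' @seealso [fit_full()], [fit_cohort()]
#' @export
fit_univariate <- function(cohort, metabolite) {
  stopifnot(metabolite %in% colnames(cohort$abundance))
  res <- .ols_simple(cohort$abundance[, metabolite, drop = FALSE],
                     cohort$phenotypes$pct_change_homa_ir)
  cbind(res[, "metabolite", drop = FALSE],
        cohort = cohort$name, model_form = "univariate",
        res[, c("beta", "se", "n", "p")])
}

# Build the covariate design (minus intercept and metabolite) for the full
# model. Race and sex are indicator-coded with the largest category within
# the cohort as reference; indicators constant on the complete cases in use
# are dropped.
.covariate_design <- function(ph) {
  dummies <- function(f, prefix) {
    f <- as.factor(f)
    tab <- sort(table(f), decreasing = TRUE)
    ref <- names(tab)[1]
    lev <- setdiff(names(tab), ref)
    if (!length(lev)) return(NULL)
    m <- vapply(lev, function(l) as.numeric(f == l), numeric(length(f)))
    colnames(m) <- paste0(prefix, lev)
    m
  }
  cbind(age = ph$age,
        dummies(ph$sex, "sex"),
        dummies(ph$race, "race"),
        triglycerides = ph$triglycerides,
        pct_change_weight = ph$pct_change_weight)
}

#' Covariate-adjusted ("full model") regression for one metabolite
#'
#' OLS of percent change in HOMA-IR on the log metabolite abundance,
#' adjusted for age, sex, race, baseline clinical triglycerides and percent
#' change in weight. Only the metabolite coefficient is reported. Race and
#' sex are indicator-coded with the cohort's largest category as reference;
#' indicators that are constant on the complete cases (e.g. a single race
#' level) are dropped automatically. A genuinely rank-deficient design is
#' an error naming the offending columns.
#'
#' @inheritParams fit_univariate
#' @return One-row data frame as in [fit_univariate()] with
#'   `model_form = "full"`.
#' @export
fit_full <- function(cohort, metabolite) {
  stopifnot(metabolite %in% colnames(cohort$abundance))
  fit_full_all(cohort, metabolites = metabolite)
}

# Full-model fits for many metabolites; the covariate block is built once.
fit_full_all <- function(cohort, metabolites = colnames(cohort$abundance)) {
  ph <- cohort$phenotypes
  y <- ph$pct_change_homa_ir
  Z <- .covariate_design(ph)
  cov_ok <- !is.na(y) & complete.cases(Z)
  out <- lapply(metabolites, function(m) {
    x <- cohort$abundance[, m]
    ok <- cov_ok & !is.na(x)
    n <- sum(ok)
    p_base <- 2L + ncol(Z)          # intercept + metabolite + covariates
    if (n < p_base + 1L || length(unique(x[ok])) < 2L)
      return(data.frame(metabolite = m, cohort = cohort$name,
                        model_form = "full", beta = NA_real_, se = NA_real_,
                        n = as.integer(n), p = NA_real_,
                        stringsAsFactors = FALSE))
    Zi <- Z[ok, , drop = FALSE]
    keep <- apply(Zi, 2, function(col) length(unique(col)) > 1L)
    Zi <- Zi[, keep, drop = FALSE]
    D <- cbind(`(Intercept)` = 1, metabolite = x[ok], Zi)
    fit <- lm.fit(D, y[ok])
    if (fit$rank < ncol(D)) {
      dropped <- colnames(D)[fit$qr$pivot[(fit$rank + 1L):ncol(D)]]
      stop("rank-deficient design for metabolite ", m, "; offending columns: ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    rss <- sum(fit$residuals^2)
    df <- n - ncol(D)
    sigma2 <- rss / df
    R <- fit$qr$qr[seq_len(ncol(D)), , drop = FALSE]
    R[lower.tri(R)] <- 0
    Rinv <- backsolve(R, diag(ncol(D)))
    V <- sigma2 * tcrossprod(Rinv)
    piv <- fit$qr$pivot
    se_all <- sqrt(diag(V))[order(piv)]
    j <- match("metabolite", colnames(D))
    beta <- fit$coefficients[["metabolite"]]
    se <- se_all[j]
    tval <- beta / se
    data.frame(metabolite = m, cohort = cohort$name, model_form = "full",
               beta = beta, se = se, n = as.integer(n),
               p = 2 * pt(-abs(tval), df), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit one model form for every metabolite in a cohort
#'
#' @param cohort A [cohort_dataset()], outliers already excluded (see
#'   [apply_outlier_exclusion()]).
#' @param model_form `"univariate"` or `"full"`.
#' @return Data frame with one row per metabolite: `metabolite`, `cohort`,
#'   `model_form`, `beta`, `se`, `n`, `p`. Metabolites that could not be
#'   fit (too few complete cases, zero variance) carry `NA` estimates.
#' @export
fit_cohort <- function(cohort, model_form = c("univariate", "full")) {
  model_form <- match.arg(model_form)
  if (model_form == "univariate") {
    res <- .ols_simple(cohort$abundance, cohort$phenotypes$pct_change_homa_ir)
    cbind(res[, "metabolite", drop = FALSE],
          cohort = cohort$name, model_form = "univariate",
          res[, c("beta", "se", "n", "p")])
  } else {
    fit_full_all(cohort)
  }
}
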