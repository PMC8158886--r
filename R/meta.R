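#' Inverse-variance fixed-effects pooling
#'
#' Pools study estimates with weights `w_i = 1/se_i^2`:
#' `beta = sum(w*b)/sum(w)`, `se = 1/sqrt(sum(w))`, z-based two-sided
#' normal inference.
#'
#' @param beta Numeric vector of study effect estimates.
#' @param se Matching standard errors (> 0).
#' @return List: `beta`, `se`, `z`, `p`.
#' @export
fixed_effects <- function(beta, se) {
  .check_estimates(beta, se)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  list(beta = b, se = s, z = z, p = 2 * pnorm(-abs(z)))
}

.check_estimates <- function(beta, se) {
  if (length(beta) == 0)
    stop("no study estimates supplied", call. = FALSE)
  if (length(beta) != length(se))
    stop("beta and se lengths differ", call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("standard errors must be positive and finite", call. = FALSE)
  invisible(TRUE)
}

#' Cochran Q test of heterogeneity
#'
#' `Q = sum(w_i (b_i - b_fixed)^2)` with fixed-effects weights
#' `w_i = 1/se_i^2`; under homogeneity Q ~ chi-squared with k - 1 df. A
#' single study returns `Q = 0`, `df = 0` and a missing p-value.
#'
#' @inheritParams fixed_effects
#' @return List: `Q`, `df`, `p`.
#' @export
cochran_q <- function(beta, se) {
  .check_estimates(beta, se)
  k <- length(beta)
  if (k == 1) return(list(Q = 0, df = 0L, p = NA_real_))
  w <- 1 / se^2
  b_fixed <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b_fixed)^2)
  list(Q = Q, df = k - 1L, p = pchisq(Q, df = k - 1, lower.tail = FALSE))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator of the between-study variance,
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effects weights, then inverse-variance pooling with random-effects
#' weights `w*_i = 1/(se_i^2 + tau2)` and z-based normal inference. With
#' one study, or whenever `Q <= k - 1`, the result coincides with the
#' fixed-effects summary.
#'
#' @inheritParams fixed_effects
#' @return List: `tau2`, `beta`, `se`, `z`, `p`.
#' @export
dersimonian_laird <- function(beta, se) {
  .check_estimates(beta, se)
  k <- length(beta)
  if (k == 1) {
    fe <- fixed_effects(beta, se)
    return(c(list(tau2 = 0), fe))
  }
  w <- 1 / se^2
  Q <- cochran_q(beta, se)$Q
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (Q - (k - 1)) / denom) else 0
  ws <- 1 / (se^2 + tau2)
  b <- sum(ws * beta) / sum(ws)
  s <- 1 / sqrt(sum(ws))
  z <- b / s
  list(tau2 = tau2, beta = b, se = s, z = z, p = 2 * pnorm(-abs(z)))
}

#' H and I-squared heterogeneity statistics
#'
#' `H = sqrt(Q/df)` (not truncated) and `I2 = max(0, (Q - df)/Q)`, the
#' proportion of total variability attributable to between-study
#' heterogeneity; `I2 = 0` when `Q = 0`.
#'
#' @param Q Cochran Q statistic (>= 0).
#' @param df Degrees of freedom, k - 1 (>= 1).
#' @return List: `H`, `I2`.
#' @export
h_and_i2 <- function(Q, df) {
  stopifnot(df >= 1, Q >= 0)
  H <- sqrt(Q / df)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) else 0
  list(H = H, I2 = I2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1. Missing entries pass through as
#' missing and do not count toward the family size m.
#'
#' @param p Numeric vector of p-values in (0, 1], `NA` allowed.
#' @return Adjusted vector, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Pooled missingness filter
#'
#' Retains metabolites whose pooled missing fraction across all cohorts'
#' samples is strictly below `threshold` and whose identity is known
#' (named); unnamed features are removed regardless of missingness. A
#' metabolite absent from a cohort's matrix counts as missing for all of
#' that cohort's samples.
#'
#' @param cohorts List of [cohort_dataset()].
#' @param annotation Annotation data frame with columns `metabolite` and
#'   (optionally) `known`; metabolites absent from the annotation are
#'   treated as unnamed.
#' @param threshold Strict upper bound on pooled missing fraction; default
#'   0.25.
#' @return List: `retained` (character), `removed` (character),
#'   `n_removed`, and `missingness` / `zeroness` (named pooled fractions
#'   over all metabolites).
#' @export
missingness_filter <- function(cohorts, annotation, threshold = 0.25) {
  mets <- unique(unlist(lapply(cohorts, function(co) colnames(co$abundance))))
  n_total <- sum(vapply(cohorts, function(co) nrow(co$abundance), 0L))
  n_missing <- setNames(numeric(length(mets)), mets)
  n_zero <- setNames(numeric(length(mets)), mets)
  for (co in cohorts) {
    present <- intersect(mets, colnames(co$abundance))
    nm <- colSums(is.na(co$abundance[, present, drop = FALSE]))
    n_missing[present] <- n_missing[present] + nm
    zf <- attr(co$abundance, "zeroness")
    if (!is.null(zf))
      n_zero[present] <- n_zero[present] + zf[present] * nrow(co$abundance)
    absent <- setdiff(mets, present)
    n_missing[absent] <- n_missing[absent] + nrow(co$abundance)
  }
  frac <- n_missing / n_total
  known <- if ("known" %in% names(annotation)) {
    annotation$metabolite[annotation$known]
  } else annotation$metabolite
  keep <- frac < threshold & mets %in% known
  list(retained = mets[keep], removed = mets[!keep],
       n_removed = sum(!keep),
       missingness = frac, zeroness = n_zero / n_total)
}

#' Meta-analyze per-cohort regression results
#'
#' Combines per-cohort regression tables (from [fit_cohort()]) into one row
#' per metabolite: fixed-effects and DerSimonian-Laird random-effects
#' summaries, Cochran Q with df and p, tau-squared, H and I-squared,
#' per-cohort beta/SE/N columns, a sign string over cohorts (`"?"` where a
#' cohort lacks the metabolite), and Benjamini-Hochberg adjusted p-values
#' across the retained metabolites. Metabolites measured in a single cohort
#' are retained (their pooled estimate equals the cohort estimate, tau2 =
#' 0) but have no defined heterogeneity p-value.
#'
#' @param results Either one data frame with a `cohort` column or a list of
#'   per-cohort data frames, each with columns `metabolite`, `cohort`,
#'   `beta`, `se`, `n`, `p`.
#' @param annotation Optional annotation table; contributes `Method`,
#'   `HMDB_ID` and taxonomy columns.
#' @param retain Optional character vector of metabolites to keep (e.g.
#'   from [missingness_filter()]); default all.
#' @param missingness,zeroness Optional named pooled fractions to report.
#' @return Data frame in the standard results schema: `Metabolite`,
#'   `N_Samples`, `N_Studies`, `Beta_Fixed`, `SE_Fixed`, `Zvalue_Fixed`,
#'   `Pvalue_Fixed`, `Beta_Random`, `SE_Random`, `Zvalue_Random`,
#'   `Pvalue_Random`, `Q`, `Q_df`, `Q_Pvalue`, `Tau2`, `H`, `I2`, one
#'   `<cohort>_Beta` / `<cohort>_SE` / `<cohort>_Num` triple per cohort,
#'   `Direction`, annotation columns, `missingness`, `zeroness`,
#'   `Pvalue_Adj_Fixed`, `Pvalue_Adj_Random`.
#' @export
run_meta <- function(results, annotation = NULL, retain = NULL,
                     missingness = NULL, zeroness = NULL) {
  if (is.data.frame(results)) results <- split(results, results$cohort)
  if (!length(results)) stop("no cohort result tables", call. = FALSE)
  cohort_names <- vapply(results, function(d) as.character(d$cohort[1]), "")
  results <- setNames(results, cohort_names)

  mets <- sort(unique(unlist(lapply(results, `[[`, "metabolite"))))
  if (!is.null(retain)) mets <- mets[mets %in% retain]
  if (!length(mets)) stop("no metabolites to meta-analyze", call. = FALSE)

  k <- length(results)
  B <- SE <- matrix(NA_real_, length(mets), k,
                    dimnames = list(mets, cohort_names))
  N <- matrix(NA_integer_, length(mets), k,
              dimnames = list(mets, cohort_names))
  for (cn in cohort_names) {
    d <- results[[cn]]
    i <- match(d$metabolite, mets)
    sel <- !is.na(i)
    B[i[sel], cn] <- d$beta[sel]
    SE[i[sel], cn] <- d$se[sel]
    N[i[sel], cn] <- d$n[sel]
  }

  rows <- lapply(seq_along(mets), function(j) {
    ok <- !is.na(B[j, ]) & !is.na(SE[j, ]) & SE[j, ] > 0
    if (!any(ok)) return(NULL)
    b <- B[j, ok]; s <- SE[j, ok]
    fe <- fixed_effects(b, s)
    qq <- cochran_q(b, s)
    re <- dersimonian_laird(b, s)
    hi <- if (qq$df >= 1) h_and_i2(qq$Q, qq$df) else list(H = NA_real_,
                                                          I2 = NA_real_)
    dir <- paste(ifelse(is.na(B[j, ]), "?",
                        ifelse(B[j, ] < 0, "-", "+")), collapse = "")
    data.frame(Metabolite = mets[j],
               N_Samples = sum(N[j, ok]), N_Studies = sum(ok),
               Beta_Fixed = fe$beta, SE_Fixed = fe$se,
               Zvalue_Fixed = fe$z, Pvalue_Fixed = fe$p,
               Beta_Random = re$beta, SE_Random = re$se,
               Zvalue_Random = re$z, Pvalue_Random = re$p,
               Q = qq$Q, Q_df = qq$df, Q_Pvalue = qq$p,
               Tau2 = re$tau2, H = hi$H, I2 = hi$I2,
               Direction = dir, stringsAsFactors = FALSE)
  })
  dropped <- mets[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    warning("dropped metabolites with no usable cohort estimate: ",
            paste(head(dropped, 5), collapse = ", "))
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])

  i <- match(tab$Metabolite, mets)
  for (cn in cohort_names) {
    tab[[paste0(cn, "_Beta")]] <- B[i, cn]
    tab[[paste0(cn, "_SE")]] <- SE[i, cn]
    tab[[paste0(cn, "_Num")]] <- N[i, cn]
  }
  if (!is.null(annotation)) {
    ai <- match(tab$Metabolite, annotation$metabolite)
    tab$Method <- annotation$method[ai]
    tab$HMDB_ID <- annotation$hmdb_id[ai]
    tab$super_class <- annotation$super_class[ai]
    tab$class <- annotation$class[ai]
    tab$sub_class <- annotation$sub_class[ai]
    if ("cv" %in% names(annotation)) tab$CV <- annotation$cv[ai]
  }
  if (!is.null(missingness))
    tab$missingness <- unname(missingness[tab$Metabolite])
  if (!is.null(zeroness))
    tab$zeroness <- unname(zeroness[tab$Metabolite])
  tab$Pvalue_Adj_Fixed <- bh_fdr(tab$Pvalue_Fixed)
  tab$Pvalue_Adj_Random <- bh_fdr(tab$Pvalue_Random)
  rownames(tab) <- NULL
  tab
}

#' Volcano-plot data export
#'
#' Tidy data for a volcano display of a meta-analysis table: random-effects
#' effect size against -log10 of the chosen p-value, colored by subclass.
#'
#' @param meta_table Output of [run_meta()].
#' @param p_column Which p-value to plot; default `"Pvalue_Adj_Random"`.
#' @return Data frame: `Metabolite`, `Beta_Random`, `neg_log10_p`,
#'   `sub_class`.
#' @export
volcano_data <- function(meta_table, p_column = "Pvalue_Adj_Random") {
  stopifnot(p_column %in% names(meta_table))
  data.frame(Metabolite = meta_table$Metabolite,
             Beta_Random = meta_table$Beta_Random,
             neg_log10_p = -log10(meta_table[[p_column]]),
             sub_class = if ("sub_class" %in% names(meta_table))
               meta_table$sub_class else NA_character_,
             stringsAsFactors = FALSE)
}
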