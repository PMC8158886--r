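#' Rank metabolites for set enrichment
#'
#' Orders the meta-analysis table by the chosen statistic, descending:
#' `"signed_z"` uses the random-effects z-score (association analysis),
#' `"q_stat"` uses the Cochran Q statistic (heterogeneity analysis; only
#' metabolites observed in at least two cohorts have a defined Q and are
#' kept). Ties break lexicographically on metabolite id so the ranking is
#' deterministic.
#'
#' @param meta_table Output of [run_meta()].
#' @param mode `"signed_z"` or `"q_stat"`.
#' @return An object of class `ranked_list`: data frame with `metabolite`
#'   and `stat`, plus a `mode` attribute.
#' @export
rank_metabolites <- function(meta_table, mode = c("signed_z", "q_stat")) {
  mode <- match.arg(mode)
  if (!nrow(meta_table)) stop("empty meta-analysis table", call. = FALSE)
  if (mode == "signed_z") {
    tab <- data.frame(metabolite = meta_table$Metabolite,
                      stat = meta_table$Zvalue_Random,
                      stringsAsFactors = FALSE)
  } else {
    keep <- meta_table$N_Studies >= 2
    tab <- data.frame(metabolite = meta_table$Metabolite[keep],
                      stat = meta_table$Q[keep], stringsAsFactors = FALSE)
  }
  tab <- tab[!is.na(tab$stat), , drop = FALSE]
  if (!nrow(tab)) stop("no metabolites with a defined statistic",
                       call. = FALSE)
  tab <- tab[order(-tab$stat, tab$metabolite), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("ranked_list", "data.frame"), mode = mode)
}

# Fast ES for hit positions `idx` (sorted, 1-based) in a ranked list with
# precomputed weights a = |stat|^w. The running sum is piecewise linear;
# its extrema can only occur immediately after a hit or immediately before
# one, so only 2*length(idx) candidates are examined. When the positive and
# negative extremes have (numerically) equal magnitude the positive one is
# taken; the 1e-9 relative slack makes the tie-break immune to the order of
# floating-point summation.
.es_at <- function(a, N, idx) {
  n <- length(idx)
  u <- a[idx]
  tot <- sum(u)
  if (tot <= 0) stop("all member statistics are zero; enrichment score ",
                     "undefined with positive weight exponent", call. = FALSE)
  H <- cumsum(u) / tot
  miss <- (idx - seq_len(n)) / (N - n)
  after <- H - miss
  before <- c(0, H[-n]) - miss
  maxv <- max(after)
  minv <- min(before)
  if (maxv + minv >= -1e-9 * max(abs(maxv), abs(minv))) maxv else minv
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: each set member ("hit") at position i increments
#' the running sum by `|stat_i|^w / sum(|stat_hits|^w)`, each non-member
#' decrements it by `1/(N - n)`. The enrichment score is the extremum of
#' the walk with the largest absolute value, sign retained, so sets
#' concentrated at the top of the list score positive and sets at the
#' bottom negative. The walk returns to 0 at the end of the list.
#'
#' @param ranked A [rank_metabolites()] result, or any data frame with
#'   `metabolite` and `stat` in ranked order.
#' @param members Character vector of set member ids.
#' @param weight_exponent Exponent w on `|stat|` for hit increments;
#'   default 1 (classic weighted GSEA), 0 gives the unweighted
#'   Kolmogorov-Smirnov walk.
#' @return List: `ES`, `running_sum` (length-N numeric, the walk after
#'   each position), `hit_positions`.
#' @export
enrichment_score <- function(ranked, members, weight_exponent = 1) {
  N <- nrow(ranked)
  idx <- which(ranked$metabolite %in% members)
  n <- length(idx)
  if (n == 0) stop("set has no members in the ranked list", call. = FALSE)
  if (n >= N) stop("set must be smaller than the ranked list", call. = FALSE)
  a <- abs(ranked$stat)^weight_exponent
  tot <- sum(a[idx])
  if (tot <= 0)
    stop("all member statistics are zero; enrichment score undefined ",
         "with positive weight exponent", call. = FALSE)
  step <- rep(-1 / (N - n), N)
  step[idx] <- a[idx] / tot
  rs <- cumsum(step)
  es <- .es_at(a, N, idx)
  list(ES = es, running_sum = rs, hit_positions = idx)
}

#' Permutation null distribution of the enrichment score
#'
#' Draws size-matched random member subsets of the ranked list and records
#' each subset's enrichment score. The null depends on the set only through
#' its size, so one sample is shared across all sets of equal size. When
#' the number of distinct memberships `choose(N, set_size)` does not exceed
#' `n_perm`, all memberships are enumerated instead of sampled, making
#' small cases exact.
#'
#' @param ranked A [rank_metabolites()] result.
#' @param set_size Number of members (< list length).
#' @param n_perm Number of permutations; default 10000. The reference
#'   analysis scale is 1e6; smaller values trade p-value resolution for
#'   runtime.
#' @param seed Integer seed (ignored in exhaustive mode, which is
#'   deterministic).
#' @param weight_exponent As in [enrichment_score()].
#' @return Numeric vector of null enrichment scores with attribute
#'   `exhaustive`.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 10000, seed = 1L,
                             weight_exponent = 1) {
  N <- nrow(ranked)
  stopifnot(n_perm >= 1, set_size >= 1, set_size < N)
  a <- abs(ranked$stat)^weight_exponent
  n_comb <- choose(N, set_size)
  if (is.finite(n_comb) && n_comb <= n_perm) {
    combs <- combn(N, set_size)
    es <- apply(combs, 2, function(idx) .es_at(a, N, idx))
    return(structure(es, exhaustive = TRUE))
  }
  set.seed(seed)
  es <- vapply(seq_len(n_perm), function(b) {
    idx <- sort.int(sample.int(N, set_size))
    .es_at(a, N, idx)
  }, numeric(1))
  structure(es, exhaustive = FALSE)
}

#' Permutation p-value for an enrichment score
#'
#' One-sided in the direction of the observed score, against the null
#' scores of the same sign: `p = (nMoreExtreme + 1) / (n_same_sign + 1)`,
#' where `nMoreExtreme` counts null scores at least as extreme as the
#' observed one. The +1 smoothing keeps p strictly positive at finite
#' permutation counts. Null scores within 1e-9 relative of the observed
#' score count as ties (i.e. as "at least as extreme"): running-sum scores
#' of different memberships can coincide exactly in exact arithmetic, and
#' the slack keeps the count independent of floating-point summation
#' order.
#'
#' @param es Observed enrichment score.
#' @param null_es Numeric vector of null scores from [permutation_null()].
#' @return List: `pval`, `nMoreExtreme`, `n_same_sign`.
#' @export
permutation_pvalue <- function(es, null_es) {
  stopifnot(length(null_es) >= 1)
  eps <- 1e-9 * abs(es)
  if (es >= 0) {
    pool <- null_es[null_es > 0]
    n_ext <- sum(pool >= es - eps)
  } else {
    pool <- null_es[null_es < 0]
    n_ext <- sum(pool <= es + eps)
  }
  list(pval = (n_ext + 1) / (length(pool) + 1),
       nMoreExtreme = n_ext, n_same_sign = length(pool))
}

#' Normalized enrichment score
#'
#' `NES = ES / mean(|null ES|)` over null scores of the same sign as the
#' observed score, putting sets of different sizes on a comparable scale.
#'
#' @inheritParams permutation_pvalue
#' @return NES, or `NA` (with a warning) if no same-sign null score exists.
#' @export
normalized_es <- function(es, null_es) {
  pool <- if (es >= 0) null_es[null_es > 0] else null_es[null_es < 0]
  if (!length(pool)) {
    warning("no same-sign null scores; NES undefined")
    return(NA_real_)
  }
  es / mean(abs(pool))
}

#' Metabolite-set enrichment analysis
#'
#' Ranks metabolites by the chosen statistic, scores every qualifying set
#' (at least `min_size` members present in the ranked list), calibrates
#' each score against a size-matched permutation null (shared across sets
#' of equal size), normalizes (NES) and applies Benjamini-Hochberg FDR
#' across the tested sets. The result is sorted by adjusted then raw
#' p-value.
#'
#' @param meta_table Output of [run_meta()].
#' @param sets Named list: set name -> member metabolite ids (e.g. HMDB
#'   subclass sets from [read_gmt()] or [generate_study()]).
#' @param mode `"signed_z"` (association) or `"q_stat"` (heterogeneity).
#' @param n_perm Permutations per set size; default 10000 (see
#'   [permutation_null()]).
#' @param min_size Minimum members present for a set to be tested;
#'   default 5.
#' @param weight_exponent As in [enrichment_score()].
#' @param seed Integer seed. Nulls are generated per distinct set size in
#'   increasing size order, so results do not depend on the ordering of
#'   `sets`.
#' @return Data frame sorted by `padj`: `pathway`, `pval`, `padj`, `ES`,
#'   `NES`, `nMoreExtreme`, `size`. The `ranked_list` used is attached as
#'   an attribute.
#' @export
run_enrichment <- function(meta_table, sets, mode = c("signed_z", "q_stat"),
                           n_perm = 10000, min_size = 5, weight_exponent = 1,
                           seed = 1L) {
  mode <- match.arg(mode)
  ranked <- rank_metabolites(meta_table, mode = mode)
  N <- nrow(ranked)
  present <- lapply(sets, function(m) unique(m[m %in% ranked$metabolite]))
  sizes <- lengths(present)
  qualify <- sizes >= min_size & sizes < N
  if (!any(qualify)) {
    warning("no set qualifies for testing (min_size = ", min_size, ")")
    return(structure(data.frame(pathway = character(0), pval = numeric(0),
                                padj = numeric(0), ES = numeric(0),
                                NES = numeric(0), nMoreExtreme = integer(0),
                                size = integer(0)),
                     ranked_list = ranked))
  }
  present <- present[qualify]
  sizes <- sizes[qualify]

  nulls <- list()
  for (sz in sort(unique(sizes)))
    nulls[[as.character(sz)]] <-
      permutation_null(ranked, sz, n_perm = n_perm, seed = seed + sz,
                       weight_exponent = weight_exponent)

  res <- lapply(names(present), function(nm) {
    es <- enrichment_score(ranked, present[[nm]],
                           weight_exponent = weight_exponent)$ES
    null_es <- nulls[[as.character(length(present[[nm]]))]]
    pv <- permutation_pvalue(es, null_es)
    data.frame(pathway = nm, pval = pv$pval, ES = es,
               NES = normalized_es(es, null_es),
               nMoreExtreme = as.integer(pv$nMoreExtreme),
               size = length(present[[nm]]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$padj <- bh_fdr(tab$pval)
  tab <- tab[order(tab$padj, tab$pval, tab$pathway),
             c("pathway", "pval", "padj", "ES", "NES", "nMoreExtreme",
               "size")]
  rownames(tab) <- NULL
  structure(tab, ranked_list = ranked)
}

#' Enrichment-plot data for one set
#'
#' Tidy export for the classic enrichment display: the running-sum curve
#' over ranked positions plus hit ticks whose lengths are the members'
#' ranking statistics.
#'
#' @inheritParams enrichment_score
#' @return List of two data frames: `curve` (`position`, `running_sum`) and
#'   `ticks` (`position`, `metabolite`, `stat`).
#' @export
enrichment_plot_data <- function(ranked, members, weight_exponent = 1) {
  es <- enrichment_score(ranked, members, weight_exponent = weight_exponent)
  list(curve = data.frame(position = seq_len(nrow(ranked)),
                          running_sum = es$running_sum),
       ticks = data.frame(position = es$hit_positions,
                          metabolite = ranked$metabolite[es$hit_positions],
                          stat = ranked$stat[es$hit_positions],
                          stringsAsFactors = FALSE))
}
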