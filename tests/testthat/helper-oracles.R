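# Independent oracle implementations used to validate the package's
# statistics. These deliberately re-derive every quantity straight from the
# defining formulas (normal equations, explicit running-sum walk, full
# membership enumeration) rather than calling package internals.

# Inverse-variance fixed effects, Cochran Q, DerSimonian-Laird moments,
# H and I^2, all from the formulas.
oracle_meta <- function(beta, se) {
  w <- 1 / se^2
  sw <- sum(w)
  beta_fixed <- sum(w * beta) / sw
  se_fixed <- sqrt(1 / sw)
  z_fixed <- beta_fixed / se_fixed
  p_fixed <- 2 * pnorm(abs(z_fixed), lower.tail = FALSE)
  k <- length(beta)
  Q <- sum(w * (beta - beta_fixed)^2)
  df <- k - 1
  q_p <- if (df >= 1) pchisq(Q, df, lower.tail = FALSE) else NA_real_
  tau2 <- if (df >= 1) max(0, (Q - df) / (sw - sum(w^2) / sw)) else 0
  wr <- 1 / (se^2 + tau2)
  beta_random <- sum(wr * beta) / sum(wr)
  se_random <- sqrt(1 / sum(wr))
  z_random <- beta_random / se_random
  p_random <- 2 * pnorm(abs(z_random), lower.tail = FALSE)
  H <- if (df >= 1) sqrt(Q / df) else NA_real_
  I2 <- if (df >= 1 && Q > 0) max(0, (Q - df) / Q) else 0
  list(beta_fixed = beta_fixed, se_fixed = se_fixed, z_fixed = z_fixed,
       p_fixed = p_fixed, Q = Q, df = df, q_p = q_p, tau2 = tau2,
       beta_random = beta_random, se_random = se_random,
       z_random = z_random, p_random = p_random, H = H, I2 = I2)
}

# OLS via the normal equations, classical SEs, t-based two-sided p.
# X must include the intercept column.
oracle_ols <- function(X, y) {
  X <- as.matrix(X)
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  r <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(r^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  tval <- b / se
  p <- 2 * pt(-abs(tval), df)
  list(beta = drop(b), se = se, p = drop(p), n = nrow(X), df = df)
}

# Enrichment score by walking the full list position by position. The
# signed extremum of largest magnitude is returned, with the positive
# extreme preferred when the two magnitudes agree to 1e-9 relative (same
# convention as the package, so exact-tie cases compare equal).
oracle_es <- function(stats, hits, w = 1) {
  N <- length(stats)
  n <- sum(hits)
  tot <- sum(abs(stats[hits])^w)
  cur <- 0
  rs <- numeric(N)
  for (i in seq_len(N)) {
    cur <- cur + if (hits[i]) abs(stats[i])^w / tot else -1 / (N - n)
    rs[i] <- cur
  }
  maxv <- max(rs, 0)
  minv <- min(rs, 0)
  if (maxv + minv >= -1e-9 * max(abs(maxv), abs(minv))) maxv else minv
}

# Exact permutation reference: enumerate every size-matched membership,
# score each with the walk oracle, and apply the same-sign +1 rule.
oracle_enrichment_exact <- function(stats, member_idx, w = 1) {
  N <- length(stats)
  n <- length(member_idx)
  es_obs <- oracle_es(stats, seq_len(N) %in% member_idx, w = w)
  combs <- combn(N, n)
  null_es <- apply(combs, 2, function(idx)
    oracle_es(stats, seq_len(N) %in% idx, w = w))
  eps <- 1e-9 * abs(es_obs)
  if (es_obs >= 0) {
    pool <- null_es[null_es > 0]
    n_ext <- sum(pool >= es_obs - eps)
  } else {
    pool <- null_es[null_es < 0]
    n_ext <- sum(pool <= es_obs + eps)
  }
  list(ES = es_obs, pval = (n_ext + 1) / (length(pool) + 1),
       nMoreExtreme = n_ext, null_es = null_es)
}

# Small two-cohort phenotype/abundance fixture with known structure.
make_fixture_cohort <- function(n = 40, p = 6, seed = 42, name = "fix",
                                confounded = FALSE) {
  set.seed(seed)
  ids <- sprintf("%s_%03d", name, seq_len(n))
  age <- rnorm(n, 55, 8)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  race <- sample(c("AA", "EA", "other"), n, replace = TRUE,
                 prob = c(.4, .5, .1))
  tg <- rnorm(n, 130, 50)
  pdw <- rnorm(n, -8, 4)
  X <- matrix(rnorm(n * p, 12, 1), n, p,
              dimnames = list(ids, sprintf("met_%02d", seq_len(p))))
  if (confounded) X[, 1] <- X[, 1] + 0.01 * tg  # shared driver with outcome
  y <- -10 * X[, 1] + 0.1 * tg + rnorm(n, 0, 5)
  ph <- data.frame(subject_id = ids, pct_change_homa_ir = y,
                   weight_baseline = rnorm(n, 95, 15),
                   pct_change_weight = pdw, age = age, sex = sex,
                   race = race, triglycerides = tg,
                   stringsAsFactors = FALSE)
  cohort_dataset(name, ph, X, scale = "log")
}
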