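# Brute-force linear-model oracle: explicit normal equations on a hand-built
# treatment-coded design matrix. Deliberately independent of lm()/emmeans.

oracle_design <- function(data, use_age = TRUE, use_season = TRUE) {
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  if (use_age) X <- cbind(X, age = data$age)
  if (use_season && nlevels(factor(data$season)) >= 2) {
    lev <- levels(factor(data$season))
    for (l in lev[-1]) X <- cbind(X, as.numeric(data$season == l))
    colnames(X)[(ncol(X) - length(lev) + 2):ncol(X)] <-
      paste0("season", lev[-1])
  }
  glev <- levels(factor(data$genotype))
  for (l in glev[-1]) X <- cbind(X, as.numeric(data$genotype == l))
  colnames(X)[(ncol(X) - length(glev) + 2):ncol(X)] <-
    paste0("genotype", glev[-1])
  X
}

oracle_ols <- function(y, X) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  rss <- sum(res^2)
  df <- length(y) - ncol(X)
  sigma2 <- rss / df
  list(beta = drop(beta), cov = sigma2 * XtXi, rss = rss, df = df,
       se = sqrt(diag(sigma2 * XtXi)))
}

# partial F for dropping the columns named in `drop_cols`
oracle_partial_f <- function(y, X, drop_cols) {
  full <- oracle_ols(y, X)
  Xr <- X[, !colnames(X) %in% drop_cols, drop = FALSE]
  red <- oracle_ols(y, Xr)
  q <- length(drop_cols)
  f <- ((red$rss - full$rss) / q) / (full$rss / full$df)
  list(F = f, df1 = q, df2 = full$df,
       p = pf(f, q, full$df, lower.tail = FALSE))
}

# least-square mean of one genotype level: prediction at the covariate grand
# mean with equal weight on every season level
oracle_lsm <- function(y, X, data, level, use_age = TRUE,
                       use_season = TRUE) {
  fit <- oracle_ols(y, X)
  row <- numeric(ncol(X))
  names(row) <- colnames(X)
  row["(Intercept)"] <- 1
  if (use_age) row["age"] <- mean(data$age)
  if (use_season && nlevels(factor(data$season)) >= 2) {
    lev <- levels(factor(data$season))
    row[paste0("season", lev[-1])] <- 1 / length(lev)
  }
  glev <- levels(factor(data$genotype))
  if (level != glev[1]) row[paste0("genotype", level)] <- 1
  est <- sum(row * fit$beta)
  se <- sqrt(drop(t(row) %*% fit$cov %*% row))
  c(lsm = est, se = se)
}

# random small association design for oracle-equivalence checks
random_design <- function(n = sample(18:30, 1), n_geno = 3,
                          n_season = sample(2:4, 1)) {
  data.frame(
    y = rnorm(n, 100, 10),
    age = runif(n, 100, 500),
    season = factor(sample(c("winter", "spring", "summer",
                             "autumn")[seq_len(n_season)], n,
                           replace = TRUE)),
    genotype = factor(sample(c("AA", "AB", "BB")[seq_len(n_geno)], n,
                             replace = TRUE))
  )
}

# keep a design usable: every factor level seen at least twice
valid_design <- function(d) {
  all(table(d$genotype) >= 2) && all(table(d$season) >= 2) &&
    nlevels(droplevels(d$genotype)) == nlevels(d$genotype) &&
    nlevels(droplevels(d$season)) == nlevels(d$season)
}
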