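test_that("with one balanced factor the model reduces to classical one-way
           ANOVA", {
  set.seed(17)
  d <- data.frame(
    y = rnorm(30, rep(c(10, 12, 15), each = 10)),
    genotype = factor(rep(c("AA", "AB", "BB"), each = 10))
  )
  fit <- fit_model(d, use_age = FALSE, use_season = FALSE)
  lsm <- least_square_means(fit)
  raw <- tapply(d$y, d$genotype, mean)
  expect_equal(lsm$lsm, as.vector(raw[lsm$level]))
  aovf <- summary(stats::aov(y ~ genotype, data = d))[[1]]
  expect_equal(fit$f_tests$F[fit$f_tests$term == "genotype"],
               aovf$`F value`[1])
  expect_equal(fit$f_tests$p[fit$f_tests$term == "genotype"],
               aovf$`Pr(>F)`[1])
})

test_that("fit, standard errors, partial F and LSMs match the brute-force
           normal-equation oracle on randomized designs", {
  set.seed(91)
  checked <- 0
  while (checked < 20) {
    d <- random_design()
    if (!valid_design(d)) next
    checked <- checked + 1
    fit <- fit_model(d)
    X <- oracle_design(d)
    ora <- oracle_ols(d$y, X)
    expect_equal(unname(coef(fit$lm)), unname(ora$beta),
                 tolerance = 1e-8)
    expect_equal(unname(sqrt(diag(vcov(fit$lm)))), unname(ora$se),
                 tolerance = 1e-8)
    gcols <- grep("^genotype", colnames(X), value = TRUE)
    pf_ <- oracle_partial_f(d$y, X, gcols)
    got <- fit$f_tests[fit$f_tests$term == "genotype", ]
    expect_equal(got$F, pf_$F, tolerance = 1e-8)
    expect_equal(got$p, pf_$p, tolerance = 1e-8)
    lsm <- least_square_means(fit)
    for (i in seq_len(nrow(lsm))) {
      o <- oracle_lsm(d$y, X, d, lsm$level[i])
      expect_equal(lsm$lsm[i], unname(o["lsm"]), tolerance = 1e-8)
      expect_equal(lsm$se[i], unname(o["se"]), tolerance = 1e-8)
    }
  }
})

test_that("least-square means are equivariant under a constant shift", {
  set.seed(5)
  d <- random_design(n = 28)
  while (!valid_design(d)) d <- random_design(n = 28)
  l0 <- least_square_means(fit_model(d))
  d2 <- d
  d2$y <- d$y + 42
  l1 <- least_square_means(fit_model(d2))
  expect_equal(l1$lsm, l0$lsm + 42)
  expect_equal(l1$se, l0$se)
})

test_that("with two levels the Tukey-adjusted p equals the two-sided t-test
           of the contrast", {
  set.seed(6)
  d <- random_design(n = 26, n_geno = 2)
  while (!valid_design(d)) d <- random_design(n = 26, n_geno = 2)
  fit <- fit_model(d)
  tk <- tukey_posthoc(fit)
  # the genotype coefficient t-test is the same contrast
  sm <- summary(fit$lm)$coefficients
  expect_equal(tk$pairs$p_adj,
               unname(sm[grep("^genotype", rownames(sm)), "Pr(>|t|)"]),
               tolerance = 1e-10)
})

test_that("compact letters share a letter exactly when levels do not
           differ", {
  set.seed(10)
  # indistinguishable groups: one shared letter
  d <- data.frame(y = rnorm(60, 10, 5),
                  genotype = factor(rep(c("AA", "AB", "BB"), 20)))
  fit <- fit_model(d, use_age = FALSE, use_season = FALSE)
  tk <- tukey_posthoc(fit)
  expect_equal(unname(tk$letters), rep("a", 3))

  # one clearly separated level gets its own letter
  d2 <- d
  d2$y <- d2$y + ifelse(d2$genotype == "BB", 50, 0)
  tk2 <- tukey_posthoc(fit_model(d2, use_age = FALSE, use_season = FALSE))
  expect_false(grepl(tk2$letters[["BB"]], tk2$letters[["AA"]], fixed = TRUE))
  expect_equal(tk2$letters[["AA"]], tk2$letters[["AB"]])
})

test_that("interaction fitting excludes low-frequency combinations before
           the fit", {
  herd <- simulate_herd(herd_config(
    n_animals = 60,
    markers = list(marker_spec("mA", c("A", "G"), 0.5),
                   marker_spec("mB", c("C", "T"), 0.92)),
    seed = 2))
  tr <- derive_traits(herd)
  combo <- paste(herd$genotypes$genotype[herd$genotypes$marker == "mA"],
                 herd$genotypes$genotype[herd$genotypes$marker == "mB"],
                 sep = "x")
  tab <- table(combo)
  expect_true(any(tab < 3)) # the rare-allele marker forces rare combos
  fit <- fit_interaction(tr, herd$genotypes, c("mA", "mB"), "TADWG",
                         min_count = 3)
  expect_true(all(fit$excluded_combinations$n < 3))
  lsm <- least_square_means(fit)
  expect_false(any(lsm$level %in% fit$excluded_combinations$combination))
  expect_lte(fit$n_used, 60 - sum(fit$excluded_combinations$n))

  # demanding more than any combination has is degenerate
  expect_error(fit_interaction(tr, herd$genotypes, c("mA", "mB"), "TADWG",
                               min_count = 100),
               "degenerate interaction")
})

test_that("model comparison prefers explanatory power, penalising useless
           terms", {
  set.seed(33)
  n <- 120
  d <- data.frame(
    age = runif(n, 100, 500),
    season = factor(sample(c("winter", "summer"), n, replace = TRUE)),
    genotype = factor(sample(c("AA", "AB", "BB"), n, replace = TRUE))
  )
  d$y <- 10 + 0.02 * d$age + ifelse(d$season == "summer", 3, 0) + rnorm(n)
  with_season <- fit_model(d)
  without <- fit_model(d, use_season = FALSE)
  best <- compare_models_r2(list(without, with_season))
  expect_true("season" %in% best$f_tests$term)

  # a pure-noise season term is penalised by adjusted R^2
  d$y <- 10 + 0.02 * d$age + rnorm(n)
  f1 <- fit_model(d, use_season = FALSE)
  f2 <- fit_model(d)
  expect_lt(f2$adj_r2 - f1$adj_r2, 0.02)

  # identical candidates: deterministic first-by-parameter-count choice
  tie <- compare_models_r2(list(f1, f1))
  expect_identical(tie$adj_r2, f1$adj_r2)

  # different responses are incomparable
  d3 <- d
  d3$y <- rnorm(n)
  expect_error(compare_models_r2(list(f1, fit_model(d3))),
               "incomparable")
})

test_that("confounded factor levels raise a singular-design error", {
  d <- data.frame(
    y = rnorm(20),
    season = factor(rep(c("winter", "summer"), each = 10)),
    genotype = factor(rep(c("AA", "BB"), each = 10))
  )
  expect_error(fit_model(d, use_age = FALSE), "singular design")
})

test_that("the marker-by-trait scan produces a complete annotated grid", {
  herd <- simulate_herd(herd_config(
    n_animals = 40,
    markers = list(marker_spec("mA", c("A", "G"), 0.5),
                   marker_spec("mB", c("C", "T"), 0.4)),
    seed = 9))
  tr <- derive_traits(herd)
  scan <- assoc_scan(tr, herd$genotypes,
                     trait_cols = c("TADWG", "TFCR", "FW"))
  expect_equal(nrow(scan), 2 * 3)
  expect_true(all(scan$p >= 0 & scan$p <= 1, na.rm = TRUE))
  expect_true(all(scan$stars[!is.na(scan$p) & scan$p < 0.05] != ""))
  grid <- attr(scan, "grid")
  expect_equal(sort(grid$trait), sort(c("TADWG", "TFCR", "FW")))
  expect_true(all(c("mA", "mB") %in% names(grid)))
})
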