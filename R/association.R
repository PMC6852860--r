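#' Assemble the modelling frame for one marker and trait
#'
#' Joins the per-animal trait table to one marker's genotype calls and picks
#' the age and season columns anchored at the trait's reference point (see
#' [trait_reference()]). Rows with a missing trait value, age or season are
#' dropped; the number dropped is recorded.
#'
#' @param traits Trait table from [derive_traits()].
#' @param genotypes Long genotype table (`animal_id`, `marker`, `genotype`).
#' @param marker Marker name.
#' @param trait Trait column name in `traits`.
#' @return Data frame with columns `animal_id`, `y`, `age`, `season`,
#'   `genotype` and attributes `n_dropped`, `trait`, `marker`.
#' @export
assoc_data <- function(traits, genotypes, marker, trait) {
  stopifnot(trait %in% names(traits))
  g <- genotypes[genotypes$marker == marker, c("animal_id", "genotype")]
  if (nrow(g) == 0) stop("no genotype calls for marker '", marker, "'")
  ref <- trait_reference(trait)
  age_col <- paste0("age_at_", ref)
  season_col <- paste0("season_at_", ref)
  stopifnot(age_col %in% names(traits), season_col %in% names(traits))
  d <- merge(traits[, c("animal_id", trait, age_col, season_col)], g,
             by = "animal_id")
  names(d) <- c("animal_id", "y", "age", "season", "genotype")
  d$genotype <- normalize_genotype(as.character(d$genotype))
  keep <- stats::complete.cases(d[, c("y", "age", "season", "genotype")])
  out <- d[keep, ]
  out$season <- factor(out$season, levels = season_levels)
  out$season <- droplevels(out$season)
  out$genotype <- factor(out$genotype)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "trait") <- trait
  attr(out, "marker") <- marker
  out
}

#' Fit the fixed-effects association model for one trait
#'
#' Ordinary least squares for
#' `y = mu + beta * age + season + genotype + e` (reference-level dummy
#' coding), the standard single-locus candidate-gene model: an age covariate,
#' season as a fixed factor and genotype as the factor of interest. Factors
#' with a single observed level are dropped from the formula (a cohort
#' weighed within one season has no season contrast). Per-term p-values are
#' partial (Type III) F tests comparing the full model against the model
#' with that term removed.
#'
#' @param data Modelling frame from [assoc_data()] (or any data frame with
#'   columns `y`, `age`, `season`, `genotype`).
#' @param use_age,use_season Set `FALSE` to drop a term a priori.
#' @param alpha Significance level carried into downstream groupings.
#' @return An object of class `assoc_fit`: list with the underlying `lm`
#'   fit, `f_tests` (term, df, F, p), `r2`, `adj_r2`, `n_used`, `n_dropped`,
#'   `alpha` and the trait/marker labels.
#' @export
fit_model <- function(data, use_age = TRUE, use_season = TRUE,
                      alpha = 0.05) {
  stopifnot(all(c("y", "genotype") %in% names(data)))
  data$genotype <- droplevels(factor(data$genotype))
  if (nlevels(data$genotype) < 2) {
    stop("genotype factor has fewer than 2 observed levels")
  }
  terms <- "genotype"
  if (use_season && "season" %in% names(data)) {
    data$season <- droplevels(factor(data$season))
    if (nlevels(data$season) >= 2) terms <- c("season", terms)
  }
  if (use_age && "age" %in% names(data)) terms <- c("age", terms)
  form <- stats::reformulate(terms, response = "y")
  fit <- stats::lm(form, data = data)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design: aliased terms ", paste(aliased, collapse = ", "))
  }
  dr <- stats::drop1(fit, scope = form, test = "F")
  f_tests <- data.frame(term = rownames(dr)[-1], df = dr$Df[-1],
                        F = dr$`F value`[-1], p = dr$`Pr(>F)`[-1],
                        stringsAsFactors = FALSE)
  sm <- summary(fit)
  structure(
    list(lm = fit, f_tests = f_tests, r2 = sm$r.squared,
         adj_r2 = sm$adj.r.squared, n_used = nrow(data),
         n_dropped = attr(data, "n_dropped") %||% 0L, alpha = alpha,
         trait = attr(data, "trait") %||% "y",
         marker = attr(data, "marker") %||% "genotype"),
    class = "assoc_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.assoc_fit <- function(x, ...) {
  cat("Association fit:", x$trait, "~ age + season +", x$marker, "\n")
  cat("  n =", x$n_used, "(", x$n_dropped, "dropped ) R2 =",
      signif(x$r2, 4), " adj R2 =", signif(x$adj_r2, 4), "\n")
  print(x$f_tests, row.names = FALSE)
  invisible(x)
}

#' Least-square means for a fitted factor
#'
#' Model-adjusted marginal means: predictions at the covariate grand mean
#' with equal weight on every level of the other factor, with standard
#' errors from the coefficient covariance (the `emmeans` reference-grid
#' machinery).
#'
#' @param fit An `assoc_fit`.
#' @param factor Factor name, default `"genotype"`.
#' @return Data frame with columns `level`, `lsm`, `se`, `df`.
#' @export
least_square_means <- function(fit, factor = "genotype") {
  stopifnot(inherits(fit, "assoc_fit"))
  if (!factor %in% all.vars(stats::formula(fit$lm))) {
    stop("factor '", factor, "' is not in the fitted model")
  }
  em <- summary(emmeans::emmeans(fit$lm, specs = factor))
  data.frame(level = as.character(em[[factor]]), lsm = em$emmean,
             se = em$SE, df = em$df, stringsAsFactors = FALSE)
}

#' Tukey post hoc comparison of factor levels
#'
#' Tukey-Kramer adjusted pairwise contrasts of least-square means
#' (studentized-range distribution on the residual degrees of freedom) and a
#' compact letter display: letters are assigned greedily from the largest
#' mean downward (ties broken by level name); levels sharing no letter
#' differ at `alpha`.
#'
#' @param fit An `assoc_fit`.
#' @param factor Factor name.
#' @param alpha Significance level for the letter display (defaults to the
#'   fit's alpha).
#' @return A list of class `tukey_grouping`: `pairs` (level1, level2,
#'   estimate, se, t, p_adj) and `letters` (named character vector).
#' @export
tukey_posthoc <- function(fit, factor = "genotype", alpha = fit$alpha) {
  lsm <- least_square_means(fit, factor)
  if (nrow(lsm) < 2) stop("fewer than 2 levels: no contrasts to test")
  em <- emmeans::emmeans(fit$lm, specs = factor)
  pr <- summary(emmeans::contrast(em, method = "pairwise"), adjust = "tukey")
  lv <- do.call(rbind, strsplit(as.character(pr$contrast), " - "))
  pairs <- data.frame(level1 = lv[, 1], level2 = lv[, 2],
                      estimate = pr$estimate, se = pr$SE, t = pr$t.ratio,
                      p_adj = pr$p.value, stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 letters = compact_letters(lsm, pairs, alpha),
                 alpha = alpha),
            class = "tukey_grouping")
}

# greedy compact letter display: walk levels by descending LSM, start a new
# letter at each level not yet covered, extend it to every following level
# not significantly different from all current members
compact_letters <- function(lsm, pairs, alpha) {
  ord <- order(-lsm$lsm, lsm$level)
  levels <- lsm$level[ord]
  p_of <- function(a, b) {
    hit <- (pairs$level1 == a & pairs$level2 == b) |
      (pairs$level1 == b & pairs$level2 == a)
    pairs$p_adj[hit][1]
  }
  groups <- list()
  for (lev in levels) {
    covered <- any(vapply(groups, function(g) lev %in% g, TRUE))
    if (!covered) {
      g <- lev
      for (nxt in levels[seq_along(levels) > match(lev, levels)]) {
        if (all(vapply(g, function(m) p_of(m, nxt) >= alpha, TRUE))) {
          g <- c(g, nxt)
        }
      }
      # drop groups fully contained in the new one
      groups <- Filter(function(old) !all(old %in% g), groups)
      groups[[length(groups) + 1L]] <- g
    }
  }
  letters_out <- stats::setNames(rep("", nrow(lsm)), levels)
  for (i in seq_along(groups)) {
    letters_out[groups[[i]]] <- paste0(letters_out[groups[[i]]],
                                       letters[i])
  }
  letters_out[lsm$level]
}

#' Fit a two-locus (or higher) genotype-interaction model
#'
#' Builds a combined-genotype factor (e.g. `"CCxAA"`) across the named
#' markers, removes combinations observed fewer than `min_count` times
#' (logged in the result), and fits the same age + season + genotype model
#' on the combined factor.
#'
#' @param traits Trait table from [derive_traits()].
#' @param genotypes Long genotype table.
#' @param markers Character vector of two (or three) marker names.
#' @param trait Trait column name.
#' @param min_count Minimum animals per combination (default 3); rarer
#'   combinations are excluded before fitting.
#' @inheritParams fit_model
#' @return An `assoc_fit` whose genotype factor is the combination, with an
#'   extra `excluded_combinations` element (data frame `combination`, `n`).
#' @export
fit_interaction <- function(traits, genotypes, markers, trait,
                            min_count = 3, use_age = TRUE, use_season = TRUE,
                            alpha = 0.05) {
  stopifnot(length(markers) >= 2)
  parts <- lapply(markers, function(m) {
    d <- assoc_data(traits, genotypes, m, trait)
    stats::setNames(d[, c("animal_id", "y", "age", "season", "genotype")],
                    c("animal_id", "y", "age", "season", m))
  })
  d <- parts[[1]]
  for (i in seq_along(markers)[-1]) {
    d <- merge(d, parts[[i]][, c("animal_id", markers[i])],
               by = "animal_id")
  }
  combo <- do.call(paste, c(lapply(markers, function(m)
    as.character(d[[m]])), sep = "x"))
  tab <- table(combo)
  low <- names(tab)[tab < min_count]
  excluded <- data.frame(combination = low,
                         n = as.integer(tab[low]), stringsAsFactors = FALSE)
  keep <- !combo %in% low
  d2 <- d[keep, c("animal_id", "y", "age", "season")]
  d2$genotype <- factor(combo[keep])
  if (nlevels(d2$genotype) < 2) {
    stop("degenerate interaction: fewer than 2 genotype combinations with ",
         "n >= ", min_count)
  }
  attr(d2, "n_dropped") <- sum(!keep)
  attr(d2, "trait") <- trait
  attr(d2, "marker") <- paste(markers, collapse = "x")
  fit <- fit_model(d2, use_age = use_age, use_season = use_season,
                   alpha = alpha)
  fit$excluded_combinations <- excluded
  fit
}

#' Choose among candidate models by adjusted R-squared
#'
#' Compares fits of the same response and returns the one with the highest
#' adjusted coefficient of determination; ties go to the model with fewer
#' estimated parameters, then to position in the list (deterministic).
#'
#' @param fits List of `assoc_fit` objects on identical response vectors.
#' @return The chosen `assoc_fit`, with the comparison table attached as
#'   attribute `comparison`.
#' @export
compare_models_r2 <- function(fits) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, TRUE, "assoc_fit")))
  ys <- lapply(fits, function(f) unname(stats::model.frame(f$lm)$y))
  if (!all(vapply(ys[-1], function(y) isTRUE(all.equal(y, ys[[1]])), TRUE))) {
    stop("incomparable models: response vectors differ")
  }
  npar <- vapply(fits, function(f) f$lm$rank, 0L)
  adj <- vapply(fits, `[[`, 0, "adj_r2")
  ord <- order(-adj, npar, seq_along(fits))
  best <- fits[[ord[1]]]
  attr(best, "comparison") <- data.frame(model = seq_along(fits),
                                         adj_r2 = adj, n_par = npar)
  best
}

#' Marker-by-trait association scan
#'
#' Fits the single-locus model for every marker x trait combination and
#' collects the genotype-term partial-F p-values into a grid, with
#' significance stars and (optionally written, never gating) an FDR column
#' per trait. Combinations whose model cannot be fitted (e.g. a trait with
#' too few complete rows) yield `NA`.
#'
#' @param traits Trait table from [derive_traits()].
#' @param genotypes Long genotype table.
#' @param markers Markers to scan (default: all in `genotypes`).
#' @param trait_cols Trait columns to scan (default: all trait columns of
#'   `traits`).
#' @param alpha Significance level used for the star coding.
#' @return A long data frame `marker`, `trait`, `p`, `stars`, `fdr`, `n`,
#'   with the wide marker x trait p-value grid as attribute `grid`.
#' @export
assoc_scan <- function(traits, genotypes, markers = NULL, trait_cols = NULL,
                       alpha = 0.05) {
  if (is.null(markers)) markers <- unique(genotypes$marker)
  if (is.null(trait_cols)) {
    trait_cols <- intersect(trait_names_for(length(attr(traits, "targets")
                                                   %||% 1:5)), names(traits))
  }
  rows <- list()
  for (m in markers) {
    for (tr in trait_cols) {
      res <- tryCatch({
        fit <- fit_model(assoc_data(traits, genotypes, m, tr),
                         alpha = alpha)
        gt <- fit$f_tests[fit$f_tests$term == "genotype", ]
        data.frame(marker = m, trait = tr, p = gt$p, n = fit$n_used,
                   stringsAsFactors = FALSE)
      }, error = function(e) data.frame(marker = m, trait = tr,
                                        p = NA_real_, n = NA_integer_,
                                        stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out$stars <- significance_stars(out$p)
  out$fdr <- stats::ave(out$p, out$trait,
                        FUN = function(p) stats::p.adjust(p, "BH"))
  grid <- stats::reshape(out[, c("marker", "trait", "p")],
                         idvar = "trait", timevar = "marker",
                         direction = "wide")
  names(grid) <- sub("^p\\.", "", names(grid))
  attr(out, "grid") <- grid
  out
}

#' Genotype LSM table for one marker across traits
#'
#' The per-marker analogue of a published genotype-means table: for each
#' trait, the least-square mean, standard error and Tukey letter of every
#' genotype, plus the genotype-term p-value.
#'
#' @inheritParams assoc_scan
#' @param marker Marker name.
#' @return Long data frame `marker`, `trait`, `genotype`, `lsm`, `se`,
#'   `letter`, `p_genotype`, `n`.
#' @export
marker_lsm_table <- function(traits, genotypes, marker, trait_cols = NULL,
                             alpha = 0.05) {
  if (is.null(trait_cols)) {
    trait_cols <- intersect(trait_names_for(length(attr(traits, "targets")
                                                   %||% 1:5)), names(traits))
  }
  rows <- list()
  for (tr in trait_cols) {
    res <- tryCatch({
      fit <- fit_model(assoc_data(traits, genotypes, marker, tr),
                       alpha = alpha)
      lsm <- least_square_means(fit)
      letters_v <- if (nrow(lsm) >= 2) tukey_posthoc(fit)$letters else
        stats::setNames("a", lsm$level)
      p <- fit$f_tests$p[fit$f_tests$term == "genotype"]
      data.frame(marker = marker, trait = tr, genotype = lsm$level,
                 lsm = lsm$lsm, se = lsm$se,
                 letter = unname(letters_v[lsm$level]),
                 p_genotype = p, n = fit$n_used, stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
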