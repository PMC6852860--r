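#' Marker specification for the synthetic herd
#'
#' Describes one biallelic SNP: its allele pair, the frequency of the first
#' allele, a single inbreeding-like coefficient `f` that bends genotype
#' proportions away from Hardy-Weinberg equilibrium, and planted additive /
#' dominance effects on daily weight gain and on daily dry matter intake.
#' Genotype probabilities are `p^2 + f p q`, `2 p q (1 - f)`, `q^2 + f p q`;
#' `f = 0` gives Hardy-Weinberg proportions and `f = 1` a cohort with no
#' heterozygotes.
#'
#' Effects follow the classical single-locus parameterisation: genotype
#' values are `-a`, `d`, `+a` for the first-allele homozygote, heterozygote
#' and second-allele homozygote respectively, in kg/day.
#'
#' @param name Marker identifier.
#' @param alleles Ordered pair of allele symbols (lexical order recommended).
#' @param allele_freq Frequency of the first allele, in (0, 1).
#' @param hwe_departure_f Inbreeding-like coefficient in `[-1, 1]`; must not
#'   make any genotype probability negative.
#' @param effect_a,effect_d Additive effect and dominance deviation on daily
#'   gain (kg/day).
#' @param intake_effect_a,intake_effect_d Corresponding effects on daily dry
#'   matter intake (kg/day).
#' @return An object of class `marker_spec`.
#' @export
marker_spec <- function(name, alleles, allele_freq, hwe_departure_f = 0,
                        effect_a = 0, effect_d = 0,
                        intake_effect_a = 0, intake_effect_d = 0) {
  stopifnot(is.character(name), length(alleles) == 2L,
            allele_freq > 0, allele_freq < 1,
            hwe_departure_f >= -1, hwe_departure_f <= 1)
  spec <- structure(
    list(name = name, alleles = alleles, allele_freq = allele_freq,
         hwe_departure_f = hwe_departure_f,
         effect_a = effect_a, effect_d = effect_d,
         intake_effect_a = intake_effect_a,
         intake_effect_d = intake_effect_d),
    class = "marker_spec"
  )
  genotype_probs(spec) # validates
  spec
}

#' Genotype class probabilities implied by a marker specification
#'
#' @param spec A `marker_spec`.
#' @return Length-3 named numeric vector (`hom_first`, `het`, `hom_second`).
#' @export
genotype_probs <- function(spec) {
  p <- spec$allele_freq; q <- 1 - p; f <- spec$hwe_departure_f
  probs <- c(hom_first = p^2 + f * p * q, het = 2 * p * q * (1 - f),
             hom_second = q^2 + f * p * q)
  if (any(probs < -1e-12)) {
    stop("marker '", spec$name, "': hwe_departure_f = ", f,
         " makes a genotype probability negative at allele_freq = ", p)
  }
  pmax(probs, 0) / sum(pmax(probs, 0))
}

#' Solve the departure coefficient that reproduces observed genotype
#' proportions
#'
#' Given observed proportions of the three genotype classes, returns the `f`
#' for which the `marker_spec` probability model reproduces the observed
#' heterozygote share at the count-implied allele frequency
#' (`f = 1 - het_obs / (2 p q)`).
#'
#' @param prop_hom_first,prop_het,prop_hom_second Observed class proportions
#'   (need not sum exactly to 1; they are renormalised).
#' @return A list with `allele_freq` and `hwe_departure_f`.
#' @export
solve_hwe_departure <- function(prop_hom_first, prop_het, prop_hom_second) {
  s <- prop_hom_first + prop_het + prop_hom_second
  ph <- prop_het / s
  p <- (prop_hom_first + prop_het / 2) / s
  list(allele_freq = p, hwe_departure_f = 1 - ph / (2 * p * (1 - p)))
}

#' Growth model specification
#'
#' Daily latent gain is `baseline_adwg + genotype value + season shift +
#' animal effect`, with the animal effect drawn once per animal from
#' `N(0, animal_sd)`. Observed weigh records perturb each weigh-to-weigh
#' interval gain so that the observed interval ADWG has standard deviation
#' `residual_sd` (kg/day) around its latent mean.
#'
#' @param baseline_adwg Baseline average daily weight gain, kg/day.
#' @param season_effects Named numeric vector of additive shifts (kg/day) for
#'   `winter`, `spring`, `summer`, `autumn`.
#' @param animal_sd Between-animal SD of daily gain, kg/day.
#' @param residual_sd Weigh-to-weigh SD on the daily-gain scale, kg/day.
#' @param initial_weight_mean,initial_weight_sd Body weight at fattening
#'   start, kg.
#' @return An object of class `gain_model_spec`.
#' @export
gain_model_spec <- function(baseline_adwg = 0.90,
                            season_effects = c(winter = -0.03, spring = 0.02,
                                               summer = -0.02, autumn = 0.03),
                            animal_sd = 0.08, residual_sd = 0.05,
                            initial_weight_mean = 85,
                            initial_weight_sd = 7) {
  stopifnot(baseline_adwg > 0, animal_sd >= 0, residual_sd >= 0,
            initial_weight_sd >= 0,
            all(c("winter", "spring", "summer", "autumn") %in%
                  names(season_effects)))
  structure(
    list(baseline_adwg = baseline_adwg, season_effects = season_effects,
         animal_sd = animal_sd, residual_sd = residual_sd,
         initial_weight_mean = initial_weight_mean,
         initial_weight_sd = initial_weight_sd),
    class = "gain_model_spec"
  )
}

#' Intake model specification
#'
#' Daily dry matter intake is `intake_coefficient * W^0.75 + genotype intake
#' value + N(0, noise_sd)`, truncated at zero, with `W` the latent body
#' weight that day (the 3/4-power of body weight is the standard metabolic
#' scaling of ruminant intake).
#'
#' @param intake_coefficient kg DMI per kg^0.75 metabolic weight per day.
#' @param noise_sd Daily intake noise SD, kg/day.
#' @return An object of class `intake_model_spec`.
#' @export
intake_model_spec <- function(intake_coefficient = 0.105, noise_sd = 0.3) {
  stopifnot(intake_coefficient > 0, noise_sd >= 0)
  structure(list(intake_coefficient = intake_coefficient,
                 noise_sd = noise_sd),
            class = "intake_model_spec")
}

#' Herd configuration
#'
#' @param n_animals Number of animals (default 296, a typical commercial
#'   fattening cohort).
#' @param markers List of [marker_spec()] objects.
#' @param start_date_range Length-2 `Date` vector; fattening start dates are
#'   drawn uniformly between them.
#' @param weigh_interval_days Days between weigh records (default 30,
#'   monthly weighing).
#' @param target_weights Strictly increasing target body weights, kg.
#' @param gain_model A [gain_model_spec()].
#' @param intake_model An [intake_model_spec()].
#' @param start_age_mean,start_age_sd Age (days) at fattening start.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `herd_config`.
#' @export
herd_config <- function(n_animals = 296,
                        markers = default_marker_panel(),
                        start_date_range = as.Date(c("2016-06-01",
                                                     "2016-11-30")),
                        weigh_interval_days = 30,
                        target_weights = c(100, 200, 300, 400, 450),
                        gain_model = gain_model_spec(),
                        intake_model = intake_model_spec(),
                        start_age_mean = 100, start_age_sd = 10,
                        seed = 1L) {
  stopifnot(n_animals >= 1, weigh_interval_days >= 1,
            length(target_weights) >= 1, all(diff(target_weights) > 0),
            all(target_weights > 0),
            inherits(gain_model, "gain_model_spec"),
            inherits(intake_model, "intake_model_spec"))
  stopifnot(all(vapply(markers, inherits, TRUE, "marker_spec")))
  structure(
    list(n_animals = as.integer(n_animals), markers = markers,
         start_date_range = as.Date(start_date_range),
         weigh_interval_days = as.integer(weigh_interval_days),
         target_weights = target_weights, gain_model = gain_model,
         intake_model = intake_model,
         start_age_mean = start_age_mean, start_age_sd = start_age_sd,
         seed = as.integer(seed)),
    class = "herd_config"
  )
}

#' Default 15-marker panel
#'
#' Allele frequencies and Hardy-Weinberg departures matching the genotype
#' distribution observed in a genotyped cohort of 296 Holstein bulls
#' (the packaged [holstein_genotype_counts()] table); all planted effects
#' are zero.
#'
#' @return List of [marker_spec()] objects.
#' @export
default_marker_panel <- function() {
  tab <- holstein_genotype_counts()
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    n3 <- c(r$hom_first, r$het, r$hom_second)
    if (min(n3) == 0) { # no spare class: keep a representable departure
      sol <- solve_hwe_departure(n3[1] + 0.5, n3[2], n3[3] + 0.5)
    } else {
      sol <- solve_hwe_departure(n3[1], n3[2], n3[3])
    }
    marker_spec(r$marker, c(r$allele_first, r$allele_second),
                allele_freq = sol$allele_freq,
                hwe_departure_f = sol$hwe_departure_f)
  })
}

#' Draw genotype calls for one marker
#'
#' Samples `n` calls from the genotype class probabilities of `spec`; calls
#' are written with alleles in the marker's stated order for homozygotes and
#' lexically sorted for heterozygotes.
#'
#' @param spec A [marker_spec()].
#' @param n Number of animals.
#' @return Character vector of `n` genotype calls.
#' @export
draw_genotypes <- function(spec, n) {
  stopifnot(n >= 1)
  probs <- genotype_probs(spec)
  g <- c(paste0(spec$alleles[1], spec$alleles[1]),
         normalize_genotype(paste0(spec$alleles[1], spec$alleles[2])),
         paste0(spec$alleles[2], spec$alleles[2]))
  sample(g, n, replace = TRUE, prob = probs)
}

season_levels <- c("winter", "spring", "summer", "autumn")

# genotype value on the (-a, d, +a) scale for one marker
genotype_value <- function(spec, call, a, d) {
  g1 <- paste0(spec$alleles[1], spec$alleles[1])
  g2 <- paste0(spec$alleles[2], spec$alleles[2])
  ifelse(call == g1, -a, ifelse(call == g2, a, d))
}

#' Simulate one animal's weigh and feed series
#'
#' Runs the daily latent-gain model from fattening start (day 0) until the
#' first weigh day whose observed weight exceeds the last target weight
#' (that weigh is the final, pre-slaughter weight), emitting weigh records at
#' the configured cadence and one feed record per day. With all noise terms
#' at zero the trajectory follows its closed form exactly: weight on day `t`
#' is `W0 + g t` and the day-`t` intake is
#' `intake_coefficient * (W0 + g t)^0.75`.
#'
#' @param config A [herd_config()].
#' @param genotypes Named character vector of this animal's calls, one per
#'   marker in `config$markers`.
#' @param start_date Fattening start date.
#' @return List with data frames `weights` (`day`, `weight_kg`) and `feed`
#'   (`day`, `dmi_kg`).
#' @export
simulate_animal <- function(config, genotypes, start_date) {
  gm <- config$gain_model; im <- config$intake_model
  gain_eff <- 0; intake_eff <- 0
  for (spec in config$markers) {
    call <- genotypes[[spec$name]]
    gain_eff <- gain_eff +
      genotype_value(spec, call, spec$effect_a, spec$effect_d)
    intake_eff <- intake_eff +
      genotype_value(spec, call, spec$intake_effect_a, spec$intake_effect_d)
  }
  animal_eff <- stats::rnorm(1, 0, gm$animal_sd)
  w0 <- max(30, stats::rnorm(1, gm$initial_weight_mean, gm$initial_weight_sd))
  last_target <- max(config$target_weights)
  # horizon: worst-case mean daily gain for this animal, plus noise headroom
  g_min <- gm$baseline_adwg + gain_eff + animal_eff +
    min(gm$season_effects)
  max_days <- ceiling((last_target + 40 - w0) / max(g_min, 0.15)) +
    2L * config$weigh_interval_days
  days <- 0:max_days
  season <- season_at(start_date, days)
  daily_gain <- gm$baseline_adwg + gain_eff + animal_eff +
    unname(gm$season_effects[as.character(season)])
  latent <- w0 + c(0, cumsum(daily_gain[-length(daily_gain)]))

  interval <- config$weigh_interval_days
  weigh_days <- as.integer(seq(0L, max_days, by = interval))
  latent_at_weigh <- latent[weigh_days + 1L]
  gain_noise <- c(0, stats::rnorm(length(weigh_days) - 1L, 0,
                                  gm$residual_sd * interval))
  observed <- latent_at_weigh + cumsum(gain_noise)
  # slaughter at the first weigh whose observed weight clears the last target
  stop_idx <- which(observed > last_target)[1]
  if (is.na(stop_idx)) stop_idx <- length(weigh_days)
  weigh_days <- weigh_days[1:stop_idx]
  observed <- round(observed[1:stop_idx], 1) # 100 g scale sensitivity

  final_day <- weigh_days[stop_idx]
  feed_days <- seq_len(final_day) - 1L
  dmi <- im$intake_coefficient * latent[feed_days + 1L]^0.75 + intake_eff
  if (im$noise_sd > 0) {
    dmi <- dmi + stats::rnorm(length(dmi), 0, im$noise_sd)
  }
  dmi <- round(pmax(dmi, 0), 3)
  list(
    weights = data.frame(day = weigh_days, weight_kg = observed),
    feed = data.frame(day = feed_days, dmi_kg = dmi)
  )
}

# deterministic per-animal substream seed (31-bit)
animal_substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Simulate a herd
#'
#' Generates the full cohort described by a [herd_config()]: roster with
#' start dates and start ages, genotype calls for every marker, monthly weigh
#' records and daily feed records. All randomness is keyed to `config$seed`;
#' each animal draws from its own substream (keyed by animal index), so a
#' given animal's records are reproducible independent of cohort size.
#'
#' @param config A [herd_config()].
#' @return An object of class `herd`: list of data frames `animals`
#'   (`animal_id`, `start_date`, `start_age_days`), `genotypes`
#'   (`animal_id`, `marker`, `genotype`), `weights`
#'   (`animal_id`, `day`, `weight_kg`) and `feed`
#'   (`animal_id`, `day`, `dmi_kg`), with the config attached as an
#'   attribute.
#' @examples
#' cfg <- herd_config(n_animals = 5, seed = 42)
#' herd <- simulate_herd(cfg)
#' head(herd$weights)
#' @export
simulate_herd <- function(config) {
  stopifnot(inherits(config, "herd_config"))
  date_span <- as.integer(diff(config$start_date_range))
  marker_names <- vapply(config$markers, `[[`, "", "name")
  animals <- vector("list", config$n_animals)
  genos <- vector("list", config$n_animals)
  weights <- vector("list", config$n_animals)
  feed <- vector("list", config$n_animals)
  for (i in seq_len(config$n_animals)) {
    set.seed(animal_substream_seed(config$seed, i))
    id <- sprintf("A%04d", i)
    start_date <- config$start_date_range[1] +
      if (date_span > 0) sample.int(date_span + 1L, 1L) - 1L else 0L
    start_age <- as.integer(max(30, round(stats::rnorm(
      1, config$start_age_mean, config$start_age_sd))))
    calls <- vapply(config$markers, function(sp) draw_genotypes(sp, 1L), "")
    names(calls) <- marker_names
    sim <- simulate_animal(config, calls, start_date)
    animals[[i]] <- data.frame(animal_id = id,
                               start_date = as.character(start_date),
                               start_age_days = start_age)
    genos[[i]] <- data.frame(animal_id = id, marker = marker_names,
                             genotype = unname(calls))
    weights[[i]] <- cbind(animal_id = id, sim$weights)
    feed[[i]] <- cbind(animal_id = id, sim$feed)
  }
  tables <- list(animals = do.call(rbind, animals),
                 genotypes = do.call(rbind, genos),
                 weights = do.call(rbind, weights),
                 feed = do.call(rbind, feed))
  tables <- lapply(tables, function(d) { rownames(d) <- NULL; d })
  structure(tables, class = "herd", config = config)
}

#' Write / read a herd as a CSV file set
#'
#' `write_herd()` emits `animals.csv`, `genotypes.csv`, `weights.csv` and
#' `feed.csv` (UTF-8, header row, "." decimal separator) into `dir`;
#' `read_herd()` reads them back. The pair round-trips losslessly.
#'
#' @param herd A `herd` object (or any list with the four tables).
#' @param dir Output directory; created if absent.
#' @return `write_herd()` the directory path, invisibly; `read_herd()` a
#'   `herd` object.
#' @export
write_herd <- function(herd, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("animals", "genotypes", "weights", "feed")) {
    utils::write.csv(herd[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_herd
#' @export
read_herd <- function(dir) {
  classes <- list(
    animals = c(animal_id = "character", start_date = "character",
                start_age_days = "integer"),
    genotypes = c(animal_id = "character", marker = "character",
                  genotype = "character"),
    weights = c(animal_id = "character", day = "integer",
                weight_kg = "numeric"),
    feed = c(animal_id = "character", day = "integer",
             dmi_kg = "numeric")
  )
  read1 <- function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing herd table: ", path)
    header <- names(utils::read.csv(path, nrows = 1))
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = classes[[nm]][intersect(
                      names(classes[[nm]]), header)])
  }
  structure(
    list(animals = read1("animals"), genotypes = read1("genotypes"),
         weights = read1("weights"), feed = read1("feed")),
    class = "herd"
  )
}
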