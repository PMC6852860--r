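#' Season at a given fattening day
#'
#' Maps `start_date + day` to its meteorological season (quarters:
#' Dec-Feb winter, Mar-May spring, Jun-Aug summer, Sep-Nov autumn).
#' Vectorised over `day`; every day receives a label.
#'
#' @param start_date Fattening start `Date` (or ISO-8601 string).
#' @param day Days since fattening start (fractional allowed; the calendar
#'   date is taken at the floor).
#' @return Factor with levels `winter`, `spring`, `summer`, `autumn`.
#' @examples
#' season_at(as.Date("2016-01-01"), c(0, 182))
#' @export
season_at <- function(start_date, day) {
  date <- as.Date(start_date) + floor(day)
  month <- as.integer(format(date, "%m"))
  idx <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 1L)[month]
  factor(season_levels[idx], levels = season_levels)
}

#' Day on which a weigh series first reaches a target weight
#'
#' Linear interpolation between the two weigh records bracketing the first
#' upward crossing of `target`; a record hitting the target exactly returns
#' that record's day. No extrapolation: a target above the final recorded
#' weight raises a `fattenassoc_not_reached` error, one below the initial
#' weight a `fattenassoc_pre_study` error.
#'
#' @param weights Data frame with columns `day` (strictly increasing) and
#'   `weight_kg` (> 0), at least two records.
#' @param target Target body weight, kg.
#' @return Fractional day since fattening start.
#' @examples
#' w <- data.frame(day = c(100, 130), weight_kg = c(95, 110))
#' days_to_reach(w, 100) # 110
#' @export
days_to_reach <- function(weights, target) {
  stopifnot(nrow(weights) >= 2, all(diff(weights$day) > 0),
            all(weights$weight_kg > 0), target > 0)
  w <- weights$weight_kg; d <- weights$day
  if (w[1] > target) {
    stop(structure(class = c("fattenassoc_pre_study", "error", "condition"),
                   list(message = sprintf(
                     "target %g kg below initial weight %g kg", target, w[1]),
                     call = sys.call(-1))))
  }
  k <- which(w >= target)[1]
  if (is.na(k)) {
    stop(structure(class = c("fattenassoc_not_reached", "error", "condition"),
                   list(message = sprintf(
                     "target %g kg above final recorded weight %g kg",
                     target, w[length(w)]), call = sys.call(-1))))
  }
  if (w[k] == target || k == 1L) return(d[k])
  d[k - 1L] + (target - w[k - 1L]) / (w[k] - w[k - 1L]) * (d[k] - d[k - 1L])
}

# sum of daily feed records over [t_a, t_b), boundary days pro-rated by
# fractional coverage (record on day d covers [d, d + 1))
interval_feed <- function(feed, t_a, t_b) {
  stopifnot(t_b >= t_a)
  lo <- pmax(feed$day, t_a)
  hi <- pmin(feed$day + 1, t_b)
  sum(feed$dmi_kg * pmax(hi - lo, 0))
}

#' Traits over one target-weight interval
#'
#' For the interval between targets `a` and `b` of `scheme`: fattening
#' period `FP = DTR_b - DTR_a`, dry matter intake `DMI` (daily records summed
#' over `[DTR_a, DTR_b)` with boundary days pro-rated), daily intake
#' `DDMI = DMI / FP`, average daily weight gain
#' `ADWG = (W_b - W_a) / FP` and feed conversion rate
#' `FCR = DMI / (W_b - W_a)`, with the target-weight gain as denominator.
#' The definitions force `FCR * ADWG = DDMI`.
#'
#' @param weights,feed Per-animal weigh and feed series (see
#'   [days_to_reach()]).
#' @param scheme Increasing vector of target weights, kg.
#' @param a,b Indices of the interval's endpoints in `scheme` (`a < b`).
#' @return List with `FP`, `DMI`, `DDMI`, `FCR`, `ADWG`.
#' @export
interval_traits <- function(weights, feed, scheme, a, b) {
  stopifnot(a >= 1, b <= length(scheme), a < b)
  t_a <- days_to_reach(weights, scheme[a])
  t_b <- days_to_reach(weights, scheme[b])
  fp <- t_b - t_a
  if (fp == 0) stop("degenerate interval: targets ", scheme[a], " and ",
                    scheme[b], " reached on the same day")
  gain <- scheme[b] - scheme[a]
  dmi <- interval_feed(feed, t_a, t_b)
  list(FP = fp, DMI = dmi, DDMI = dmi / fp, FCR = dmi / gain,
       ADWG = gain / fp)
}

#' Whole-window totals and final weight
#'
#' Totals run from the day the first target is reached (`DTR_W1`) to the
#' final weigh: `FW` is the last recorded weight, `TDMI` the summed intake
#' over `[DTR_W1, last weigh day)`, `TDDMI = TDMI / days`,
#' `TADWG = (FW - W1) / days` and `TFCR = TDMI / (FW - W1)`, so that
#' `TFCR * TADWG = TDDMI`.
#'
#' @inheritParams interval_traits
#' @return List with `FW`, `FP`, `TDMI`, `TDDMI`, `TFCR`, `TADWG`.
#' @export
total_traits <- function(weights, feed, scheme) {
  t_w1 <- days_to_reach(weights, scheme[1])
  last_day <- weights$day[nrow(weights)]
  fw <- weights$weight_kg[nrow(weights)]
  days <- last_day - t_w1
  if (days <= 0) stop("degenerate window: first target reached at the final",
                      " weighing")
  tdmi <- interval_feed(feed, t_w1, last_day)
  gain <- fw - scheme[1]
  list(FW = fw, FP = days, TDMI = tdmi, TDDMI = tdmi / days,
       TFCR = tdmi / gain, TADWG = gain / days)
}

trait_names_for <- function(n_targets) {
  w <- paste0("W", seq_len(n_targets))
  ivl <- paste0(w[-n_targets], "-", w[-1])
  c(paste0("DTR", w), paste(ivl, "FP"), "FW",
    paste(ivl, "DMI"), "TDMI", paste(ivl, "DDMI"), "TDDMI",
    paste(ivl, "FCR"), "TFCR", paste(ivl, "ADWG"), "TADWG")
}

#' Derive the per-animal trait table from raw herd records
#'
#' Computes, for every animal, the days to reach each target weight
#' (`DTRW1..DTRWk`), the per-interval fattening period, intake, daily
#' intake, feed conversion rate and daily gain, the whole-window totals and
#' the final weight, plus the season and age (days) at each target and at
#' the final weighing (the covariate anchors of the association models).
#' Animals that never reach a target get `NA` for every trait depending on
#' it (no extrapolation) and are reported in the `exclusions` attribute.
#'
#' @param herd A `herd` object ([simulate_herd()] / [read_herd()]).
#' @param targets Increasing target weights, kg.
#' @return Data frame, one row per animal, with an `exclusions` attribute
#'   (data frame `animal_id`, `target`, `reason`).
#' @export
derive_traits <- function(herd, targets = c(100, 200, 300, 400, 450)) {
  stopifnot(all(diff(targets) > 0))
  k <- length(targets)
  wlab <- paste0("W", seq_len(k))
  weights_by <- split(herd$weights, herd$weights$animal_id)
  feed_by <- split(herd$feed, herd$feed$animal_id)
  animals <- herd$animals
  has_age <- !is.null(animals$start_age_days)
  excl <- list()
  rows <- vector("list", nrow(animals))
  for (i in seq_len(nrow(animals))) {
    id <- animals$animal_id[i]
    w <- weights_by[[id]]; f <- feed_by[[id]]
    if (is.null(w) || nrow(w) < 2) {
      excl[[length(excl) + 1L]] <- data.frame(
        animal_id = id, target = NA_real_, reason = "insufficient_weighs")
      next
    }
    dtr <- rep(NA_real_, k)
    for (j in seq_len(k)) {
      dtr[j] <- tryCatch(days_to_reach(w, targets[j]), error = function(e) {
        reason <- if (inherits(e, "fattenassoc_pre_study")) "pre_study"
        else "not_reached"
        excl[[length(excl) + 1L]] <<- data.frame(
          animal_id = id, target = targets[j], reason = reason)
        NA_real_
      })
    }
    ivl <- matrix(NA_real_, k - 1L, 5,
                  dimnames = list(NULL, c("FP", "DMI", "DDMI", "FCR",
                                          "ADWG")))
    for (j in seq_len(k - 1L)) {
      if (!is.na(dtr[j]) && !is.na(dtr[j + 1L])) {
        it <- interval_traits(w, f, targets, j, j + 1L)
        ivl[j, ] <- unlist(it)
      }
    }
    tot <- if (!is.na(dtr[1])) total_traits(w, f, targets) else
      list(FW = w$weight_kg[nrow(w)], FP = NA_real_, TDMI = NA_real_,
           TDDMI = NA_real_, TFCR = NA_real_, TADWG = NA_real_)
    start_date <- as.Date(animals$start_date[i])
    start_age <- if (has_age) animals$start_age_days[i] else 0
    last_day <- w$day[nrow(w)]
    seasons <- as.character(season_at(start_date, ifelse(is.na(dtr), 0,
                                                         dtr)))
    seasons[is.na(dtr)] <- NA_character_
    row <- c(
      stats::setNames(as.list(dtr), paste0("DTR", wlab)),
      stats::setNames(as.list(ivl[, "FP"]),
                      paste(paste0(wlab[-k], "-", wlab[-1]), "FP")),
      list(FW = tot$FW),
      stats::setNames(as.list(ivl[, "DMI"]),
                      paste(paste0(wlab[-k], "-", wlab[-1]), "DMI")),
      list(TDMI = tot$TDMI),
      stats::setNames(as.list(ivl[, "DDMI"]),
                      paste(paste0(wlab[-k], "-", wlab[-1]), "DDMI")),
      list(TDDMI = tot$TDDMI),
      stats::setNames(as.list(ivl[, "FCR"]),
                      paste(paste0(wlab[-k], "-", wlab[-1]), "FCR")),
      list(TFCR = tot$TFCR),
      stats::setNames(as.list(ivl[, "ADWG"]),
                      paste(paste0(wlab[-k], "-", wlab[-1]), "ADWG")),
      list(TADWG = tot$TADWG),
      stats::setNames(as.list(seasons), paste0("season_at_", wlab)),
      list(season_at_slaughter = as.character(season_at(start_date,
                                                        last_day))),
      stats::setNames(as.list(start_age + dtr), paste0("age_at_", wlab)),
      list(age_at_slaughter = start_age + last_day)
    )
    rows[[i]] <- data.frame(c(list(animal_id = id), row),
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(animal_id = character(), target = numeric(),
               reason = character())
  attr(out, "targets") <- targets
  out
}

#' Reference anchor of a trait
#'
#' Association models adjust each trait for age and season "at the
#' corresponding target weight". This maps a trait name to the column
#' suffix anchoring its covariates: a `DTRWk` trait to `Wk`, an interval
#' trait to the interval's end target, totals and `FW` to `slaughter`.
#'
#' @param trait Trait name as produced by [derive_traits()].
#' @return Character scalar, e.g. `"W3"` or `"slaughter"`.
#' @export
trait_reference <- function(trait) {
  if (grepl("^DTRW[0-9]+$", trait)) return(sub("^DTR", "", trait))
  m <- regmatches(trait, regexec("^W[0-9]+-(W[0-9]+) ", trait))[[1]]
  if (length(m) == 2L) return(m[2])
  "slaughter"
}
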