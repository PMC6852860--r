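linear_weights <- function(w0, gain, days) {
  data.frame(day = days, weight_kg = w0 + gain * days)
}

test_that("days to reach a target interpolates the first upward crossing", {
  w <- data.frame(day = c(100, 130), weight_kg = c(95, 110))
  expect_equal(days_to_reach(w, 100), 110)

  # exact hit returns the record's day
  w2 <- data.frame(day = c(60, 90, 120), weight_kg = c(80, 100, 120))
  expect_equal(days_to_reach(w2, 100), 90)

  # a local decrease: the first upward crossing wins
  w3 <- data.frame(day = c(0, 30, 60, 90),
                   weight_kg = c(100, 120, 115, 130))
  expect_equal(days_to_reach(w3, 118), 30 * 18 / 20)

  expect_error(days_to_reach(w, 90), class = "fattenassoc_pre_study")
  expect_error(days_to_reach(w, 200), class = "fattenassoc_not_reached")
})

test_that("days to reach is nondecreasing in the target", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    w <- data.frame(day = sort(sample(0:400, n)),
                    weight_kg = 90 + cumsum(runif(n, -5, 30)))
    targets <- sort(runif(4, w$weight_kg[1], max(w$weight_kg)))
    dtr <- vapply(targets, function(t) days_to_reach(w, t), 0)
    expect_true(all(diff(dtr) >= 0))
  }
})

test_that("interval traits recover constants and their defining identity", {
  w <- linear_weights(100, 2, c(0, 25, 50))
  f <- data.frame(day = 0:49, dmi_kg = 6)
  it <- interval_traits(w, f, c(100, 200), 1, 2)
  expect_equal(it$FP, 50)
  expect_equal(it$DMI, 300)
  expect_equal(it$DDMI, 6)
  expect_equal(it$ADWG, 2)
  expect_equal(it$FCR, 3)
  expect_equal(it$FCR * it$ADWG, it$DDMI)

  tot <- total_traits(w, f, c(100, 200))
  expect_equal(tot$FW, 200)
  expect_equal(tot$TFCR, 3)
  expect_equal(tot$TFCR * tot$TADWG, tot$TDDMI)
})

test_that("boundary feed days are pro-rated by fractional coverage", {
  f <- data.frame(day = 0:9, dmi_kg = c(2, 4, 6, 8, 10, 10, 8, 6, 4, 2))
  # window [1.5, 3.25): half of day 1, all of day 2, a quarter of day 3
  expect_equal(fattenassoc:::interval_feed(f, 1.5, 3.25),
               0.5 * 4 + 6 + 0.25 * 8)
  expect_equal(fattenassoc:::interval_feed(f, 0, 10), sum(f$dmi_kg))
  expect_equal(fattenassoc:::interval_feed(f, 4, 4), 0)
})

test_that("noise-free simulated animals match closed forms through the trait
           layer", {
  cfg <- noise_free_config()
  herd <- simulate_herd(cfg)
  w <- herd$weights[, c("day", "weight_kg")]
  f <- herd$feed[, c("day", "dmi_kg")]
  # weight is 80 + t, so 200 kg is reached exactly on day 120
  expect_equal(days_to_reach(w, 200), 120)
  it <- interval_traits(w, f, c(100, 200), 1, 2)
  expect_equal(it$FP, 100)
  expect_equal(it$ADWG, 1)
  # interval DMI equals the discrete closed-form intake sum (dmi records are
  # stored at 1 g resolution)
  closed <- sum(0.1 * (80 + 20:119)^0.75)
  expect_equal(it$DMI, closed, tolerance = 3e-4)
})

test_that("derived trait tables satisfy the feed-efficiency identities for
           every animal and interval", {
  herd <- simulate_herd(herd_config(n_animals = 15, seed = 3))
  tr <- derive_traits(herd)
  for (ivl in c("W1-W2", "W2-W3", "W3-W4", "W4-W5")) {
    fcr <- tr[[paste(ivl, "FCR")]]
    adwg <- tr[[paste(ivl, "ADWG")]]
    ddmi <- tr[[paste(ivl, "DDMI")]]
    ok <- !is.na(fcr)
    expect_true(any(ok))
    expect_equal(fcr[ok] * adwg[ok], ddmi[ok], tolerance = 1e-9)
  }
  expect_equal(tr$TFCR * tr$TADWG, tr$TDDMI, tolerance = 1e-9)
  # DTR columns are nondecreasing across targets within animal
  dtr <- as.matrix(tr[, paste0("DTRW", 1:5)])
  diffs <- t(apply(dtr, 1, diff))
  expect_true(all(diffs >= 0, na.rm = TRUE))
})

test_that("animals that never reach a target are excluded, not
           extrapolated", {
  herd <- simulate_herd(herd_config(n_animals = 4, seed = 21))
  # truncate every weigh series below 400 kg
  herd$weights <- herd$weights[herd$weights$weight_kg < 400, ]
  tr <- derive_traits(herd)
  expect_true(all(is.na(tr$DTRW5)))
  excl <- attr(tr, "exclusions")
  expect_true(all(c(450) %in% excl$target))
  expect_true(all(excl$reason %in% c("not_reached", "pre_study")))
  expect_gte(sum(excl$reason == "not_reached" & excl$target == 450), 4)
})

test_that("season mapping is total and follows meteorological quarters", {
  expect_equal(as.character(season_at(as.Date("2016-01-01"), 0)), "winter")
  expect_equal(as.character(season_at(as.Date("2016-01-01"), 182)),
               "summer")
  s <- season_at(as.Date("2015-06-15"), 0:730)
  expect_false(anyNA(s))
  expect_setequal(levels(s), c("winter", "spring", "summer", "autumn"))
  # a season boundary: Feb 29 -> winter, Mar 1 -> spring
  expect_equal(as.character(season_at(as.Date("2016-02-29"), 0:1)),
               c("winter", "spring"))
})
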