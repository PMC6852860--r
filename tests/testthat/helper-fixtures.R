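`%||%` <- function(a, b) if (is.null(a)) b else a

# a herd configuration with every noise source at zero, for closed-form
# checks: weight on day t is exactly w0 + baseline * t
noise_free_config <- function(n = 1, baseline = 1.0, w0 = 80,
                              intake_coef = 0.1, markers = NULL,
                              seed = 99L) {
  herd_config(
    n_animals = n,
    markers = markers %||% list(marker_spec("m1", c("A", "G"), 0.5)),
    start_date_range = as.Date(c("2016-01-01", "2016-01-01")),
    gain_model = gain_model_spec(
      baseline_adwg = baseline,
      season_effects = c(winter = 0, spring = 0, summer = 0, autumn = 0),
      animal_sd = 0, residual_sd = 0,
      initial_weight_mean = w0, initial_weight_sd = 0),
    intake_model = intake_model_spec(intake_coefficient = intake_coef,
                                     noise_sd = 0),
    seed = seed
  )
}

published_gene_action <- function() {
  read.csv(test_path("fixtures", "gene_action_published.csv"),
           stringsAsFactors = FALSE)
}
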