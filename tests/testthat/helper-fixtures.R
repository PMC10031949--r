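# shared fixtures: study-like truth and small tables built in code

study_days <- c(0, 1, 3, 6, 9, 15, 28, 56)

truth_params <- function() default_mn_params()

study_design <- function(n_animals = 8, bn = 500) {
  mn_design(sprintf("A%02d", seq_len(n_animals)), study_days,
            bn_range = c(bn, bn))
}

# noiseless MN table: expected counts rounded at very large BN, so observed
# proportions match the curve to ~1e-7
noiseless_mn_table <- function(params = truth_params(), days = study_days,
                               n_animals = 4, bn = 1e7) {
  grid <- expand.grid(animal = sprintf("A%02d", seq_len(n_animals)), day = days,
                      stringsAsFactors = FALSE)
  data.frame(animal = grid$animal, day = grid$day, anticoagulant = "EDTA",
             bn = bn, mn = round(model_mn(params, grid$day) * bn))
}

binomial_mn_table <- function(seed, n_animals = 8, bn = 500,
                              params = truth_params()) {
  simulate_mn(params, study_design(n_animals, bn),
              dispersion_spec("binomial"), seed = seed)
}

lymphocyte_profile <- function(cv = 0) {
  hema_profile("lymphocyte", baseline_mean = 4, nadir_day = 15,
               nadir_fraction = 0.2, recovery_day = 27, cv = cv)
}

hema_days <- c(-12, -8, -3, 1, 3, 6, 9, 12, 15, 18, 21, 24, 27, 30, 42, 56)
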