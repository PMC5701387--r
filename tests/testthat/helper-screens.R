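# small screen configurations used across tests; effect-class sizes scale
# with the strain count, keeping the seeded fraction near the default screen

scaled_effect_classes <- function(n_strains, sigma_strain = 0.2) {
  f <- n_strains / 3822
  ec <- default_effect_classes(sigma_strain)
  for (i in seq_along(ec)) ec[[i]]$n <- max(2L, as.integer(round(ec[[i]]$n * f)))
  ec
}

small_config <- function(n_strains = 200L, n_events = 300L, seed = 42L,
                         effect_classes = list(), ...) {
  screen_config(n_strains = n_strains, n_events_per_strain = n_events,
                effect_classes = effect_classes, seed = seed, ...)
}

# direct normal-equations OLS, independent of the package's fitting path
oracle_ols_residuals <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.vector(y - X %*% beta)
}

# strain summaries built directly (bypassing the generator) for tests that
# need exact control over the summary values
fake_summaries <- function(S, mV, mC, ids = sprintf("s%03d", seq_along(S)),
                           plate = 1L) {
  data.frame(strain_id = ids, plate = plate, well = NA_character_,
             n_events = 1000L, S = S, mV = mV, mC = mC,
             cv_S = 0.1, cv_mV = 0.1, cv_mC = 0.1,
             qc_pass = TRUE, qc_reason = NA_character_)
}
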