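# Shared fixtures, built once per test run. Sizes are chosen so the whole
# suite runs on one CPU in a few minutes while keeping enough signal for
# the statistical checks.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_toy <- function() fixture("toy", function() make_toy_locus(seed = 1L))

# narrow enumeration config keeping toy design counts small
fx_toy_config <- function() peg_config(pbs_min = 11L, pbs_max = 13L,
                                       rtt_min = 10L, rtt_max = 16L,
                                       flank = 60L)

# simulated table, documented generator conditions (sigma = 5, n = 2000)
fx_sim_signal <- function() fixture("sim_signal", function()
  simulate_training_table(sim_config(seed = 1L, n_rows = 2000L, sigma = 5)))

# all effects zero: efficiency is pure noise
fx_sim_null <- function() fixture("sim_null", function() {
  eff <- c(cas9_score = 0, fold_d1 = 0, pbs_gc = 0, is_dPAM = 0,
           target_pos = 0, target_end_flank = 0, n_sub = 0, n_ins = 0,
           n_del = 0)
  simulate_training_table(sim_config(seed = 2L, n_rows = 2000L,
                                     effects = eff, sigma = 5))
})

# only target_pos carries signal (for attribution ranking)
fx_sim_single <- function() fixture("sim_single", function() {
  eff <- c(target_pos = -10)
  simulate_training_table(sim_config(seed = 5L, n_rows = 800L,
                                     effects = eff, sigma = 5))
})

fx_cv_signal <- function() fixture("cv_signal", function()
  nested_cv_train(fx_sim_signal(), model_type = "pe3", n_candidates = 8L,
                  nrounds = 200L, seed = 11L))

fx_cv_null <- function() fixture("cv_null", function()
  nested_cv_train(fx_sim_null(), model_type = "pe3", n_candidates = 8L,
                  nrounds = 200L, seed = 11L))

fx_cv_single <- function() fixture("cv_single", function()
  nested_cv_train(fx_sim_single(), model_type = "pe3", n_candidates = 4L,
                  nrounds = 150L, seed = 13L))

# small, quickly trained PE2/PE3 model pair for pipeline tests
fx_models <- function() fixture("models", function() {
  tab <- simulate_training_table(sim_config(seed = 7L, n_rows = 400L))
  list(pe2 = nested_cv_train(tab, model_type = "pe2", n_candidates = 2L,
                             outer_k = 3L, nrounds = 60L, seed = 7L),
       pe3 = nested_cv_train(tab, model_type = "pe3", n_candidates = 2L,
                             outer_k = 3L, nrounds = 60L, seed = 7L),
       table = tab)
})
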