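test_that("trial simulation is reproducible and well-formed", {
  sim <- build_simulation()
  expect_equal(nrow(run_trials(0, sim$grid, sim$banks, sim$prior)), 0)
  r1 <- run_trials(50, sim$grid, sim$banks, sim$prior, t = 0.2, seed = 42)
  r2 <- run_trials(50, sim$grid, sim$banks, sim$prior, t = 0.2, seed = 42)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 100)  # two rows (variables) per trial
  expect_true(all(r1$true_gravity == 9.820))
  expect_true(all(r1$true_velocity %in% 3:10))
  expect_true(all(r1$decoded_velocity_mle %in% 3:10))
  expect_true(all(r1$decoded_velocity_bayes %in% 3:10))
  expect_true(all(r1$decoded_gravity_bayes %in% sim$grid$gravities))
  # a different seed gives different trials
  r3 <- run_trials(50, sim$grid, sim$banks, sim$prior, t = 0.2, seed = 43)
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("batch decisions equal one-at-a-time readouts", {
  sim <- build_simulation()
  rec <- run_trials(8, sim$grid, sim$banks, sim$prior, t = 0.2, seed = 314)
  for (i in seq_len(nrow(rec))) {
    row <- rec[i, ]
    s <- optical_value(trajectory(row$true_gravity, row$true_velocity), 0.2,
                       row$variable)
    # reconstruct this trial's response from its recorded seed; gamma_dot was
    # drawn second, continuing the same stream
    resp_g <- encode(sim$banks$gamma,
                     optical_value(trajectory(row$true_gravity, row$true_velocity),
                                   0.2, "gamma"),
                     seed = row$response_seed)
    resp <- if (row$variable == "gamma") resp_g
            else encode(sim$banks$gamma_dot, s, seed = NULL)
    m <- mle_velocity_readout(sim$grid, sim$banks[[row$variable]], resp, 0.2,
                              row$variable)
    b <- bayes_velocity_readout(sim$grid, sim$banks[[row$variable]], resp, 0.2,
                                row$variable, sim$prior)
    expect_equal(row$decoded_velocity_mle, m$v_h)
    expect_equal(row$decoded_gravity_mle, m$gravity)
    expect_equal(row$decoded_velocity_bayes, b$v_h)
    expect_equal(row$decoded_gravity_bayes, b$gravity)
  }
})

test_that("summaries count exact velocity matches with binomial errors", {
  sim <- build_simulation()
  rec <- run_trials(30, sim$grid, sim$banks, sim$prior, seed = 9)
  sm <- summarize_trials(rec)
  expect_equal(nrow(sm), 4)
  expect_true(all(sm$fraction >= 0 & sm$fraction <= 1))
  expect_equal(sm$se, sqrt(sm$fraction * (1 - sm$fraction) / sm$n))
  # perfect and hopeless decoders hit the boundary fractions
  all_right <- rec
  all_right$decoded_velocity_mle <- all_right$true_velocity
  expect_true(all(summarize_trials(all_right)$fraction[
    summarize_trials(all_right)$decoder == "mle"] == 1))
  none <- rec
  none$decoded_velocity_bayes <- none$true_velocity + 100
  sm0 <- summarize_trials(none)
  expect_true(all(sm0$fraction[sm0$decoder == "bayes"] == 0))
  expect_warning(summarize_trials(rec[0, ]), "undefined")
})

test_that("a broken random decoder sits at the 1/8 chance level", {
  sim <- build_simulation()
  rec <- run_trials(1000, sim$grid, sim$banks, sim$prior, seed = 77)
  set.seed(1234)
  rec$decoded_velocity_mle <- sample(sim$grid$velocities, nrow(rec), replace = TRUE)
  sm <- summarize_trials(rec)
  p <- sm$fraction[sm$decoder == "mle"]
  se <- sqrt(0.125 * 0.875 / 1000)
  expect_true(all(abs(p - 0.125) <= 3 * se))
})

test_that("sweeping one prior mean reproduces a plain run with that prior", {
  sim <- build_simulation()
  sw <- prior_sweep(9.329, 0.5, 200, sim$grid, sim$banks, seed = 6)
  rec <- run_trials(200, sim$grid, sim$banks, gravity_prior(9.329, 0.5), seed = 6)
  sm <- summarize_trials(rec)
  for (i in seq_len(nrow(sm))) {
    cell <- sw$table[sw$table$decoder == sm$decoder[i] &
                     sw$table$variable == sm$variable[i], ]
    expect_equal(cell$fraction, sm$fraction[i])
    expect_equal(cell$n_correct, sm$n_correct[i])
  }
  expect_equal(sw$chance_level, 1 / 8)
})

test_that("sweep points share one set of encoded responses", {
  sim <- build_simulation()
  sw1 <- prior_sweep(c(8.838, 9.820), 0.5, 100, sim$grid, sim$banks, seed = 21)
  sw2 <- prior_sweep(c(9.820, 10.802, 11.784), 0.5, 100, sim$grid, sim$banks,
                     seed = 21)
  # identical response hashes: adding sweep points never perturbs the trials
  expect_identical(sw1$response_hash, sw2$response_hash)
  # and the shared prior mean yields identical cells
  c1 <- sw1$table[sw1$table$prior_mean == 9.820, ]
  c2 <- sw2$table[sw2$table$prior_mean == 9.820, ]
  rownames(c1) <- rownames(c2) <- NULL
  expect_identical(c1, c2)
  # the MLE baseline is constant across prior means
  mle <- sw2$table[sw2$table$decoder == "mle" & sw2$table$variable == "gamma_dot", ]
  expect_equal(length(unique(mle$fraction)), 1L)
  expect_error(prior_sweep(numeric(0), 0.5, 10, sim$grid, sim$banks), "non-empty")
  expect_error(prior_sweep(9.82, 0, 10, sim$grid, sim$banks), "positive")
})

test_that("results round-trip through CSV and carry provenance in JSON", {
  sim <- build_simulation()
  cfg <- sim_config(n_trials = 10, seed = 5)
  rec <- run_trials(10, sim$grid, sim$banks, sim$prior, seed = 5)
  csv <- tempfile(fileext = ".csv")
  write_results(rec, csv, "csv")
  back <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(back, as.data.frame(rec))
  # byte-identical output across reruns of the same config
  csv2 <- tempfile(fileext = ".csv")
  write_results(run_trials(10, sim$grid, sim$banks, sim$prior, seed = 5),
                csv2, "csv")
  expect_identical(readLines(csv), readLines(csv2))
  js <- tempfile(fileext = ".json")
  write_results(rec, js, "json", cfg = cfg)
  payload <- jsonlite::read_json(js)
  expect_equal(payload$seed, 5)
  expect_equal(payload$config_hash, unname(config_hash(cfg)))
  expect_equal(payload$config$n_trials, 10)
  # sweeps write the tidy table with the documented columns
  sw <- prior_sweep(c(9.82, 10.802), 0.5, 20, sim$grid, sim$banks, seed = 5)
  swcsv <- tempfile(fileext = ".csv")
  write_results(sw, swcsv, "csv")
  tab <- utils::read.csv(swcsv)
  expect_equal(names(tab),
               c("prior_mean", "decoder", "variable", "n", "n_correct",
                 "fraction", "se"))
  expect_error(write_results(list(), tempfile(), "csv"), "trial_records")
})

test_that("the rate-of-change variable dominates where the prior carries signal", {
  sim <- build_simulation()
  # prior means within half a grid step (0.05g) of the true gravity: here the
  # prior disambiguates and the gamma_dot advantage is large; far from the
  # truth both variables collapse toward chance and the ordering washes out
  near <- c(9.329, 9.820, 10.311)
  sw <- prior_sweep(near, 0.5, 1000, sim$grid, sim$banks, seed = 1)
  bay <- sw$table[sw$table$decoder == "bayes", ]
  gd <- bay$fraction[bay$variable == "gamma_dot"]
  ga <- bay$fraction[bay$variable == "gamma"]
  expect_true(all(gd > ga))
  expect_gt(mean(gd - ga), 0.1)
  # the strong-prior rescue also shows up against the MLE baseline
  mle <- sw$table[sw$table$decoder == "mle" & sw$table$variable == "gamma_dot", ]
  expect_true(all(gd > mle$fraction))
})
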