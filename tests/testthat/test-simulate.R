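test_that("severity-to-amplitude draws stay inside their band", {
  set.seed(1)
  expect_identical(severity_to_amplitude(0), 0)
  for (rep in 1:20) {
    a2 <- severity_to_amplitude(2)
    expect_gte(a2, 1); expect_lt(a2, 3)
    a3 <- severity_to_amplitude(3)
    expect_gte(a3, 3); expect_lt(a3, 10)
  }
  set.seed(77); d1 <- severity_to_amplitude(3)
  set.seed(77); d2 <- severity_to_amplitude(3)
  expect_identical(d1, d2)
  expect_error(severity_to_amplitude(5), "0..4")
  expect_error(severity_to_amplitude(-1), "0..4")
})

test_that("config validation enforces the physical invariants", {
  expect_error(simulation_config(sampling_rate = 0), "sampling_rate")
  expect_error(simulation_config(rest_duration = -1), "rest_duration")
  expect_error(simulation_config(n_rest_intervals = 0), "n_rest_intervals")
  expect_error(simulation_config(noise_sd = -0.1), "noise_sd")
  expect_error(
    simulation_config(amplitude_bands = list("0" = c(0, 0.5))), "severity 0")
  expect_error(
    simulation_config(amplitude_bands = list("0" = c(0, 0), "1" = c(0, 2),
                                             "2" = c(1, 3), "3" = c(3, 10))),
    "overlap")
})

test_that("noise-free severity-0 recordings give all-zero rest moduli", {
  cfg <- noise_free_config(seed = 2, n_per_severity = c("0" = 2))
  co <- simulate_cohort(cfg)
  for (inst in preprocess_cohort(co))
    expect_lt(max(inst$moduli), 1e-12)
})

test_that("noise-free tremor modulus is a rectified sinusoid with the closed-form peak", {
  cfg <- simulation_config(n_per_severity = c("3" = 1), noise_sd = 0,
                           rest_duration = 10, n_rest_intervals = 2,
                           nonrest_duration = 3, seed = 9)
  co <- simulate_cohort(cfg)
  truth <- co$truth[1, ]
  inst <- preprocess_cohort(co)[[1]]
  expected_peak <- (2 * pi * truth$tremor_freq)^2 *
    (truth$displacement_amp_cm / 100 / 2) / 9.81
  # finite-sample mean-centering leaves a tiny residual offset
  expect_equal(max(inst$moduli), expected_peak, tolerance = 5e-3)
  # rectified sinusoid: all moduli within [0, peak]
  expect_true(all(inst$moduli <= expected_peak * 1.005))
})

test_that("recordings carry tremor only inside rest intervals", {
  cfg <- simulation_config(n_per_severity = c("3" = 1), noise_sd = 0, seed = 5)
  co <- simulate_cohort(cfg)
  r <- co$recordings[[1]]
  ann <- r$annotations
  rest <- ann[ann$label == "rest", ]
  expect_equal(nrow(rest), cfg$n_rest_intervals)
  # intervals tile the recording without overlap
  o <- order(ann$start)
  expect_equal(ann$start[o][-1], ann$end[o][-nrow(ann)])
})

test_that("cohort generation is deterministic and counts are honoured", {
  cfg <- simulation_config(n_per_severity = c("0" = 1, "1" = 1, "2" = 1, "3" = 1),
                           rest_duration = 2, nonrest_duration = 2,
                           n_rest_intervals = 1, seed = 10)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$recordings[[3]]$recording$data,
                   co2$recordings[[3]]$recording$data)
  expect_equal(nrow(co1$truth), 4)
  expect_false(anyDuplicated(co1$truth$instance_id) > 0)
  expect_identical(co1$truth$group, c("HC", "PD", "PD", "PD"))
  # HC => score 0 and no amplitude
  expect_true(all(co1$truth$displacement_amp_cm[co1$truth$group == "HC"] == 0))

  # the default configuration mirrors the published cohort: 25 instances
  def <- simulation_config()
  expect_equal(sum(def$n_per_severity), 25)
  expect_equal(unname(def$n_per_severity[c("0", "1", "2", "3")]), c(11, 6, 5, 3))
})

test_that("mean rest modulus increases with severity when bands are separated", {
  worse <- 0
  for (s in 1:10) {
    cfg <- simulation_config(n_per_severity = c("1" = 1, "2" = 1, "3" = 1),
                             amplitude_bands = list("1" = c(3.4, 3.6),
                                                    "2" = c(6.0, 6.2),
                                                    "3" = c(9.9, 10.1)),
                             tremor_freq_range = c(4.95, 5.05),
                             rest_duration = 4, n_rest_intervals = 2,
                             nonrest_duration = 2, noise_sd = 0.005, seed = s)
    inst <- preprocess_cohort(simulate_cohort(cfg))
    means <- vapply(inst, function(z) mean(z$moduli), numeric(1))
    if (any(diff(means) <= 0)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})
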