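test_that("entrapment efficiency and drug loading follow their formulas", {
  expect_equal(entrapment_efficiency(10, 0), 100)
  expect_equal(entrapment_efficiency(10, 10), 0)
  expect_equal(entrapment_efficiency(10, 2), 80)
  expect_error(entrapment_efficiency(0, 0), "positive")
  expect_error(entrapment_efficiency(10, 12), "\\[0, total_drug\\]")

  expect_equal(drug_loading(5, 5, 20), 0)
  expect_equal(drug_loading(25, 5, 20), 50)  # entrapped == lipid
  expect_equal(drug_loading(6, 1, 20), 20)   # 5 / 25
  expect_error(drug_loading(6, 1, 0), "positive")
  expect_gt(drug_loading(10, 1, 30), 0)
  expect_lt(drug_loading(10, 1, 30), 100)
})

test_that("cumulative permeation applies the per-area mass balance", {
  s <- permeation_series(1, 1, receptor_volume = 12, sample_volume = 0.5,
                         diffusion_area = 3.5)
  expect_equal(cumulative_permeation(s), 12 / 3.5, tolerance = 1e-4)
  z <- permeation_series(1:4, rep(0, 4), receptor_volume = 12)
  expect_equal(cumulative_permeation(z), rep(0, 4))
  expect_error(permeation_series(1, 1, receptor_volume = 0.4,
                                 sample_volume = 0.5), "smaller")
})

test_that("constant-flux sampling is reconstructed to the simulator truth", {
  # zero-order mass input into the receptor is a constant-flux donor
  tt <- c(1, 2, 4, 6, 8, 12, 24)
  dose <- 100; V <- 12; Vs <- 0.5; A <- 3.5
  sim <- simulate_release_sampling("zero_order", list(k0 = 0.002), tt,
                                   medium_volume = V, sample_volume = Vs,
                                   dose = dose)
  s <- permeation_series(tt, sim$concentrations, receptor_volume = V,
                         sample_volume = Vs, diffusion_area = A)
  expect_equal(cumulative_permeation(s), dose * sim$true_cr / A,
               tolerance = 1e-6)
  # splitting a sampling interval (mass-balance-consistent intermediate
  # concentrations) leaves shared timepoints unchanged
  tt2 <- sort(c(tt, 3, 10))
  sim2 <- simulate_release_sampling("zero_order", list(k0 = 0.002), tt2,
                                    medium_volume = V, sample_volume = Vs,
                                    dose = dose)
  s2 <- permeation_series(tt2, sim2$concentrations, receptor_volume = V,
                          sample_volume = Vs, diffusion_area = A)
  expect_equal(cumulative_permeation(s2)[match(tt, tt2)],
               cumulative_permeation(s), tolerance = 1e-9)
})

test_that("transfollicular cumulation is the exact route difference", {
  expect_equal(transfollicular_cumulation(10, 4), 6)
  expect_equal(transfollicular_cumulation(c(3, 3), c(3, 3)), c(0, 0))
  full <- c(1, 2.5, 4); blocked <- c(0.5, 1, 1.5)
  expect_equal(transfollicular_cumulation(full, blocked) + blocked, full)
  expect_error(transfollicular_cumulation(1:3, 1:2), "length")
  expect_error(transfollicular_cumulation(1:3, 1:3, times = 1:3,
                                          times_blocked = c(1, 2, 4)),
               "align")
})

test_that("an injected follicular route is recovered from paired skins", {
  tt <- c(1, 2, 4, 8, 24)
  dose <- 200; V <- 12; Vs <- 0.5; A <- 3.5
  # transepidermal route (present in both skins) + follicular shunt
  epi <- simulate_release_sampling("higuchi", list(k_h = 0.01), tt,
                                   medium_volume = V, sample_volume = Vs,
                                   dose = dose)
  fol <- simulate_release_sampling("first_order", list(k1 = 0.05), tt,
                                   medium_volume = V, sample_volume = Vs,
                                   dose = dose)
  # receptor mixing is linear: full-skin concentrations are the route sum
  full <- permeation_series(tt, epi$concentrations + fol$concentrations,
                            receptor_volume = V, sample_volume = Vs,
                            diffusion_area = A)
  blocked <- permeation_series(tt, epi$concentrations, receptor_volume = V,
                               sample_volume = Vs, diffusion_area = A,
                               condition = "blocked")
  trans <- transfollicular_cumulation(cumulative_permeation(full),
                                      cumulative_permeation(blocked),
                                      times = tt)
  expect_equal(trans, dose * fol$true_cr / A, tolerance = 1e-6)
})

test_that("Draize PII equals the plain mean of all recorded scores", {
  sls <- data.frame(timepoint_h = c(1, 24, 48, 72),
                    erythema = c(1.5, 1.5, 1.25, 1), edema = 0)
  r <- draize_pii(sls)
  expect_equal(r$pii, 0.66)
  expect_equal(r$pii_raw, 5.25 / 8)
  expect_equal(r$class, "Slight irritation")

  zero <- data.frame(timepoint_h = c(1, 24, 48, 72), erythema = 0, edema = 0)
  expect_equal(draize_pii(zero)$pii, 0)
  expect_equal(draize_pii(zero)$class, "No irritation")

  severe <- data.frame(timepoint_h = c(1, 24, 48, 72), erythema = 4, edema = 4)
  expect_equal(draize_pii(severe)$pii, 4)
  expect_equal(draize_pii(severe)$class, "Moderate irritation")

  # brute-force oracle: PII is the arithmetic mean of the 2T scores
  set.seed(21)
  for (i in 1:20) {
    obs <- data.frame(timepoint_h = 1:4,
                      erythema = sample(seq(0, 4, 0.25), 4, TRUE),
                      edema = sample(seq(0, 4, 0.25), 4, TRUE))
    expect_equal(draize_pii(obs)$pii_raw,
                 mean(c(obs$erythema, obs$edema)))
  }
  expect_error(draize_pii(data.frame(timepoint_h = 1, erythema = 5,
                                     edema = 0)), "\\[0, 4\\]")
})

test_that("irritation class bands use the conventional cut points", {
  expect_equal(draize_class(c(0, 0.4, 0.5, 1.9, 2.0, 4.9, 5.0, 8.0)),
               c("No irritation", "No irritation", "Slight irritation",
                 "Slight irritation", "Moderate irritation",
                 "Moderate irritation", "Severe irritation",
                 "Severe irritation"))
})
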