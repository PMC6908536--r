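# Rate model, sinogram synthesis, NU-4 extraction, NECR, randoms fit.

test_that("necr follows RT^2/(RT+RS+RR) and never exceeds the trues rate", {
  expect_equal(necr(100, 50, 50), 50)
  expect_equal(necr(123, 0, 0), 123)
  expect_equal(necr(0, 0, 0), 0)
  expect_error(necr(-1, 0, 0), ">= 0")
  set.seed(5)
  rt <- runif(50, 0, 1e6); rs <- runif(50, 0, 1e6); rr <- runif(50, 0, 1e6)
  expect_true(all(necr(rt, rs, rr) <= rt))
})

test_that("rates vanish at zero activity and spurious terms need prompt gammas", {
  r0 <- simulate_rates("F-18", activities = 0)
  expect_equal(unlist(r0[, c("r_true", "r_scatter", "r_random", "necr")]),
               c(r_true = 0, r_scatter = 0, r_random = 0, necr = 0))
  p <- rate_model_params()
  a <- c(1, 10, 50, 100)
  pure <- simulate_rates("F-18", a, p)
  # a hypothetical twin of 18F carrying a 99.9% 1157 keV prompt gamma
  twin <- radionuclide("F-18-gamma", 109.8 * 60, 0.967,
                       mean_positron_energy = 249.8, max_positron_energy = 633.5,
                       prompt_gammas = data.frame(energy_kev = 1157, yield = 0.999))
  loaded <- simulate_rates(twin, a, p)
  expect_equal(pure$r_true, loaded$r_true)             # same positron physics
  expect_true(all(loaded$r_scatter > pure$r_scatter))
  expect_true(all(loaded$r_random > pure$r_random))
  expect_true(all(loaded$necr < pure$necr))            # strict at every activity
  # pure emitter: scatter is exactly SF/(1-SF) of trues
  expect_equal(pure$r_scatter, 0.3 / 0.7 * pure$r_true, tolerance = 1e-12)
})

test_that("NECR curve with dead time is single-peaked over the activity range", {
  a <- seq(1, 300, by = 1)
  r <- simulate_rates("F-18", a, rate_model_params())
  s <- sign(diff(r$necr))
  expect_equal(sum(diff(s) != 0), 1)   # one rise -> fall transition
  expect_true(all(r$necr <= r$r_true))
})

test_that("frame durations respect the quarter-half-life rule", {
  for (nm in c("F-18", "Ga-68", "Sc-44g", "Cu-64")) {
    fr <- frame_schedule(nm, 100, 1.5)
    dur <- fr$t_end[1] - fr$t_start[1]
    expect_lte(dur, get_nuclide(nm)$half_life / 4)
    expect_equal(nrow(fr),
                 max(1, floor(decay_time(nm, 100, 1.5) / dur)))
  }
  expect_equal(frame_schedule("F-18")$t_end[1], 900)     # 15 min
  expect_equal(frame_schedule("Ga-68")$t_end[1], 900)    # 15 min
  expect_equal(frame_schedule("Sc-44g")$t_end[1], 1800)  # 30 min
})

test_that("sinogram synthesis: zero rates, source trace, determinism", {
  ph <- build_nec_phantom()
  geom <- sinogram_geometry(frame_duration = 900)
  z <- simulate_sinograms(list(r_true = 0, r_scatter = 0, r_random = 0),
                          ph, geom, seed = 1)
  expect_true(all(z$prompt == 0) && all(z$delayed == 0))
  sg <- simulate_sinograms(list(r_true = 1e5, r_scatter = 0, r_random = 0),
                           ph, geom, seed = 2)
  s <- petbench:::.radial_centers(geom)
  theta <- pi * (seq_len(geom$n_angles) - 1) / geom$n_angles
  peak_s <- s[apply(sg$prompt, 2, which.max)]
  expect_lt(max(abs(peak_s - 17.5 * cos(theta))), 2 * geom$radial_bin_mm)
  expect_equal(max(abs(peak_s)), 17.5, tolerance = 0.05)  # trace amplitude
  sg2 <- simulate_sinograms(list(r_true = 1e5, r_scatter = 0, r_random = 0),
                            ph, geom, seed = 2)
  expect_identical(sg$prompt, sg2$prompt)
})

test_that("NU-4 extraction round-trips the generating rates within 3%", {
  ph <- build_nec_phantom()
  geom <- sinogram_geometry(frame_duration = 900)
  truth <- simulate_rates("F-18", activities = 20, rate_model_params())
  sg <- simulate_sinograms(truth, ph, geom, seed = 31)
  got <- nu4_extract_rates(sg$prompt, sg$delayed, geom)
  expect_equal(got$r_true, truth$r_true, tolerance = 0.03)
  expect_equal(got$r_scatter, truth$r_scatter, tolerance = 0.03)
  expect_equal(got$r_random, truth$r_random, tolerance = 0.03)
})

test_that("NU-4 extraction degenerate inputs behave", {
  geom <- sinogram_geometry(frame_duration = 100)
  prompt <- matrix(0, geom$n_radial, geom$n_angles)
  prompt[(geom$n_radial + 1) %/% 2, ] <- 1000   # centered delta line
  delayed <- matrix(0, geom$n_radial, geom$n_angles)
  got <- nu4_extract_rates(prompt, delayed, geom)
  expect_equal(got$r_random, 0)
  expect_lt(got$r_scatter / got$r_true, 0.01)
})

test_that("randoms quadratic fit: exact data, noisy data, degenerate design", {
  a <- seq(2, 100, length.out = 20)
  exact <- 3 * a^2 + 0.5 * a
  fit <- fit_randoms_quadratic(a, exact)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$coefficients[["quadratic"]], 3, tolerance = 1e-9)
  lin <- fit_randoms_quadratic(a, 7 * a)
  expect_lt(abs(lin$coefficients[["quadratic"]]), 1e-9)
  expect_error(fit_randoms_quadratic(rep(5, 10), rnorm(10)), "distinct")
})
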