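test_that("single fixed acceptor at R0 transfers with efficiency one half", {
  expect_equal(donor_transfer_efficiency(53.1, R0 = 53.1), 0.5)
  expect_equal(donor_transfer_efficiency(numeric(0)), 0)
})

test_that("per-donor efficiency equals direct S/(1+S) for few fixed acceptors", {
  R0 <- 53.1
  for (r in list(40, c(40, 80), c(30, 60, 120))) {
    S <- sum((R0 / r)^6)
    expect_identical(donor_transfer_efficiency(r, R0), S / (1 + S))
  }
})

test_that("proximity FRET is zero at zero density and rises with density", {
  expect_equal(simulate_proximity_fret(0, mc_settings = small_mc())$E_prox, 0)
  lo <- simulate_proximity_fret(500, mc_settings = small_mc(21))
  hi <- simulate_proximity_fret(1000, mc_settings = small_mc(21))
  expect_gt(hi$E_prox, lo$E_prox)
  expect_true(lo$E_prox > 0 && lo$E_prox < 1)
})

test_that("a larger exclusion radius never increases proximity FRET", {
  tight <- simulate_proximity_fret(800, exclusion_radius = 10,
                                   mc_settings = small_mc(33))
  loose <- simulate_proximity_fret(800, exclusion_radius = 50,
                                   mc_settings = small_mc(33))
  expect_lte(loose$E_prox, tight$E_prox)
})

test_that("excessive density for the cutoff errors out", {
  expect_error(simulate_proximity_fret(1e9), "too high")
  expect_error(simulate_proximity_fret(-5), "non-negative")
})

test_that("proximity curve interpolates monotonically between grid values", {
  grid0 <- 0
  m0 <- build_proximity_curve(density_grid = grid0, mc_settings = small_mc())
  expect_equal(m0$E_prox_curve, 0)

  m <- build_proximity_curve(density_grid = c(0, 100, 400, 1000),
                             mc_settings = small_mc(2))
  # interpolation identity at grid points
  expect_equal(predict(m, m$density_grid), m$E_prox_curve)
  # monotone curve; midpoints lie between neighbours (random grids)
  expect_true(all(diff(m$E_prox_curve) >= 0))
  set.seed(14)
  for (i in 1:5) {
    g <- sort(c(0, runif(4, 10, 1500)))
    mi <- build_proximity_curve(density_grid = g,
                                mc_settings = small_mc(i))
    mids <- (g[-1] + g[-length(g)]) / 2
    v <- predict(mi, mids)
    lo <- pmin(mi$E_prox_curve[-1], mi$E_prox_curve[-length(g)])
    hi <- pmax(mi$E_prox_curve[-1], mi$E_prox_curve[-length(g)])
    expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
  }
  expect_error(build_proximity_curve(density_grid = c(100, 50)),
               "increasing")
})

test_that("dilute-limit slope is stable across seeds within MC error", {
  d <- 50  # receptors/um^2, dilute for R0 ~ 53 A
  ms <- lapply(c(101, 202, 303), function(s)
    simulate_proximity_fret(d, mc_settings = proximity_mc_settings(
      n_donors = 5000L, n_replicates = 4L, seed = s)))
  slopes <- vapply(ms, function(m) m$E_prox / d, numeric(1))
  ses <- vapply(ms, function(m) m$mc_se / d, numeric(1))
  expect_lt(max(slopes) - min(slopes), 6 * max(ses))
})

test_that("FRET correction subtracts the curve at each vesicle's density", {
  model <- build_proximity_curve(density_grid = c(0, 200, 600),
                                 mc_settings = small_mc(7))
  Ep200 <- predict(model, 200)
  tab <- data.frame(vesicle_id = 1:3,
                    E = c(0.30, Ep200 - 0.10, 0.2),
                    C_A = c(200, 200, 5000),
                    quality_flags = "")
  out <- correct_fret(tab, model, tolerance = 0.05)
  expect_equal(out$E_D[1], 0.30 - Ep200)
  # far below the stochastic floor: clipped to zero and flagged
  expect_equal(out$E_D[2], 0)
  expect_match(out$quality_flags[2], "below_proximity")
  # density beyond the grid: flagged extrapolation
  expect_match(out$quality_flags[3], "proximity_extrapolated")
})

test_that("pure monomers with proximity background correct back to zero FRET", {
  model <- build_proximity_curve(
    density_grid = c(0, 50, 100, 200, 400, 800),
    mc_settings = proximity_mc_settings(n_donors = 5000L, n_replicates = 3L,
                                        seed = 17))
  # near-zero association: essentially no specific dimers
  base <- list(K_diss = 1e9, E_intrinsic = 0.8, n_vesicles = 200L,
               T_bounds = c(10, 800), proximity_model = model, seed = 19)
  # noiseless: the correction cancels the stochastic background exactly
  cfg0 <- do.call(synthetic_config, c(base, sigma_E = 0, sigma_rel = 0))
  fx0 <- synth_corrected(cfg0, model)
  expect_lt(max(abs(fx0$records$E_D)), 1e-5)
  # intensity noise: residual stays at the (one-sided, clip-limited) noise
  # floor of the sensitized-emission subtraction
  cfg1 <- do.call(synthetic_config, c(base, sigma_E = 0, sigma_rel = 0.02))
  fx1 <- synth_corrected(cfg1, model)
  ok <- fx1$records$quality_flags == ""
  expect_lt(abs(mean(fx1$records$E[ok] - fx1$records$E_prox[ok])), 0.01)
  expect_lt(mean(fx1$records$E_D[ok]), 0.01)
})

test_that("proximity curves round trip through their text serialization", {
  m <- build_proximity_curve(density_grid = c(0, 100, 500),
                             mc_settings = small_mc(8))
  path <- tempfile(fileext = ".tsv")
  write_proximity_curve(m, path)
  back <- read_proximity_curve(path)
  expect_equal(back$E_prox_curve, m$E_prox_curve, tolerance = 1e-10)
  expect_equal(back$R0, m$R0)
  expect_equal(back$mc_settings, m$mc_settings)
  unlink(path)
})
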