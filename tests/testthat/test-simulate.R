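test_that("with no sinks the full dose is conserved in the body", {
  p <- make_toy_params(vmax = 0, clsys = 0)
  for (reg in list(dose_regimen(40, 1),
                   dose_regimen(25, 0.5, dosing_interval_tau = 12,
                                n_doses = 3L))) {
    t_end <- if (reg$n_doses > 1) 36 else 12
    sim <- pbpk_simulate(p, reg, t_end = t_end)
    dose_ng <- reg$dose_amount * reg$n_doses * 1e6
    expect_lt(abs(total_amount(sim) - dose_ng) / dose_ng, 1e-3)
    expect_equal(sim$eliminated[length(sim$times)], 0, tolerance = 1e-8)
  }
})

test_that("fast-exchange limit matches the one-compartment closed form", {
  # pstc and flows huge, kp = 1, B:P = 1, fu = 1: the whole body collapses
  # to a single well-stirred volume with linear clearance CL from venous
  # blood (large cardiac output removes the flow limitation on mixing)
  CL <- 20
  p <- make_toy_params(kp = 1, pstc = 1e6, vmax = 0, clsys = CL,
                       fu = 1, bp = 1, co = 5e4)
  V <- sum(vapply(p$tissues, `[[`, numeric(1), "volume")) +
    p$venous_volume + p$arterial_volume
  grid <- seq(0.05, 8, by = 0.05)
  sim <- pbpk_simulate(p, dose_regimen(80, 1), t_end = 8,
                       output_grid = grid)
  expected <- one_cpt_infusion(grid, 80, 1, V, CL)
  expect_lt(max(abs(sim$plasma_conc - expected) / expected), 0.01)
})

test_that("linear kinetics give dose-proportional, superposable profiles", {
  p <- make_toy_params(vmax = 1e9, km = 1e9, clsys = 0)  # linear flux
  grid <- seq(0.1, 12, by = 0.1)
  s40 <- pbpk_simulate(p, dose_regimen(40, 1), 12, output_grid = grid)
  s80 <- pbpk_simulate(p, dose_regimen(80, 1), 12, output_grid = grid)
  expect_lt(max(abs(s80$plasma_conc / 2 - s40$plasma_conc) /
                  s40$plasma_conc), 1e-3)

  # superposition: multiple-dose profile equals sum of shifted singles
  tau <- 6
  smulti <- pbpk_simulate(p, dose_regimen(40, 1, dosing_interval_tau = tau,
                                          n_doses = 3L), 18,
                          output_grid = seq(0.25, 18, by = 0.25))
  slong <- pbpk_simulate(p, dose_regimen(40, 1), 20,
                         output_grid = seq(0.01, 20, by = 0.01))
  super <- sapply(smulti$times, function(t) {
    sum(sapply(0:2, function(k) {
      ts <- t - k * tau
      if (ts <= 0.005) 0 else sim_plasma_at(slong, ts)
    }))
  })
  keep <- super > max(super) * 1e-4
  expect_lt(max(abs(smulti$plasma_conc[keep] - super[keep]) / super[keep]),
            0.01)
})

test_that("saturable uptake raises dose-normalized exposure with dose", {
  p <- make_toy_params(vmax = 4e8, km = 150, vmax_eff = 4e8, km_eff = 150,
                       fu = 0.05, bp = 0.6)
  grid <- seq(0.1, 12, by = 0.1)
  auc_dn <- sapply(c(20, 300), function(d) {
    sim <- pbpk_simulate(p, dose_regimen(d, 1), 12, output_grid = grid)
    sum(diff(grid) * (head(sim$plasma_conc, -1) +
                        tail(sim$plasma_conc, -1)) / 2) / d
  })
  expect_gt(auc_dn[2], auc_dn[1])
})

test_that("high-Km saturable flux converges to its linear-clearance limit", {
  # vmax/km fixed; km far above all concentrations => linear behaviour
  clint <- 2e5  # (ng/h)/(ng/ml)
  grids <- seq(0.1, 12, by = 0.1)
  sims <- lapply(c(1e5, 1e7), function(km)
    pbpk_simulate(make_toy_params(vmax = clint * km, km = km,
                                  vmax_eff = 0),
                  dose_regimen(40, 1), 12, output_grid = grids))
  expect_lt(max(abs(sims[[1]]$plasma_conc - sims[[2]]$plasma_conc) /
                  sims[[2]]$plasma_conc), 0.01)
})

test_that("steady-state accumulation follows the terminal-slope prediction", {
  p <- make_toy_params(vmax = 0, clsys = 15)  # linear elimination
  tau <- 12
  reg <- dose_regimen(60, 1, dosing_interval_tau = tau, n_doses = 8L)
  grid <- sort(unique(c(seq(0.25, 96, by = 0.25), 1:8 * tau - 1e-6)))
  sim <- pbpk_simulate(p, reg, 96, output_grid = grid)
  troughs <- sim_plasma_at(sim, 1:8 * tau - 1e-6)
  # trough ratios converge geometrically to 1
  ratios <- troughs[-1] / troughs[-8]
  expect_true(all(diff(ratios) < 1e-3))
  # accumulation of trough concentrations matches 1/(1 - exp(-lz*tau))
  single <- pbpk_simulate(p, dose_regimen(60, 1), 40,
                          output_grid = seq(0.25, 40, by = 0.25))
  lz <- sim_terminal_lambda(single, 20, 40)
  acc_pred <- 1 / (1 - exp(-lz * tau))
  acc_sim <- troughs[8] / troughs[1]
  expect_lt(abs(acc_sim - acc_pred) / acc_pred, 0.02)
})

test_that("mass balance and non-negativity hold across a parameter sweep", {
  set.seed(41)
  for (i in 1:8) {
    p <- make_toy_params(
      kp = runif(1, 0.1, 5), pstc = runif(1, 0.5, 50),
      vmax = runif(1, 0, 5e8), km = runif(1, 50, 5000),
      clsys = runif(1, 0, 10), fu = runif(1, 0.05, 1),
      bp = runif(1, 0.55, 1.2))
    ndoses <- sample(1:3, 1)
    reg <- dose_regimen(runif(1, 10, 300), runif(1, 0.5, 1.5),
                        dosing_interval_tau = if (ndoses > 1) 12 else NA,
                        n_doses = ndoses)
    t_end <- if (ndoses > 1) 12 * ndoses else 12
    sim <- pbpk_simulate(p, reg, t_end)
    dose_ng <- reg$dose_amount * reg$n_doses * 1e6
    expect_lt(sim$mass_balance_rel_err, 1e-3)
    expect_true(all(sim$amounts >= 0))
    expect_true(all(sim$plasma_conc >= 0))
  }
})

test_that("simulation rejects inadequate spans and bad grids", {
  p <- make_toy_params()
  expect_error(pbpk_simulate(p, dose_regimen(10, 1), t_end = 0.5),
               "t_end")
  expect_error(pbpk_simulate(p, dose_regimen(10, 1), 12,
                             output_grid = c(2, 1)), "output_grid")
  expect_error(pbpk_simulate(p, dose_regimen(10, 1), 12,
                             output_grid = c(1, 20)), "output_grid")
})

test_that("molar-to-mass conversion follows uM x g/mol = ng/ml", {
  expect_equal(convert_molar_to_mass_concentration(1, 1000), 1000)
  expect_equal(convert_molar_to_mass_concentration(0, 123.4), 0)
  expect_error(convert_molar_to_mass_concentration(1, -5), "mw")
  expect_error(convert_molar_to_mass_concentration(-1, 5), "c_molar")
})

test_that("simulation exports tidy delimited text", {
  p <- make_toy_params(clsys = 5)
  sim <- pbpk_simulate(p, dose_regimen(20, 1), 6)
  path <- tempfile(fileext = ".csv")
  write_simulation(sim, path)
  tab <- read.csv(path, check.names = FALSE)
  expect_identical(names(tab)[1:2], c("time_h", "plasma_ng_per_ml"))
  expect_true("liver_ev" %in% names(tab))
  expect_true("eliminated_ng" %in% names(tab))
  expect_equal(nrow(tab), length(sim$times))
  unlink(path)
})
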