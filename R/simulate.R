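#' Simulate the whole-body PBPK model
#'
#' Integrates the permeability-limited 14-tissue system (venous and arterial
#' blood pools, lung in series, remaining tissues in parallel) under
#' zero-order intravenous infusion input with saturable hepatic uptake
#' (OATP1B1) and biliary efflux (P-gp). Infusion on/off switches are handled
#' as exact integration breakpoints, never smoothed.
#'
#' @param params a [pbpk_parameter_set()].
#' @param regimen a [dose_regimen()].
#' @param t_end end of simulation, h; must cover the full regimen.
#' @param output_grid optional strictly increasing vector of output times in
#'   `[0, t_end]`; by default a grid dense around each infusion.
#' @param rtol,atol integrator relative tolerance and absolute tolerance
#'   (ng).
#' @return An object of class `pbpk_sim` with elements `times` (h),
#'   `plasma_conc` (ng/ml), `amounts` (ng; one column per blood pool and
#'   tissue sub-compartment), `eliminated` (ng), `infused` (cumulative ng),
#'   and `mass_balance_rel_err`.
#' @export
pbpk_simulate <- function(params, regimen, t_end, output_grid = NULL,
                          rtol = 1e-8, atol = 1e-3) {
  .chk(inherits(params, "pbpk_parameter_set"), "invalid parameter set")
  .chk(inherits(regimen, "dose_regimen"), "invalid regimen")
  last_start <- if (regimen$n_doses > 1L)
    (regimen$n_doses - 1L) * regimen$dosing_interval_tau else 0
  .chk(is.finite(t_end) && t_end >= last_start + regimen$infusion_duration,
       "t_end must cover the full dosing regimen")

  if (is.null(output_grid))
    output_grid <- default_output_grid(regimen, t_end)
  .chk(all(diff(output_grid) > 0) && min(output_grid) >= 0 &&
         max(output_grid) <= t_end,
       "output_grid must be strictly increasing within [0, t_end]")

  windows <- infusion_windows(regimen)
  rate_ng_h <- regimen$dose_amount * 1e6 / regimen$infusion_duration

  brk <- sort(unique(c(0, t_end, output_grid,
                       windows$start[windows$start <= t_end],
                       windows$end[windows$end <= t_end])))
  rate_of <- function(t) {
    # rate on segment starting at t (evaluate at midpoint-safe left edge)
    inw <- any(t >= windows$start - 1e-12 & t < windows$end - 1e-12)
    if (inw) rate_ng_h else 0
  }
  seg_rates <- vapply(brk[-length(brk)], rate_of, numeric(1))

  mod <- .cpp_model(params)
  states <- tryCatch(
    pbpk_integrate_cpp(mod, brk, seg_rates, rtol, atol, 500000L),
    error = function(e) stop(structure(
      class = c("saapk_simulation_error", "error", "condition"),
      list(message = conditionMessage(e), call = sys.call(-1)))))

  idx <- match(output_grid, brk)
  states <- states[idx, , drop = FALSE]
  states[states < 0 & states > -atol] <- 0  # integrator jitter only

  ntis <- length(params$tissues)
  nm <- vapply(params$tissues, `[[`, character(1), "tissue_name")
  colnames(states) <- c("venous", "arterial",
                        as.vector(rbind(paste0(nm, "_vas"),
                                        paste0(nm, "_ev"))),
                        "eliminated")

  bp <- params$compound$blood_to_plasma_ratio
  plasma <- states[, "venous"] / params$venous_volume / 1000 / bp

  infused <- vapply(output_grid, function(t) {
    sum(pmax(0, pmin(t, windows$end) - windows$start)) * rate_ng_h
  }, numeric(1))
  total <- rowSums(states)
  dose_ng <- regimen$dose_amount * regimen$n_doses * 1e6
  mb <- max(abs(total - infused)) / dose_ng

  structure(list(times = output_grid, plasma_conc = plasma,
                 amounts = states[, -ncol(states), drop = FALSE],
                 eliminated = states[, "eliminated"], infused = infused,
                 mass_balance_rel_err = mb,
                 params = params, regimen = regimen),
            class = "pbpk_sim")
}

infusion_windows <- function(regimen) {
  k <- seq_len(regimen$n_doses) - 1L
  tau <- if (regimen$n_doses > 1L) regimen$dosing_interval_tau else 0
  list(start = k * tau, end = k * tau + regimen$infusion_duration)
}

default_output_grid <- function(regimen, t_end) {
  w <- infusion_windows(regimen)
  pts <- c(0, t_end)
  for (i in seq_along(w$start)) {
    s <- w$start[i]; e <- min(w$end[i], t_end)
    pts <- c(pts, seq(s, e, length.out = 13),
             e + c(1 / 12, 1 / 6, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10, 12))
  }
  sort(unique(pts[pts >= 0 & pts <= t_end]))
}

.cpp_model <- function(params) {
  tis <- params$tissues
  V <- vapply(tis, `[[`, numeric(1), "volume")
  fv <- vapply(tis, `[[`, numeric(1), "vascular_fraction")
  upt <- .get_transporter(params, "OATP1B1")
  eff <- .get_transporter(params, "P-gp")
  iliv <- which(vapply(tis, `[[`, character(1), "tissue_name") == "liver")
  list(Vvas = V * fv, Vev = V * (1 - fv),
       Q = vapply(tis, `[[`, numeric(1), "blood_flow"),
       kp = vapply(tis, `[[`, numeric(1), "kp"),
       pstc = vapply(tis, `[[`, numeric(1), "pstc"),
       iliv = iliv - 1L,
       CO = params$cardiac_output,
       Vven = params$venous_volume, Vart = params$arterial_volume,
       fub = .fu_blood(params$compound),
       CLsys = params$systemic_linear_clearance,
       vmax_upt = if (is.null(upt)) 0 else upt$vmax,
       km_upt = if (is.null(upt)) 1 else upt$km * 1000,   # ng/ml -> ng/L
       vmax_eff = if (is.null(eff)) 0 else eff$vmax,
       km_eff = if (is.null(eff)) 1 else eff$km * 1000)
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf(paste0("PBPK simulation: %.4g mg x %d (%.0f-min infusion), ",
                     "%d output times to %.3g h\n"),
              x$regimen$dose_amount, x$regimen$n_doses,
              x$regimen$infusion_duration * 60, length(x$times),
              max(x$times)))
  cat(sprintf("  Cmax (plasma) %.4g ng/ml; mass-balance rel. err. %.2g\n",
              max(x$plasma_conc), x$mass_balance_rel_err))
  invisible(x)
}

#' @export
as.data.frame.pbpk_sim <- function(x, ...) {
  data.frame(time_h = x$times, plasma_ng_per_ml = x$plasma_conc,
             x$amounts, eliminated_ng = x$eliminated,
             check.names = FALSE)
}

#' Convert a molar concentration to a mass concentration
#'
#' Micromolar times molar mass in g/mol gives ng/ml directly
#' (1 umol/L x 1 g/mol = 1 ug/L = 1 ng/ml).
#'
#' @param c_molar concentration, uM (>= 0).
#' @param mw molar mass, g/mol (> 0).
#' @return Concentration in ng/ml.
#' @export
convert_molar_to_mass_concentration <- function(c_molar, mw) {
  .chk(all(is.finite(c_molar)) && all(c_molar >= 0),
       "c_molar must be >= 0")
  .chk(is.finite(mw) && mw > 0, "mw must be > 0")
  c_molar * mw
}

#' Interpolate simulated plasma concentrations at arbitrary times
#' @param sim a `pbpk_sim`.
#' @param times times (h) within the simulated span.
#' @return Concentrations, ng/ml.
#' @export
sim_plasma_at <- function(sim, times) {
  .chk(inherits(sim, "pbpk_sim"), "sim must be a pbpk_sim")
  .chk(min(times) >= min(sim$times) && max(times) <= max(sim$times),
       "times outside simulated span")
  stats::approx(sim$times, sim$plasma_conc, xout = times)$y
}
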