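#' Kinetic parameter set for single-cell Hoechst staining
#'
#' Bundles the mass-action rate constants governing one ensemble. The
#' Hoechst-DNA dissociation rate is fixed at `k_off = k1 * 1e-7` (the
#' reported dissociation constant of 1e-7), and is not a free parameter.
#'
#' @param k1 Hoechst-DNA association, 1/(uM min)
#' @param k2 DNA binding-site scaling, dimensionless
#' @param k3 membrane permeability, amol/(uM um^2 min)
#' @param k4 Hoechst-transporter association, 1/(uM min)
#' @param k5 transporter dissociation/efflux, 1/min
#' @param k6 absolute transporter expression, uM/T_Level
#' @param k7 cytosolic/nuclear transporter ratio, dimensionless
#' @param k8 expression slope (modes I/II) or Hill coefficient (mode III)
#' @param k9 Hill half-maximal level, T_Level (mode III only)
#' @return object of class `sp_params`
#' @export
sp_params <- function(k1, k2, k3, k4, k5, k6, k7, k8, k9 = NA_real_) {
  p <- list(k1 = k1, k_off = k1 * 1e-7, k2 = k2, k3 = k3, k4 = k4,
            k5 = k5, k6 = k6, k7 = k7, k8 = k8, k9 = k9)
  if (any(vapply(p[c(1, 3:9)], function(v) !is.na(v) && v <= 0, logical(1))))
    stop("kinetic parameters must be strictly positive")
  structure(p, class = "sp_params")
}

#' @export
print.sp_params <- function(x, ...) {
  cat("Kinetic parameter set:\n")
  v <- unlist(x)
  print(signif(v[!is.na(v)], 4))
  invisible(x)
}

#' Staining conditions
#'
#' @param H_e extracellular Hoechst concentration, uM (held constant; the
#'   extracellular bath is assumed infinitely large)
#' @param duration staining time, min
#' @param i_T transporter inhibition fraction: 0.99 with inhibitor (+FTC),
#'   0 without (-FTC)
#' @export
sp_conditions <- function(H_e = 5, duration = 90, i_T = 0) {
  stopifnot(H_e >= 0, duration > 0, i_T >= 0, i_T <= 1)
  structure(list(H_e = H_e, duration = duration, i_T = i_T),
            class = "sp_conditions")
}

#' Mass-action reaction rates of the staining system
#'
#' The eight elementary rates: plasma-membrane diffusion (r1), Hoechst-DNA
#' association/dissociation (r2, r3), cytosolic transporter binding and
#' efflux (r4, r5), nuclear-membrane diffusion (r6, in amol/min; positive
#' from nucleus to cytosol), and nuclear transporter binding and efflux
#' (r7, r8). Cytosolic efflux (r5) discharges dye to the extracellular sink;
#' nuclear efflux (r8) discharges into the cytosol.
#'
#' @param state named numeric: x1..x5 concentrations, uM
#' @param cell list with V_C, A_C, V_N, A_N and DNA_T, T_CA, T_NA (uM totals)
#' @param params an [sp_params]
#' @param cond an [sp_conditions]
#' @return named numeric r1..r8
#' @export
reaction_rates <- function(state, cell, params, cond) {
  x <- as.numeric(state[c("x1", "x2", "x3", "x4", "x5")])
  DNA <- cell$DNA_T - x[2]
  T_C <- cell$T_CA - x[3]
  T_N <- cell$T_NA - x[5]
  c(r1 = params$k3 * (cell$A_C / cell$V_C) * (cond$H_e - x[1]),
    r2 = params$k1 * x[4] * DNA,
    r3 = params$k_off * x[2],
    r4 = params$k4 * x[1] * T_C,
    r5 = params$k5 * x[3],
    r6 = params$k3 * cell$A_N * (x[4] - x[1]),
    r7 = params$k4 * x[4] * T_N,
    r8 = params$k5 * x[5])
}

# Constant totals for one cell at given inhibition.
cell_totals <- function(cell, params, cond) {
  act <- effective_transporter_activity(cell$T_CTA, cell$T_NTA,
                                        params$k6, cond$i_T)
  list(DNA_T = dna_binding_site_concentration(cell$DNA_L, params$k2, cell$V_N),
       T_CA = act$T_CA, T_NA = act$T_NA)
}

#' Simulate Hoechst staining of a single cell
#'
#' Integrates the five-state stiff ODE system (compiled right-hand side,
#' `lsoda`) from a dye-free initial state over the staining duration. The
#' conserved totals (DNA sites, cytosolic and nuclear transporter) enter
#' algebraically, so conservation is exact by construction. An integration
#' that exhausts the deterministic work cap (`maxsteps`), fails, or exceeds
#' the wall-clock timeout returns an aborted status rather than an error.
#'
#' @param cell one-row list/data.frame with morphology (V_C, A_C, V_N, A_N),
#'   DNA_L and relative transporter activities T_CTA, T_NTA
#' @param params an [sp_params]
#' @param cond an [sp_conditions]
#' @param timeout wall-clock limit in seconds (0 forces an abort)
#' @param times optional time grid for a trajectory; default endpoint only
#' @param rtol,atol integrator tolerances (uM for atol)
#' @param maxsteps deterministic work cap per output interval
#' @return list with `state` (named x1..x5 at t = duration, clipped to 0 for
#'   reporting), `totals` (DNA_T, T_CA, T_NA), `aborted`, and `trajectory`
#'   (matrix, if `times` given)
#' @export
simulate_cell_staining <- function(cell, params, cond = sp_conditions(),
                                   timeout = 10, times = NULL,
                                   rtol = 1e-6, atol = 1e-9,
                                   maxsteps = 10000) {
  tot <- cell_totals(cell, params, cond)
  empty <- setNames(rep(NA_real_, 5), paste0("x", 1:5))
  if (timeout <= 0)
    return(list(state = empty, totals = tot, aborted = TRUE,
                trajectory = NULL))
  p <- c(params$k1, params$k_off, params$k3, params$k4, params$k5,
         cell$A_C, cell$V_C, cell$A_N, cell$V_N,
         cond$H_e, tot$DNA_T, tot$T_CA, tot$T_NA)
  tms <- if (is.null(times)) c(0, cond$duration) else sort(unique(c(0, times)))
  out <- tryCatch({
    setTimeLimit(elapsed = timeout, transient = TRUE)
    on.exit(setTimeLimit(elapsed = Inf, transient = TRUE), add = TRUE)
    suppressWarnings(deSolve::lsoda(
      y = rep(0, 5), times = tms, func = "sp_derivs", parms = p,
      dllname = "sidepop", initfunc = "sp_initmod",
      rtol = rtol, atol = atol, maxsteps = maxsteps))
  }, error = function(e) NULL)
  ok <- !is.null(out) && nrow(out) == length(tms) &&
    all(is.finite(out[nrow(out), -1]))
  if (!ok)
    return(list(state = empty, totals = tot, aborted = TRUE,
                trajectory = NULL))
  final <- pmax(out[nrow(out), -1], 0) # clip tiny negative excursions
  names(final) <- paste0("x", 1:5)
  list(state = final, totals = tot, aborted = FALSE,
       trajectory = if (is.null(times)) NULL else {
         colnames(out) <- c("time", paste0("x", 1:5)); out
       })
}

#' Simulate Hoechst staining across a whole population
#'
#' Runs [simulate_cell_staining()] for every cell of an assigned population
#' under one inhibition condition. Aborted cells are flagged (never silently
#' dropped); if the total wall-clock budget is exhausted, the remaining cells
#' are flagged and the population is marked aborted, as is a population whose
#' cells all abort individually.
#'
#' @param pop population with assigned `T_CTA`/`T_NTA`
#'   ([assign_transporter_levels()])
#' @param params an [sp_params]
#' @param cond an [sp_conditions]
#' @param timeout_per_cell per-cell wall-clock limit, s
#' @param timeout_total population wall-clock budget, s
#' @param ... passed to [simulate_cell_staining()]
#' @return list with `states` (n x 5 matrix), `aborted` (logical per cell),
#'   `population_aborted`
#' @export
simulate_population_staining <- function(pop, params, cond = sp_conditions(),
                                         timeout_per_cell = 10,
                                         timeout_total = Inf, ...) {
  stopifnot(!is.null(pop$T_CTA), !is.null(pop$T_NTA))
  n <- nrow(pop)
  states <- matrix(NA_real_, n, 5,
                   dimnames = list(NULL, paste0("x", 1:5)))
  aborted <- rep(TRUE, n)
  t0 <- proc.time()[["elapsed"]]
  budget_hit <- FALSE
  for (i in seq_len(n)) {
    if (proc.time()[["elapsed"]] - t0 > timeout_total) {
      budget_hit <- TRUE
      break
    }
    res <- simulate_cell_staining(pop[i, ], params, cond,
                                  timeout = timeout_per_cell, ...)
    if (!res$aborted) {
      states[i, ] <- res$state
      aborted[i] <- FALSE
    }
  }
  list(states = states, aborted = aborted,
       population_aborted = budget_hit || all(aborted))
}
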