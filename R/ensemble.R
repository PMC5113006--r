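#' Log-range table of the kinetic parameter space
#'
#' One row per free parameter with the lower/upper bounds sampled by the
#' ensemble designs. In modes I/II the slope parameter k8 spans 1e-2..1e2 and
#' k9 is unused; in mode III k8 is a Hill coefficient on 1..10 and k9 is
#' drawn uniformly on (0, 1) in linear space.
#'
#' @param mode heterogeneity mode "I", "II" or "III"
#' @return data.frame with columns `param`, `lower`, `upper`, `log10`
#' @export
sp_param_ranges <- function(mode = c("I", "II", "III")) {
  mode <- match.arg(mode)
  r <- data.frame(
    param = c("k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8"),
    lower = c(1e-1, 1e-3, 1e-6, 1e-6, 1e-6, 1e-6, 1e-5,
              if (mode == "III") 1e0 else 1e-2),
    upper = c(1e5, 1e3, 1e4, 1e12, 1e12, 1e6, 1e5,
              if (mode == "III") 1e1 else 1e2),
    log10 = TRUE
  )
  if (mode == "III")
    r <- rbind(r, data.frame(param = "k9", lower = 0, upper = 1,
                             log10 = FALSE))
  r
}

#' Latin hypercube design of kinetic parameter sets
#'
#' Draws M parameter sets by stratified (Latin hypercube) sampling: each
#' log-scaled column is sampled uniformly in log10 space over its range with
#' exactly one draw per 1/M stratum, then antilogged; k9 (mode III) is
#' sampled uniformly in linear space. k_off is bound to k1 * 1e-7
#' throughout. Optional genetic refinement improves the maximin spread of
#' the unit design.
#'
#' @param M number of parameter sets
#' @param mode heterogeneity mode (fixes the k8/k9 interpretation and range)
#' @param seed design seed
#' @param ranges range table, default [sp_param_ranges()]
#' @param refine_iterations generations of lhs::geneticLHS refinement
#'   (0 = plain random Latin hypercube)
#' @return object of class `sp_design`: list of [sp_params()] with the unit
#'   design and ranges attached
#' @export
lhcs_kinetic_parameters <- function(M, mode = c("I", "II", "III"), seed = 1,
                                    ranges = NULL, refine_iterations = 0) {
  mode <- match.arg(mode)
  if (is.null(ranges)) ranges <- sp_param_ranges(mode)
  stopifnot(M >= 1, all(ranges$upper > ranges$lower))
  Q <- nrow(ranges)
  unit <- with_seed(substream_seed(seed, "parameter-design"), {
    if (refine_iterations > 0)
      lhs::geneticLHS(M, Q, pop = 20, gen = refine_iterations)
    else lhs::randomLHS(M, Q)
  })
  colnames(unit) <- ranges$param
  vals <- unit
  for (q in seq_len(Q)) {
    if (ranges$log10[q]) {
      lo <- log10(ranges$lower[q])
      vals[, q] <- 10^(lo + unit[, q] * (log10(ranges$upper[q]) - lo))
    } else {
      vals[, q] <- ranges$lower[q] +
        unit[, q] * (ranges$upper[q] - ranges$lower[q])
    }
  }
  sets <- lapply(seq_len(M), function(m) {
    v <- as.list(vals[m, ])
    sp_params(k1 = v$k1, k2 = v$k2, k3 = v$k3, k4 = v$k4, k5 = v$k5,
              k6 = v$k6, k7 = v$k7, k8 = v$k8,
              k9 = if (mode == "III") v$k9 else NA_real_)
  })
  structure(list(sets = sets, unit_design = unit, values = vals,
                 ranges = ranges, mode = mode, seed = seed),
            class = "sp_design")
}

#' @export
print.sp_design <- function(x, ...) {
  cat(sprintf("LHCS kinetic parameter design: M = %d sets, mode %s, %d parameters\n",
              length(x$sets), x$mode, ncol(x$unit_design)))
  invisible(x)
}

#' NRMSE goodness-of-fit score
#'
#' Normalized root-mean-square-error fit of a simulated vector to a
#' reference: 1 - ||sim - ref|| / ||ref - mean(ref)||. A perfect fit scores
#' 1; fitting no better than the reference mean scores 0; arbitrarily poor
#' fits go to negative infinity.
#'
#' @param sim,ref numeric vectors of equal length (e.g. the 4 %SP values)
#' @return score <= 1
#' @export
nrmse_fit_score <- function(sim, ref) {
  stopifnot(length(sim) == length(ref))
  denom <- sqrt(sum((ref - mean(ref))^2))
  if (denom == 0) stop("undefined normalization: constant reference vector")
  1 - sqrt(sum((sim - ref)^2)) / denom
}

#' Per-cell side-population response distribution
#'
#' Because cells are indexed, the same cell's staining can be compared under
#' inhibition and no inhibition: -dH_proj = H_proj(+FTC) - H_proj(-FTC), so a
#' larger value means a greater staining decrease without inhibitor (a
#' stronger single-cell SP response).
#'
#' @param scored an `sp_scored` pair from [hoechst_scores()]
#' @return object of class `sp_response`: numeric -dH_proj per cell plus the
#'   shape metrics of [distribution_shape()]
#' @export
single_cell_responses <- function(scored) {
  stopifnot(inherits(scored, "sp_scored"))
  p <- scored$plus; m <- scored$minus
  common <- intersect(p$cell_id, m$cell_id)
  if (!setequal(p$cell_id, m$cell_id))
    warning("conditions share only ", length(common), " cell ids")
  if (length(common) == 0) stop("pairing error: no shared cell ids")
  v <- p$H_proj[match(common, p$cell_id)] -
    m$H_proj[match(common, m$cell_id)]
  shape <- if (length(v) >= 3 && sd(v) > 0) distribution_shape(v) else
    list(skewness = NA_real_, kurtosis = NA_real_, BC = NA_real_)
  structure(list(values = setNames(v, common), skewness = shape$skewness,
                 kurtosis = shape$kurtosis, BC = shape$BC),
            class = "sp_response")
}

#' Moment-based shape metrics and bimodality coefficient
#'
#' Population (biased) standardized moments: skewness = m3/m2^(3/2),
#' kurtosis = m4/m2^2 (non-excess), and the bimodality coefficient
#' BC = (skewness^2 + 1)/kurtosis. BC lies in (0, 1]: 1 for an exactly
#' two-valued distribution, ~1/3 for a normal, ~5/9 for a uniform.
#'
#' @param values numeric sample, >= 3 values with nonzero variance
#' @return list with `skewness`, `kurtosis`, `BC`
#' @export
distribution_shape <- function(values) {
  stopifnot(length(values) >= 3)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("degenerate distribution: zero variance")
  skew <- mean((values - m)^3) / m2^1.5
  kurt <- mean((values - m)^4) / m2^2
  list(skewness = skew, kurtosis = kurt, BC = (skew^2 + 1) / kurt)
}

#' Classify a single-cell SP response distribution
#'
#' Subpopulation responses (a distinct strongly-responding minority) show
#' high skewness and a high bimodality coefficient; Full responses (the whole
#' population shifts together) show low values of both. The continuous
#' (skewness, BC) coordinates are the primary output; the label thresholds
#' are configurable conventions.
#'
#' @param dist an `sp_response` (or list with `skewness` and `BC`)
#' @param thresholds list with `skew_hi`, `bc_hi`, `skew_lo`, `bc_lo`
#' @return list with `label` ("Full", "Subpopulation" or "Intermediate"),
#'   `skewness`, `BC`
#' @export
classify_response <- function(dist,
                              thresholds = list(skew_hi = 1, bc_hi = 0.555,
                                                skew_lo = 0.5, bc_lo = 0.45)) {
  s <- dist$skewness; bc <- dist$BC
  label <- if (is.na(s) || is.na(bc)) "Intermediate"
  else if (s > thresholds$skew_hi && bc > thresholds$bc_hi) "Subpopulation"
  else if (s < thresholds$skew_lo && bc < thresholds$bc_lo) "Full"
  else "Intermediate"
  list(label = label, skewness = s, BC = bc)
}

#' @export
print.sp_response <- function(x, ...) {
  cl <- classify_response(x)
  cat(sprintf("Single-cell SP response: %d cells, skewness %.3f, kurtosis %.3f, BC %.3f (%s)\n",
              length(x$values), x$skewness, x$kurtosis, x$BC, cl$label))
  invisible(x)
}

#' Run one ensemble: a kinetic parameter set across all assay conditions
#'
#' Simulates the same base population under the 4 transporter conditions,
#' each with (+FTC, i_T = 0.99) and without (-FTC, i_T = 0) inhibition —
#' 8 population simulations — then applies the full analysis pipeline per
#' condition pair: Hoechst Scores, projection-gated %SP, mean score shifts,
#' smoothed densities, delta-FTC, and delta-SP against the control
#' (condition 1, the highest-transporter/untreated sample).
#'
#' @param params an [sp_params()] set
#' @param base_pop an `sp_population` (shared across all 8 runs; identical
#'   cell indices)
#' @param mode heterogeneity mode for [assign_transporter_levels()]
#' @param ref an [sp_reference] (expression PDFs, geometric means, reference
#'   surfaces and %SP for the selection comparisons)
#' @param cond staining conditions (the +FTC run overrides `i_T` to
#'   `i_T_inhibited`)
#' @param i_T_inhibited inhibition fraction of the +FTC condition
#' @param grid common score grid for all surfaces
#' @param lambda density smoothing penalty
#' @param timeout_per_cell,timeout_total abort budgets per cell / per
#'   population, seconds
#' @param keep_events keep the per-condition scored event tables?
#' @return object of class `sp_ensemble` with per-condition `%SP`, mean
#'   score shifts, surfaces, single-cell responses, abort accounting and
#'   (via [evaluate_selection_criteria()]) selection results
#' @export
run_ensemble <- function(params, base_pop, mode = "III", ref,
                         cond = sp_conditions(), i_T_inhibited = 0.99,
                         grid = sp_score_grid(), lambda = 10,
                         timeout_per_cell = 10, timeout_total = Inf,
                         keep_events = FALSE) {
  seed <- attr(base_pop, "seed")
  out <- list(mode = mode, params = params, n_cells = nrow(base_pop),
              conditions = vector("list", 4), aborted = FALSE,
              abort_counts = integer(4))
  for (ci in 1:4) {
    pop <- assign_transporter_levels(base_pop, mode, ci, params, ref, seed)
    sims <- lapply(c(i_T_inhibited, 0), function(it) {
      simulate_population_staining(
        pop, params,
        sp_conditions(cond$H_e, cond$duration, i_T = it),
        timeout_per_cell = timeout_per_cell, timeout_total = timeout_total)
    })
    if (sims[[1]]$population_aborted || sims[[2]]$population_aborted) {
      out$aborted <- TRUE
      out$abort_reason <- sprintf("condition %d population aborted", ci)
      return(structure(out, class = "sp_ensemble"))
    }
    ev_p <- events_from_simulation(pop, sims[[1]], "+FTC")
    ev_m <- events_from_simulation(pop, sims[[2]], "-FTC")
    out$abort_counts[ci] <- sum(sims[[1]]$aborted | sims[[2]]$aborted)
    sc <- tryCatch(hoechst_scores(ev_p, ev_m), error = function(e) NULL)
    if (is.null(sc)) {
      out$aborted <- TRUE
      out$abort_reason <- sprintf("condition %d degenerate signals", ci)
      return(structure(out, class = "sp_ensemble"))
    }
    pdf_p <- score_pdf2d(sc$plus, grid, lambda)
    pdf_m <- score_pdf2d(sc$minus, grid, lambda)
    out$conditions[[ci]] <- list(
      percent_sp = percent_sp(sc),
      delta_hrs_mean = mean(sc$minus$HRS) - mean(sc$plus$HRS),
      delta_hbs_mean = mean(sc$minus$HBS) - mean(sc$plus$HBS),
      pdf_plus = pdf_p, pdf_minus = pdf_m,
      dftc = delta_ftc(pdf_m, pdf_p),
      overlap = overlap_coefficient(pdf_p, pdf_m),
      response = single_cell_responses(sc),
      scored = if (keep_events) sc else NULL
    )
  }
  for (ci in 1:4)
    out$conditions[[ci]]$dsp <-
      delta_sp(out$conditions[[ci]]$dftc, out$conditions[[1]]$dftc)
  out$percent_sp <- vapply(out$conditions, `[[`, numeric(1), "percent_sp")
  out$delta_hrs_mean <- vapply(out$conditions, `[[`, numeric(1),
                               "delta_hrs_mean")
  out$delta_hbs_mean <- vapply(out$conditions, `[[`, numeric(1),
                               "delta_hbs_mean")
  structure(out, class = "sp_ensemble")
}

#' @export
print.sp_ensemble <- function(x, ...) {
  if (x$aborted) {
    cat("Aborted ensemble:", x$abort_reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("SP ensemble (mode %s, %d cells/condition):\n",
              x$mode, x$n_cells))
  cat("  %SP by condition:      ",
      paste(sprintf("%.2f", x$percent_sp), collapse = "  "), "\n")
  cat("  mean dHRS by condition:",
      paste(sprintf("%+.3f", x$delta_hrs_mean), collapse = "  "), "\n")
  invisible(x)
}

#' Qualitative SP-response selection criteria
#'
#' An ensemble is accepted as exhibiting a side-population response only if
#' it meets every criterion: (1) the two highest transporter conditions show
#' negative mean Red and Blue score shifts (overall staining decrease);
#' (2) the +/-FTC densities overlap by at least `min_overlap` (the whole
#' population must not simply shift); (3) the simulated mean score shifts
#' correlate positively with the reference shifts across the 4 conditions
#' (both channels); (4) the mean zero-lag cross-correlation against the
#' reference surfaces is positive within each surface category (PDF+, PDF-,
#' delta-FTC, and delta-SP over conditions 2-4); (5) the control %SP is at
#' least `min_control_sp` and exceeds the lowest-transporter condition's by
#' at least `min_differential_sp`. An undefined correlation (constant
#' surface) counts as a failure of its criterion.
#'
#' @param res a completed (non-aborted) `sp_ensemble`
#' @param ref an [sp_reference] carrying `exp_delta_hrs`, `exp_delta_hbs`
#'   and per-condition reference `surfaces`
#' @param thresholds list: `min_overlap` (default 0.25), `min_control_sp`
#'   (5), `min_differential_sp` (2.5), `overlap_all_conditions` (TRUE:
#'   apply the overlap floor to every condition rather than the two highest)
#' @return list with `pass` and a named logical `criteria` plus `reasons`
#' @export
evaluate_selection_criteria <- function(res, ref,
                                        thresholds = sp_selection_thresholds()) {
  stopifnot(inherits(res, "sp_ensemble"))
  if (res$aborted) stop("cannot apply selection criteria to an aborted ensemble")
  if (is.null(ref$surfaces) || is.null(ref$exp_delta_hrs))
    stop("missing reference data for selection")
  th <- thresholds
  crit <- logical(5)
  reasons <- character(0)

  hi <- 1:2 # conditions ordered by decreasing transporter level
  crit[1] <- all(res$delta_hrs_mean[hi] < 0) && all(res$delta_hbs_mean[hi] < 0)
  if (!crit[1]) reasons <- c(reasons,
    "two highest transporter conditions must decrease mean staining")

  ov <- vapply(res$conditions, `[[`, numeric(1), "overlap")
  which_ov <- if (isTRUE(th$overlap_all_conditions)) 1:4 else hi
  crit[2] <- all(ov[which_ov] >= th$min_overlap)
  if (!crit[2]) reasons <- c(reasons, sprintf(
    "+/-FTC density overlap below %.2f", th$min_overlap))

  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }
  c_hrs <- safe_cor(res$delta_hrs_mean, ref$exp_delta_hrs)
  c_hbs <- safe_cor(res$delta_hbs_mean, ref$exp_delta_hbs)
  crit[3] <- !is.na(c_hrs) && !is.na(c_hbs) && c_hrs > 0 && c_hbs > 0
  if (!crit[3]) reasons <- c(reasons,
    "mean score shifts must correlate positively with the reference")

  ncc <- function(sim, refd) {
    tryCatch(normalized_cross_correlation(sim, refd),
             error = function(e) NA_real_)
  }
  cats <- list(
    pdf_plus = vapply(1:4, function(ci) ncc(res$conditions[[ci]]$pdf_plus,
                                            ref$surfaces[[ci]]$pdf_plus),
                      numeric(1)),
    pdf_minus = vapply(1:4, function(ci) ncc(res$conditions[[ci]]$pdf_minus,
                                             ref$surfaces[[ci]]$pdf_minus),
                       numeric(1)),
    dftc = vapply(1:4, function(ci) ncc(res$conditions[[ci]]$dftc,
                                        ref$surfaces[[ci]]$dftc),
                  numeric(1)),
    dsp = vapply(2:4, function(ci) ncc(res$conditions[[ci]]$dsp,
                                       ref$surfaces[[ci]]$dsp),
                 numeric(1))
  )
  cat_means <- vapply(cats, function(v) mean(v), numeric(1))
  crit[4] <- !anyNA(cat_means) && all(cat_means > 0)
  if (!crit[4]) reasons <- c(reasons,
    "mean surface cross-correlation with the reference must be positive in every category")

  crit[5] <- res$percent_sp[1] >= th$min_control_sp &&
    (res$percent_sp[1] - res$percent_sp[4]) >= th$min_differential_sp
  if (!crit[5]) reasons <- c(reasons, sprintf(
    "control %%SP >= %.1f and differential %%SP >= %.1f required",
    th$min_control_sp, th$min_differential_sp))

  names(crit) <- c("staining_decrease", "overlap", "shift_correlation",
                   "surface_correlation", "sp_size")
  list(pass = all(crit), criteria = crit, reasons = reasons,
       cross_correlations = cat_means)
}

#' Selection threshold configuration
#'
#' All tunable selection constants in one place, at the assay defaults:
#' 25% minimum density overlap, 5% minimum control SP, 2.5% minimum
#' control-vs-lowest differential SP, 1st-percentile projection gate, and
#' 0.99 inhibition fraction.
#'
#' @param min_overlap,min_control_sp,min_differential_sp,percentile,i_T_inhibited
#'   see description
#' @param overlap_all_conditions apply the overlap floor to all 4 conditions
#' @export
sp_selection_thresholds <- function(min_overlap = 0.25, min_control_sp = 5,
                                    min_differential_sp = 2.5,
                                    percentile = 1, i_T_inhibited = 0.99,
                                    overlap_all_conditions = TRUE) {
  list(min_overlap = min_overlap, min_control_sp = min_control_sp,
       min_differential_sp = min_differential_sp, percentile = percentile,
       i_T_inhibited = i_T_inhibited,
       overlap_all_conditions = overlap_all_conditions)
}

#' Ensemble screen of kinetic parameter space
#'
#' Draws M kinetic parameter sets by Latin hypercube design, runs each as a
#' full ensemble (4 transporter conditions x +/-FTC over one shared base
#' population), applies the selection criteria against the reference, and
#' scores accepted ensembles by NRMSE fit of their %SP vector. Aborted
#' ensembles are reported separately and never enter the pass/fail
#' denominator.
#'
#' @param ref an [sp_reference]
#' @param M number of parameter sets
#' @param N cells per population
#' @param mode heterogeneity mode
#' @param seed master seed (population, design and any noise substreams)
#' @param thresholds [sp_selection_thresholds()]
#' @param timeout_per_cell,timeout_total abort budgets, seconds
#' @param verbose print progress every 10 ensembles
#' @param ... passed to [run_ensemble()]
#' @return object of class `sp_screen`: per-set results table, abort/pass
#'   accounting, and the full `sp_ensemble` list
#' @export
sp_screen <- function(ref, M = 100, N = 100, mode = "III", seed = 1,
                      thresholds = sp_selection_thresholds(),
                      timeout_per_cell = 2, timeout_total = 60,
                      verbose = FALSE, ...) {
  design <- lhcs_kinetic_parameters(M, mode, seed)
  base_pop <- sp_population(ref, N, seed)
  results <- vector("list", M)
  tab <- data.frame(set = seq_len(M), aborted = FALSE, pass = NA,
                    fit = NA_real_, control_sp = NA_real_)
  for (m in seq_len(M)) {
    ens <- run_ensemble(design$sets[[m]], base_pop, mode, ref,
                        i_T_inhibited = thresholds$i_T_inhibited,
                        timeout_per_cell = timeout_per_cell,
                        timeout_total = timeout_total, ...)
    if (ens$aborted) {
      tab$aborted[m] <- TRUE
    } else {
      sel <- evaluate_selection_criteria(ens, ref, thresholds)
      ens$selection <- sel
      tab$pass[m] <- sel$pass
      tab$control_sp[m] <- ens$percent_sp[1]
      tab$fit[m] <- nrmse_fit_score(ens$percent_sp, ref$exp_sp)
    }
    results[[m]] <- ens
    if (verbose && m %% 10 == 0)
      message(sprintf("screened %d/%d parameter sets", m, M))
  }
  non_aborted <- sum(!tab$aborted)
  structure(list(
    table = tab, ensembles = results, design = design, mode = mode,
    N = N, seed = seed,
    n_aborted = M - non_aborted,
    n_pass = sum(tab$pass, na.rm = TRUE),
    fail_fraction = if (non_aborted > 0)
      sum(!tab$pass, na.rm = TRUE) / non_aborted else NA_real_
  ), class = "sp_screen")
}

#' @export
print.sp_screen <- function(x, ...) {
  M <- nrow(x$table)
  cat(sprintf("LHCS side-population screen: M = %d parameter sets, mode %s, N = %d cells\n",
              M, x$mode, x$N))
  cat(sprintf("  aborted: %d | passing: %d | failing: %d (%.1f%% of non-aborted)\n",
              x$n_aborted, x$n_pass, M - x$n_aborted - x$n_pass,
              100 * x$fail_fraction))
  if (x$n_pass > 0) {
    best <- x$table[which(x$table$pass), ]
    cat(sprintf("  best fit score among passing sets: %.4f\n",
                max(best$fit)))
  }
  invisible(x)
}

#' @export
summary.sp_screen <- function(object, ...) {
  tab <- object$table
  out <- list(
    M = nrow(tab), n_aborted = object$n_aborted, n_pass = object$n_pass,
    fail_percent = 100 * object$fail_fraction,
    fit_passing = tab$fit[which(tab$pass)],
    control_sp = tab$control_sp
  )
  class(out) <- "summary.sp_screen"
  out
}

#' @export
print.summary.sp_screen <- function(x, ...) {
  cat(sprintf("Screen of %d parameter sets: %d aborted, %d passing (%.1f%% of non-aborted fail)\n",
              x$M, x$n_aborted, x$n_pass, x$fail_percent))
  if (length(x$fit_passing))
    cat("  fit scores of passing sets:",
        paste(sprintf("%.3f", sort(x$fit_passing, decreasing = TRUE)),
              collapse = ", "), "\n")
  invisible(x)
}
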