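test_that("kinetic parameter design stratifies every range in log space", {
  des <- lhcs_kinetic_parameters(100, mode = "III", seed = 5)
  expect_length(des$sets, 100)
  # one draw per 1/M stratum per column of the unit design
  for (q in seq_len(ncol(des$unit_design)))
    expect_equal(sort(findInterval(des$unit_design[, q],
                                   seq(0, 1, by = 0.01),
                                   rightmost.closed = TRUE)), 1:100)
  ranges <- sp_param_ranges("III")
  for (q in seq_len(nrow(ranges))) {
    v <- des$values[, ranges$param[q]]
    expect_true(all(v >= ranges$lower[q] & v <= ranges$upper[q]))
  }
  # k3 lies within its published screen range
  expect_true(all(des$values[, "k3"] >= 1e-6 & des$values[, "k3"] <= 1e4))
  # k_off bound, k9 linear-uniform
  expect_equal(des$sets[[1]]$k_off, des$sets[[1]]$k1 * 1e-7)
  expect_gt(stats::ks.test(des$values[, "k9"], "punif")$p.value, 0.01)
  des2 <- lhcs_kinetic_parameters(100, mode = "III", seed = 5)
  expect_identical(des$values, des2$values)
  # modes I/II sample the k8 slope range and omit k9
  des12 <- lhcs_kinetic_parameters(50, mode = "I", seed = 5)
  expect_false("k9" %in% colnames(des12$values))
  expect_true(all(des12$values[, "k8"] >= 1e-2 & des12$values[, "k8"] <= 1e2))
})

test_that("NRMSE fit score has the documented fixed points", {
  ref <- c(20, 3.6, 0.7, 0.12)
  expect_identical(nrmse_fit_score(ref, ref), 1)
  expect_equal(nrmse_fit_score(rep(mean(ref), 4), ref), 0)
  # sim = 2*ref - mean(ref) has residual exactly equal to the reference
  # spread, so the score is 0; scaling the residual further goes negative
  expect_equal(nrmse_fit_score(2 * ref - mean(ref), ref), 0,
               tolerance = 1e-12)
  expect_equal(nrmse_fit_score(4 * ref - 3 * mean(ref), ref), -2,
               tolerance = 1e-12)
  expect_lt(nrmse_fit_score(c(100, 50, 25, 10), ref), 0)
  expect_error(nrmse_fit_score(ref, rep(1, 4)), "constant reference")
})

test_that("single-cell responses difference the paired projections", {
  sc <- structure(list(
    plus = data.frame(cell_id = 1:5, H_proj = c(1, 2, 3, 4, 5)),
    minus = data.frame(cell_id = 5:1, H_proj = c(5, 4, 3, 2, 1))),
    class = "sp_scored")
  resp <- single_cell_responses(sc)
  expect_true(all(resp$values == 0)) # identical per-cell projections
  sc$minus$H_proj <- sc$minus$H_proj - 2 / sqrt(2) * sqrt(2)
  resp2 <- single_cell_responses(sc)
  expect_equal(unname(resp2$values), rep(2, 5))
  expect_equal(mean(resp2$values),
               mean(sc$plus$H_proj) - mean(sc$minus$H_proj))
  bad <- sc; bad$minus$cell_id <- 11:15
  expect_error(suppressWarnings(single_cell_responses(bad)),
               "pairing error")
})

test_that("moment shape metrics give the analytic BC landmarks", {
  two_point <- rep(c(0, 1), each = 500)
  s <- distribution_shape(two_point)
  expect_equal(s$skewness, 0)
  expect_equal(s$kurtosis, 1)
  expect_identical(s$BC, 1) # exactly two-valued distribution
  set.seed(6)
  gauss <- distribution_shape(rnorm(2e5))
  expect_equal(gauss$BC, 1 / 3, tolerance = 0.02)
  unif <- distribution_shape(runif(2e5))
  expect_equal(unif$BC, (0 + 1) / (9 / 5), tolerance = 0.02)
  expect_equal(unif$BC, 0.5556, tolerance = 0.02)
  expect_error(distribution_shape(rep(3, 10)), "zero variance")
  # Pearson inequality keeps BC in (0, 1] for any two-valued+ sample
  for (i in 1:20) {
    v <- sample(c(0, 1, 5), 50, replace = TRUE)
    if (sd(v) == 0) next
    bc <- distribution_shape(v)$BC
    expect_gt(bc, 0); expect_lte(bc, 1 + 1e-12)
  }
})

test_that("response classification follows the (skewness, BC) map", {
  set.seed(8)
  sub <- c(rnorm(900, 0, 0.05), rnorm(100, 5, 0.05))
  cl_sub <- classify_response(distribution_shape(sub))
  expect_identical(cl_sub$label, "Subpopulation")
  cl_full <- classify_response(distribution_shape(rnorm(1000)))
  expect_identical(cl_full$label, "Full")
  extreme <- list(skew_hi = 1e6, bc_hi = 1, skew_lo = -1e6, bc_lo = 0)
  expect_identical(classify_response(cl_sub, extreme)$label, "Intermediate")
})

test_that("a transporter-free ensemble shows no side population", {
  ref <- test_ref()
  pop <- test_pop(40)
  # k6 minute: transporter activity effectively absent, so +/-FTC coincide
  p <- sp_params(k1 = 10, k2 = 1, k3 = 0.05, k4 = 1, k5 = 1, k6 = 1e-12,
                 k7 = 1, k8 = 6, k9 = 0.65)
  ens <- suppressWarnings(run_ensemble(p, pop, "III", ref))
  expect_false(ens$aborted)
  expect_equal(ens$delta_hrs_mean, rep(0, 4), tolerance = 1e-6)
  # at N = 40 the 1st-percentile gate sits above exactly one event (2.5%)
  expect_equal(ens$percent_sp, rep(2.5, 4), tolerance = 1e-9)
  sel <- evaluate_selection_criteria(ens, ref)
  expect_false(sel$pass)
  expect_false(sel$criteria[["staining_decrease"]]) # zero shift is not negative
  # every condition produced a full-length response vector
  for (co in ens$conditions) expect_length(co$response$values, 40)
})

test_that("a full population shift fails the overlap criterion", {
  ref <- test_ref()
  pop <- test_pop(40)
  # uniform strong efflux: k9 far below the expression range makes every
  # cell respond, shifting the entire -FTC population
  p <- sp_params(k1 = 10, k2 = 1, k3 = 0.05, k4 = 1e4, k5 = 1e3,
                 k6 = 500, k7 = 1, k8 = 2, k9 = 0.01)
  ens <- suppressWarnings(run_ensemble(p, pop, "III", ref))
  expect_false(ens$aborted)
  ov <- vapply(ens$conditions, `[[`, numeric(1), "overlap")
  expect_lt(min(ov), 0.25)
  sel <- evaluate_selection_criteria(ens, ref)
  expect_false(sel$criteria[["overlap"]])
})

test_that("ground-truth recovery: the generating set passes with fit 1", {
  p_star <- sp_demo_params()
  gt <- suppressWarnings(generate_ground_truth_reference(
    p_star, list(N = 60, mode = "III"), seed = 7))
  pop <- sp_population(gt, 60, seed = 7)
  ens <- suppressWarnings(run_ensemble(p_star, pop, "III", gt))
  expect_false(ens$aborted)
  sel <- evaluate_selection_criteria(ens, gt)
  expect_true(sel$pass)
  expect_identical(nrmse_fit_score(ens$percent_sp, gt$exp_sp), 1)
  expect_identical(ens$percent_sp, gt$exp_sp) # exact self-consistency
})

test_that("neighbours of the generating set outscore random draws", {
  p_star <- sp_demo_params()
  gt <- suppressWarnings(generate_ground_truth_reference(
    p_star, list(N = 60, mode = "III"), seed = 7))
  pop <- sp_population(gt, 60, seed = 7)
  jitter_fit <- vapply(1:5, function(i) {
    set.seed(100 + i)
    f <- 10^rnorm(9, 0, 0.05)
    p <- sp_params(p_star$k1 * f[1], p_star$k2 * f[2], p_star$k3 * f[3],
                   p_star$k4 * f[4], p_star$k5 * f[5], p_star$k6 * f[6],
                   p_star$k7 * f[7], p_star$k8 * f[8],
                   min(p_star$k9 * f[9], 0.999))
    ens <- suppressWarnings(run_ensemble(p, pop, "III", gt))
    nrmse_fit_score(ens$percent_sp, gt$exp_sp)
  }, numeric(1))
  rand_fit <- vapply(1:5, function(i) {
    des <- lhcs_kinetic_parameters(5, "III", seed = 200 + i)
    ens <- suppressWarnings(run_ensemble(des$sets[[i]], pop, "III", gt,
                                         timeout_per_cell = 2))
    if (ens$aborted) -1e3 else nrmse_fit_score(ens$percent_sp, gt$exp_sp)
  }, numeric(1))
  expect_gt(mean(jitter_fit), mean(rand_fit))
})

test_that("aborted ensembles are excluded from selection denominators", {
  ref <- test_ref()
  scr <- suppressWarnings(sp_screen(ref, M = 4, N = 10, seed = 3,
                                    timeout_per_cell = 0)) # force aborts
  expect_equal(scr$n_aborted, 4)
  expect_true(is.na(scr$fail_fraction))
  expect_true(all(is.na(scr$table$pass)))
})
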