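test_that("parameter constructor binds k_off to k1 and validates signs", {
  p <- sp_params(k1 = 100, k2 = 1, k3 = 1, k4 = 1, k5 = 1, k6 = 1,
                 k7 = 1, k8 = 1)
  expect_identical(p$k_off, 100 * 1e-7)
  expect_error(sp_params(k1 = -1, k2 = 1, k3 = 1, k4 = 1, k5 = 1,
                         k6 = 1, k7 = 1, k8 = 1), "positive")
})

test_that("reaction rates vanish at their equilibria and follow mass action", {
  cell <- test_cell()
  p <- sp_demo_params()
  cond <- sp_conditions()
  tot <- list(DNA_T = dna_binding_site_concentration(1, p$k2, cell$V_N),
              T_CA = p$k6 * cell$T_CTA, T_NA = p$k6 * cell$T_NTA)
  cellt <- c(cell, tot)
  st <- c(x1 = 5, x2 = 0, x3 = 0, x4 = 5, x5 = 0)
  r <- reaction_rates(st, cellt, p, cond)
  expect_equal(r[["r1"]], 0) # plasma-membrane diffusion equilibrium
  expect_equal(r[["r6"]], 0) # nuclear diffusion equilibrium

  # hand-computed bimolecular rate: r2 = k1 * x4 * DNA with DNA = 2 uM
  p10 <- sp_params(k1 = 10, k2 = 1, k3 = 1, k4 = 1, k5 = 1, k6 = 1,
                   k7 = 1, k8 = 1)
  cellt2 <- c(cell, list(DNA_T = 2, T_CA = 0, T_NA = 0))
  r2 <- reaction_rates(c(x1 = 0, x2 = 0, x3 = 0, x4 = 1, x5 = 0),
                       cellt2, p10, cond)
  expect_equal(r2[["r2"]], 20)
  expect_true(all(r2[c("r2", "r3", "r4", "r5", "r7", "r8")] >= 0))
})

test_that("initial state is dye-free and a diffusion-only cell equilibrates at H_e", {
  cell <- test_cell(DNA_L = 0, T_CTA = 0, T_NTA = 0)
  p <- sp_params(k1 = 10, k2 = 1, k3 = 1, k4 = 1, k5 = 1, k6 = 1,
                 k7 = 1, k8 = 1)
  res <- simulate_cell_staining(cell, p, sp_conditions(H_e = 5, duration = 600),
                                times = c(0, 600))
  expect_false(res$aborted)
  expect_equal(unname(res$trajectory[1, -1]), rep(0, 5)) # no dye at t = 0
  expect_equal(res$state[["x1"]], 5, tolerance = 1e-5)
  expect_equal(res$state[["x4"]], 5, tolerance = 1e-5)
  expect_equal(res$state[["x2"]], 0)
  expect_equal(res$state[["x3"]], 0)
})

test_that("conserved totals bound every state along dense trajectories", {
  cell <- test_cell()
  p <- sp_demo_params()
  res <- simulate_cell_staining(cell, p, sp_conditions(),
                                times = seq(0, 90, by = 1))
  expect_false(res$aborted)
  tr <- res$trajectory
  DNA_T <- res$totals$DNA_T
  expect_true(all(tr[, "x2"] >= -1e-9 & tr[, "x2"] <= DNA_T + 1e-9))
  expect_true(all(tr[, "x3"] >= -1e-9 & tr[, "x3"] <= res$totals$T_CA + 1e-9))
  expect_true(all(tr[, "x5"] >= -1e-9 & tr[, "x5"] <= res$totals$T_NA + 1e-9))
  expect_true(all(tr[, -1] > -1e-9))
})

test_that("amount balance d/dt[V_C(x1+x3) + V_N(x2+x4+x5)] = V_C(r1 - r5)", {
  cell <- test_cell()
  p <- sp_demo_params()
  cond <- sp_conditions()
  cellt <- c(cell, cell_totals <- list(
    DNA_T = dna_binding_site_concentration(1, p$k2, cell$V_N),
    T_CA = p$k6 * cell$T_CTA, T_NA = p$k6 * cell$T_NTA))
  # algebraic identity at random admissible states
  set.seed(42)
  for (i in 1:50) {
    st <- c(x1 = runif(1, 0, 5), x2 = runif(1, 0, cellt$DNA_T),
            x3 = runif(1, 0, cellt$T_CA), x4 = runif(1, 0, 5),
            x5 = runif(1, 0, cellt$T_NA))
    r <- reaction_rates(st, cellt, p, cond)
    dx <- c(r[["r1"]] - r[["r4"]] + r[["r6"]] / cell$V_C +
              cell$V_N / cell$V_C * r[["r8"]],
            r[["r2"]] - r[["r3"]],
            r[["r4"]] - r[["r5"]],
            -r[["r2"]] + r[["r3"]] - r[["r6"]] / cell$V_N - r[["r7"]],
            r[["r7"]] - r[["r8"]])
    lhs <- cell$V_C * (dx[1] + dx[3]) + cell$V_N * (dx[2] + dx[4] + dx[5])
    rhs <- cell$V_C * (r[["r1"]] - r[["r5"]])
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # and numerically along a dense trajectory: total amount == integral of
  # net uptake V_C(r1 - r5). A mild parameter set keeps the uptake
  # transient resolvable by trapezoidal quadrature on the output grid.
  pm <- sp_params(k1 = 1, k2 = 1, k3 = 0.002, k4 = 1, k5 = 1, k6 = 1,
                  k7 = 1, k8 = 1)
  totm <- list(DNA_T = dna_binding_site_concentration(1, 1, cell$V_N),
               T_CA = cell$T_CTA, T_NA = cell$T_NTA)
  cellm <- c(cell, totm)
  res2 <- simulate_cell_staining(cell, pm, sp_conditions(duration = 20),
                                 times = seq(0, 20, by = 0.005),
                                 rtol = 1e-10, atol = 1e-12,
                                 maxsteps = 1e6)
  tr <- res2$trajectory
  amount <- cell$V_C * (tr[, "x1"] + tr[, "x3"]) +
    cell$V_N * (tr[, "x2"] + tr[, "x4"] + tr[, "x5"])
  net <- apply(tr, 1, function(row) {
    r <- reaction_rates(row[-1], cellm, pm, sp_conditions(duration = 20))
    cell$V_C * (r[["r1"]] - r[["r5"]])
  })
  dt <- diff(tr[, "time"])
  integral <- c(0, cumsum(dt * (head(net, -1) + net[-1]) / 2))
  expect_lt(max(abs(amount - integral)) / max(amount), 1e-4)
})

test_that("stiff integrator agrees with a brute-force RK4 oracle", {
  set.seed(2024)
  cond <- sp_conditions(duration = 30)
  for (i in 1:20) {
    p <- random_mild_params()
    cell <- test_cell(DNA_L = runif(1, 0.5, 2), T_CTA = runif(1, 0, 1),
                      T_NTA = runif(1, 0, 1))
    prod <- simulate_cell_staining(cell, p, cond)
    expect_false(prod$aborted)
    oracle <- rk4_staining(cell, p, cond, dt = 0.005)
    scale <- pmax(abs(oracle), 1e-6)
    expect_lt(max(abs(prod$state - oracle) / scale), 1e-4)
  }
})

test_that("final DNA-bound dye is monotone in total binding sites", {
  p <- sp_params(k1 = 10, k2 = 1, k3 = 0.1, k4 = 1, k5 = 1, k6 = 1,
                 k7 = 1, k8 = 1)
  x2_final <- vapply(c(0.25, 0.5, 1, 2, 4), function(dna_l) {
    cell <- test_cell(DNA_L = dna_l, T_CTA = 0, T_NTA = 0)
    simulate_cell_staining(cell, p, sp_conditions())$state[["x2"]]
  }, numeric(1))
  expect_true(all(diff(x2_final) > 0))
})

test_that("inhibition increases intracellular dye when efflux is strong", {
  cell <- test_cell(T_CTA = 1, T_NTA = 1)
  p <- sp_params(k1 = 10, k2 = 1, k3 = 0.05, k4 = 1e3, k5 = 1e2,
                 k6 = 50, k7 = 1, k8 = 1)
  amt <- vapply(c(0.99, 0), function(it) {
    res <- simulate_cell_staining(cell, p, sp_conditions(i_T = it))
    a <- hoechst_amounts(as.list(res$state), cell)
    a$H_b + a$H_f
  }, numeric(1))
  expect_gt(amt[1], amt[2]) # +FTC cell holds more dye at 90 min
})

test_that("population runs flag aborts and are deterministic", {
  ref <- test_ref()
  pop <- assign_transporter_levels(test_pop(10), "III", 1, sp_demo_params(),
                                   ref, seed = 7)
  sim <- simulate_population_staining(pop, sp_demo_params())
  expect_equal(sum(sim$aborted), 0)
  expect_false(sim$population_aborted)
  expect_equal(nrow(sim$states), 10)

  sim2 <- simulate_population_staining(pop, sp_demo_params())
  expect_identical(sim$states, sim2$states) # bitwise reproducible

  forced <- simulate_population_staining(pop, sp_demo_params(),
                                         timeout_per_cell = 0)
  expect_true(all(forced$aborted))
  expect_true(forced$population_aborted)
})
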