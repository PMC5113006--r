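# Shared fixtures, built once per test run.

.fixtures <- new.env()

test_ref <- function() {
  if (is.null(.fixtures$ref))
    .fixtures$ref <- suppressWarnings(
      generate_reference_distributions(seed = 7, n_events = 1500))
  .fixtures$ref
}

test_pop <- function(n = 40) {
  key <- paste0("pop", n)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- sp_population(test_ref(), n, seed = 7)
  .fixtures[[key]]
}

# A single well-behaved cell for kinetics tests.
test_cell <- function(DNA_L = 1, T_CTA = 0.5, T_NTA = 0.5) {
  m <- morphology_from_radii(10, 5.5)
  c(m, list(DNA_L = DNA_L, T_CTA = T_CTA, T_NTA = T_NTA))
}

# Independent brute-force oracle: classical fixed-step RK4 on the staining
# system, with the rate laws written out from first principles (membrane
# diffusion, DNA binding, transporter binding/efflux). Deliberately does not
# reuse the package right-hand side.
rk4_staining <- function(cell, params, cond, dt = 0.005) {
  DNA_T <- cell$DNA_L * (7.3e8 / 80) * params$k2 / 6.022e23 * 1e18 / cell$V_N
  T_CA <- params$k6 * (1 - cond$i_T) * cell$T_CTA
  T_NA <- params$k6 * (1 - cond$i_T) * cell$T_NTA
  f <- function(x) {
    diff_in <- params$k3 * (cell$A_C / cell$V_C) * (cond$H_e - x[1])
    bindDNA <- params$k1 * x[4] * (DNA_T - x[2])
    unbindDNA <- params$k_off * x[2]
    bindTC <- params$k4 * x[1] * (T_CA - x[3])
    effluxC <- params$k5 * x[3]
    nucflux <- params$k3 * cell$A_N * (x[4] - x[1]) # amol/min, out of nucleus
    bindTN <- params$k4 * x[4] * (T_NA - x[5])
    effluxN <- params$k5 * x[5]
    c(diff_in - bindTC + nucflux / cell$V_C + cell$V_N / cell$V_C * effluxN,
      bindDNA - unbindDNA,
      bindTC - effluxC,
      -bindDNA + unbindDNA - nucflux / cell$V_N - bindTN,
      bindTN - effluxN)
  }
  # keep the explicit scheme inside its stability region
  rate_scale <- max(params$k3 * cell$A_C / cell$V_C,
                    params$k3 * cell$A_N / cell$V_N,
                    params$k1 * DNA_T, params$k4 * T_CA, params$k4 * T_NA,
                    params$k5, params$k_off, 1e-6)
  dt <- min(dt, 0.5 / rate_scale)
  x <- rep(0, 5)
  nstep <- ceiling(cond$duration / dt)
  h <- cond$duration / nstep
  for (i in seq_len(nstep)) {
    k1v <- f(x)
    k2v <- f(x + h / 2 * k1v)
    k3v <- f(x + h / 2 * k2v)
    k4v <- f(x + h * k3v)
    x <- x + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  }
  setNames(x, paste0("x", 1:5))
}

# Non-stiff random parameter draw for oracle-equivalence checks.
random_mild_params <- function() {
  lu <- function(lo, hi) 10^runif(1, log10(lo), log10(hi))
  sp_params(k1 = lu(0.1, 10), k2 = lu(0.1, 10), k3 = lu(0.01, 0.5),
            k4 = lu(0.1, 50), k5 = lu(0.1, 50), k6 = lu(0.1, 10),
            k7 = lu(0.2, 5), k8 = runif(1, 1, 5), k9 = runif(1, 0.3, 0.7))
}
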