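#' Convert cell and nuclear radii to spherical morphology
#'
#' Cells and nuclei are treated as concentric spheres; the cytosolic volume is
#' the whole-cell volume minus the nuclear volume. Volumes are returned in
#' picolitres (1 pl = 1000 um^3), surface areas in um^2.
#'
#' @param r_cell whole-cell radius, um
#' @param r_nuc nuclear radius, um; must be strictly smaller than `r_cell`
#' @return list with `V_C`, `A_C`, `V_N`, `A_N`
#' @export
morphology_from_radii <- function(r_cell, r_nuc) {
  if (any(r_nuc <= 0) || any(r_cell <= 0))
    stop("radii must be strictly positive")
  if (any(r_nuc >= r_cell))
    stop("geometry error: nuclear radius must be smaller than cell radius")
  v_cell <- 4 / 3 * pi * r_cell^3 / 1000 # um^3 -> pl
  v_nuc <- 4 / 3 * pi * r_nuc^3 / 1000
  list(
    V_C = v_cell - v_nuc,
    A_C = 4 * pi * r_cell^2,
    V_N = v_nuc,
    A_N = 4 * pi * r_nuc^2
  )
}

#' Sample correlated cell and nuclear radii from a gridded joint density
#'
#' Whole-cell radii are drawn by Latin hypercube sampling of the marginal CDF;
#' for each draw the nuclear radius comes from the conditional CDF along the
#' nuclear-radius axis at the nearest whole-cell-radius grid line. Grid cells
#' with `r_nuc >= r_cell` are zeroed before normalization so every sampled
#' pair is geometrically valid.
#'
#' @param ref a [sp_reference] object (or any list with `radii$r_cell`,
#'   `radii$r_nuc`, `radii$density`)
#' @param n number of cells
#' @param seed integer seed for the LHCS draws
#' @return data.frame with columns `r_cell`, `r_nuc` (um)
#' @export
sample_radii <- function(ref, n, seed) {
  rj <- ref$radii
  stopifnot(is.matrix(rj$density),
            nrow(rj$density) == length(rj$r_cell),
            ncol(rj$density) == length(rj$r_nuc))
  if (n == 0L) return(data.frame(r_cell = numeric(0), r_nuc = numeric(0)))
  dens <- rj$density
  # geometry guard
  bad <- outer(rj$r_cell, rj$r_nuc, function(rc, rn) rn >= rc)
  dens[bad] <- 0
  if (sum(dens) <= 0) stop("invalid reference: radii density is degenerate")

  marg <- rowSums(dens)
  u <- matrix(lhs_vector(2L * n, seed = substream_seed(seed, "radii")),
              ncol = 2)
  r_cell <- sample_gridded_pdf(rj$r_cell, marg, u[, 1])
  idx <- vapply(r_cell, function(r) which.min(abs(rj$r_cell - r)), integer(1))
  r_nuc <- numeric(n)
  for (i in seq_len(n)) {
    cond <- dens[idx[i], ]
    if (sum(cond) <= 0) {
      # fall back to the nearest row with mass below the sampled cell radius
      ok <- which(rowSums(dens) > 0)
      cond <- dens[ok[which.min(abs(ok - idx[i]))], ]
    }
    r_nuc[i] <- sample_gridded_pdf(rj$r_nuc, cond, u[i, 2])
  }
  r_nuc <- pmin(r_nuc, r_cell * (1 - 1e-9))
  data.frame(r_cell = r_cell, r_nuc = r_nuc)
}

#' DNA Hoechst-binding-site concentration for one cell
#'
#' The A549 genome (7.3e8 base pairs) offers one Hoechst binding site per 80
#' base pairs; the per-cell site count scales with the relative DNA level and
#' the dimensionless scaling parameter k2, is converted to a molar amount via
#' Avogadro's number and divided by the nuclear volume (amol/pl == uM).
#'
#' @param DNA_L relative DNA level (mode-normalized)
#' @param k2 dimensionless binding-site scaling term
#' @param V_N nuclear volume, pl
#' @return binding-site concentration, uM
#' @export
dna_binding_site_concentration <- function(DNA_L, k2, V_N) {
  stopifnot(all(DNA_L >= 0), k2 > 0, all(V_N > 0))
  sites <- DNA_L * (7.3e8 / 80) * k2
  amol <- sites / 6.022e23 * 1e18
  amol / V_N
}

#' Hill cooperativity of transporter activity
#'
#' Cooperative transporter interactions map a relative expression level to an
#' activity level: theta(T) = T^k8 / (k9^k8 + T^k8), bounded in [0, 1) and
#' monotone in T.
#'
#' @param T_level relative transporter level (T_Level units), >= 0
#' @param k8_hill Hill coefficient, > 0
#' @param k9 half-maximal level, > 0
#' @return activity level in [0, 1)
#' @export
hill_activity <- function(T_level, k8_hill, k9) {
  stopifnot(all(T_level >= 0), k8_hill > 0, k9 > 0)
  tk <- T_level^k8_hill
  ifelse(T_level == 0, 0, tk / (k9^k8_hill + tk))
}

#' Split a total transporter level between cytosol and nucleus
#'
#' The compartments hold transporter at the fixed ratio T_CT = k7 * T_NT, so
#' T_CT = T * k7/(1+k7) and T_NT = T/(1+k7); the two parts always sum back to
#' the total exactly.
#'
#' @param T_total total relative transporter level
#' @param k7 cytosolic/nuclear ratio, >= 0
#' @return list with `T_CT`, `T_NT`
#' @export
split_compartments <- function(T_total, k7) {
  stopifnot(all(T_total >= 0), k7 >= 0)
  T_NT <- T_total / (1 + k7)
  list(T_CT = T_total - T_NT, T_NT = T_NT)
}

#' Effective (absolute) transporter activity under inhibition
#'
#' Scales relative compartment activities to absolute concentrations with k6
#' (uM per T_Level unit) and applies the inhibition fraction: i_T = 0.99 in
#' the inhibited (+FTC) condition, 0 without inhibitor.
#'
#' @param T_CTA,T_NTA relative compartment transporter activities
#' @param k6 absolute expression scale, uM/T_Level
#' @param i_T inhibition fraction in [0, 1]
#' @return list with `T_CA`, `T_NA` (uM)
#' @export
effective_transporter_activity <- function(T_CTA, T_NTA, k6, i_T) {
  stopifnot(i_T >= 0, i_T <= 1)
  list(T_CA = k6 * (1 - i_T) * T_CTA, T_NA = k6 * (1 - i_T) * T_NTA)
}

#' Build a heterogeneous in-silico cell population
#'
#' Samples `n` cells' radii (and hence volumes/areas) and relative DNA levels
#' from the reference distributions by Latin hypercube sampling. Transporter
#' levels are assigned separately per condition with
#' [assign_transporter_levels()].
#'
#' @param ref a [sp_reference] object
#' @param n population size
#' @param seed master seed; expanded into per-purpose substreams
#' @return object of class `sp_population`: data.frame of per-cell morphology
#'   with attributes recording seed provenance
#' @export
sp_population <- function(ref, n, seed) {
  radii <- sample_radii(ref, n, seed)
  morph <- morphology_from_radii(radii$r_cell, radii$r_nuc)
  u_dna <- lhs_vector(n, seed = substream_seed(seed, "dna"))
  dna <- sample_gridded_pdf(ref$dna$x, ref$dna$density, u_dna)
  pop <- data.frame(
    cell_id = seq_len(max(n, 0L)),
    r_cell = radii$r_cell, r_nuc = radii$r_nuc,
    V_C = morph$V_C, A_C = morph$A_C, V_N = morph$V_N, A_N = morph$A_N,
    DNA_L = dna
  )
  structure(pop, class = c("sp_population", "data.frame"), seed = seed)
}

#' @export
print.sp_population <- function(x, ...) {
  cat(sprintf("In-silico cell population: %d cells (seed %s)\n",
              nrow(x), format(attr(x, "seed"))))
  cat(sprintf("  cell radius   %.2f-%.2f um, nuclear radius %.2f-%.2f um\n",
              min(x$r_cell), max(x$r_cell), min(x$r_nuc), max(x$r_nuc)))
  cat(sprintf("  DNA level     %.2f-%.2f (mode-normalized)\n",
              min(x$DNA_L), max(x$DNA_L)))
  if (!is.null(x$T_CTA))
    cat(sprintf("  transporter   mode %s, condition %d\n",
                attr(x, "heterogeneity_mode"), attr(x, "condition")))
  invisible(x)
}

#' Assign per-cell transporter activities under a heterogeneity mode
#'
#' Three population-level models of transporter heterogeneity share the same
#' single-cell kinetics and differ only in how expression is distributed:
#' \describe{
#'   \item{mode I (concentration-uniform)}{every cell carries the identical
#'     transporter concentration-equivalent; the condition level is the
#'     reference geometric mean raised through the k8-controlled spread
#'     (g_i/g_1)^k8, split between compartments by k7.}
#'   \item{mode II (number-uniform)}{mode-I concentrations are converted to
#'     molar amounts with each cell's compartment volume, averaged over the
#'     population, and the identical amount is handed to every cell, so
#'     concentration-equivalents scale inversely with volume.}
#'   \item{mode III (experimental-distribution)}{per-cell total levels are
#'     drawn from the condition's expression PDF using one shared LHCS vector
#'     across all four conditions, split by k7, then passed through the Hill
#'     cooperativity [hill_activity()] with (k8, k9).}
#' }
#'
#' @param pop an `sp_population`
#' @param mode "I", "II" or "III"
#' @param condition_index transporter condition 1-4 (1 = untreated control,
#'   highest expression)
#' @param params a [sp_params] kinetic parameter set
#' @param ref a [sp_reference] object
#' @param seed seed for the shared mode-III LHCS vector (condition-independent)
#' @return the population with per-cell `T_Total`, `T_CTA`, `T_NTA` columns
#' @export
assign_transporter_levels <- function(pop, mode = c("I", "II", "III"),
                                      condition_index, params, ref, seed) {
  mode <- match.arg(mode)
  stopifnot(condition_index %in% 1:4)
  n <- nrow(pop)
  if (mode %in% c("I", "II")) {
    g <- ref$abcg2_geomeans
    level <- (g[condition_index] / g[1])^params$k8
    parts <- split_compartments(level, params$k7)
    T_CTA <- rep(parts$T_CT, n)
    T_NTA <- rep(parts$T_NT, n)
    if (mode == "II") {
      # equal molar amount per cell: average the mode-I amounts, hand the
      # mean amount to every cell, convert back by compartment volume
      amt_C <- mean(T_CTA * pop$V_C)
      amt_N <- mean(T_NTA * pop$V_N)
      T_CTA <- amt_C / pop$V_C
      T_NTA <- amt_N / pop$V_N
    }
    pop$T_Total <- rep(level, n)
  } else {
    if (is.null(ref$abcg2_pdfs) || length(ref$abcg2_pdfs) < condition_index)
      stop("invalid reference: mode III requires abcg2 expression PDFs")
    u <- lhs_vector(n, seed = substream_seed(seed, "transporter"))
    pdf <- ref$abcg2_pdfs[[condition_index]]
    T_total <- sample_gridded_pdf(pdf$x, pdf$density, u)
    parts <- split_compartments(T_total, params$k7)
    T_CTA <- hill_activity(parts$T_CT, params$k8, params$k9)
    T_NTA <- hill_activity(parts$T_NT, params$k8, params$k9)
    pop$T_Total <- T_total
  }
  pop$T_CTA <- T_CTA
  pop$T_NTA <- T_NTA
  attr(pop, "heterogeneity_mode") <- mode
  attr(pop, "condition") <- as.integer(condition_index)
  pop
}
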