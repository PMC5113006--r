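#' Hoechst Score transformation of a paired +/- inhibitor sample
#'
#' Both conditions' raw Red/Blue signals are z-scored with the mean and
#' standard deviation of the *inhibited* (+FTC) condition only, so the +FTC
#' events have per-channel mean 0 and sd 1 by construction and the -FTC
#' scores are expressed in +FTC standard-deviation units. Aborted events are
#' excluded from both the reference statistics and the output.
#'
#' @param events_plus,events_minus event tables (see
#'   [events_from_simulation()]) for the +inhibitor and -inhibitor conditions
#' @return list of class `sp_scored` with elements `plus` and `minus`
#'   (data.frames with cell_id, HRS, HBS, H_proj) and `reference_stats`
#' @export
hoechst_scores <- function(events_plus, events_minus) {
  keep_p <- !events_plus$aborted
  keep_m <- !events_minus$aborted
  p <- events_plus[keep_p, ]
  m <- events_minus[keep_m, ]
  if (nrow(p) == 0 || nrow(m) == 0) stop("empty event table")
  stats <- list(mean_red = mean(p$HR_sig), sd_red = sd(p$HR_sig),
                mean_blue = mean(p$HB_sig), sd_blue = sd(p$HB_sig))
  if (!all(is.finite(unlist(stats))) || stats$sd_red == 0 ||
      stats$sd_blue == 0)
    stop("degenerate reference: +inhibitor channel has zero variance")
  score <- function(ev) {
    HRS <- (ev$HR_sig - stats$mean_red) / stats$sd_red
    HBS <- (ev$HB_sig - stats$mean_blue) / stats$sd_blue
    data.frame(cell_id = ev$cell_id, HRS = HRS, HBS = HBS,
               H_proj = hoechst_projection(HRS, HBS))
  }
  structure(list(plus = score(p), minus = score(m),
                 reference_stats = stats),
            class = "sp_scored")
}

#' Signed diagonal projection of Hoechst Scores
#'
#' Projects a (Red Score, Blue Score) pair onto the main diagonal of the
#' score plane: H_proj = (HRS + HBS)/sqrt(2). Negative values indicate less
#' staining than the inhibited reference in both channels combined.
#'
#' @param HRS,HBS Hoechst Red/Blue Scores
#' @export
hoechst_projection <- function(HRS, HBS) (HRS + HBS) / sqrt(2)

#' Automated %SP by projection gating
#'
#' The gate is the given percentile (default 1st) of the +inhibitor
#' projection scores — the lower edge of the non-side population. The side
#' population size is the percentage of -inhibitor events strictly below
#' that gate; ties at the gate count as non-SP.
#'
#' @param scored an `sp_scored` object from [hoechst_scores()]
#' @param percentile gate percentile of the +inhibitor projections
#' @return %SP (0-100)
#' @export
percent_sp <- function(scored, percentile = 1) {
  stopifnot(inherits(scored, "sp_scored"))
  thr <- as.numeric(quantile(scored$plus$H_proj, percentile / 100))
  100 * mean(scored$minus$H_proj < thr)
}

#' Gridded 2D density over the Hoechst Score plane
#'
#' Low-level constructor; see [score_pdf2d()] for estimation from events.
#'
#' @param x,y grid axes (HRS, HBS)
#' @param z values on the grid (length(x) by length(y))
#' @param kind "pdf" (non-negative, unit integral) or "delta" (zero integral)
#' @export
sp_density2d <- function(x, y, z, kind = c("pdf", "delta")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(z), nrow(z) == length(x), ncol(z) == length(y))
  total <- trapz2(x, y, z)
  if (kind == "pdf") {
    stopifnot(all(z >= 0))
    if (abs(total - 1) > 1e-6) stop("pdf surface must integrate to 1")
  } else if (abs(total) > 1e-6) stop("delta surface must integrate to 0")
  structure(list(x = x, y = y, z = z, kind = kind), class = "sp_density2d")
}

#' @export
print.sp_density2d <- function(x, ...) {
  cat(sprintf("Hoechst Score %s surface: %d x %d grid on [%g, %g] x [%g, %g]\n",
              x$kind, length(x$x), length(x$y),
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
plot.sp_density2d <- function(x, ...) {
  graphics::image(x$x, x$y, x$z, xlab = "Hoechst Red Score",
                  ylab = "Hoechst Blue Score", ...)
  invisible(x)
}

# Whittaker smoother matrix: (I + lambda D2'D2)^-1 applied along one axis.
whittaker_matrix <- function(n, lambda) {
  if (n < 3 || lambda <= 0) return(diag(n))
  D <- diff(diag(n), differences = 2)
  solve(diag(n) + lambda * crossprod(D))
}

#' Smoothed 2D probability density of scored events
#'
#' Bins events on a fixed score grid and applies a penalized
#' (second-difference, Whittaker) smoother along both axes — the standard
#' fast scatter-plot smoother for cytometry-sized data. Negative ringing is
#' clipped to zero and the surface renormalized to unit trapezoidal
#' integral. The grid defaults to [-6, 6]^2 with 121 points per axis and
#' should be shared across all conditions of a sample so difference surfaces
#' are well defined.
#'
#' @param scores data.frame with `HRS`, `HBS` (e.g. `scored$minus`)
#' @param grid list with numeric axes `x` and `y`
#' @param lambda smoothing penalty on second differences (both axes)
#' @param clamp clamp out-of-grid events to the edge bins (with a warning)
#'   instead of erroring
#' @return an [sp_density2d()] of kind "pdf"
#' @export
score_pdf2d <- function(scores, grid = sp_score_grid(), lambda = 10,
                        clamp = TRUE) {
  x <- grid$x; y <- grid$y
  stopifnot(nrow(scores) >= 2)
  hx <- scores$HRS; hy <- scores$HBS
  out <- hx < min(x) | hx > max(x) | hy < min(y) | hy > max(y)
  if (any(out)) {
    if (!clamp) stop("events fall outside the score grid")
    warning(sprintf("%d events clamped to the score-grid edge", sum(out)))
    hx <- pmin(pmax(hx, min(x)), max(x))
    hy <- pmin(pmax(hy, min(y)), max(y))
  }
  ix <- findInterval(hx, c(-Inf, x[-1] - diff(x) / 2))
  iy <- findInterval(hy, c(-Inf, y[-1] - diff(y) / 2))
  H <- matrix(0, length(x), length(y))
  for (k in seq_along(ix)) H[ix[k], iy[k]] <- H[ix[k], iy[k]] + 1
  Sx <- whittaker_matrix(length(x), lambda)
  Sy <- whittaker_matrix(length(y), lambda)
  Z <- Sx %*% H %*% t(Sy)
  Z[Z < 0] <- 0
  Z <- Z / trapz2(x, y, Z)
  sp_density2d(x, y, Z, "pdf")
}

#' Default shared Hoechst Score grid
#'
#' @param lim half-width of the symmetric score range
#' @param n points per axis
#' @export
sp_score_grid <- function(lim = 6, n = 121) {
  ax <- seq(-lim, lim, length.out = n)
  list(x = ax, y = ax)
}

#' Difference surface between -FTC and +FTC densities
#'
#' Point-wise PDF(-FTC) - PDF(+FTC) on a common grid; positive lobes mark
#' score regions enriched when efflux is uninhibited (the SP signature sits
#' as a positive lobe at low scores).
#'
#' @param pdf_minus,pdf_plus `sp_density2d` objects of kind "pdf", same grid
#' @return an `sp_density2d` of kind "delta" (zero integral)
#' @export
delta_ftc <- function(pdf_minus, pdf_plus) {
  check_same_grid(pdf_minus, pdf_plus)
  sp_density2d(pdf_minus$x, pdf_minus$y, pdf_minus$z - pdf_plus$z, "delta")
}

#' Difference between two delta-FTC surfaces (test - control)
#'
#' @param dftc_test,dftc_control `sp_density2d` objects of kind "delta"
#' @export
delta_sp <- function(dftc_test, dftc_control) {
  check_same_grid(dftc_test, dftc_control)
  sp_density2d(dftc_test$x, dftc_test$y, dftc_test$z - dftc_control$z,
               "delta")
}

check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$x, b$x)) || !isTRUE(all.equal(a$y, b$y)))
    stop("surfaces are defined on different grids")
  invisible(TRUE)
}

#' Overlap coefficient of two densities
#'
#' Integral of the point-wise minimum of two unit-mass densities; 1 for
#' identical densities, 0 for disjoint supports.
#'
#' @param pdf_a,pdf_b `sp_density2d` objects of kind "pdf", same grid
#' @return fraction in [0, 1]
#' @export
overlap_coefficient <- function(pdf_a, pdf_b) {
  check_same_grid(pdf_a, pdf_b)
  stopifnot(pdf_a$kind == "pdf", pdf_b$kind == "pdf")
  trapz2(pdf_a$x, pdf_a$y, pmin(pdf_a$z, pdf_b$z))
}

#' Zero-lag normalized 2D cross-correlation
#'
#' Pearson correlation of the mean-centered, flattened surfaces (aligned,
#' i.e. no lag search). Constant surfaces have no defined correlation.
#'
#' @param d_a,d_b `sp_density2d` objects on the same grid
#' @return correlation in [-1, 1]
#' @export
normalized_cross_correlation <- function(d_a, d_b) {
  check_same_grid(d_a, d_b)
  a <- as.vector(d_a$z); b <- as.vector(d_b$z)
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined correlation: constant surface")
  cor(a, b)
}
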