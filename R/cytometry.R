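#' Spectral constants for in-silico flow cytometry
#'
#' Quantum yield (Q), relative excitation efficiency (E) and the emission
#' overlap with the Hoechst Red (R) and Blue (B) detection channels, for
#' DNA-bound (`_b`) and free (`_f`) Hoechst 33342. Defaults are the
#' calibrated signal factors of the simulated cytometer.
#'
#' @param Q_b,E_b,R_b,B_b DNA-bound dye factors
#' @param Q_f,E_f,R_f,B_f free-dye factors
#' @export
sp_spectral_constants <- function(Q_b = 0.34, E_b = 0.9902, R_b = 29.86,
                                  B_b = 4650, Q_f = 0.038, E_f = 0.6764,
                                  R_f = 464.2, B_f = 1914) {
  k <- list(Q_b = Q_b, E_b = E_b, R_b = R_b, B_b = B_b,
            Q_f = Q_f, E_f = E_f, R_f = R_f, B_f = B_f)
  stopifnot(all(unlist(k) > 0))
  structure(k, class = "sp_spectral_constants")
}

#' Molar Hoechst amounts of a stained cell
#'
#' Partitions the end-state concentrations into DNA-bound (`H_b = x2 * V_N`)
#' and non-DNA-bound ("free", `H_f`) molar amounts. By default the free pool
#' includes transporter-bound dye (x3, x5) alongside the free cytosolic and
#' nuclear dye, since the spectral model distinguishes only DNA-bound from
#' non-DNA-bound species; `include_transporter_bound = FALSE` restricts
#' `H_f` to genuinely unbound dye.
#'
#' @param state named x1..x5 concentrations, uM (vectors accepted)
#' @param cell list with `V_C`, `V_N` (pl)
#' @param include_transporter_bound count x3/x5 in the free pool?
#' @return list with `H_b`, `H_f` in amol
#' @export
hoechst_amounts <- function(state, cell, include_transporter_bound = TRUE) {
  H_b <- state[["x2"]] * cell$V_N
  H_f <- state[["x1"]] * cell$V_C + state[["x4"]] * cell$V_N
  if (include_transporter_bound)
    H_f <- H_f + state[["x3"]] * cell$V_C + state[["x5"]] * cell$V_N
  list(H_b = H_b, H_f = H_f)
}

#' Spectral signal matrix
#'
#' The 2x2 linear map from (H_b, H_f) amounts to (Hoechst Red, Hoechst Blue)
#' detector signals: each entry is the product quantum yield x excitation
#' efficiency x channel emission overlap for that species/channel pair.
#'
#' @param k an [sp_spectral_constants]
#' @return 2x2 matrix with rows (red, blue) and columns (bound, free)
#' @export
build_signal_matrix <- function(k = sp_spectral_constants()) {
  matrix(c(k$Q_b * k$E_b * k$R_b, k$Q_b * k$E_b * k$B_b,
           k$Q_f * k$E_f * k$R_f, k$Q_f * k$E_f * k$B_f),
         nrow = 2, dimnames = list(c("red", "blue"), c("bound", "free")))
}

#' Convert Hoechst amounts to detector signals
#'
#' @param H_b,H_f amounts in amol (vectors accepted)
#' @param S signal matrix from [build_signal_matrix()]
#' @return list with `HR_sig`, `HB_sig` (arbitrary signal units)
#' @export
to_signals <- function(H_b, H_f, S = build_signal_matrix()) {
  list(HR_sig = S["red", "bound"] * H_b + S["red", "free"] * H_f,
       HB_sig = S["blue", "bound"] * H_b + S["blue", "free"] * H_f)
}

#' In-silico flow cytometry of a simulated population
#'
#' Converts per-cell end states into an event table of Hoechst Red/Blue
#' signals. Optional multiplicative log-normal detector noise (seeded) is
#' available for robustness studies; none is added by default.
#'
#' @param pop the population (for volumes and cell ids)
#' @param sim result of [simulate_population_staining()]
#' @param condition_label label stored per event (e.g. "+FTC")
#' @param S signal matrix
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   detector noise; 0 (default) adds none
#' @param seed seed for the noise draws
#' @param include_transporter_bound see [hoechst_amounts()]
#' @return data.frame (event table): cell_id, condition, t_level, HR_sig,
#'   HB_sig, aborted
#' @export
events_from_simulation <- function(pop, sim, condition_label = "",
                                   S = build_signal_matrix(),
                                   noise_cv = 0, seed = 1,
                                   include_transporter_bound = TRUE) {
  st <- as.data.frame(sim$states)
  amt <- hoechst_amounts(st, pop, include_transporter_bound)
  sig <- to_signals(amt$H_b, amt$H_f, S)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- with_seed(substream_seed(seed, "detector-noise"), {
      matrix(exp(rnorm(2L * nrow(pop), -sdlog^2 / 2, sdlog)), ncol = 2)
    })
    sig$HR_sig <- sig$HR_sig * noise[, 1]
    sig$HB_sig <- sig$HB_sig * noise[, 2]
  }
  data.frame(cell_id = pop$cell_id, condition = condition_label,
             t_level = if (is.null(pop$T_Total)) NA_real_ else pop$T_Total,
             HR_sig = sig$HR_sig, HB_sig = sig$HB_sig,
             aborted = sim$aborted)
}

#' Read / write event tables as CSV
#'
#' @param events event table data.frame
#' @param path file path
#' @export
write_events_csv <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param hoechst_red,hoechst_blue column names holding the two channels
#' @export
read_events_csv <- function(path, hoechst_red = "HR_sig",
                            hoechst_blue = "HB_sig") {
  ev <- utils::read.csv(path)
  stopifnot(hoechst_red %in% names(ev), hoechst_blue %in% names(ev))
  names(ev)[names(ev) == hoechst_red] <- "HR_sig"
  names(ev)[names(ev) == hoechst_blue] <- "HB_sig"
  if (is.null(ev$aborted)) ev$aborted <- FALSE
  ev
}
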