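#' Ionic parameter sets for the reduced action-potential model
#'
#' The simulator uses a reduced Hodgkin-Huxley-style membrane model with
#' currents I_Na, I_CaL, I_Kr, I_Ks, I_to, I_K1, a hyperpolarisation-activated
#' pacemaker current I_f and a small background sodium leak.  Each current is
#' `G_x * (gates) * (V - E_x)` with two-parameter Boltzmann gate steady
#' states.  Two calibrated phenotypes are shipped:
#'
#' * **immature** (iPSC-CM-like): low I_K1, present I_f, small I_Na -- beats
#'   spontaneously with a maximum diastolic potential near -80 mV, a slow
#'   upstroke and a long action potential (APD90 about 360 ms, intrinsic
#'   cycle length about 940 ms);
#' * **adult** (ventricular): large I_K1 and I_Na, no I_f -- quiescent until
#'   stimulated, resting near -88 mV, fast upstroke, APD90 about 223 ms at a
#'   982-ms cycle length.
#'
#' Conductances are in mS/uF, potentials in mV, time constants in ms and the
#' membrane capacitance is normalised (`cm = 1` uF/uF so currents are uA/uF).
#'
#' @param overrides named numeric vector of parameter overrides.
#' @return A named numeric vector of class `ionic_params` with a
#'   `phenotype` attribute (`"immature"` or `"adult"`).
#' @examples
#' p <- adult_params()
#' p["g_kr"]
#' @export
immature_params <- function(overrides = NULL) {
  p <- c(
    g_na = 3, g_cal = 0.2, g_kr = 0.08, g_ks = 0.01, g_to = 0.02,
    g_k1 = 0.1, g_f = 0.036, g_bna = 0.0033,
    e_na = 60, e_ca = 45, e_k = -88, e_f = -20, cm = 1,
    tau_f_amp = 1400, tau_xr = 320, tau_xs = 400, tau_y = 800,
    v_init = -75
  )
  new_ionic_params(p, "immature", overrides)
}

#' @rdname immature_params
#' @export
adult_params <- function(overrides = NULL) {
  p <- c(
    g_na = 12, g_cal = 0.32, g_kr = 0.18, g_ks = 0.015, g_to = 0.15,
    g_k1 = 0.6, g_f = 0, g_bna = 0,
    e_na = 60, e_ca = 45, e_k = -88, e_f = -20, cm = 1,
    tau_f_amp = 800, tau_xr = 320, tau_xs = 400, tau_y = 450,
    v_init = -87
  )
  new_ionic_params(p, "adult", overrides)
}

new_ionic_params <- function(p, phenotype, overrides = NULL) {
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    bad <- setdiff(names(overrides), names(p))
    if (length(bad))
      stop("unknown ionic parameter(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  if (any(p[grep("^g_", names(p))] < 0))
    stop("all conductances must be >= 0")
  structure(p, phenotype = phenotype, class = "ionic_params")
}

#' @export
print.ionic_params <- function(x, ...) {
  cat("<ionic_params> phenotype:", attr(x, "phenotype"), "\n")
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}

#' Drug specification for hERG (I_Kr) block
#'
#' Two block schemes act on the I_Kr conductance `G_Kr`:
#' `"simple_block"` scales `G_Kr` once by `1 - block_fraction` (the 1--50%
#' conductance-scaling sweep), while `"state_dependent"` models open-channel
#' binding: the bound fraction `b` obeys
#' `db/dt = k_on * conc * p_open * (1 - b) - k_off * b`, where `p_open` is
#' the instantaneous I_Kr open probability, and the conductance is scaled by
#' `1 - b`.  The state-dependent defaults emulate a potent hERG blocker at
#' its clinical concentration (2.72 ng/mL), with rates calibrated so
#' steady-state block is roughly 35%.
#'
#' @param mode one of `"none"`, `"simple_block"`, `"state_dependent"`.
#' @param block_fraction fraction of `G_Kr` removed, in `[0, 0.5]`
#'   (simple-block mode).
#' @param concentration drug concentration in ng/mL (state-dependent mode).
#' @param k_on binding rate, per ng/mL per ms.
#' @param k_off unbinding rate, per ms.
#' @return A list of class `drug_spec`.
#' @export
drug_spec <- function(mode = c("none", "simple_block", "state_dependent"),
                      block_fraction = 0,
                      concentration = 2.72,
                      k_on = 7.4e-4,
                      k_off = 8e-4) {
  mode <- match.arg(mode)
  if (mode == "simple_block") {
    if (!is.numeric(block_fraction) || block_fraction < 0 || block_fraction > 0.5)
      stop("block_fraction must lie in [0, 0.5]")
  }
  if (mode == "state_dependent") {
    if (concentration < 0) stop("drug concentration must be >= 0")
    if (k_on < 0 || k_off < 0) stop("binding rates must be >= 0")
  }
  structure(list(mode = mode,
                 block_fraction = if (mode == "simple_block") block_fraction else 0,
                 concentration = if (mode == "state_dependent") concentration else 0,
                 k_on = k_on, k_off = k_off),
            class = "drug_spec")
}

#' Pacing protocol
#'
#' Adult cells are stimulated with a depolarising current pulse at a fixed
#' cycle length; immature cells beat spontaneously (set `spontaneous =
#' TRUE`, in which case `cycle_length` is ignored).  Conditioning beats run
#' noise-free to a quasi-steady state; the stochastic noise current is then
#' applied throughout the final `noisy_beats` beats and the last beat's
#' window is recorded.
#'
#' @param cycle_length ms between stimuli (paced mode).
#' @param stim_amplitude stimulus amplitude, uA/uF (depolarising).
#' @param stim_duration stimulus duration, ms.
#' @param conditioning_beats noise-free beats run before noise starts.
#' @param noisy_beats beats with the noise current applied (the recorded
#'   action potential is the last of these).
#' @param spontaneous if `TRUE` the cell is unpaced and beats are counted
#'   from detected upstrokes.
#' @return A list of class `pacing_protocol`.
#' @export
pacing_protocol <- function(cycle_length = 982,
                            stim_amplitude = 60,
                            stim_duration = 1,
                            conditioning_beats = 20,
                            noisy_beats = 100,
                            spontaneous = FALSE) {
  if (!spontaneous && cycle_length <= 0) stop("cycle_length must be positive")
  if (noisy_beats < 0 || conditioning_beats < 0)
    stop("beat counts must be >= 0")
  structure(list(cycle_length = cycle_length,
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration,
                 conditioning_beats = as.integer(conditioning_beats),
                 noisy_beats = as.integer(noisy_beats),
                 spontaneous = isTRUE(spontaneous)),
            class = "pacing_protocol")
}

#' Stochastic noise-current specification
#'
#' The membrane potential receives a stochastic increment
#' `xi * n * sqrt(dt)` with `n ~ N(0, 1)`, applied on a fixed noise grid of
#' step `dt` (which the simulator takes equal to its output grid, 1 ms).
#' `xi` is the diffusion coefficient -- the amplitude of the physiological
#' noise current -- and defaults to 0.3.
#'
#' @param xi diffusion coefficient (noise amplitude), dimensionless; >= 0.
#' @param dt noise/integration grid step in ms; > 0.
#' @param seed RNG seed for the noise stream.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(xi = 0.3, dt = 1, seed = 1L) {
  if (xi < 0) stop("xi must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(xi = xi, dt = dt, seed = seed), class = "noise_spec")
}

#' One stochastic Forward-Euler voltage update
#'
#' Computes `V - I_total * dt / cm + xi * n * sqrt(dt)`: the deterministic
#' Forward-Euler drift plus the stochastic noise increment.  Exposed mainly
#' so the noise model can be inspected and validated in isolation; the
#' compiled simulator applies the identical update.
#'
#' @param v membrane potential, mV.
#' @param i_total total transmembrane current, uA/uF.
#' @param spec a [noise_spec()].
#' @param n standard-normal draw(s), supplied by the caller's seeded RNG.
#' @param cm membrane capacitance (uF/uF), default 1.
#' @return Updated potential(s), mV.
#' @examples
#' euler_noise_step(-80, 0, noise_spec(xi = 0), n = 0)  # unchanged
#' @export
euler_noise_step <- function(v, i_total, spec = noise_spec(), n, cm = 1) {
  stopifnot(inherits(spec, "noise_spec"))
  if (!all(is.finite(v))) stop("non-finite membrane potential V")
  if (!all(is.finite(i_total))) stop("non-finite total current I_total")
  v - i_total * spec$dt / cm + spec$xi * n * sqrt(spec$dt)
}

#' Apply a simple conductance-scaling I_Kr block
#'
#' Returns a copy of the parameter set with `G_Kr` scaled by
#' `1 - block_fraction`; all other parameters are untouched.  A 1--50%
#' block sweep corresponds to scale factors 0.99 down to 0.50.
#'
#' @param params an [immature_params()] / [adult_params()] set.
#' @param block_fraction fraction of I_Kr conductance removed, in `[0, 1]`
#'   (the sweep uses `[0, 0.5]`).
#' @return A modified `ionic_params` object.
#' @examples
#' p <- adult_params()
#' pb <- apply_simple_block(p, 0.5)
#' pb[["g_kr"]] / p[["g_kr"]]  # 0.5
#' @export
apply_simple_block <- function(params, block_fraction) {
  stopifnot(inherits(params, "ionic_params"))
  if (!is.numeric(block_fraction) || length(block_fraction) != 1 ||
      block_fraction < 0 || block_fraction > 1)
    stop("block_fraction must be a single number in [0, 1]")
  params[["g_kr"]] <- params[["g_kr"]] * (1 - block_fraction)
  params
}

#' One step of the state-dependent I_Kr block scheme
#'
#' Advances the bound fraction of the open-channel-block model by one
#' Forward-Euler step:
#' `b' = b + dt * (k_on * conc * p_open * (1 - b) - k_off * b)`,
#' and returns the effective `G_Kr` multiplier `1 - b'`.  With `p_open`
#' held at 1 the bound fraction relaxes to the closed-form steady state
#' `k_on*conc / (k_on*conc + k_off)`.
#'
#' @param open_probability instantaneous I_Kr open probability in `[0, 1]`.
#' @param bound_fraction_prev bound fraction before the step, in `[0, 1]`.
#' @param drug a [drug_spec()] with `mode = "state_dependent"`.
#' @param dt time step, ms.
#' @return A list with elements `multiplier` (effective G_Kr scale) and
#'   `bound_fraction` (after the step).
#' @export
state_dependent_gkr_factor <- function(open_probability, bound_fraction_prev,
                                       drug, dt) {
  stopifnot(inherits(drug, "drug_spec"))
  if (drug$mode != "state_dependent")
    stop("drug mode must be 'state_dependent'")
  if (any(open_probability < 0 | open_probability > 1))
    stop("open_probability must lie in [0, 1]")
  if (any(bound_fraction_prev < 0 | bound_fraction_prev > 1))
    stop("bound_fraction_prev must lie in [0, 1]")
  b <- bound_fraction_prev +
    dt * (drug$k_on * drug$concentration * open_probability *
            (1 - bound_fraction_prev) - drug$k_off * bound_fraction_prev)
  b <- pmin(1, pmax(0, b))
  list(multiplier = 1 - b, bound_fraction = b)
}
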