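#' Lumped-element model of the sensing aperture
#'
#' Describes the electrical environment of the sensing zone: the resistance of
#' the conducting fluid through the aperture constriction, in parallel with a
#' parasitic capacitance from the electrode separation, plus a small series
#' inductance that accounts for high-frequency lead effects. The geometry is a
#' square aperture of side `side_length`; the resistive sensing zone extends
#' axially over `sensing_length`.
#'
#' Defaults describe a 30 um x 30 um aperture in roughly physiological saline
#' (resistivity 0.625 ohm m, i.e. conductivity 1.6 S/m). `R_f` is derived from
#' the slab geometry as `sensing_length / (fluid_conductivity * side_length^2)`
#' unless supplied. The default parasitic capacitance is calibrated so the RC
#' corner `1/(2*pi*R_f*C_p)` of the empty cell sits at 2 MHz, the band in
#' which the phase deviation of a transiting dielectric bead is maximal.
#'
#' @param side_length Side of the square aperture (m).
#' @param sensing_length Axial extent of the sensing zone (m).
#' @param fluid_conductivity Conductivity of the suspending fluid (S/m).
#' @param eta_slab Fraction of `R_f` attributed to the bead-occupied slab,
#'   in (0, 1). The metal shell of a metallized bead can shunt this slab,
#'   which is what makes negative impedance pulses possible.
#' @param R_f Sensing-zone fluid resistance (ohm). Computed from geometry if
#'   `NULL`.
#' @param C_p Parasitic/electrode capacitance (F). Defaults to placing the RC
#'   corner at 2 MHz.
#' @param L_s Series parasitic inductance (H).
#' @return An object of class `aperture_model`.
#' @examples
#' ap <- aperture_model()
#' ap$R_f                      # ~20.8 kOhm
#' baseline_spectrum(ap, 45e3) # essentially resistive at 45 kHz
#' @export
aperture_model <- function(side_length = 30e-6,
                           sensing_length = 30e-6,
                           fluid_conductivity = 1.6,
                           eta_slab = 0.3,
                           R_f = NULL,
                           C_p = NULL,
                           L_s = 1e-6) {
  check_number(side_length, "side_length", 0, strict_lower = TRUE)
  check_number(sensing_length, "sensing_length", 0, strict_lower = TRUE)
  check_number(fluid_conductivity, "fluid_conductivity", 0, strict_lower = TRUE)
  check_number(eta_slab, "eta_slab", 0, strict_lower = TRUE)
  if (eta_slab >= 1) stop_domain("eta_slab must be < 1")
  if (is.null(R_f))
    R_f <- sensing_length / (fluid_conductivity * side_length^2)
  check_number(R_f, "R_f", 0, strict_lower = TRUE)
  if (is.null(C_p)) C_p <- 1 / (2 * pi * 2e6 * R_f)
  check_number(C_p, "C_p", 0)
  check_number(L_s, "L_s", 0)
  structure(list(side_length = side_length,
                 sensing_length = sensing_length,
                 fluid_conductivity = fluid_conductivity,
                 eta_slab = eta_slab,
                 R_f = R_f, C_p = C_p, L_s = L_s),
            class = "aperture_model")
}

#' @export
print.aperture_model <- function(x, ...) {
  cat("<aperture_model>\n")
  cat(sprintf("  square aperture %.1f um, sensing length %.1f um\n",
              x$side_length * 1e6, x$sensing_length * 1e6))
  cat(sprintf("  fluid %.3g S/m; R_f = %.4g Ohm (eta_slab = %.2f)\n",
              x$fluid_conductivity, x$R_f, x$eta_slab))
  cat(sprintf("  C_p = %.3g F, L_s = %.3g H; RC corner %.3g Hz\n",
              x$C_p, x$L_s, 1 / (2 * pi * x$R_f * x$C_p)))
  invisible(x)
}

# equal-area circular diameter of the square aperture
effective_diameter <- function(aperture) {
  2 * aperture$side_length / sqrt(pi)
}

#' Resistive-pulse amplitude of a nonconducting sphere (Coulter principle)
#'
#' DeBlois-Bean amplitude for a sphere of diameter `d` transiting an aperture
#' of effective circular diameter `D_eff` (the equal-area circle of the square
#' aperture) filled with fluid of resistivity `rho = 1/fluid_conductivity`:
#'
#' \deqn{\Delta R = \frac{4 \rho d^3}{\pi D_{eff}^4}
#'       \left[1 - 0.8 (d/D_{eff})^3\right]^{-1}}
#'
#' The bracketed factor is the usual finite-size correction; for
#' `d << D_eff` the amplitude scales as the displaced volume (`d^3`).
#'
#' @param diameter Bead diameter (m); must be smaller than the effective
#'   aperture diameter.
#' @param aperture An [aperture_model()].
#' @return Pulse amplitude in ohm (0 for `diameter = 0`).
#' @examples
#' coulter_delta_r(8.2e-6, aperture_model())  # ~338 Ohm
#' @export
coulter_delta_r <- function(diameter, aperture) {
  if (!is.numeric(diameter) || any(is.na(diameter)) || any(diameter < 0))
    stop_domain("diameter must be non-negative")
  Deff <- effective_diameter(aperture)
  if (any(diameter >= Deff))
    stop_domain("diameter must be smaller than the effective aperture diameter (",
                format(Deff), " m)")
  rho <- 1 / aperture$fluid_conductivity
  4 * rho * diameter^3 / (pi * Deff^4) / (1 - 0.8 * (diameter / Deff)^3)
}

#' Circuit description of a single bead
#'
#' Bundles the physical and circuit parameters of one bead. The resistive
#' amplitude `delta_R` follows [coulter_delta_r()]. A nonmetallized bead is a
#' dielectric sphere: it adds `delta_R` to the sensing-zone resistance and a
#' small capacitance `C_b` in parallel with the cell's parasitic capacitance.
#' A metallized bead additionally carries a shell branch - the nanostructured
#' silver film is modelled as a resistor `R_sh` in series with a
#' metal-electrolyte interface capacitance `C_sh`, in parallel with the
#' displaced-slab branch - whose parameters follow the metallization density
#' through [metallization_to_shell()].
#'
#' @param diameter Bead diameter (m).
#' @param m_density Metallization density in \[0, 1\]; 0 means nonmetallized.
#' @param aperture An [aperture_model()] (used to derive `delta_R` and the
#'   default shell calibration).
#' @param delta_R Resistive pulse amplitude (ohm); derived from the Coulter
#'   formula if `NULL`.
#' @param C_b Effective bead capacitance (F). The default, 1e-16 F, is the
#'   sub-femtofarad scale of an 8 um dielectric sphere (~ eps0*eps_r*d/2).
#' @param R0,C0 Shell calibration passed to [metallization_to_shell()].
#' @return An object of class `bead_model` with fields `diameter`, `kind`
#'   (`"nonmetallized"` or `"metallized"`), `delta_R`, `C_b`, `R_sh`, `C_sh`,
#'   `m_density`.
#' @examples
#' bead_model(8.2e-6, m_density = 0)     # nonmetallized: R_sh = Inf
#' bead_model(8.2e-6, m_density = 0.8)   # metallized shell
#' @export
bead_model <- function(diameter = 8.2e-6, m_density = 0,
                       aperture = aperture_model(),
                       delta_R = NULL, C_b = 1e-16,
                       R0 = NULL, C0 = 6e-11) {
  check_number(diameter, "diameter", 0, strict_lower = TRUE)
  if (diameter >= aperture$side_length)
    stop_domain("bead diameter must be smaller than the aperture side")
  check_number(m_density, "m_density", 0, upper = 1)
  if (is.null(delta_R)) delta_R <- coulter_delta_r(diameter, aperture)
  check_number(delta_R, "delta_R", 0, strict_lower = TRUE)
  check_number(C_b, "C_b", 0, strict_lower = TRUE)
  sh <- metallization_to_shell(m_density, aperture, R0 = R0, C0 = C0)
  structure(list(diameter = diameter,
                 kind = if (m_density == 0) "nonmetallized" else "metallized",
                 delta_R = delta_R, C_b = C_b,
                 R_sh = sh$R_sh, C_sh = sh$C_sh,
                 m_density = m_density),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> %.1f um %s", x$diameter * 1e6, x$kind))
  if (x$kind == "metallized")
    cat(sprintf(" (m = %.3f, R_sh = %.3g Ohm, C_sh = %.3g F)",
                x$m_density, x$R_sh, x$C_sh))
  cat(sprintf("; delta_R = %.3g Ohm\n", x$delta_R))
  invisible(x)
}

#' Map metallization density to shell circuit elements
#'
#' Monotone link from the metallization density `m` to the shell branch:
#' `R_sh = R0 / m` (the denser the silver film, the lower its resistance) and
#' `C_sh = C0 * m` (interface capacitance grows with covered area). At `m = 0`
#' the shell branch disappears (`R_sh = Inf`, `C_sh = 0`) and the bead is
#' electrically nonmetallized.
#'
#' @param m_density Metallization density in \[0, 1\].
#' @param aperture An [aperture_model()]; sets the default `R0`.
#' @param R0 Shell resistance at full metallization (ohm). Default
#'   `0.1 * eta_slab * R_f`, i.e. a fully metallized shell conducts ten times
#'   better than the fluid slab it displaces.
#' @param C0 Interface capacitance at full metallization (F). Default 60 pF,
#'   the electric double-layer scale (~20-30 uF/cm^2) over an 8 um bead.
#' @return List with `R_sh` and `C_sh`.
#' @export
metallization_to_shell <- function(m_density, aperture = aperture_model(),
                                   R0 = NULL, C0 = 6e-11) {
  check_number(m_density, "m_density", 0, upper = 1)
  if (is.null(R0)) R0 <- 0.1 * aperture$eta_slab * aperture$R_f
  check_number(R0, "R0", 0, strict_lower = TRUE)
  check_number(C0, "C0", 0, strict_lower = TRUE)
  if (m_density == 0) return(list(R_sh = Inf, C_sh = 0))
  list(R_sh = R0 / m_density, C_sh = C0 * m_density)
}

#' Baseline impedance spectrum of the empty sensing cell
#'
#' Empty-cell impedance at angular frequency `w = 2*pi*f`:
#' \deqn{Z_{base}(\omega) = j\omega L_s + \frac{R_f}{1 + j\omega R_f C_p}}
#' The magnitude is flat at `R_f` below the RC corner `1/(2*pi*R_f*C_p)` and
#' declines above it; the series inductance raises the phase back towards
#' positive values at very high frequency.
#'
#' @param aperture An [aperture_model()].
#' @param freqs Vector of frequencies (Hz), all positive.
#' @return Complex impedance (ohm), one value per frequency.
#' @examples
#' ap <- aperture_model(R_f = 1e4, C_p = 1e-11, L_s = 0)
#' corner <- 1 / (2 * pi * ap$R_f * ap$C_p)
#' Mod(baseline_spectrum(ap, corner)) / ap$R_f  # 1/sqrt(2)
#' @export
baseline_spectrum <- function(aperture, freqs) {
  if (!is.numeric(freqs) || any(is.na(freqs)) || any(freqs <= 0))
    stop_domain("freqs must be positive")
  w <- 2 * pi * freqs
  1i * w * aperture$L_s + aperture$R_f / (1 + 1i * w * aperture$R_f * aperture$C_p)
}

#' Series perturbation of the sensing zone by one bead
#'
#' The bead occupies a slab of the sensing zone carrying resistance
#' `R_slab = eta_slab * R_f`. With the bead present that slab becomes the
#' parallel combination of the displaced-fluid branch `R_slab + delta_R` and,
#' for a metallized bead, the shell branch `Z_sh = R_sh + 1/(j*w*C_sh)`:
#' \deqn{\Delta B(\omega) = (R_{slab} + \Delta R) \parallel Z_{sh}(\omega) - R_{slab}}
#' For a nonmetallized bead the shell branch is absent and
#' `DeltaB = delta_R` (real and positive) at every frequency. For a metallized
#' bead with `R_sh < R_slab` the shell shunts the slab once the interface
#' capacitance stops blocking, so `Re(DeltaB)` turns negative in a mid-frequency
#' band while remaining positive at sufficiently low frequency - the
#' frequency-specific negative pulse signature. Setting `C_sh = Inf`
#' (a purely conductive conformal layer) removes the block and makes
#' `Re(DeltaB)` negative at all frequencies.
#'
#' The bead capacitance `C_b` does not appear here: it acts in parallel with
#' the cell's parasitic capacitance and is applied by [total_impedance()].
#'
#' @param bead A [bead_model()].
#' @param aperture An [aperture_model()].
#' @param f Frequencies (Hz), positive.
#' @return Complex perturbation (ohm), one value per frequency.
#' @export
bead_element <- function(bead, aperture, f) {
  if (!is.numeric(f) || any(is.na(f)) || any(f <= 0))
    stop_domain("f must be positive")
  R_slab <- aperture$eta_slab * aperture$R_f
  R1 <- R_slab + bead$delta_R
  if (is.infinite(bead$R_sh) || bead$C_sh == 0)
    return(rep(complex(real = bead$delta_R), length(f)))
  w <- 2 * pi * f
  Z_sh <- if (is.infinite(bead$C_sh)) complex(real = rep(bead$R_sh, length(w)))
          else bead$R_sh + 1 / (1i * w * bead$C_sh)
  R1 * Z_sh / (R1 + Z_sh) - R_slab
}

#' Total cell impedance with a partially inserted bead
#'
#' Composes the full measured impedance for pulse-shape scalar `s` in
#' \[0, 1\] (0 = bead absent, 1 = bead centred in the sensing zone):
#' \deqn{Z(\omega, s) = j\omega L_s + \left(R_f + s\,\Delta B(\omega)\right)
#'       \parallel \frac{1}{j\omega (C_p + s\,C_b)}}
#' `s = 0` reproduces [baseline_spectrum()] exactly.
#'
#' @param aperture An [aperture_model()].
#' @param bead_element_value Complex perturbation from [bead_element()]
#'   (recycled against `f`).
#' @param s Pulse-shape scalar in \[0, 1\].
#' @param f Frequencies (Hz).
#' @param C_b Bead capacitance (F) applied at the outer node; default 0.
#' @return Complex impedance (ohm) per frequency.
#' @export
total_impedance <- function(aperture, bead_element_value, s, f, C_b = 0) {
  if (!is.numeric(s) || any(is.na(s)) || any(s < 0) || any(s > 1))
    stop_domain("s must lie in [0, 1]")
  if (!is.numeric(f) || any(is.na(f)) || any(f <= 0))
    stop_domain("f must be positive")
  w <- 2 * pi * f
  inner <- aperture$R_f + s * bead_element_value
  C <- aperture$C_p + s * C_b
  # parallel(inner, 1/(jwC)) = inner / (1 + jwC*inner); exact also at C = 0
  1i * w * aperture$L_s + inner / (1 + 1i * w * C * inner)
}

#' Noise-free peak response of a bead at each carrier frequency
#'
#' Convenience wrapper returning the peak changes a centred bead (`s = 1`)
#' produces relative to the empty cell: `dZp = |Z(s=1)| - |Z_base|` (ohm) and
#' `dPhip = arg Z(s=1) - arg Z_base` (degrees), per frequency. These are the
#' quantities the pulse-detection stage recovers from the synthesized
#' waveforms in the absence of noise.
#'
#' @param bead A [bead_model()].
#' @param aperture An [aperture_model()].
#' @param freqs Frequencies (Hz).
#' @return List with numeric vectors `dZp` and `dPhip`.
#' @export
bead_peak_response <- function(bead, aperture, freqs) {
  z0 <- baseline_spectrum(aperture, freqs)
  z1 <- total_impedance(aperture, bead_element(bead, aperture, freqs),
                        s = 1, f = freqs, C_b = bead$C_b)
  list(dZp = Mod(z1) - Mod(z0),
       dPhip = (Arg(z1) - Arg(z0)) * 180 / pi)
}

#' Acquisition settings of the multifrequency lock-in emulation
#'
#' @param sample_rate Samples per second (default 57000).
#' @param freqs Strictly increasing vector of the 6 carrier frequencies (Hz);
#'   default 45 kHz, 150 kHz, 380 kHz, 2 MHz, 11 MHz, 35 MHz.
#' @param duration Trace length (s).
#' @param noise_sd_mag Gaussian noise sd on magnitude channels (ohm).
#' @param noise_sd_phase Gaussian noise sd on phase channels (degrees).
#' @param drift_amp Amplitude of the slow sinusoidal baseline drift added to
#'   magnitude channels (ohm).
#' @param drift_freq Drift frequency (Hz); much slower than a transit.
#' @param seed Integer seed controlling all randomness of the synthesis.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sample_rate = 57000,
                               freqs = c(45e3, 150e3, 380e3, 2e6, 11e6, 35e6),
                               duration = 2,
                               noise_sd_mag = 10,
                               noise_sd_phase = 0.5,
                               drift_amp = 100,
                               drift_freq = 1,
                               seed = 1L) {
  check_number(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  if (!is.numeric(freqs) || length(freqs) != 6L || any(diff(freqs) <= 0) ||
      any(freqs <= 0))
    stop_domain("freqs must be 6 strictly increasing positive frequencies")
  check_number(duration, "duration", 0, strict_lower = TRUE)
  check_number(noise_sd_mag, "noise_sd_mag", 0)
  check_number(noise_sd_phase, "noise_sd_phase", 0)
  check_number(drift_amp, "drift_amp", 0)
  check_number(drift_freq, "drift_freq", 0, strict_lower = TRUE)
  structure(list(sample_rate = sample_rate, freqs = freqs,
                 duration = duration, noise_sd_mag = noise_sd_mag,
                 noise_sd_phase = noise_sd_phase, drift_amp = drift_amp,
                 drift_freq = drift_freq, seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Saturable link from probe concentration to mean metallization density
#'
#' Four-parameter-logistic-shaped binding curve mapping probe concentration
#' (nM) to the mean per-bead metallization density:
#' `m(c) = floor + (ceiling - floor) * c^h / (c50^h + c^h)`.
#' `m(0) = floor` (background metallization) and `m -> ceiling` as
#' `c -> Inf`; at `c = c50` the curve sits exactly halfway.
#'
#' @param conc Probe concentration (nM), non-negative.
#' @param binding_params List with `floor`, `ceiling` (both in \[0, 1\]),
#'   `c50` (nM, > 0) and `hill` (> 0).
#' @return Mean metallization density in \[0, 1\].
#' @export
dose_to_metallization <- function(conc,
                                  binding_params = list(floor = 0.01,
                                                        ceiling = 0.85,
                                                        c50 = 30, hill = 1.2)) {
  if (!is.numeric(conc) || any(is.na(conc)) || any(conc < 0))
    stop_domain("conc must be non-negative")
  p <- binding_params
  stopifnot(p$floor >= 0, p$ceiling <= 1, p$floor <= p$ceiling,
            p$c50 > 0, p$hill > 0)
  frac <- ifelse(conc == 0, 0, conc^p$hill / (p$c50^p$hill + conc^p$hill))
  p$floor + (p$ceiling - p$floor) * frac
}

#' Specification of one synthetic assay trial
#'
#' @param n_beads Number of bead transits (default 60, the per-trial
#'   aggregate used throughout).
#' @param probe_concentration Probe concentration (nM) driving the mean
#'   metallization via [dose_to_metallization()].
#' @param binding_params Binding-curve parameters, see
#'   [dose_to_metallization()].
#' @param heterogeneity_sd Log-scale sd of the per-bead lognormal
#'   metallization spread (default 0.6); draws are mean-preserving and then
#'   clipped to \[0, 1\].
#' @param bead_diameter Bead diameter (m), default 8.2 um.
#' @param tau Pulse full width at half maximum (s). The default 2e-4 s is the
#'   transit time of the ~38 um sensing region at 10 uL/min through the
#'   30 um x 30 um aperture.
#' @param amp_scale_sd Sd of the multiplicative pulse-height factor modelling
#'   off-centre transits (mean 1, clipped to (0, 1.2\]).
#' @param min_spacing Minimum separation between pulse apexes (s); default
#'   `10 * tau`.
#' @param seed Integer seed for the per-trial draws.
#' @return Object of class `trial_spec`.
#' @export
trial_spec <- function(n_beads = 60,
                       probe_concentration = 0,
                       binding_params = list(floor = 0.01, ceiling = 0.85,
                                             c50 = 30, hill = 1.2),
                       heterogeneity_sd = 0.6,
                       bead_diameter = 8.2e-6,
                       tau = 2e-4,
                       amp_scale_sd = 0.05,
                       min_spacing = 10 * tau,
                       seed = 1L) {
  check_number(n_beads, "n_beads", 1)
  check_number(probe_concentration, "probe_concentration", 0)
  check_number(heterogeneity_sd, "heterogeneity_sd", 0)
  check_number(bead_diameter, "bead_diameter", 0, strict_lower = TRUE)
  check_number(tau, "tau", 0, strict_lower = TRUE)
  check_number(amp_scale_sd, "amp_scale_sd", 0)
  check_number(min_spacing, "min_spacing", 0)
  structure(list(n_beads = as.integer(n_beads),
                 probe_concentration = probe_concentration,
                 binding_params = binding_params,
                 heterogeneity_sd = heterogeneity_sd,
                 bead_diameter = bead_diameter,
                 tau = tau, amp_scale_sd = amp_scale_sd,
                 min_spacing = min_spacing, seed = as.integer(seed)),
            class = "trial_spec")
}

# draw per-bead metallization densities: mean-preserving lognormal, clipped
draw_m_density <- function(n, m_mean, sdlog) {
  if (m_mean == 0 || sdlog == 0) return(rep(m_mean, n))
  pmin(1, pmax(0, m_mean * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)))
}

# Place n apex times in [margin, duration - margin] with minimum spacing,
# drawn from the exact uniform distribution conditional on the spacing:
# n uniforms in the slack interval, sorted, plus the mandatory gaps.
place_events <- function(n, duration, min_spacing, margin) {
  lo <- margin
  hi <- duration - margin
  slack <- (hi - lo) - (n - 1) * min_spacing
  if (slack < 0)
    stop_domain("cannot place ", n, " events with spacing ", min_spacing,
                " s in ", duration, " s; increase the trial duration")
  lo + sort(runif(n, 0, slack)) + (seq_len(n) - 1) * min_spacing
}

#' Synthesize a multifrequency trial waveform
#'
#' Forward-simulates the magnitude and phase traces of one assay trial.
#' Per-bead metallization densities are drawn lognormally around
#' [dose_to_metallization()] and clipped to \[0, 1\]; apex times are placed
#' uniformly at random subject to a minimum spacing; each transit follows a
#' symmetric Gaussian bell `s(t) = exp(-(t - t0)^2 / (2 * (tau/2.355)^2))`
#' (FWHM = `tau`), scaled by the off-centre factor, and the instantaneous
#' magnitude/phase at each carrier follow [total_impedance()] evaluated at
#' `s(t)`. Gaussian noise is added per channel, and a slow sinusoidal drift
#' is added to the magnitude channels. All randomness derives from
#' `spec$seed` and `config$seed`; the function does not touch the caller's
#' RNG state.
#'
#' @param spec A [trial_spec()].
#' @param aperture An [aperture_model()].
#' @param config An [acquisition_config()].
#' @return List with `ts`, a `multifreq_ts` object (fields `t`, `mag`,
#'   `phase`, `config`), and `truth`, a data frame of ground-truth events
#'   (`t0`, `tau`, `diameter_um`, `m_density`, `kind`, `amp_scale`).
#' @examples
#' tr <- synthesize_trial(trial_spec(n_beads = 3, seed = 7),
#'                        aperture_model(),
#'                        acquisition_config(duration = 0.2, seed = 7))
#' nrow(tr$truth)
#' @export
synthesize_trial <- function(spec, aperture = aperture_model(),
                             config = acquisition_config()) {
  stopifnot(inherits(spec, "trial_spec"),
            inherits(aperture, "aperture_model"),
            inherits(config, "acquisition_config"))
  fs <- config$sample_rate
  n <- floor(config$duration * fs)
  t <- (seq_len(n) - 1) / fs
  freqs <- config$freqs
  nf <- length(freqs)
  z0 <- baseline_spectrum(aperture, freqs)
  sigma <- spec$tau / 2.355
  margin <- max(0.05 * config$duration, 6 * sigma)

  with_seed(spec$seed + 1000L * config$seed, {
    m_mean <- dose_to_metallization(spec$probe_concentration,
                                    spec$binding_params)
    m <- draw_m_density(spec$n_beads, m_mean, spec$heterogeneity_sd)
    t0 <- place_events(spec$n_beads, config$duration, spec$min_spacing, margin)
    amp <- pmin(1.2, pmax(1e-3, 1 + rnorm(spec$n_beads, 0, spec$amp_scale_sd)))

    mag <- matrix(rep(Mod(z0), each = n), n, nf)
    phase <- matrix(rep(Arg(z0) * 180 / pi, each = n), n, nf)
    beads <- lapply(m, function(mi)
      bead_model(spec$bead_diameter, m_density = mi, aperture = aperture))

    for (b in seq_len(spec$n_beads)) {
      bead <- beads[[b]]
      dB <- bead_element(bead, aperture, freqs)
      i0 <- round(t0[b] * fs) + 1L
      half <- ceiling(5 * sigma * fs)
      idx <- max(1L, i0 - half):min(n, i0 + half)
      s <- exp(-(t[idx] - t0[b])^2 / (2 * sigma^2))
      for (k in seq_len(nf)) {
        zk <- total_impedance(aperture, dB[k], s, freqs[k], C_b = bead$C_b)
        mag[idx, k] <- mag[idx, k] + amp[b] * (Mod(zk) - Mod(z0[k]))
        phase[idx, k] <- phase[idx, k] +
          amp[b] * (Arg(zk) - Arg(z0[k])) * 180 / pi
      }
    }

    if (config$drift_amp > 0) {
      ph0 <- runif(nf, 0, 2 * pi)
      for (k in seq_len(nf))
        mag[, k] <- mag[, k] +
          config$drift_amp * sin(2 * pi * config$drift_freq * t + ph0[k])
    }
    if (config$noise_sd_mag > 0)
      mag <- mag + matrix(rnorm(n * nf, 0, config$noise_sd_mag), n, nf)
    if (config$noise_sd_phase > 0)
      phase <- phase + matrix(rnorm(n * nf, 0, config$noise_sd_phase), n, nf)

    truth <- data.frame(t0 = t0, tau = spec$tau,
                        diameter_um = spec$bead_diameter * 1e6,
                        m_density = m,
                        kind = vapply(beads, `[[`, "", "kind"),
                        amp_scale = amp)
  })

  ts <- structure(list(t = t, mag = mag, phase = phase, config = config),
                  class = "multifreq_ts")
  list(ts = ts, truth = truth)
}

#' @export
print.multifreq_ts <- function(x, ...) {
  cat(sprintf("<multifreq_ts> %d samples at %g Hz (%.3g s), carriers: %s\n",
              length(x$t), x$config$sample_rate,
              length(x$t) / x$config$sample_rate,
              paste(freq_label(x$config$freqs), collapse = ", ")))
  invisible(x)
}

#' Simulate per-bead peak records directly (no waveform)
#'
#' Fast path that skips waveform synthesis and pulse detection: for each bead
#' it evaluates the noise-free peak response via [bead_peak_response()] and
#' adds per-channel Gaussian measurement noise at the acquisition noise
#' levels. Useful for gating and metric studies where the detector itself is
#' not under test; [synthesize_trial()] plus the pulse stage is the faithful
#' route.
#'
#' @inheritParams synthesize_trial
#' @return List with `records` (a bead-record data frame as produced by
#'   [extract_bead_records()]) and `truth` (per-bead metallization
#'   densities).
#' @export
simulate_bead_records <- function(spec, aperture = aperture_model(),
                                  config = acquisition_config()) {
  stopifnot(inherits(spec, "trial_spec"))
  freqs <- config$freqs
  with_seed(spec$seed + 1000L * config$seed, {
    m_mean <- dose_to_metallization(spec$probe_concentration,
                                    spec$binding_params)
    m <- draw_m_density(spec$n_beads, m_mean, spec$heterogeneity_sd)
    amp <- pmin(1.2, pmax(1e-3, 1 + rnorm(spec$n_beads, 0, spec$amp_scale_sd)))
    resp <- vapply(seq_along(m), function(b) {
      bead <- bead_model(spec$bead_diameter, m_density = m[b],
                         aperture = aperture)
      r <- bead_peak_response(bead, aperture, freqs)
      c(r$dZp, r$dPhip)
    }, numeric(2 * length(freqs)))
    resp <- t(resp)
    resp[, seq_along(freqs)] <- resp[, seq_along(freqs)] * amp
    resp[, length(freqs) + seq_along(freqs)] <-
      resp[, length(freqs) + seq_along(freqs)] * amp
    noise <- cbind(matrix(rnorm(length(m) * length(freqs), 0, config$noise_sd_mag),
                          ncol = length(freqs)),
                   matrix(rnorm(length(m) * length(freqs), 0, config$noise_sd_phase),
                          ncol = length(freqs)))
    resp <- resp + noise
  })
  lab <- freq_label(freqs)
  records <- data.frame(timestamp = seq_along(m) / spec$n_beads)
  for (k in seq_along(freqs)) records[[paste0("dZp_", lab[k])]] <- resp[, k]
  for (k in seq_along(freqs))
    records[[paste0("dPhi_", lab[k])]] <- resp[, length(freqs) + k]
  records$gate <- "ungated"
  list(records = records, truth = data.frame(m_density = m, amp_scale = amp))
}
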