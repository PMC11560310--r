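#' Synthetic slow-exchange peak-volume table
#'
#' Generates per-temperature (cis, trans) peak volumes for a set of
#' residues obeying a two-state equilibrium with the given enthalpy and
#' entropy differences: V_cis / V_trans = K(T) =
#' exp(-(dH - T dS)/(R T)), optionally perturbed by multiplicative
#' log-normal noise.  With zero noise the table round-trips through
#' \code{\link{cisPopulation}} and \code{\link{vantHoffFit}} to the
#' generating parameters at machine precision.
#'
#' @param dH enthalpy difference in J/mol.
#' @param dS entropy difference in J/(K mol).
#' @param temperatures kelvin, within 270-320 K.
#' @param residues residue labels.
#' @param noiseSD standard deviation of the log-normal multiplicative
#'   noise (0 = noiseless).
#' @param vTrans trans peak volume (arbitrary units).
#' @param seed random seed (used when noiseSD > 0).
#' @return data.frame with columns \code{residue}, \code{isomer},
#'   \code{temperature}, \code{volume}, \code{height} (heights mirror
#'   volumes).
#' @export
peakVolumeTable <- function(dH, dS, temperatures, residues = c("E55", "Q56",
                                                               "E59"),
                            noiseSD = 0, vTrans = 100, seed = 1L) {
  if (any(temperatures < 270 | temperatures > 320))
    stop("temperatures must lie within 270-320 K")
  K <- exp(-(dH - temperatures * dS) / (.RGAS * temperatures))
  gen <- function() {
    rows <- list()
    for (r in residues) for (i in seq_along(temperatures)) {
      noise <- if (noiseSD > 0) exp(stats::rnorm(2, 0, noiseSD)) else c(1, 1)
      vc <- vTrans * K[i] * noise[1]
      vt <- vTrans * noise[2]
      rows[[length(rows) + 1]] <- data.frame(
        residue = r, isomer = c("cis", "trans"),
        temperature = temperatures[i], volume = c(vc, vt),
        height = c(vc, vt))
    }
    do.call(rbind, rows)
  }
  if (noiseSD > 0) .withSeed(seed, gen()) else gen()
}

#' Synthetic monoexponential relaxation decay
#'
#' I(t) = I0 exp(-rate t) with optional Gaussian noise, emulating the
#' per-delay intensity tables of R1/R1rho relaxation experiments.
#'
#' @param rate decay rate in s^-1.
#' @param delays delay times in s.
#' @param I0 initial intensity.
#' @param noiseSD relative Gaussian noise level (fraction of I0).
#' @param seed random seed.
#' @return data.frame with columns \code{delay}, \code{intensity},
#'   \code{sigma}.
#' @export
relaxationDecayTable <- function(rate, delays, I0 = 100, noiseSD = 0,
                                 seed = 1L) {
  I <- I0 * exp(-rate * delays)
  sig <- rep(noiseSD * I0, length(delays))
  if (noiseSD > 0)
    I <- .withSeed(seed, I + stats::rnorm(length(I), 0, noiseSD * I0))
  data.frame(delay = delays, intensity = I,
             sigma = if (noiseSD > 0) sig else NA_real_)
}

#' Synthetic Stejskal-Tanner diffusion decay
#'
#' I(g) = I0 exp(-D gamma^2 g^2 delta^2 (Delta - delta/3)), the pulsed
#' field gradient echo attenuation, with optional relative Gaussian noise.
#'
#' @param D diffusion coefficient in m^2/s.
#' @param gradients gradient strengths in T/m, nonnegative increasing.
#' @param delta gradient pulse length in s (default 4 ms).
#' @param Delta diffusion delay in s (default 200 ms).
#' @param gamma gyromagnetic ratio in rad s^-1 T^-1 (default 1H).
#' @param I0 initial intensity.
#' @param noiseSD relative Gaussian noise level.
#' @param seed random seed.
#' @return data.frame with columns \code{gradient}, \code{intensity},
#'   \code{sigma}, and attributes \code{delta}, \code{Delta},
#'   \code{gamma}.
#' @export
dosyDecayTable <- function(D, gradients, delta = 0.004, Delta = 0.2,
                           gamma = 2.6752218744e8, I0 = 100, noiseSD = 0,
                           seed = 1L) {
  stopifnot(all(gradients >= 0), !is.unsorted(gradients), Delta > delta / 3)
  b <- gamma^2 * gradients^2 * delta^2 * (Delta - delta / 3)
  I <- I0 * exp(-D * b)
  if (noiseSD > 0)
    I <- .withSeed(seed, I + stats::rnorm(length(I), 0, noiseSD * I0))
  out <- data.frame(gradient = gradients, intensity = I,
                    sigma = if (noiseSD > 0) rep(noiseSD * I0,
                                                 length(gradients))
                            else NA_real_)
  attr(out, "delta") <- delta
  attr(out, "Delta") <- Delta
  attr(out, "gamma") <- gamma
  out
}
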