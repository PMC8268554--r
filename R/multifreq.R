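# Two-frequency separation of the direct temperature contribution from the
# perfusion contribution to the reconstructed conductivity change.
#
# With dsigma = Tc dT + alpha (sqrt(omega) - 1)(1 + Tc dT) and alpha known at
# two frequencies, the weighted difference
#   dsigma_LF - (aLF/aHF) dsigma_HF = (1 - aLF/aHF) Tc dT
# isolates the temperature term, while the plain difference
#   dsigma_LF - dsigma_HF = (aLF - aHF)(sqrt(omega) - 1)(1 + Tc dT)
# isolates the perfusion term.

#' Temperature change from two-frequency reconstructions
#'
#' @param delta_sigma_lf,delta_sigma_hf fractional conductivity changes per
#'   element at the low and high frequency (relative to the unheated
#'   baseline).
#' @param alpha_lf,alpha_hf plasma volume fractions at the two frequencies
#'   (must differ; `alpha_hf > 0`).
#' @param tc temperature coefficient (fraction per C).
#' @return per-element temperature change (C).
#' @export
#' @examples
#' separate_temperature(0.10, 0.10)  # pure-temperature case: 5 C
separate_temperature <- function(delta_sigma_lf, delta_sigma_hf,
                                 alpha_lf = 0.24, alpha_hf = 0.08,
                                 tc = 0.02) {
  if (alpha_lf == alpha_hf) stop("alpha_lf and alpha_hf must differ")
  stopifnot(alpha_hf > 0, tc > 0,
            length(delta_sigma_lf) == length(delta_sigma_hf))
  r <- alpha_lf / alpha_hf
  (delta_sigma_lf - r * delta_sigma_hf) / ((1 - r) * tc)
}

#' Relative perfusion from two-frequency reconstructions
#'
#' `sqrt(omega) - 1 = (dsigma_LF - dsigma_HF) / ((aLF - aHF)(1 + Tc dT))`.
#' The temperature term can come from [separate_temperature()] (default
#' pipeline), from a simulation, or be neglected (`delta_T = NULL`).
#' Noise-induced negative radicands are floored at `omega = 0` and flagged
#' via the `"floored"` attribute.
#'
#' @inheritParams separate_temperature
#' @param delta_T per-element temperature change used in the `1 + Tc dT`
#'   factor, or `NULL` to neglect it.
#' @param sqrt_omega if `FALSE`, read the perfusion term as `omega - 1`
#'   without the vessel cross-section square root.
#' @return per-element relative perfusion `omega`.
#' @export
separate_perfusion <- function(delta_sigma_lf, delta_sigma_hf,
                               alpha_lf = 0.24, alpha_hf = 0.08, tc = 0.02,
                               delta_T = NULL, sqrt_omega = TRUE) {
  if (alpha_lf == alpha_hf) stop("alpha_lf and alpha_hf must differ")
  stopifnot(length(delta_sigma_lf) == length(delta_sigma_hf))
  fac <- if (is.null(delta_T)) 1 else 1 + tc * delta_T
  if (any(fac <= 0, na.rm = TRUE))
    stop("1 + Tc * delta_T must be positive")
  s <- (delta_sigma_lf - delta_sigma_hf) / ((alpha_lf - alpha_hf) * fac)
  root <- 1 + s
  floored <- which(root < 0)
  root <- pmax(root, 0)
  out <- if (sqrt_omega) root^2 else root
  attr(out, "floored") <- floored
  out
}
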