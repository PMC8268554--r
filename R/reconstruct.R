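# Iterative Gauss-Newton difference imaging with reference-model updating,
# prior regions / penalties and the adaptive (1 + 1 + 3) prior-region scheme.

#' Reconstruction configuration
#'
#' Settings for [eit_reconstruct()].
#'
#' @param lambda regularization hyperparameter (> 0).
#' @param penalty `"tid"` (tissue-dependent), `"fixed"` (constant
#'   `base_penalty` inside the prior region) or `"none"` (penalty 1
#'   everywhere).
#' @param base_penalty penalty value inside the prior region (the strict
#'   value; also the muscle anchor of the tissue-dependent form).
#' @param prior_mask logical per-element prior region, or `NULL` for none.
#' @param n_iterations Gauss-Newton iterations (>= 1; the reference model is
#'   updated and the Jacobian recomputed each iteration unless
#'   `frozen_jacobian`).
#' @param positivity zero negative accumulated conductivity changes before
#'   each iteration.
#' @param smoothing_radius Gaussian radius (m) used for adaptive-mask
#'   extraction and, when `smooth_output`, for the final change map.
#' @param smooth_output apply the Gaussian filter to the returned change map.
#' @param adaptive use the adaptive prior-region scheme (1 iteration without
#'   prior, 1 with the thresholded mask at `relaxed_penalty`, then 3 with the
#'   refined mask at `base_penalty`; 5 inverse solves in total).
#' @param adaptive_threshold mask threshold as a fraction of the maximum
#'   absolute smoothed change.
#' @param relaxed_penalty penalty of the intermediate adaptive stage.
#' @param frozen_jacobian reuse the first iteration's Jacobian (cheaper, less
#'   accurate).
#' @return list of class `recon_config`.
#' @export
recon_config <- function(lambda = 0.01,
                         penalty = c("tid", "fixed", "none"),
                         base_penalty = 0.001, prior_mask = NULL,
                         n_iterations = 3L, positivity = FALSE,
                         smoothing_radius = 0.01, smooth_output = FALSE,
                         adaptive = FALSE, adaptive_threshold = 0.25,
                         relaxed_penalty = 0.1, frozen_jacobian = FALSE) {
  penalty <- match.arg(penalty)
  stopifnot(lambda > 0, base_penalty > 0, n_iterations >= 1L,
            relaxed_penalty > 0, adaptive_threshold > 0,
            adaptive_threshold < 1, smoothing_radius >= 0)
  structure(list(lambda = lambda, penalty = penalty,
                 base_penalty = base_penalty, prior_mask = prior_mask,
                 n_iterations = as.integer(n_iterations),
                 positivity = positivity,
                 smoothing_radius = smoothing_radius,
                 smooth_output = smooth_output, adaptive = adaptive,
                 adaptive_threshold = adaptive_threshold,
                 relaxed_penalty = relaxed_penalty,
                 frozen_jacobian = frozen_jacobian),
            class = "recon_config")
}

# penalty vector for one iteration: 1 outside the prior region, the selected
# penalty form inside; "none" ignores the mask
penalty_vector <- function(config, mask, sigma_ref, labels, base, table) {
  n <- length(sigma_ref)
  pen <- rep(1, n)
  if (config$penalty == "none" || is.null(mask)) return(pen)
  inside <- which(mask)
  if (!length(inside)) return(pen)
  if (config$penalty == "fixed") {
    pen[inside] <- base
  } else {
    pen[inside] <- tissue_dependent_penalty(sigma_ref, labels, base,
                                            table)[inside]
  }
  pen
}

#' Reconstruct conductivity changes by iterative difference imaging
#'
#' Fits the conductivity-change map that explains the voltage difference
#' between a reference frame `vref` and a changed-state frame `v`, by
#' repeated linearized Gauss-Newton steps: at each iteration the forward
#' problem and the adjoint Jacobian are recomputed at the current
#' conductivity estimate, a regularized one-step update is taken, and the
#' reference model is updated. With `config$adaptive`, a prior-region mask is
#' derived from an initial unconstrained reconstruction, refined once under a
#' relaxed penalty, and then used for three strict-penalty iterations.
#'
#' @param mesh an `eit_mesh` with electrodes placed and labels set.
#' @param vref reference `eit_frame` (pre-heating state).
#' @param v `eit_frame` of the changed (heated) state.
#' @param sigma_ref per-element reference conductivity (S/m), consistent with
#'   `vref`.
#' @param config a [recon_config()].
#' @param table tissue table (for the tissue-dependent penalty).
#' @return object of class `eit_recon` with elements `delta_sigma` (S/m),
#'   `delta_pct` (% of the reference conductivity; `NA` where the reference
#'   is 0), `sigma` (final conductivity), `residuals` (per-iteration mean and
#'   sd of the absolute voltage misfit entering the iteration), `masks`
#'   (prior masks used per iteration), `diverged` flag and the configuration.
#' @seealso [recon_config()], [one_step_gn()], [tissue_dependent_penalty()]
#' @export
eit_reconstruct <- function(mesh, vref, v, sigma_ref,
                            config = recon_config(),
                            table = tissue_table()) {
  stopifnot(inherits(config, "recon_config"),
            length(sigma_ref) == nrow(mesh$tets),
            length(v$values) == length(vref$values))
  pattern <- v$pattern
  labels <- mesh$labels
  n_it <- if (config$adaptive) 5L else config$n_iterations
  sigma_t <- sigma_ref
  J <- NULL
  res_mean <- res_sd <- numeric(0)
  masks <- list()
  mask_t <- if (config$adaptive) NULL else config$prior_mask
  mask_stage1 <- mask_stage2 <- NULL
  diverged <- FALSE
  grew <- 0L
  for (t in seq_len(n_it)) {
    if (config$positivity)
      sigma_t <- sigma_ref + positivity_constraint(sigma_t - sigma_ref)
    if (is.null(J) || !config$frozen_jacobian) {
      sol <- compute_jacobian(mesh, sigma_t, pattern)
      J <- sol$J
      v_model <- sol$frame$values
    } else {
      v_model <- solve_forward(mesh, sigma_t, pattern)$values
    }
    y <- v$values - v_model
    res_mean <- c(res_mean, mean(abs(y)))
    res_sd <- c(res_sd, stats::sd(abs(y)))
    if (t >= 3L && res_mean[t] > res_mean[t - 1L]) {
      grew <- grew + 1L
      if (grew >= 2L) { diverged <- TRUE; break }
    } else grew <- 0L
    base <- if (config$adaptive && t == 2L) config$relaxed_penalty else
      config$base_penalty
    pen <- penalty_vector(config, mask_t, sigma_ref, labels, base, table)
    R <- regularization_matrix(J, pen)
    xhat <- one_step_gn(J, y, config$lambda, R)
    sigma_t <- pmax(sigma_t + xhat, 0)
    masks[[t]] <- mask_t
    if (config$adaptive && t <= 2L) {
      ds <- smooth_field(sigma_t - sigma_ref, mesh, config$smoothing_radius)
      thr <- config$adaptive_threshold * max(abs(ds))
      mk <- abs(ds) > thr
      if (!any(mk)) {
        warning("adaptive mask empty after thresholding; ",
                "falling back to whole-domain prior")
        mk <- rep(TRUE, length(ds))
      }
      if (t == 1L) mask_stage1 <- mk else mask_stage2 <- mk
      mask_t <- mk
    }
  }
  delta <- sigma_t - sigma_ref
  if (config$smooth_output && config$smoothing_radius > 0)
    delta <- smooth_field(delta, mesh, config$smoothing_radius)
  structure(list(
    delta_sigma = delta,
    delta_pct = ifelse(sigma_ref > 0, 100 * delta / sigma_ref, NA_real_),
    sigma = sigma_ref + delta,
    sigma_ref = sigma_ref,
    residuals = data.frame(iteration = seq_along(res_mean),
                           mean_abs = res_mean, sd_abs = res_sd),
    fitted_voltages = v_model,
    masks = masks,
    adaptive_masks = list(stage1 = mask_stage1, stage2 = mask_stage2),
    diverged = diverged,
    n_solves = length(res_mean),
    config = config,
    mesh = mesh,
    call = match.call()), class = "eit_recon")
}

#' @export
print.eit_recon <- function(x, ...) {
  cat("EIT difference-imaging reconstruction\n")
  cat("  elements:", length(x$delta_sigma),
      " iterations (inverse solves):", x$n_solves,
      if (x$diverged) " [stopped: residual diverged]" else "", "\n")
  cat("  lambda:", x$config$lambda, " penalty:", x$config$penalty,
      if (x$config$adaptive) "(adaptive prior)" else "", "\n")
  r <- x$residuals
  cat("  |dv| residual (mean):",
      paste(signif(r$mean_abs, 3), collapse = " -> "), "V\n")
  q <- stats::quantile(x$delta_pct[is.finite(x$delta_pct)],
                       c(0, 0.5, 1))
  cat("  delta sigma (% of reference): min ", signif(q[1], 3), ", median ",
      signif(q[2], 3), ", max ", signif(q[3], 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.eit_recon <- function(object, ...) {
  d <- object$delta_pct[is.finite(object$delta_pct)]
  out <- list(residuals = object$residuals,
              delta_pct = summary(d),
              n_elements = length(object$delta_sigma),
              n_solves = object$n_solves,
              diverged = object$diverged,
              config = object$config)
  class(out) <- "summary.eit_recon"
  out
}

#' @export
print.summary.eit_recon <- function(x, ...) {
  cat("Iterative difference-imaging reconstruction (", x$n_solves,
      " inverse solves", if (x$diverged) ", diverged" else "", ")\n", sep = "")
  cat("Per-iteration |dv| residual:\n")
  print(x$residuals, row.names = FALSE)
  cat("Reconstructed change (% of reference conductivity):\n")
  print(x$delta_pct)
  invisible(x)
}

#' @export
coef.eit_recon <- function(object, ...) object$delta_sigma

#' @export
residuals.eit_recon <- function(object, ...) object$residuals

#' @export
fitted.eit_recon <- function(object, ...) object$fitted_voltages

#' Predict temperature change from a reconstruction
#'
#' Converts the reconstructed fractional conductivity change to a temperature
#' change by inverting the conductivity-temperature model (see
#' [temperature_from_conductivity()]).
#'
#' @param object an `eit_recon`.
#' @param model a [conductivity_change_model()].
#' @param omega_curve optional perfusion-temperature function (see
#'   [temperature_from_conductivity()]); `NULL` inverts the pure
#'   temperature-coefficient relation.
#' @param ... unused.
#' @return per-element temperature change (degrees C; `NA` where the
#'   reference conductivity is 0).
#' @export
predict.eit_recon <- function(object, model = conductivity_change_model(),
                              omega_curve = NULL, ...) {
  frac <- object$delta_pct / 100
  out <- rep(NA_real_, length(frac))
  ok <- is.finite(frac)
  out[ok] <- temperature_from_conductivity(frac[ok], model, omega_curve)
  out
}

#' @export
plot.eit_recon <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  r <- x$residuals
  graphics::plot(r$iteration, r$mean_abs, type = "b", log = "y",
                 xlab = "iteration", ylab = "mean |dv| (V)",
                 main = "Voltage residual", ...)
  d <- x$delta_pct[is.finite(x$delta_pct)]
  graphics::hist(d, breaks = 40, xlab = "delta sigma (%)",
                 main = "Reconstructed change")
  invisible(x)
}
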