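# Thermophysiology: Pennes bioheat simulation with temperature-dependent
# perfusion, the conductivity-change model coupling temperature and perfusion
# to tissue conductivity at two frequencies, and its inverse.

BLOOD_RHO <- 1050    # kg/m^3
BLOOD_C <- 3617      # J/(kg C)

#' Temperature-dependent perfusion model
#'
#' Relative perfusion `omega(T)` is 1 up to a vasodilation onset
#' temperature, rises piecewise-linearly to `omega_max` at the plateau
#' temperature, and is constant beyond it. The onset (40 C in muscle and
#' fat) reflects that thermoregulatory vasodilation in deep tissue responds
#' to hyperthermic, not normothermic, temperatures; disordered tumor
#' vasculature gets at most a weak, early response. Two variants bound the
#' physiological uncertainty: an optimistic (strong vasodilation) and a
#' pessimistic (weak) model for the perfusion-responsive tissues; all other
#' tissues keep `omega = 1`.
#'
#' @param variant `"optimistic"` or `"pessimistic"`.
#' @param params optional data.frame overriding the built-in curve table
#'   (columns `name`, `omega_max`, `t_plateau` and optionally `t_onset`,
#'   default 37).
#' @return list of class `perfusion_model`.
#' @export
perfusion_model <- function(variant = c("optimistic", "pessimistic"),
                            params = NULL) {
  variant <- match.arg(variant)
  if (is.null(params)) {
    params <- if (variant == "optimistic")
      data.frame(name = c("muscle", "fat", "tumor"),
                 omega_max = c(12, 4, 2), t_plateau = c(45, 45, 43),
                 t_onset = c(40, 40, 37))
    else
      data.frame(name = c("muscle", "fat", "tumor"),
                 omega_max = c(3, 1.5, 1), t_plateau = c(45, 45, 43),
                 t_onset = c(40, 40, 37))
  }
  if (is.null(params$t_onset)) params$t_onset <- 37
  stopifnot(all(params$omega_max >= 1), all(params$t_plateau > params$t_onset),
            all(params$t_onset >= 37))
  structure(list(variant = variant, params = params),
            class = "perfusion_model")
}

#' Relative perfusion at a temperature
#'
#' `omega = 1 + (omega_max - 1) * clamp((T - T_onset) / (T_plateau -
#' T_onset), 0, 1)`, with `T_onset = 37` unless the model's curve table says
#' otherwise.
#'
#' @param T temperature(s), degrees C.
#' @param tissue tissue name (scalar) or vector of names/ids recycled
#'   against `T`.
#' @param model a [perfusion_model()].
#' @param table tissue table (to resolve integer ids).
#' @return relative perfusion `omega` (>= 1 under the built-in curves).
#' @export
perfusion_ratio <- function(T, tissue, model = perfusion_model(),
                            table = tissue_table()) {
  if (is.numeric(tissue)) tissue <- table$name[tissue]
  i <- match(tissue, model$params$name)
  omax <- ifelse(is.na(i), 1, model$params$omega_max[i])
  tp <- ifelse(is.na(i), 45, model$params$t_plateau[i])
  ton <- ifelse(is.na(i), 37, model$params$t_onset[i])
  frac <- pmin(pmax((T - ton) / (tp - ton), 0), 1)
  1 + (omax - 1) * frac
}

#' Gaussian power-deposition field
#'
#' Isotropic Gaussian stand-in for a focused hyperthermia power deposition,
#' peaked at the target centre and zero outside the phantom.
#'
#' @param grid a `thermal_grid`.
#' @param center focus centre (m).
#' @param spread Gaussian standard deviation (m).
#' @param peak peak volumetric power (W/m^3); ignored if `total_power` given.
#' @param total_power total deposited power (W); scales the field so the
#'   volume integral over the phantom matches.
#' @return per-voxel power density (W/m^3).
#' @export
gaussian_power_deposition <- function(grid, center, spread, peak = 3e4,
                                      total_power = NULL) {
  stopifnot(spread > 0)
  pts <- grid_coords(grid)
  r2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
        (pts[, 3] - center[3])^2
  q <- exp(-r2 / (2 * spread^2))
  q[grid$labels < 1L] <- 0
  if (!is.null(total_power)) {
    tot <- sum(q) * grid$spacing^3
    q <- q * total_power / tot
  } else q <- q * peak
  q
}

#' Pennes bioheat simulation
#'
#' Transient solution of the bioheat equation
#' `rho c dT/dt = div(k grad T) + wb cb (Ta - T) + q_ext`
#' on the rectilinear grid, with temperature-dependent perfusion
#' `wb = wb0 * omega(T)` re-evaluated every step. The solver works on the
#' temperature elevation above the arterial temperature `Ta`; metabolic heat
#' is assumed balanced at baseline (fixed body-core temperature), so the
#' unheated steady state is exactly `Ta`. Boundary voxels outside the
#' phantom hold a fixed temperature (water-bolus-cooled surface); `NA`
#' labels are insulated.
#'
#' The default implicit (backward Euler) scheme factors the diffusion
#' operator once and treats the perfusion sink with its coefficient lagged
#' one step, which is unconditionally stable in the diffusion term and
#' stable in the perfusion term for `dt` well below the perfusion time
#' constant (minutes). The explicit scheme is provided for reference and
#' rejects CFL-unstable steps.
#'
#' @param grid a `thermal_grid`.
#' @param q_ext per-voxel power deposition (W/m^3).
#' @param table tissue table (thermal properties).
#' @param perfusion a [perfusion_model()].
#' @param duration simulated time (s).
#' @param dt time step (s).
#' @param Ta arterial / baseline temperature (C).
#' @param boundary_temperature temperature of exterior (label 0) voxels;
#'   scalar or per-voxel vector.
#' @param T0 initial temperature; defaults to `Ta`.
#' @param scheme `"implicit"` (default) or `"explicit"`.
#' @return list of class `temperature_field`: `T` per voxel (exterior voxels
#'   at the boundary temperature, `NA` in voids), `omega` (relative
#'   perfusion at the final temperature) and the grid.
#' @export
solve_pennes <- function(grid, q_ext, table = tissue_table(),
                         perfusion = perfusion_model("pessimistic"),
                         duration = 3600, dt = 1, Ta = 37,
                         boundary_temperature = Ta, T0 = NULL,
                         scheme = c("implicit", "explicit")) {
  scheme <- match.arg(scheme)
  stopifnot(duration > 0, dt > 0, length(q_ext) == prod(grid$dims))
  d <- grid$dims
  s <- grid$spacing
  lab <- grid$labels
  act <- which(!is.na(lab) & lab >= 1L)
  na <- length(act)
  map <- rep(NA_integer_, prod(d)); map[act] <- seq_len(na)
  kv <- table$k[lab[act]]
  Cv <- table$rho[lab[act]] * table$c[lab[act]] * s^3
  wb0 <- table$wb0[lab[act]]
  tnames <- table$name[lab[act]]
  thetab <- rep(boundary_temperature - Ta, length.out = prod(d))
  # 6-neighbour conductances
  ii <- jj <- xx <- list(); nb <- 0L
  diag_extra <- rep(0, na)
  rhs_bc <- rep(0, na)
  arr_idx <- array(seq_len(prod(d)), dim = d)
  for (sh in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    from <- arr_idx
    to <- shift_array(array(as.numeric(arr_idx), dim = d), sh)
    ok <- !is.na(to)
    f <- as.integer(from[ok]); t2 <- as.integer(to[ok])
    af <- !is.na(map[f]); at <- !is.na(map[t2])
    both <- af & at
    if (any(both)) {
      kf <- table$k[lab[f[both]]]; kt <- table$k[lab[t2[both]]]
      g <- 2 * kf * kt / (kf + kt) * s
      nb <- nb + 1L
      ii[[nb]] <- map[f[both]]; jj[[nb]] <- map[t2[both]]; xx[[nb]] <- g
    }
    bcf <- af & !at & (lab[t2] == 0L) & !is.na(lab[t2])
    if (any(bcf)) {
      g <- table$k[lab[f[bcf]]] * s
      diag_extra[map[f[bcf]]] <- diag_extra[map[f[bcf]]] + g
      rhs_bc[map[f[bcf]]] <- rhs_bc[map[f[bcf]]] + g * thetab[t2[bcf]]
    }
    bct <- at & !af & (lab[f] == 0L) & !is.na(lab[f])
    if (any(bct)) {
      g <- table$k[lab[t2[bct]]] * s
      diag_extra[map[t2[bct]]] <- diag_extra[map[t2[bct]]] + g
      rhs_bc[map[t2[bct]]] <- rhs_bc[map[t2[bct]]] + g * thetab[f[bct]]
    }
  }
  iiv <- unlist(ii); jjv <- unlist(jj); xxv <- unlist(xx)
  L <- Matrix::sparseMatrix(i = c(iiv, jjv, seq_len(na)),
                            j = c(jjv, iiv, seq_len(na)),
                            x = c(-xxv, -xxv, rep(0, na)),
                            dims = c(na, na))
  Matrix::diag(L) <- -Matrix::rowSums(L) + diag_extra
  q <- q_ext[act] * s^3
  theta <- if (is.null(T0)) rep(0, na) else rep(T0 - Ta, length.out = prod(d))[act]
  nstep <- ceiling(duration / dt)
  wcoef <- function(th) wb0 * BLOOD_C *
    perfusion_ratio(Ta + th, tnames, perfusion, table)
  if (scheme == "explicit") {
    gmax <- Matrix::diag(L) + wcoef(rep(100, na)) * s^3
    if (dt > min(Cv / gmax))
      stop("explicit scheme unstable at dt = ", dt,
           "; largest stable step about ", signif(min(Cv / gmax), 3), " s")
    for (n in seq_len(nstep)) {
      W <- wcoef(theta) * s^3
      theta <- theta + dt / Cv *
        (-as.numeric(L %*% theta) - W * theta + q + rhs_bc)
    }
  } else {
    M <- L + Matrix::Diagonal(na, Cv / dt)
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE,
                           perm = TRUE)
    for (n in seq_len(nstep)) {
      W <- wcoef(theta) * s^3
      rhs <- Cv / dt * theta + q + rhs_bc - W * theta
      theta <- as.numeric(Matrix::solve(ch, rhs))
    }
  }
  Tout <- rep(NA_real_, prod(d))
  Tout[act] <- Ta + theta
  ext <- !is.na(lab) & lab == 0L
  Tout[ext] <- Ta + thetab[ext]
  omega <- rep(NA_real_, prod(d))
  omega[act] <- perfusion_ratio(Tout[act], tnames, perfusion, table)
  structure(list(T = Tout, omega = omega, grid = grid, Ta = Ta,
                 perfusion = perfusion), class = "temperature_field")
}

#' Conductivity-temperature coupling model
#'
#' During heating the tissue conductivity changes through (i) the direct
#' temperature dependence of the tissue fluids, `Tc * dT` with temperature
#' coefficient `Tc`, and (ii) a perfusion term: vasodilation raises the
#' plasma volume fraction, `alpha * (sqrt(omega) - 1) * (1 + Tc * dT)`, where
#' `alpha` is the effective plasma fraction at the measurement frequency and
#' the square root maps relative flow to vessel cross-section. Setting
#' `sqrt_omega = FALSE` uses the raw `omega - 1` reading instead.
#'
#' @param tc temperature coefficient (fraction per C).
#' @param alpha effective plasma volume fraction (LF 0.24, HF 0.08).
#' @param t_ref baseline temperature (C).
#' @param sqrt_omega use `sqrt(omega)` for the vessel cross-section relation.
#' @return list of class `cc_model`.
#' @export
conductivity_change_model <- function(tc = 0.02, alpha = 0.08, t_ref = 37,
                                      sqrt_omega = TRUE) {
  stopifnot(tc >= 0, alpha >= 0, alpha < 1)
  structure(list(tc = tc, alpha = alpha, t_ref = t_ref,
                 sqrt_omega = sqrt_omega), class = "cc_model")
}

#' Fractional conductivity change from temperature and perfusion
#'
#' `dsigma / sigma_ref = Tc dT + alpha (sqrt(omega) - 1)(1 + Tc dT)`.
#'
#' @param delta_T temperature elevation(s) above baseline (C).
#' @param omega relative perfusion (1 = baseline).
#' @param model a [conductivity_change_model()].
#' @return fractional conductivity change (0.1 = +10%).
#' @export
conductivity_change <- function(delta_T, omega, model = conductivity_change_model()) {
  stopifnot(all(is.finite(delta_T)), all(is.finite(omega)), all(omega >= 0))
  f <- if (model$sqrt_omega) sqrt(omega) else omega
  model$tc * delta_T + model$alpha * (f - 1) * (1 + model$tc * delta_T)
}

#' Invert the conductivity-change model to a temperature change
#'
#' Solves `conductivity_change(dT, omega(t_ref + dT)) = input` for `dT` by
#' bisection (to 1e-6 C) given a perfusion-temperature curve; with
#' `omega_curve = NULL` (perfusion fixed at baseline) it reduces to the
#' linear inversion `dT = input / Tc`. Inputs outside the attainable range
#' on [-15, 15] C are clipped and flagged via the `"clipped"` attribute.
#'
#' @param delta_sigma_fraction fractional conductivity change(s).
#' @param model a [conductivity_change_model()].
#' @param omega_curve function(T) returning relative perfusion, or `NULL`.
#' @return temperature change(s), degrees C.
#' @export
temperature_from_conductivity <- function(delta_sigma_fraction,
                                          model = conductivity_change_model(),
                                          omega_curve = NULL) {
  if (is.null(omega_curve)) {
    out <- delta_sigma_fraction / model$tc
    attr(out, "clipped") <- integer(0)
    return(out)
  }
  g <- function(dT) conductivity_change(dT, omega_curve(model$t_ref + dT),
                                        model)
  lo <- -15; hi <- 15
  glo <- g(lo); ghi <- g(hi)
  if (g(0) > g(1)) stop("conductivity change is not increasing in temperature")
  clip <- which(delta_sigma_fraction < glo | delta_sigma_fraction > ghi)
  x <- pmin(pmax(delta_sigma_fraction, glo), ghi)
  out <- vapply(x, function(ds) {
    a <- lo; b <- hi
    for (i in 1:60) {
      m <- (a + b) / 2
      if (g(m) < ds) a <- m else b <- m
      if (b - a < 1e-7) break
    }
    (a + b) / 2
  }, numeric(1))
  attr(out, "clipped") <- clip
  out
}

#' Conductivity field from temperature and perfusion fields
#'
#' Applies the conductivity-change model per element: every tissue gets the
#' direct `Tc` term; the perfusion term is applied only to
#' perfusion-responsive tissues (muscle, fat, tumor).
#'
#' @param delta_T per-element temperature elevation (C).
#' @param omega per-element relative perfusion.
#' @param sigma_ref per-element baseline conductivity (S/m).
#' @param labels per-element tissue ids.
#' @param table tissue table (provides `tc` and the frequency's `alpha`).
#' @param frequency `"lf"` or `"hf"`.
#' @param sqrt_omega see [conductivity_change_model()].
#' @return per-element conductivity (S/m).
#' @export
fields_to_sigma <- function(delta_T, omega, sigma_ref, labels,
                            table = tissue_table(),
                            frequency = c("lf", "hf"), sqrt_omega = TRUE) {
  frequency <- match.arg(frequency)
  acol <- if (frequency == "lf") "alpha_lf" else "alpha_hf"
  tc <- table$tc[labels]
  alpha <- ifelse(table$perfusion_responsive[labels], table[[acol]][labels], 0)
  om <- ifelse(table$perfusion_responsive[labels], omega, 1)
  f <- if (sqrt_omega) sqrt(om) else om
  frac <- tc * delta_T + alpha * (f - 1) * (1 + tc * delta_T)
  sigma_ref * (1 + frac)
}
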