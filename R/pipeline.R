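# Scenario orchestration and error metrics: spherical-heating benchmark
# scenarios, the full simulated hyperthermia-treatment pipeline (Scenario 1:
# 37 C reference, no prior mask; Scenario 2: planning-based reference and
# temperature-thresholded prior region), noise sweeps and binned error
# statistics.

#' Binned reconstruction-error statistics
#'
#' Computes the error `rec - true`, bins it by the true change in
#' fixed-width bins (the sliding histogram, 1 unit of change per bin by
#' default), and reports mean and standard deviation per bin, overall and
#' per tissue. Statistics are restricted to the evaluation mask; bins with
#' fewer than `min_bin` members are dropped.
#'
#' @param rec reconstructed values (e.g. conductivity change in %).
#' @param true true values, same units and length.
#' @param labels optional tissue ids for a per-tissue breakdown.
#' @param mask optional logical evaluation mask.
#' @param bin_width histogram bin width (same units as `true`).
#' @param min_bin minimum members per reported bin.
#' @param table tissue table (names the per-tissue rows).
#' @return list of class `metrics_report`: `bins` (data.frame: center, n,
#'   mean, sd), `overall` (mean, sd, max_abs, n) and `per_tissue`.
#' @export
error_stats <- function(rec, true, labels = NULL, mask = NULL,
                        bin_width = 1, min_bin = 10,
                        table = tissue_table()) {
  stopifnot(length(rec) == length(true))
  keep <- is.finite(rec) & is.finite(true)
  if (!is.null(mask)) keep <- keep & mask
  if (!any(keep)) stop("empty evaluation mask")
  err <- (rec - true)[keep]
  tr <- true[keep]
  lo <- floor(min(tr) / bin_width) * bin_width
  edges <- seq(lo, max(tr) + bin_width, by = bin_width)
  bin <- findInterval(tr, edges, rightmost.closed = TRUE)
  bs <- vapply(seq_len(length(edges) - 1L), function(b) {
    e <- err[bin == b]
    c(n = length(e), mean = mean(e), sd = stats::sd(e))
  }, numeric(3))
  bins <- data.frame(center = (edges[-length(edges)] + edges[-1]) / 2,
                     n = bs[1, ], mean = bs[2, ], sd = bs[3, ])
  bins <- bins[bins$n >= min_bin, , drop = FALSE]
  overall <- data.frame(tissue = "all", n = length(err), mean = mean(err),
                        sd = stats::sd(err), max_abs = max(abs(err)))
  if (!is.null(labels)) {
    lb <- labels[keep]
    per <- do.call(rbind, lapply(sort(unique(lb)), function(L) {
      e <- err[lb == L]
      data.frame(tissue = table$name[L], n = length(e), mean = mean(e),
                 sd = stats::sd(e), max_abs = max(abs(e)))
    }))
    overall <- rbind(per, overall)
  }
  structure(list(bins = bins, overall = overall), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Reconstruction error statistics\n")
  print(x$overall, row.names = FALSE)
  cat("Binned by true change (", nrow(x$bins), " bins):\n", sep = "")
  cat("  max |bin mean|:", signif(max(abs(x$bins$mean)), 3),
      "  max bin sd:", signif(max(x$bins$sd), 3), "\n")
  invisible(x)
}

#' Run a spherical-heating benchmark scenario
#'
#' Builds the phantom, applies one of the canonical heated-sphere scenarios
#' (and its anomaly, if any), simulates reference and heated measurements,
#' reconstructs with the given configuration and computes the binned error
#' statistics of the conductivity change (%), by default after
#' interpolation to the rectilinear grid and the 1.2 cm averaging filter.
#'
#' @param id scenario id (see [scenario_fixture()]).
#' @param spec a [phantom_spec()].
#' @param recon a [recon_config()]; its `prior_mask` is replaced by the
#'   heated sphere unless the adaptive scheme is selected.
#' @param snr_db measurement SNR in dB (`Inf` = noise free).
#' @param seed noise seed.
#' @param filter_edge averaging-filter cube edge (m); `NULL` skips the
#'   grid/filter path and evaluates per element.
#' @param grid_spacing rectilinear grid spacing (m) for the filter path.
#' @param table tissue table.
#' @param anomaly_in_truth if `TRUE` (default) the scenario's anomaly (when
#'   present) modifies the measured body but not the reconstruction
#'   reference, emulating an inaccurate reference model.
#' @return list with the reconstruction (`recon`), true and reconstructed
#'   change maps (%), the prior mask, and `metrics` (a `metrics_report`).
#' @export
run_sphere_scenario <- function(id = "P1", spec = phantom_spec(),
                                recon = recon_config(), snr_db = Inf,
                                seed = 1L, filter_edge = 0.012,
                                grid_spacing = 0.004,
                                table = tissue_table(),
                                anomaly_in_truth = TRUE) {
  ph <- build_phantom(spec, table)
  mesh <- place_electrodes(ph$mesh)
  pattern <- build_pattern(16L, 7L)
  sc <- scenario_fixture(id)
  sigma_true <- apply_gaussian_heating(ph$sigma, sc, mesh)
  if (!is.null(sc$anomaly) && anomaly_in_truth)
    sigma_true <- insert_spherical_anomaly(sigma_true, mesh,
                                           sc$anomaly$center,
                                           sc$anomaly$diameter,
                                           sc$anomaly$sigma_value)
  vref <- solve_forward(mesh, ph$sigma, pattern)
  v <- solve_forward(mesh, sigma_true, pattern)
  if (is.finite(snr_db)) v <- add_measurement_noise(v, vref, snr_db, seed)
  mask <- scenario_prior_mask(mesh, sc)
  if (!recon$adaptive) recon$prior_mask <- mask
  fit <- eit_reconstruct(mesh, vref, v, ph$sigma, recon, table)
  dtrue <- ifelse(ph$sigma > 0, 100 * (sigma_true - ph$sigma) / ph$sigma,
                  NA_real_)
  drec <- fit$delta_pct
  if (!is.null(filter_edge)) {
    grid <- thermal_grid(spec, grid_spacing, table)
    vt <- interpolate_and_filter(dtrue, mesh, grid, filter_edge)
    vr <- interpolate_and_filter(drec, mesh, grid, filter_edge)
    vmask <- points_to_grid(grid, tet_centroids(mesh), as.numeric(mask),
                            tet_volumes(mesh)) > 0.5
    vmask[is.na(vmask)] <- FALSE
    metrics <- error_stats(vr, vt, grid$labels, vmask, table = table)
  } else {
    metrics <- error_stats(drec, dtrue, mesh$labels, mask, table = table)
  }
  list(recon = fit, delta_true_pct = dtrue, delta_rec_pct = drec,
       prior_mask = mask, metrics = metrics, mesh = mesh,
       sigma_ref = ph$sigma, sigma_true = sigma_true, scenario = sc)
}

#' Configuration of a simulated hyperthermia-treatment run
#'
#' @param spec a [phantom_spec()].
#' @param scenario 1 (reconstruction reference: conductivity at 37 C, no
#'   prior mask) or 2 (reference: conductivity predicted by the planning
#'   thermal simulation with the optimistic perfusion model; prior region
#'   from thresholding that prediction at `tmask`).
#' @param frequency `"lf"`, `"hf"` or both.
#' @param perfusion_truth,perfusion_ref perfusion-model variants of the
#'   actual treatment and of the planning simulation.
#' @param grid_spacing thermal-grid spacing (m).
#' @param power_peak peak power deposition (W/m^3), chosen so the tumor
#'   region reaches hyperthermic temperatures (40-45 C) after one hour.
#' @param power_spread Gaussian spread of the deposition (m).
#' @param power_center focus centre; default: the phantom's tumor.
#' @param duration,dt thermal simulation time and step (s).
#' @param tmask prior-region temperature threshold (C).
#' @param snr_db measurement SNR (dB), `Inf` = noise free.
#' @param seed noise seed.
#' @param recon a [recon_config()]; the pipeline sets its prior mask. The
#'   default applies Gaussian output smoothing at the thermal length.
#' @param filter_edge averaging-filter edge (m) for voxel statistics.
#' @param table tissue table.
#' @return list of class `ht_config`.
#' @export
ht_config <- function(spec = phantom_spec(), scenario = 2L,
                      frequency = c("lf", "hf"),
                      perfusion_truth = "pessimistic",
                      perfusion_ref = "optimistic",
                      grid_spacing = 0.008, power_peak = 2.5e4,
                      power_spread = 0.03, power_center = NULL,
                      duration = 3600, dt = 10, tmask = 39,
                      snr_db = Inf, seed = 1L,
                      recon = recon_config(smooth_output = TRUE),
                      filter_edge = 0.012, table = tissue_table()) {
  stopifnot(scenario %in% c(1L, 2L))
  frequency <- match.arg(frequency, several.ok = TRUE)
  if (is.null(power_center)) {
    tum <- Filter(function(i) identical(i$tissue, "tumor"), spec$inclusions)
    power_center <- if (length(tum)) tum[[1]]$center else c(0, 0, 0)
  }
  structure(list(spec = spec, scenario = as.integer(scenario),
                 frequency = frequency, perfusion_truth = perfusion_truth,
                 perfusion_ref = perfusion_ref,
                 grid_spacing = grid_spacing, power_peak = power_peak,
                 power_spread = power_spread, power_center = power_center,
                 duration = duration, dt = dt, tmask = tmask,
                 snr_db = snr_db, seed = as.integer(seed), recon = recon,
                 filter_edge = filter_edge, table = table),
            class = "ht_config")
}

# per-element single-frequency temperature estimate: invert the
# conductivity-change model tissue by tissue with the given perfusion curves
invert_sigma_to_temperature <- function(ds_frac, labels, table, frequency,
                                        perfusion) {
  acol <- if (frequency == "lf") "alpha_lf" else "alpha_hf"
  out <- rep(NA_real_, length(ds_frac))
  for (L in sort(unique(labels))) {
    sel <- which(labels == L & is.finite(ds_frac))
    if (!length(sel)) next
    resp <- table$perfusion_responsive[L]
    mdl <- conductivity_change_model(
      tc = table$tc[L], alpha = if (resp) table[[acol]][L] else 0)
    curve <- if (resp) {
      nm <- table$name[L]
      function(T) perfusion_ratio(T, nm, perfusion, table)
    } else NULL
    out[sel] <- temperature_from_conductivity(ds_frac[sel], mdl, curve)
  }
  out
}

#' Run the simulated hyperthermia-treatment pipeline
#'
#' End-to-end emulation of EIT monitoring of a one-hour treatment: a thermal
#' simulation with the pessimistic perfusion model plays the actual
#' treatment, one with the optimistic model plays the (imperfect) planning
#' prediction. Conductivity fields at the requested frequencies are derived
#' from the temperature and perfusion fields, boundary voltages are
#' simulated, and the conductivity change is reconstructed against the
#' scenario's reference (37 C baseline for Scenario 1, planning prediction
#' with a temperature-thresholded prior region for Scenario 2). Reconstructed
#' changes are converted back to temperature per frequency and, when both
#' frequencies are run, jointly through the two-frequency separation.
#'
#' @param config an [ht_config()].
#' @return list of class `ht_run`: temperature fields, per-frequency
#'   reconstructions (`fits`), total fractional change maps rel. the 37 C
#'   baseline (`ds_total`, truth `ds_true`), per-frequency (`Trec`) and
#'   two-frequency (`Trec_2f`, `omega_2f`) estimates at the elements,
#'   element truth `T_true`, the prior mask, and voxel-level `metrics`
#'   (conductivity % and temperature error) computed after the averaging
#'   filter within the evaluation mask.
#' @export
run_scenario <- function(config = ht_config()) {
  stopifnot(inherits(config, "ht_config"))
  table <- config$table
  ph <- build_phantom(config$spec, table)
  mesh <- place_electrodes(ph$mesh)
  pattern <- build_pattern(16L, 7L)
  labels <- mesh$labels
  ctr <- tet_centroids(mesh)
  grid <- thermal_grid(config$spec, config$grid_spacing, table)
  q <- gaussian_power_deposition(grid, config$power_center,
                                 config$power_spread, config$power_peak)
  pm_truth <- perfusion_model(config$perfusion_truth)
  pm_ref <- perfusion_model(config$perfusion_ref)
  T_truth <- solve_pennes(grid, q, table, pm_truth,
                          duration = config$duration, dt = config$dt)
  T_ref <- solve_pennes(grid, q, table, pm_ref,
                        duration = config$duration, dt = config$dt)
  Tt <- interp_grid_at(grid, ifelse(is.na(T_truth$T), 37, T_truth$T), ctr)
  To <- interp_grid_at(grid, ifelse(is.na(T_ref$T), 37, T_ref$T), ctr)
  om_t <- perfusion_ratio(Tt, labels, pm_truth, table)
  om_o <- perfusion_ratio(To, labels, pm_ref, table)
  prior <- if (config$scenario == 2L) To > config$tmask else NULL
  freqs <- config$frequency
  fits <- list(); ds_total <- list(); ds_true <- list(); Trec <- list()
  sigma37 <- list()
  for (f in freqs) {
    s37 <- sigma_from_labels(labels, table, f)
    s_true <- fields_to_sigma(Tt - 37, om_t, s37, labels, table, f)
    s_ref <- if (config$scenario == 2L)
      fields_to_sigma(To - 37, om_o, s37, labels, table, f) else s37
    v <- solve_forward(mesh, s_true, pattern, f)
    vref <- solve_forward(mesh, s_ref, pattern, f)
    if (is.finite(config$snr_db))
      v <- add_measurement_noise(v, vref, config$snr_db, config$seed)
    rc <- config$recon
    rc$prior_mask <- prior
    fit <- eit_reconstruct(mesh, vref, v, s_ref, rc, table)
    ok <- s37 > 0
    dtot <- ifelse(ok, (s_ref + fit$delta_sigma - s37) / s37, NA_real_)
    dtru <- ifelse(ok, (s_true - s37) / s37, NA_real_)
    fits[[f]] <- fit
    ds_total[[f]] <- dtot
    ds_true[[f]] <- dtru
    sigma37[[f]] <- s37
    Trec[[f]] <- 37 + invert_sigma_to_temperature(dtot, labels, table, f,
                                                  pm_truth)
  }
  out <- list(mesh = mesh, grid = grid, config = config,
              T_truth_vox = T_truth, T_ref_vox = T_ref,
              T_true = Tt, T_plan = To, prior_mask = prior,
              fits = fits, ds_total = ds_total, ds_true = ds_true,
              Trec = Trec)
  if (all(c("lf", "hf") %in% freqs)) {
    a_lf <- table$alpha_lf[1]; a_hf <- table$alpha_hf[1]
    tc <- table$tc[1]
    dT2 <- separate_temperature(ds_total$lf, ds_total$hf, a_lf, a_hf, tc)
    out$Trec_2f <- 37 + dT2
    # clamp the temperature estimate to the physical range for the
    # perfusion step so junk estimates in low-sensitivity elements cannot
    # make the 1 + Tc dT factor non-positive
    out$omega_2f <- separate_perfusion(ds_total$lf, ds_total$hf, a_lf, a_hf,
                                       tc,
                                       delta_T = pmin(pmax(dT2, -15), 15))
  }
  # voxel-level metrics after the averaging filter, within the evaluation mask
  emask <- if (is.null(prior)) rep(TRUE, length(labels)) else prior
  vmask <- points_to_grid(grid, ctr, as.numeric(emask), tet_volumes(mesh)) > 0.5
  vmask[is.na(vmask)] <- FALSE
  f1 <- freqs[1]
  vr <- interpolate_and_filter(100 * ds_total[[f1]], mesh, grid,
                               config$filter_edge)
  vt <- interpolate_and_filter(100 * ds_true[[f1]], mesh, grid,
                               config$filter_edge)
  out$metrics_sigma <- error_stats(vr, vt, grid$labels, vmask, table = table)
  Tmap <- if (!is.null(out$Trec_2f)) out$Trec_2f else Trec[[f1]]
  vTr <- interpolate_and_filter(Tmap, mesh, grid, config$filter_edge)
  vTt <- interpolate_and_filter(Tt, mesh, grid, config$filter_edge)
  out$metrics_temperature <- error_stats(vTr, vTt, grid$labels, vmask,
                                         bin_width = 0.5, table = table)
  class(out) <- "ht_run"
  out
}

#' @export
print.ht_run <- function(x, ...) {
  cat("Simulated hyperthermia-treatment EIT run (Scenario ",
      x$config$scenario, ", ", paste(x$config$frequency, collapse = "+"),
      ")\n", sep = "")
  cat("  peak treatment temperature: ",
      signif(max(x$T_true, na.rm = TRUE), 4), " C (plan: ",
      signif(max(x$T_plan, na.rm = TRUE), 4), " C)\n", sep = "")
  if (!is.null(x$prior_mask))
    cat("  prior region: ", sum(x$prior_mask), " elements\n", sep = "")
  ov <- x$metrics_temperature$overall
  all <- ov[ov$tissue == "all", ]
  cat("  temperature error (filtered, in mask): mean ",
      signif(all$mean, 3), " C, sd ", signif(all$sd, 3), " C, max |.| ",
      signif(all$max_abs, 3), " C\n", sep = "")
  invisible(x)
}

#' Noise sweep on a spherical-heating scenario
#'
#' Reconstructs a fixed scenario at several measurement SNR levels (and
#' optionally several hyperparameter values), with replicate noise seeds,
#' and tabulates the in-mask error statistics.
#'
#' @param id scenario id.
#' @param snr_list SNR levels in dB (may include `Inf`).
#' @param seeds integer noise seeds.
#' @param lambda_list hyperparameter values to cross with the SNR levels.
#' @param spec,recon,table as in [run_sphere_scenario()].
#' @param filter_edge,grid_spacing analysis-path settings.
#' @return data.frame, one row per (snr, lambda, seed): overall in-mask
#'   `mean`, `sd` and `median_abs` error (%).
#' @export
noise_sweep <- function(id = "P1", snr_list = c(40, 30, 20, 10),
                        seeds = 1:3, lambda_list = NULL,
                        spec = phantom_spec(), recon = recon_config(),
                        table = tissue_table(), filter_edge = 0.012,
                        grid_spacing = 0.004) {
  stopifnot(length(snr_list) >= 2L)
  if (is.null(lambda_list)) lambda_list <- recon$lambda
  ph <- build_phantom(spec, table)
  mesh <- place_electrodes(ph$mesh)
  pattern <- build_pattern(16L, 7L)
  sc <- scenario_fixture(id)
  sigma_true <- apply_gaussian_heating(ph$sigma, sc, mesh)
  vref <- solve_forward(mesh, ph$sigma, pattern)
  v0 <- solve_forward(mesh, sigma_true, pattern)
  mask <- scenario_prior_mask(mesh, sc)
  dtrue <- ifelse(ph$sigma > 0, 100 * (sigma_true - ph$sigma) / ph$sigma,
                  NA_real_)
  ctr <- tet_centroids(mesh)
  if (!is.null(filter_edge)) {
    grid <- thermal_grid(spec, grid_spacing, table)
    vt <- interpolate_and_filter(dtrue, mesh, grid, filter_edge)
    vmask <- points_to_grid(grid, ctr, as.numeric(mask),
                            tet_volumes(mesh)) > 0.5
    vmask[is.na(vmask)] <- FALSE
  } else {
    vt <- dtrue
    vmask <- mask
  }
  rows <- list()
  for (snr in snr_list) for (lam in lambda_list) for (sd_ in seeds) {
    v <- add_measurement_noise(v0, vref, snr, sd_)
    rc <- recon
    rc$lambda <- lam
    rc$prior_mask <- mask
    fit <- eit_reconstruct(mesh, vref, v, ph$sigma, rc, table)
    vr <- if (!is.null(filter_edge))
      interpolate_and_filter(fit$delta_pct, mesh, grid, filter_edge)
    else fit$delta_pct
    e <- (vr - vt)[vmask & is.finite(vr) & is.finite(vt)]
    rows[[length(rows) + 1L]] <-
      data.frame(snr_db = snr, lambda = lam, seed = sd_, mean = mean(e),
                 sd = stats::sd(e), median_abs = stats::median(abs(e)))
  }
  do.call(rbind, rows)
}
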