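# The iterative reconstruction estimator and its S3 interface.

test_that("zero voltage difference reconstructs zero change", {
  fx <- fx_phantom()
  fit <- eit_reconstruct(fx$mesh, fx$vref, fx$vref, fx$sigma,
                         recon_config(n_iterations = 1L))
  expect_lt(sqrt(sum(fit$delta_sigma^2)) / sqrt(sum(fx$sigma^2)), 1e-6)
})

test_that("heated-sphere reconstruction is accurate with a known prior", {
  fx <- fx_phantom()
  p1 <- fx_p1()
  cfg <- recon_config(lambda = 0.01, penalty = "tid",
                      prior_mask = p1$mask, n_iterations = 3L)
  fit <- eit_reconstruct(fx$mesh, fx$vref, p1$v, fx$sigma, cfg)
  err <- fit$delta_pct - p1$dtrue
  # per-element error statistics inside the heated region stay below 10%
  expect_lt(abs(mean(err[p1$mask])), 10)
  expect_lt(sd(err[p1$mask]), 10)
  # voltage residual decreases monotonically over the iterations
  expect_true(all(diff(fit$residuals$mean_abs) < 0))
  expect_equal(fit$n_solves, 3L)
  expect_false(fit$diverged)
  # S3 surface
  expect_s3_class(fit, "eit_recon")
  expect_identical(coef(fit), fit$delta_sigma)
  expect_equal(nrow(residuals(fit)), 3L)
  expect_output(print(fit), "difference-imaging")
  s <- summary(fit)
  expect_s3_class(s, "summary.eit_recon")
  # temperature prediction through the pure-Tc inverse
  dT <- predict(fit, conductivity_change_model(tc = 0.02, alpha = 0))
  expect_equal(dT[p1$mask], fit$delta_pct[p1$mask] / 2, tolerance = 1e-12)
})

test_that("adaptive prior scheme uses 5 solves and recovers the region", {
  r <- run_sphere_scenario("P1", phantom_spec(target_elements = 8000),
                           recon_config(penalty = "tid", adaptive = TRUE),
                           filter_edge = NULL)
  expect_equal(r$recon$n_solves, 5L)
  m2 <- r$recon$adaptive_masks$stage2
  expect_false(is.null(r$recon$adaptive_masks$stage1))
  # the refined mask covers >= 90% of the region with true change above
  # half its peak
  dtrue <- r$delta_true_pct
  hot <- is.finite(dtrue) & dtrue > max(dtrue[is.finite(dtrue)]) / 2
  expect_gte(mean(m2[hot]), 0.9)
})

test_that("adaptive prior rescues reconstruction under a reference-model
           anomaly", {
  spec <- phantom_spec(target_elements = 8000)
  r_fix <- run_sphere_scenario("air", spec,
                               recon_config(penalty = "tid",
                                            n_iterations = 3L),
                               filter_edge = NULL)
  r_ad <- run_sphere_scenario("air", spec,
                              recon_config(penalty = "tid",
                                           adaptive = TRUE),
                              filter_edge = NULL)
  sd_fix <- subset(r_fix$metrics$overall, tissue == "all")$sd
  sd_ad <- subset(r_ad$metrics$overall, tissue == "all")$sd
  expect_gte(sd_fix / sd_ad, 2)
})

test_that("tissue-dependent penalty narrows the per-tissue response spread", {
  fx <- fx_phantom()
  sc <- heating_scenario(center = c(-0.05, 0.01, 0), R = 0.03, peak = 0.4,
                         diameter = 0.09)
  st <- apply_gaussian_heating(fx$sigma, sc, fx$mesh)
  mask <- scenario_prior_mask(fx$mesh, sc)
  v <- solve_forward(fx$mesh, st, fx$pattern)
  dtrue <- 100 * (st - fx$sigma) / fx$sigma
  slope_spread <- function(penalty) {
    fit <- eit_reconstruct(fx$mesh, fx$vref, v, fx$sigma,
                           recon_config(penalty = penalty,
                                        prior_mask = mask,
                                        n_iterations = 1L))
    sl <- vapply(sort(unique(fx$mesh$labels[mask])), function(L) {
      s <- mask & fx$mesh$labels == L & is.finite(dtrue) & dtrue > 1
      if (sum(s) < 10) return(NA_real_)
      sum(fit$delta_pct[s] * dtrue[s]) / sum(dtrue[s]^2)
    }, numeric(1))
    diff(range(sl, na.rm = TRUE))
  }
  expect_lt(slope_spread("tid"), slope_spread("fixed"))
})

test_that("noise degrades reconstruction monotonically and a larger
           hyperparameter mitigates it", {
  sw <- noise_sweep("P1", snr_list = c(40, 30, 20, 10), seeds = 1:2,
                    spec = phantom_spec(target_elements = 8000),
                    filter_edge = NULL)
  agg <- aggregate(median_abs ~ snr_db, sw, mean)
  agg <- agg[order(-agg$snr_db), ]
  expect_true(all(diff(agg$median_abs) > 0))
  sw2 <- noise_sweep("P1", snr_list = c(20, 30), seeds = 1:2,
                     lambda_list = c(0.01, 0.1),
                     spec = phantom_spec(target_elements = 8000),
                     filter_edge = NULL)
  a2 <- aggregate(sd ~ lambda, subset(sw2, snr_db == 20), mean)
  expect_lt(a2$sd[a2$lambda == 0.1], a2$sd[a2$lambda == 0.01])
  # bookkeeping: one row per snr x lambda x seed
  expect_equal(nrow(sw2), 2L * 2L * 2L)
})
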