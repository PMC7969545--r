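test_that("fluxes are concentration times MAR with missing propagated", {
  sim <- build_synthetic_core(constant_scenario(
    elements = list(Zn = element_spec(2, noise_cv = 0))), seed = 1,
    noise = FALSE)
  df <- date_and_flux(sim$profile)
  fp <- df$fp
  expect_equal(fp$flux, fp$conc * fp$mar)
  # C = 2 ug/g at MAR 500 g/m2/yr would give 1000 ug/m2/yr
  expect_equal(2 * 500, 1000)
  p <- as.data.frame(sim$profile)
  p$zn_ug_g[4] <- NA
  fp2 <- compute_fluxes(core_profile(p), df$fit)
  expect_true(is.na(fp2$flux[fp2$layer_id == 4]))
  expect_false(fp2$included[fp2$layer_id == 4])
  # display conversion is formatting only
  expect_equal(flux_as_mg(6.5), 0.0065)
  expect_equal(flux_as_ug(0.0065), 6.5)
})

test_that("background flux is the pre-cutoff mean of included layers", {
  fp <- structure(data.frame(
    element = "Pb", layer_id = 1:4, year = c(1980, 1890, 1870, 1860),
    conc = 1, mar = 100, flux = c(9, 4, 6, 40), duration_yr = 1,
    included = c(TRUE, TRUE, TRUE, FALSE)),   # layer 4: event layer
    class = c("flux_profile", "data.frame"))
  expect_equal(unname(background_flux(fp, 1900)), 5)
  expect_error(background_flux(fp, 1850), "older than")
})

test_that("erosion and atmospheric components obey their closed forms", {
  f_b <- c(Pb = 10)
  fp <- structure(data.frame(element = "Pb", layer_id = 1:3,
                             year = c(2000, 1995, 1880),
                             conc = 1, mar = c(100, 200, 100),
                             flux = c(10, 30, 10), duration_yr = 1,
                             included = TRUE),
                  class = c("flux_profile", "data.frame"))
  f_v <- erosion_flux(fp, f_b, mar_ref = 100)
  expect_equal(f_v, c(0, 10, 0))           # MAR = ref -> 0; 2x ref -> F_B
  expect_equal(erosion_flux(fp, c(Pb = 0), 100), c(0, 0, 0))
  expect_error(erosion_flux(fp, f_b, 0), "positive")
  f_a <- atmospheric_flux(fp, f_b, f_v)
  expect_equal(f_a, c(0, 10, 0))
  expect_equal(f_b[["Pb"]] + f_v + f_a, fp$flux)
})

test_that("constant composition forces F_A to zero for any MAR history", {
  for (seed in 1:5) {
    sim <- build_synthetic_core(random_mar_scenario(seed), seed = seed,
                                noise = FALSE)
    df <- date_and_flux(sim$profile)
    app <- apportion(df$fp, df$fit)
    ok <- app$layers$included & !is.na(app$layers$f_a)
    scale <- max(app$layers$f_tot[ok])
    expect_lt(max(abs(app$layers$f_a[ok])) / scale, 1e-9)
    expect_lt(abs(share_of(app, "Zn")), 1e-7)
  }
})

test_that("apportionment conserves mass and scales with concentration", {
  sim <- build_synthetic_core(scenario_remote_highland(), seed = 4)
  df <- date_and_flux(sim$profile, quiet = TRUE)
  app <- apportion(df$fp, df$fit)
  ok <- app$layers$included & !is.na(app$layers$f_tot)
  resid <- with(app$layers[ok, ], f_b + f_v + f_a - f_tot)
  expect_lt(max(abs(resid)), 1e-8 * max(app$layers$f_tot[ok]))

  # scale equivariance: k-fold concentrations -> k-fold components
  k <- 3.7
  p2 <- as.data.frame(sim$profile)
  p2$hg_ug_g <- p2$hg_ug_g * k
  app2 <- apportion(compute_fluxes(core_profile(p2), df$fit), df$fit)
  for (col in c("f_tot", "f_b", "f_v", "f_a")) {
    a <- app$layers[app$layers$element == "Hg" & ok, col]
    b <- app2$layers[app2$layers$element == "Hg" & ok, col]
    expect_equal(b, k * a, tolerance = 1e-9, label = col)
  }
})

test_that("background window choice barely moves F_B on constant cores", {
  sim <- build_synthetic_core(constant_scenario(span = 260), seed = 1,
                              noise = FALSE)
  df <- date_and_flux(sim$profile)
  sens <- background_sensitivity(df$fp, c(1800, 1850, 1900))
  rel <- apply(sens, 1, function(r) diff(range(r)) / mean(r))
  expect_lt(max(rel), 0.001)
})

test_that("period summary yields means, Factor and Recent correctly", {
  sim <- build_synthetic_core(step_scenario(), seed = 1, noise = FALSE)
  df <- date_and_flux(sim$profile)
  ps <- period_summary(df$fp)
  # constant concentration: conc factor 1, flux factor = MAR factor = 2
  expect_equal(ps$conc_factor, 1, tolerance = 1e-6)
  expect_equal(ps$flux_factor, 2, tolerance = 0.03)
  expect_equal(ps$flux_factor, ps$flux_post / ps$flux_pre)
  # Recent = mean of the two topmost included samples
  top2 <- df$fp[df$fp$included, ]
  top2 <- utils::head(top2[order(-top2$year), ], 2)
  expect_equal(ps$conc_recent, mean(top2$conc))
  expect_error(period_summary(df$fp, split_year = 1600), "empty period")

  # restricting to the measured CRS range drops extrapolated-age layers
  p <- as.data.frame(sim$profile)
  p$pb210_bq_kg[p$depth_top_cm >= 10] <- NA
  dfe <- date_and_flux(core_profile(p), quiet = TRUE)  # tail straddles the
  # MAR step, so the tail fit is rightly rejected with a warning
  fp_meas <- compute_fluxes(core_profile(p), dfe$fit,
                            use_extrapolated = FALSE)
  expect_true(any(dfe$fp$included & dfe$fp$source_flag == "extrapolated"))
  expect_false(any(fp_meas$included & fp_meas$source_flag == "extrapolated"))
})

test_that("layer exclusion is manual or by robust MAR z-score", {
  sim <- build_synthetic_core(scenario_peri_urban(), seed = 7, noise = FALSE)
  df <- date_and_flux(sim$profile)
  truth_ev <- sim$truth$layers$layer_id[sim$truth$layers$event]
  expect_length(truth_ev, 3)

  fpz <- exclude_layers(df$fp, z_threshold = 5)
  expect_setequal(attr(fpz, "excluded"), truth_ev)
  expect_true(all(!fpz$included[fpz$layer_id %in% truth_ev]))

  fpm <- exclude_layers(df$fp, layer_ids = truth_ev[1:2])
  expect_setequal(attr(fpm, "excluded"), truth_ev[1:2])
  expect_error(exclude_layers(df$fp, layer_ids = 9999), "unknown layer")

  # a quiet core triggers nothing
  quiet <- build_synthetic_core(constant_scenario(), seed = 1, noise = FALSE)
  dq <- date_and_flux(quiet$profile)
  expect_length(attr(exclude_layers(dq$fp, z_threshold = 5), "excluded"), 0)

  # excluded layers never reach period summaries (two events are post-1950)
  ps_all <- period_summary(df$fp)
  ps_exc <- period_summary(fpz)
  expect_false(isTRUE(all.equal(ps_all$flux_post, ps_exc$flux_post)))
  expect_false(any(is.na(ps_exc$flux_factor)))
  # ... nor the background mean when they fall inside the window
  fp_pre <- df$fp
  fp_pre$year[fp_pre$layer_id == truth_ev[1]] <- 1890  # drag event pre-1900
  fb_with <- background_flux(fp_pre, 1900)
  fb_without <- background_flux(exclude_layers(fp_pre, truth_ev[1]), 1900)
  expect_false(isTRUE(all.equal(fb_with, fb_without)))
})

test_that("depleted post-background composition yields negative F_A", {
  scn <- constant_scenario(
    span = 260,
    elements = list(Cd = element_spec(2, atm_share = -0.15, noise_cv = 0)))
  sim <- build_synthetic_core(scn, seed = 1, noise = FALSE)
  df <- date_and_flux(sim$profile)
  app <- apportion(df$fp, df$fit)
  expect_lt(share_of(app, "Cd"), -5)
  expect_true("Cd" %in% app$negative_f_a$element)
  # retained, not clipped
  expect_true(any(app$layers$f_a < 0, na.rm = TRUE))
})
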