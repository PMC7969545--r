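test_that("supported 210Pb estimators behave as documented", {
  p <- core_profile(data.frame(depth_top_cm = seq(0, 2, 0.5)[1:4],
                               depth_bottom_cm = seq(0.5, 2, 0.5),
                               dbd_g_cm3 = 0.2,
                               pb210_bq_kg = c(120, 60, 40, 30),
                               ra226_bq_kg = c(20, 22, 18, NA)))
  expect_equal(as.numeric(estimate_supported(p, "ra226-mean")), 20)

  # simulator truth: asymptote recovers the generated supported level
  scn <- constant_scenario(mar = 100, span = 400)
  sim <- build_synthetic_core(scn, seed = 1, noise = FALSE)
  est <- estimate_supported(sim$profile, "deep-asymptote")
  expect_lt(abs(est - scn$supported) / scn$supported, 0.05)

  # no equilibrium reached: warn but still return
  hot <- core_profile(data.frame(depth_top_cm = seq(0, 4.5, 0.5),
                                 depth_bottom_cm = seq(0.5, 5, 0.5),
                                 dbd_g_cm3 = 0.2,
                                 pb210_bq_kg = 400 * exp(-0.3 * (1:10))))
  expect_warning(est2 <- estimate_supported(hot, "deep-asymptote"),
                 "equilibrium")
  expect_gt(est2, 0)
  p2 <- p; p2$ra226_bq_kg <- NA_real_
  expect_error(estimate_supported(core_profile(p2), "ra226-mean"),
               "deep-asymptote")
})

test_that("unsupported profile subtracts, clips at zero and accumulates mass", {
  p <- core_profile(data.frame(depth_top_cm = c(0, 0.5, 1),
                               depth_bottom_cm = c(0.5, 1, 1.5),
                               dbd_g_cm3 = 0.2,
                               pb210_bq_kg = c(120, 15, 25)))
  ap <- unsupported_profile(p, 20)
  expect_equal(ap$unsupported, c(100, 0, 5))
  expect_equal(ap$clipped, c(FALSE, TRUE, FALSE))
  expect_equal(ap$mass_bottom, c(0.1, 0.2, 0.3))
  p$dbd_g_cm3 <- NA_real_
  expect_error(unsupported_profile(core_profile(p, validate = FALSE), 20),
               "dry-mass")
})

test_that("residual inventory integrates activity over cumulative mass", {
  mk_ap <- function(act, dm = 0.1) {
    n <- length(act)
    unsupported_profile(core_profile(data.frame(
      depth_top_cm = (0:(n - 1)) * 0.5, depth_bottom_cm = (1:n) * 0.5,
      dry_mass_g_cm2 = dm, pb210_bq_kg = act + 20)), 20)
  }
  expect_error(cumulative_residual_inventory(mk_ap(100)[1, ]), ">= 2")
  inv0 <- cumulative_residual_inventory(mk_ap(c(0, 0, 0)))
  expect_equal(inv0$inventory, rep(0, 4))

  # closed-form oracle: A(m) = A0 exp(-k m); I(0) = 10 * A0 / k
  a0 <- 200; k <- 8
  n <- 60; dm <- 0.05
  m_mid <- (1:n) * dm - dm / 2
  inv <- cumulative_residual_inventory(mk_ap(a0 * exp(-k * m_mid), dm = dm))
  closed <- 10 * a0 / k * (1 - exp(-k * n * dm))
  expect_lt(abs(inv$inventory[1] - closed) / closed, 0.01)
  expect_true(all(diff(inv$inventory) <= 0))
})

test_that("missing-inventory tail fit reproduces the hand-calculated case", {
  # activities halving over equal unit mass steps: decay ln(2) per step,
  # missing inventory = 10 * A(bottom) / ln(2) = 10 * 8 * 2^-3.5 / ln(2)
  ap <- unsupported_profile(core_profile(data.frame(
    depth_top_cm = 0:3, depth_bottom_cm = 1:4, dry_mass_g_cm2 = 1,
    pb210_bq_kg = c(8, 4, 2, 1) + 20)), 20)
  ap <- correct_missing_inventory(ap, tail_k = 4, eq_tol = 0)
  fit <- attr(ap, "tail_fit")
  expect_equal(fit$slope, -log(2), tolerance = 1e-10)
  expect_equal(attr(ap, "missing_inventory"), 10 * 8 * 2^-3.5 / log(2),
               tolerance = 1e-10)

  # already at equilibrium: correction vanishes
  ap0 <- unsupported_profile(core_profile(data.frame(
    depth_top_cm = 0:3, depth_bottom_cm = 1:4, dry_mass_g_cm2 = 1,
    pb210_bq_kg = c(220, 120, 20, 20))), 20)
  expect_equal(attr(correct_missing_inventory(ap0), "missing_inventory"), 0)

  # non-decaying tail is an error, not a silent fit
  apb <- unsupported_profile(core_profile(data.frame(
    depth_top_cm = 0:3, depth_bottom_cm = 1:4, dry_mass_g_cm2 = 1,
    pb210_bq_kg = c(21, 22, 23, 24))), 20)
  expect_error(correct_missing_inventory(apb, eq_tol = 0), "slope")
})

test_that("CRS identities hold: surface age zero, half-life at I0/2", {
  sim <- build_synthetic_core(constant_scenario(span = 250), seed = 1,
                              noise = FALSE)
  fit <- suppressWarnings(crs_date(sim$profile, coring_year = 2014))
  b <- fit$boundaries
  expect_equal(b$age[1], 0)
  expect_equal(b$year[1], 2014)
  # the age-inventory relation is exact at every boundary ...
  ok <- b$inventory > 0
  expect_equal(b$age[ok], log(b$inventory[1] / b$inventory[ok]) / fit$lambda)
  # ... so halving the inventory means exactly one half-life
  age_half <- approx(log(b$inventory[ok]), b$age[ok],
                     xout = log(b$inventory[1] / 2))$y
  expect_equal(age_half, 22.3, tolerance = 1e-6)
  expect_true(all(diff(fit$layers$age[fit$layers$source_flag == "crs"]) > 0))
})

test_that("forward-inverse CRS round trip recovers ages and MAR", {
  sim <- build_synthetic_core(scenario_remote_highland(), seed = 1,
                              noise = FALSE)
  fit <- suppressWarnings(crs_date(sim$profile, coring_year = 2014))
  L <- merge(fit$layers, sim$truth$layers, by = "layer_id")
  recent <- L$source_flag == "crs" & L$age <= 150
  expect_gt(sum(recent), 10)
  expect_lt(max(abs(L$year[recent] - L$true_year[recent])), 1)
  expect_lt(max(abs(L$mar[recent] / L$true_mar[recent] - 1)), 0.02)
  expect_true(all(L$mar[L$source_flag == "crs"] > 0))
})

test_that("noise-free CRS recovery error shrinks with layer thickness", {
  err_at <- function(layer_cm) {
    scn <- scenario_remote_highland()
    scn$layer_cm <- layer_cm
    sim <- build_synthetic_core(scn, seed = 1, noise = FALSE)
    fit <- suppressWarnings(crs_date(sim$profile, coring_year = 2014))
    L <- merge(fit$layers, sim$truth$layers, by = "layer_id")
    crs <- L$source_flag == "crs" & L$age <= 150
    max(abs(L$year[crs] - L$true_year[crs]))
  }
  errs <- vapply(c(1.0, 0.5, 0.25), err_at, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("missing-inventory correction restores truncated-core ages", {
  sim <- build_synthetic_core(constant_scenario(mar = 70, span = 260),
                              seed = 1, noise = FALSE)
  full <- crs_date(sim$profile, coring_year = 2014)
  # drop the deepest ~10% of the inventory (layers older than ~74 yr)
  cut_depth <- max(full$layers$depth_bottom_cm[full$layers$age < 74],
                   na.rm = TRUE)
  short <- core_profile(
    as.data.frame(sim$profile)[sim$profile$depth_bottom_cm <= cut_depth, ])
  trunc <- crs_date(short, coring_year = 2014, correct_missing = TRUE)
  expect_gt(trunc$missing_inventory, 0)
  L <- merge(full$layers, trunc$layers, by = "layer_id",
             suffixes = c(".full", ".trunc"))
  expect_lt(max(abs(L$year.full - L$year.trunc)), 2)
  # without the correction the deep truncated ages drift old
  raw <- crs_date(short, coring_year = 2014, correct_missing = FALSE)
  Lr <- merge(full$layers, raw$layers, by = "layer_id",
              suffixes = c(".full", ".raw"))
  expect_gt(max(abs(Lr$year.full - Lr$year.raw)),
            max(abs(L$year.full - L$year.trunc)))
})

test_that("age extrapolation is the anchor OLS and stays monotone", {
  # hand-checked OLS: years {1908,1902,1896,1891} at unit depth spacing
  # -> slope -5.7 yr/cm, next midpoint 1885.0
  prof <- core_profile(data.frame(depth_top_cm = 0:4, depth_bottom_cm = 1:5,
                                  dbd_g_cm3 = 0.2))
  fit <- structure(list(
    layers = data.frame(layer_id = 1:4, depth_top_cm = 0:3,
                        depth_bottom_cm = 1:4, depth_mid_cm = 0:3 + 0.5,
                        mass_mid = NA_real_, unsupported = NA_real_,
                        age = 2014 - c(1908, 1902, 1896, 1891),
                        age_sd = NA_real_,
                        year = c(1908, 1902, 1896, 1891),
                        mar = c(100, 101, 99, 100), mar_sd = NA_real_,
                        source_flag = "crs"),
    coring_year = 2014), class = "crs_fit")
  out <- extrapolate_ages(fit, prof, n_anchor = 4)
  ex <- out$layers[out$layers$source_flag == "extrapolated", ]
  expect_equal(nrow(ex), 1)
  expect_equal(ex$year, 1885.0, tolerance = 1e-9)
  expect_equal(ex$mar, 100)
  expect_lte(ex$year, min(fit$layers$year))
  expect_error(extrapolate_ages(fit, prof, n_anchor = 5), ">= 5")

  # constant-MAR core: extrapolated years track truth within 2 yr to 250 yr
  sim <- build_synthetic_core(constant_scenario(mar = 70, span = 260),
                              seed = 2, noise = FALSE)
  p <- as.data.frame(sim$profile)
  p$pb210_bq_kg[p$depth_top_cm >= 6] <- NA   # undate the deep half
  f2 <- crs_date(core_profile(p), coring_year = 2014)
  L <- merge(f2$layers, sim$truth$layers, by = "layer_id")
  ex2 <- L$source_flag == "extrapolated"
  expect_gt(sum(ex2), 5)
  expect_lt(max(abs(L$year[ex2] - L$true_year[ex2])), 2)
  expect_true(all(L$year[ex2] <= min(L$year[L$source_flag == "crs"])))
})

test_that("age-model export carries the chronology and its provenance", {
  sim <- build_synthetic_core(scenario_remote_highland(), seed = 5)
  fit <- suppressWarnings(crs_date(sim$profile, coring_year = 2014))
  path <- withr::local_tempfile(fileext = ".csv")
  write_age_model(fit, path)
  txt <- readLines(path)
  expect_true(any(grepl("supported_bq_kg", txt)))
  tab <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(tab), nrow(fit$layers))
  expect_true(all(c("year", "mar_g_m2_yr", "source_flag") %in% names(tab)))
})
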