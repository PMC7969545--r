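test_that("MAR histories interpolate control points and encode the presets", {
  scn <- constant_scenario(mar = 80)
  m <- simulate_mar_history(scn)
  expect_true(all(m$mar == 80))

  rem <- simulate_mar_history(scenario_remote_highland())
  ratio <- mean(rem$mar[rem$year >= 1950 & rem$year <= 1970]) /
    mean(rem$mar[rem$year < 1950])
  expect_equal(ratio, 2.0)
  per <- simulate_mar_history(scenario_peri_urban())
  expect_equal(per$mar / rem$mar, rep(5, nrow(rem)))

  bad <- constant_scenario()
  expect_error({bad$mar[1, 2] <- -5; scenario(mar = bad$mar,
                                              elements = bad$elements)},
               "positive")
})

test_that("concentration construction inverts the apportionment algebra", {
  scn <- constant_scenario(elements = list(Zn = element_spec(80, noise_cv = 0)))
  cc <- simulate_concentrations(scn)
  expect_true(all(cc$conc == 80))
  expect_true(all(cc$f_a == 0))

  # target atmospheric share is hit exactly on the annual grid
  scn2 <- scenario_remote_highland()
  m2 <- simulate_mar_history(scn2)
  cc2 <- simulate_concentrations(scn2, m2)
  hg <- cc2[cc2$element == "Hg", ]
  post <- hg$year >= 1950
  f_tot <- hg$conc * m2$mar
  expect_equal(sum(hg$f_a[post]) / sum(f_tot[post]), 0.42,
               tolerance = 1e-10)

  # doubling MAR with no atmospheric input leaves C and doubles F_tot
  s1 <- constant_scenario(mar = 100); s2 <- constant_scenario(mar = 200)
  c1 <- simulate_concentrations(s1); c2 <- simulate_concentrations(s2)
  expect_equal(c1$conc, c2$conc)
  expect_equal(c2$conc * 200, 2 * c1$conc * 100)
})

test_that("the 210Pb forward model honours its closed forms", {
  scn <- constant_scenario(mar = 100, span = 260)
  slabs <- simulate_pb210(scn)
  lam <- pb210_lambda()
  # surface activity ~ P/MAR (1000 Bq/kg per Bq/g)
  expect_equal(slabs$unsup_bq_kg[1], 1000 * scn$supply / 100,
               tolerance = 0.005)
  # inventory within the span + analytic tail = P/lambda exactly
  tail_inv <- scn$supply * exp(-lam * scn$span_yr) / lam
  expect_equal(sum(slabs$unsup_inv) + tail_inv, scn$supply / lam,
               tolerance = 1e-12)
  # truncating at age 120 removes exp(-lambda*120) of the inventory; the
  # missing-inventory estimator recovers that tail within 10% relative
  sim <- build_synthetic_core(scn, seed = 1, noise = FALSE)
  fit0 <- crs_date(sim$profile, coring_year = 2014)
  keep <- fit0$layers$layer_id[fit0$layers$age < 120]
  short <- core_profile(
    as.data.frame(sim$profile)[sim$profile$layer_id %in% keep, ])
  ap <- correct_missing_inventory(
    unsupported_profile(short, estimate_supported(short)), tail_k = 4)
  true_tail <- scn$supply * exp(-lam * 120) / lam
  expect_lt(abs(attr(ap, "missing_inventory") - true_tail) / true_tail, 0.10)
})

test_that("synthetic cores are deterministic and conserve truth components", {
  a <- build_synthetic_core(scenario_peri_urban(), seed = 9)
  b <- build_synthetic_core(scenario_peri_urban(), seed = 9)
  expect_identical(a, b)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_synthetic_core(a, d1); p2 <- write_synthetic_core(b, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  tr <- a$truth$elements
  ok <- !is.na(tr$f_v)
  expect_equal(tr$f_b[ok] + tr$f_v[ok] + tr$f_a[ok], tr$f_tot[ok])
  expect_true(all(concentration(a$profile, "Hg") >= 0))

  # events flagged in the truth but deliberately not in the profile
  expect_equal(sum(a$truth$layers$event), 3)
  expect_false(any(a$profile$event_layer))
})

test_that("noise-free end-to-end run recovers per-element flux factors", {
  sim <- build_synthetic_core(scenario_remote_highland(), seed = 1,
                              noise = FALSE)
  df <- date_and_flux(sim$profile)
  ps <- period_summary(df$fp)
  tr <- merge(sim$truth$elements, sim$truth$layers, by = "layer_id")
  for (el in unique(tr$element)) {
    d <- tr[tr$element == el & !tr$event, ]
    truth_factor <- mean(d$f_tot[d$true_year >= 1950]) /
      mean(d$f_tot[d$true_year < 1950])
    est <- ps$flux_factor[ps$element == el]
    expect_lt(abs(est / truth_factor - 1), 0.05, label = el)
  }
})

test_that("pipeline estimates converge to truth as layers thin", {
  err_at <- function(layer_cm) {
    scn <- scenario_remote_highland()
    scn$layer_cm <- layer_cm
    sim <- build_synthetic_core(scn, seed = 1, noise = FALSE)
    df <- date_and_flux(sim$profile)
    app <- apportion(df$fp, df$fit)
    tr <- sim$truth
    fb_true <- tr$mar_ref_true * scn$elements$Hg$background
    c(fb = abs(app$f_b[["Hg"]] / fb_true - 1),
      mar = abs(app$mar_ref / tr$mar_ref_true - 1))
  }
  errs <- sapply(c(1.0, 0.5, 0.25), err_at)
  expect_true(all(diff(errs["fb", ]) <= 1e-9))
  expect_true(all(diff(errs["mar", ]) <= 1e-9))
  expect_lt(errs["fb", 3], 0.02)
})

test_that("degenerate scenarios are rejected", {
  scn <- constant_scenario(span = 200, layer_cm = 20)
  expect_error(build_synthetic_core(scn, seed = 1), "mismatch")
  expect_error(element_spec(-1), "background")
  expect_error(element_spec(1, atm_share = 0.3, atm_flux = cbind(1950, 5)),
               "not both")
  expect_error(scenario_preset("nope"), "unknown preset")
})
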