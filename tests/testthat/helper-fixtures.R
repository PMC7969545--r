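# Shared fixtures: small profiles and fast scenarios built in code.

# two-layer hand profile with everything present
tiny_profile <- function() {
  core_profile(data.frame(
    depth_top_cm = c(0, 0.5), depth_bottom_cm = c(0.5, 1),
    dbd_g_cm3 = 0.2, pb210_bq_kg = c(120, 80), pb210_sd = c(6, 5),
    ra226_bq_kg = c(20, 22), hg_ug_g = c(0.1, 0.08),
    c_pct = c(8, 7), n_pct = c(0.6, 0.55), s_pct = c(0.6, 0.5)))
}

# constant-MAR, constant-composition scenario (fast property workhorse)
constant_scenario <- function(mar = 100, span = 200, layer_cm = 0.5,
                              elements = list(Zn = element_spec(80, noise_cv = 0)),
                              ...) {
  scenario(coring_year = 2014, span_yr = span, layer_cm = layer_cm,
           dbd = 0.15, supply = 130, supported = 25,
           mar = cbind(c(2014 - span + 1, 2014), c(mar, mar)),
           elements = elements, ...)
}

# MAR exactly doubled from 1950 onward, constant composition
step_scenario <- function(elements = list(Zn = element_spec(80, noise_cv = 0))) {
  scenario(coring_year = 2014, span_yr = 260, layer_cm = 0.5, dbd = 0.15,
           supply = 130, supported = 25,
           mar = cbind(c(1755, 1949, 1950, 2014), c(100, 100, 200, 200)),
           elements = elements)
}

# random positive piecewise-linear MAR history (for null-property loops)
random_mar_scenario <- function(seed,
                               elements = list(Zn = element_spec(80, noise_cv = 0))) {
  set.seed(seed)
  yrs <- c(1755, sort(sample(1760:2010, 4)), 2014)
  vals <- stats::runif(6, 40, 300)
  scenario(coring_year = 2014, span_yr = 260, layer_cm = 0.5, dbd = 0.15,
           supply = 130, supported = 25, mar = cbind(yrs, vals),
           elements = elements)
}

# full inverse pipeline: profile -> chronology -> fluxes; quiet = TRUE
# silences the expected deep-inventory truncation notice on noisy cores
date_and_flux <- function(profile, coring_year = 2014, quiet = FALSE, ...) {
  fit <- if (quiet)
    suppressWarnings(crs_date(profile, coring_year = coring_year, ...))
  else crs_date(profile, coring_year = coring_year, ...)
  list(fit = fit, fp = compute_fluxes(profile, fit))
}

share_of <- function(app, element, window = "post-1950", component = "F_A") {
  sh <- app$shares
  sh$share_pct[sh$element == element & sh$window == window &
                 sh$component == component]
}
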