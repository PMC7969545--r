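# Synthetic sediment-core simulator.
#
# Forward model: an annual deposition series with a prescribed MAR history
# and constant unsupported-210Pb supply P is discretized into core layers.
# Element concentrations are built by inverting the apportionment algebra
# (C(t) = C_B + F_A_true(t)/MAR(t)), so the true background / erosion /
# atmospheric components are known exactly per layer and sum to the total
# flux before noise.

#' Per-element simulation settings
#'
#' @param background background concentration C_B (ug g^-1): the
#'   concentration of erosion-derived matter.
#' @param atm_share target atmospheric/point-source share of the post-1950
#'   total flux, as a fraction (e.g. 0.42). May be negative to emulate a
#'   post-background depletion of the element (diagnostic negative-F_A
#'   case). Mutually exclusive with `atm_flux`.
#' @param atm_flux piecewise-linear control points for the atmospheric flux
#'   itself: 2-column matrix/data.frame (year, ug m^-2 yr^-1).
#' @param atm_shape pulse shape control points (year, weight) for the
#'   `atm_share` mode; zero outside the covered years. Default: onset 1950,
#'   peak 1980, 70% of peak at the coring year.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   concentration noise (default 0.11, mid-range of typical replicate
#'   RSDs).
#' @return list of class `element_spec`.
#' @export
element_spec <- function(background, atm_share = NULL, atm_flux = NULL,
                         atm_shape = NULL, noise_cv = 0.11) {
  stopifnot(background >= 0, noise_cv >= 0)
  if (!is.null(atm_share) && !is.null(atm_flux))
    stop("give atm_share or atm_flux, not both")
  if (!is.null(atm_share) && atm_share >= 1)
    stop("atm_share must be < 1")
  structure(list(background = background, atm_share = atm_share,
                 atm_flux = atm_flux, atm_shape = atm_shape,
                 noise_cv = noise_cv), class = "element_spec")
}

#' Define a synthetic-core scenario
#'
#' All knobs of the forward model: time span, layer slicing, dry-bulk
#' density, ²¹⁰Pb supply and supported level, the MAR history as
#' piecewise-linear control points, per-element settings, instantaneous
#' event layers, and C/N/S organic-matter settings.
#'
#' @param coring_year calendar year of coring.
#' @param span_yr years simulated (default 260).
#' @param layer_cm output layer thickness (cm, default 0.5).
#' @param dbd dry bulk density at the surface (g cm^-3).
#' @param dbd_ramp linear down-core compaction (g cm^-3 per cm, default 0).
#' @param supply unsupported ²¹⁰Pb supply rate P (Bq m^-2 yr^-1, constant).
#' @param supported supported ²¹⁰Pb level (Bq kg^-1).
#' @param mar 2-column matrix/data.frame of MAR control points
#'   (year, g m^-2 yr^-1), piecewise-linearly interpolated; must be
#'   positive.
#' @param elements named list of [element_spec()]s.
#' @param events list of `c(year, thickness_multiplier)` instantaneous
#'   event layers: a flood bed of `multiplier` years' worth of
#'   background-composition catchment material deposited at once.
#' @param cns list: `c_base` (%), `c_amp` (pulse amplitude, follows the Hg
#'   atmospheric shape when present), `cn_ratio`, `sc_ratio`, `noise_cv`.
#' @param pb_noise_cv Gaussian counting-noise CV on total ²¹⁰Pb
#'   (default 0.05).
#' @return list of class `core_scenario`.
#' @export
scenario <- function(coring_year = 2014, span_yr = 260, layer_cm = 0.5,
                     dbd = 0.15, dbd_ramp = 0, supply = 130, supported = 25,
                     mar, elements, events = list(),
                     cns = list(c_base = 8, c_amp = 2.5, cn_ratio = 13,
                                sc_ratio = 0.08, noise_cv = 0.05),
                     pb_noise_cv = 0.05) {
  mar <- as.matrix(as.data.frame(mar))
  if (ncol(mar) != 2) stop("mar must have 2 columns (year, value)")
  if (any(mar[, 2] <= 0)) stop("MAR control points must be positive")
  stopifnot(supply > 0, supported > 0, dbd > 0, layer_cm > 0, span_yr > 1)
  structure(list(coring_year = coring_year, span_yr = span_yr,
                 layer_cm = layer_cm, dbd = dbd, dbd_ramp = dbd_ramp,
                 supply = supply, supported = supported, mar = mar,
                 elements = elements, events = events, cns = cns,
                 pb_noise_cv = pb_noise_cv),
            class = "core_scenario")
}

scenario_years <- function(scn)
  seq(scn$coring_year - scn$span_yr + 1, scn$coring_year)

#' Annual MAR history of a scenario
#'
#' Piecewise-linear interpolation of the scenario's MAR control points on
#' the annual grid. Deterministic.
#'
#' @param scn a [scenario()].
#' @return data.frame `year`, `mar` (g m^-2 yr^-1).
#' @export
simulate_mar_history <- function(scn) {
  yrs <- scenario_years(scn)
  m <- stats::approx(scn$mar[, 1], scn$mar[, 2], xout = yrs, rule = 2)$y
  if (any(m <= 0)) stop("interpolated MAR must stay positive")
  data.frame(year = yrs, mar = m)
}

# piecewise-linear shape, zero outside the control range
.shape_at <- function(shape, years) {
  s <- stats::approx(shape[, 1], shape[, 2], xout = years, rule = 1)$y
  ifelse(is.na(s), 0, s)
}

#' Annual true concentrations and atmospheric fluxes
#'
#' Inverts the apportionment construction: erosion-derived matter carries
#' the background concentration at any MAR, and the atmospheric component
#' adds `F_A(t) / MAR(t)` on top. For `atm_share` elements the pulse shape
#' is scaled so that the atmospheric share of the post-1950 summed total
#' flux equals the target exactly (on the annual grid, pre-noise).
#'
#' @param scn a [scenario()].
#' @param mar annual MAR from [simulate_mar_history()] (computed when
#'   omitted).
#' @return data.frame: `year`, `element`, `conc` (pre-noise, ug g^-1),
#'   `f_a` (ug m^-2 yr^-1).
#' @export
simulate_concentrations <- function(scn, mar = simulate_mar_history(scn)) {
  out <- lapply(names(scn$elements), function(el) {
    es <- scn$elements[[el]]
    f_a <- rep(0, nrow(mar))
    if (!is.null(es$atm_flux)) {
      af <- as.matrix(as.data.frame(es$atm_flux))
      f_a <- .shape_at(af, mar$year)
    } else if (!is.null(es$atm_share) && es$atm_share != 0) {
      shape <- es$atm_shape
      if (is.null(shape))
        shape <- cbind(c(1950, 1980, scn$coring_year), c(0, 1, 0.7))
      s <- .shape_at(as.matrix(as.data.frame(shape)), mar$year)
      post <- mar$year >= 1950
      s_sum <- sum(s[post])
      if (s_sum <= 0) stop("atmospheric shape is zero over the post-1950 window")
      bg_sum <- es$background * sum(mar$mar[post])
      q <- es$atm_share * bg_sum / ((1 - es$atm_share) * s_sum)
      f_a <- q * s
    }
    conc <- es$background + f_a / mar$mar
    if (any(conc < 0)) {
      conc <- pmax(conc, 0)  # truncate depletion below zero concentration
      f_a <- (conc - es$background) * mar$mar
    }
    data.frame(year = mar$year, element = el, conc = conc, f_a = f_a)
  })
  do.call(rbind, out)
}

#' Annual ²¹⁰Pb forward model
#'
#' Matter deposited at age `a` before coring carries unsupported activity
#' `P / MAR * exp(-lambda * a)`. Each year is split into `n_sub` sub-slabs
#' whose unsupported inventory is the exact integral of the supply decay
#' over the sub-interval, so the total inventory is `P / lambda` exactly
#' and discretization bias in the inverse CRS model is negligible.
#'
#' @param scn a [scenario()].
#' @param mar annual MAR history.
#' @param lambda decay constant (default [pb210_lambda()]).
#' @param n_sub sub-annual steps (default 12).
#' @return data.frame of deposition slabs, youngest first: `year`,
#'   `age_top`/`age_bot` (yr before coring), `mass` (g m^-2), `unsup_inv`
#'   (Bq m^-2), `unsup_bq_kg`.
#' @export
simulate_pb210 <- function(scn, mar = simulate_mar_history(scn),
                           lambda = pb210_lambda(), n_sub = 12) {
  yrs <- rev(mar$year)                       # youngest first
  m <- rev(mar$mar)
  age0 <- scn$coring_year - yrs              # age of the young edge
  sub <- seq_len(n_sub) - 1
  age_top <- rep(age0, each = n_sub) + sub / n_sub
  age_bot <- age_top + 1 / n_sub
  mass <- rep(m / n_sub, each = n_sub)
  inv <- scn$supply * (exp(-lambda * age_top) - exp(-lambda * age_bot)) / lambda
  data.frame(year = rep(yrs, each = n_sub), age_top = age_top,
             age_bot = age_bot, mass = mass, unsup_inv = inv,
             unsup_bq_kg = 1000 * inv / mass)
}

#' Build a synthetic core with known ground truth
#'
#' Runs the full forward model: annual MAR, concentration and ²¹⁰Pb series,
#' slicing into layers of the configured thickness, event-layer injection,
#' and measurement noise. Event layers are inserted as separate beds of
#' background-composition material with ambient activity diluted by their
#' thickness multiplier (the classic flood-layer signature); they are
#' flagged in the truth but NOT in the profile, so detection rules can be
#' tested against the truth.
#'
#' @param scn a [scenario()] (see [scenario_remote_highland()],
#'   [scenario_peri_urban()]).
#' @param seed integer seed fixing all randomness; identical
#'   (scenario, seed) pairs give identical output.
#' @param noise apply measurement noise (default TRUE). With `FALSE` the
#'   output is the exact pre-noise forward model.
#' @param n_sub sub-annual discretization steps (default 12).
#' @return list of class `synthetic_core`: `$profile` (a [core_profile()]),
#'   `$truth` (per-layer true year, MAR, event flag; per-element true
#'   `f_b`, `f_v`, `f_a`, `f_tot` with `f_b + f_v + f_a = f_tot` exactly
#'   pre-noise; scalars `supply`, `supported`, `mar_ref_true`), and
#'   `$scenario`.
#' @export
build_synthetic_core <- function(scn, seed = NULL, noise = TRUE, n_sub = 12) {
  if (!is.null(seed)) set.seed(seed)
  mar <- simulate_mar_history(scn)
  conc <- simulate_concentrations(scn, mar)
  slabs <- simulate_pb210(scn, mar, n_sub = n_sub)
  slabs$mass_cm2 <- slabs$mass / 1e4         # g m^-2 -> g cm^-2

  # depth of each slab via (possibly depth-dependent) dry bulk density
  n <- nrow(slabs)
  thick <- numeric(n); z <- 0
  if (scn$dbd_ramp == 0) {
    thick <- slabs$mass_cm2 / scn$dbd
  } else {
    for (i in seq_len(n)) {                  # incremental compaction ramp
      thick[i] <- slabs$mass_cm2[i] / (scn$dbd + scn$dbd_ramp * z)
      z <- z + thick[i]
    }
  }
  bot <- cumsum(thick); top <- bot - thick
  total <- bot[n]
  n_layer <- floor(total / scn$layer_cm)
  if (n_layer < 10)
    stop("span/thickness mismatch: only ", n_layer, " layers would result")
  z1 <- (seq_len(n_layer) - 1) * scn$layer_cm
  z2 <- z1 + scn$layer_cm

  els <- names(scn$elements)
  conc_m <- matrix(unlist(lapply(els, function(el)
    conc$conc[conc$element == el])), ncol = length(els),
    dimnames = list(NULL, els))              # rows follow mar$year order
  fa_m <- matrix(unlist(lapply(els, function(el)
    conc$f_a[conc$element == el])), ncol = length(els),
    dimnames = list(NULL, els))
  yr_idx <- match(slabs$year, mar$year)      # slab -> year row
  hg_shape <- if ("Hg" %in% els && any(fa_m[, "Hg"] != 0))
    fa_m[, "Hg"] / max(abs(fa_m[, "Hg"])) else rep(0, nrow(mar))
  c_year <- scn$cns$c_base + scn$cns$c_amp * hg_shape

  agg <- function(v_slab, w) as.vector(v_slab %*% w) # weighted layer sums
  # overlap weight matrix: slab x layer fractions of slab thickness
  W <- matrix(0, n, n_layer)
  for (j in seq_len(n_layer)) {
    ov <- pmax(0, pmin(bot, z2[j]) - pmax(top, z1[j]))
    W[, j] <- ov / thick
  }
  mass_l <- agg(slabs$mass, W)
  wmean <- function(v) agg(v * slabs$mass, W) / mass_l
  # true deposition time = mean calendar time (age 0 = coring), not the
  # integer year label: year t's deposit spans ages [cy - t, cy - t + 1)
  year_l <- wmean(scn$coring_year - (slabs$age_top + slabs$age_bot) / 2)
  mar_l <- wmean(mar$mar[yr_idx])
  inv_l <- agg(slabs$unsup_inv, W)
  unsup_l <- 1000 * inv_l / mass_l           # Bq kg^-1
  conc_l <- sapply(els, function(el) wmean(conc_m[yr_idx, el]))
  fa_l <- sapply(els, function(el) wmean(fa_m[yr_idx, el]))
  c_l <- wmean(c_year[yr_idx])

  L <- data.frame(layer_id = seq_len(n_layer), depth_top_cm = z1,
                  depth_bottom_cm = z2, dry_mass_g_cm2 = mass_l / 1e4,
                  unsup = unsup_l, year = year_l, mar = mar_l,
                  event = FALSE, c_pct = c_l)
  conc_l <- matrix(conc_l, ncol = length(els), dimnames = list(NULL, els))
  fa_l <- matrix(fa_l, ncol = length(els), dimnames = list(NULL, els))

  # inject event beds as separate rows at the depth of their year
  if (length(scn$events) > 0) {
    ev_years <- vapply(scn$events, `[`, numeric(1), 1)
    ev_mult <- vapply(scn$events, `[`, numeric(1), 2)
    for (k in order(ev_years, decreasing = TRUE)) {
      y <- ev_years[k]; mult <- ev_mult[k]
      i_year <- which(mar$year == round(y))
      if (length(i_year) == 0) stop("event year ", y, " outside the span")
      pos <- max(which(L$year >= y & !L$event), 1)  # insert below this layer
      amb <- L$unsup[pos]                    # ambient activity at that depth
      ev_mass <- mult * mar$mar[i_year] / 1e4      # g cm^-2
      ev <- L[1, ]
      ev$dry_mass_g_cm2 <- ev_mass
      ev$unsup <- amb / mult                 # diluted flood-bed signature
      ev$year <- y; ev$mar <- NA_real_; ev$event <- TRUE
      ev$c_pct <- scn$cns$c_base
      L <- rbind(L[seq_len(pos), ], ev, L[-seq_len(pos), ])
      conc_l <- rbind(conc_l[seq_len(pos), , drop = FALSE],
                      vapply(els, function(el) scn$elements[[el]]$background,
                             numeric(1)),
                      conc_l[-seq_len(pos), , drop = FALSE])
      fa_l <- rbind(fa_l[seq_len(pos), , drop = FALSE],
                    rep(0, length(els)),
                    fa_l[-seq_len(pos), , drop = FALSE])
    }
    # rebuild the depth scale from layer masses and the dbd model
    th <- numeric(nrow(L)); z <- 0
    for (i in seq_len(nrow(L))) {
      th[i] <- L$dry_mass_g_cm2[i] / (scn$dbd + scn$dbd_ramp * z)
      z <- z + th[i]
    }
    L$depth_bottom_cm <- cumsum(th)
    L$depth_top_cm <- L$depth_bottom_cm - th
    L$layer_id <- seq_len(nrow(L))
  }

  # measurement noise
  pb_true <- L$unsup + scn$supported
  pb_sd <- scn$pb_noise_cv * pb_true
  ra_sd <- 0.05 * scn$supported
  if (noise) {
    pb_obs <- pmax(stats::rnorm(nrow(L), pb_true, pb_sd), 0)
    ra_obs <- pmax(stats::rnorm(nrow(L), scn$supported, ra_sd), 0)
    for (el in els) {
      cv <- scn$elements[[el]]$noise_cv
      if (cv > 0) {
        sdl <- sqrt(log(1 + cv^2))
        conc_l[, el] <- conc_l[, el] *
          stats::rlnorm(nrow(L), -sdl^2 / 2, sdl)  # mean-one lognormal
      }
    }
    ccv <- scn$cns$noise_cv
    sdl <- sqrt(log(1 + ccv^2))
    L$c_pct <- L$c_pct * stats::rlnorm(nrow(L), -sdl^2 / 2, sdl)
  } else {
    pb_obs <- pb_true
    ra_obs <- rep(scn$supported, nrow(L))
  }

  prof <- data.frame(layer_id = L$layer_id,
                     depth_top_cm = L$depth_top_cm,
                     depth_bottom_cm = L$depth_bottom_cm,
                     dry_mass_g_cm2 = L$dry_mass_g_cm2,
                     pb210_bq_kg = pb_obs, pb210_sd = pb_sd,
                     ra226_bq_kg = ra_obs, ra226_sd = rep(ra_sd, nrow(L)),
                     c_pct = L$c_pct,
                     n_pct = L$c_pct / scn$cns$cn_ratio,
                     s_pct = L$c_pct * scn$cns$sc_ratio,
                     event_layer = FALSE)    # events unflagged on purpose
  for (el in els) prof[[paste0(tolower(el), "_ug_g")]] <- conc_l[, el]
  profile <- core_profile(prof)

  # ground truth: components built to sum to the total flux exactly
  mar_ref_true <- mean(mar$mar[mar$year < 1900])
  truth_el <- do.call(rbind, lapply(els, function(el) {
    cb <- scn$elements[[el]]$background
    f_b <- rep(cb * mar_ref_true, nrow(L))
    f_v <- cb * (L$mar - mar_ref_true)
    f_a <- fa_l[, el]
    data.frame(element = el, layer_id = L$layer_id,
               conc_true = cb + ifelse(is.na(L$mar), 0, f_a / L$mar),
               f_b = f_b, f_v = f_v, f_a = f_a, f_tot = f_b + f_v + f_a)
  }))
  rownames(truth_el) <- NULL
  truth <- list(
    layers = data.frame(layer_id = L$layer_id, depth_top_cm = L$depth_top_cm,
                        depth_bottom_cm = L$depth_bottom_cm,
                        true_year = L$year, true_mar = L$mar,
                        event = L$event),
    elements = truth_el, mar_annual = mar, supply = scn$supply,
    supported = scn$supported, mar_ref_true = mar_ref_true,
    cutoff_year = 1900)
  structure(list(profile = profile, truth = truth, scenario = scn),
            class = "synthetic_core")
}

#' @export
print.synthetic_core <- function(x, ...) {
  cat("Synthetic sediment core:", nrow(x$profile), "layers,",
      length(attr(x$profile, "elements")), "elements,",
      sum(x$truth$layers$event), "event layer(s)\n")
  invisible(x)
}

#' Shipped scenarios: remote highland and peri-urban lakes
#'
#' Two contrasting presets. `scenario_remote_highland()` emulates a small
#' high-elevation lake: low, pre-1950-constant MAR that doubles after 1950,
#' dips around 1985-1992 and partly recovers; erosion-dominated trace
#' elements; Hg carrying a large (42%) post-1950 atmospheric share.
#' `scenario_peri_urban()` emulates a lake near a city: 5x higher MAR,
#' strong post-1950 atmospheric pulses for Pb, As and Hg, and three
#' instantaneous flood beds. Background concentrations follow typical
#' Andean volcanic-soil lake sediments.
#'
#' @return a [scenario()].
#' @export
scenario_remote_highland <- function() {
  mar <- cbind(c(1755, 1949, 1950, 1970, 1985, 1992, 2014),
               c(70, 70, 140, 140, 140, 100, 120))
  scenario(
    coring_year = 2014, span_yr = 260, layer_cm = 0.5, dbd = 0.15,
    supply = 130, supported = 25, mar = mar,
    elements = list(
      Cr = element_spec(16.7, noise_cv = 0.16),
      Ni = element_spec(8.8, noise_cv = 0.11),
      Cu = element_spec(24.7, atm_share = 0.10,
                        atm_shape = cbind(c(1950, 1990, 2014), c(0, 0.5, 1)),
                        noise_cv = 0.11),
      Zn = element_spec(76.3, noise_cv = 0.11),
      As = element_spec(14.2, atm_share = 0.20,
                        atm_shape = cbind(c(1950, 1985, 2014), c(0, 1, 0.8)),
                        noise_cv = 0.12),
      Cd = element_spec(0.42, noise_cv = 0.13),
      Pb = element_spec(22.7, atm_share = 0.12,
                        atm_shape = cbind(c(1950, 1985, 2014), c(0, 1, 0.8)),
                        noise_cv = 0.07),
      Hg = element_spec(0.094, atm_share = 0.42,
                        atm_shape = cbind(c(1950, 1975, 1990, 2014),
                                          c(0, 1, 0.8, 0.9)),
                        noise_cv = 0.11)))
}

#' @rdname scenario_remote_highland
#' @export
scenario_peri_urban <- function() {
  mar <- cbind(c(1755, 1949, 1950, 1970, 1985, 1992, 2014),
               c(350, 350, 700, 700, 700, 500, 600))
  scenario(
    coring_year = 2014, span_yr = 260, layer_cm = 0.5, dbd = 0.25,
    supply = 160, supported = 30, mar = mar,
    elements = list(
      Cr = element_spec(27.1, noise_cv = 0.16),
      Ni = element_spec(8.1, noise_cv = 0.11),
      Cu = element_spec(31.7, atm_share = 0.28, noise_cv = 0.11),
      Zn = element_spec(178.8, atm_share = 0.25, noise_cv = 0.11),
      As = element_spec(25.9, atm_share = 0.36, noise_cv = 0.12),
      Cd = element_spec(2.11, atm_share = 0.16, noise_cv = 0.13),
      Pb = element_spec(76.8, atm_share = 0.50, noise_cv = 0.07),
      Hg = element_spec(0.111, atm_share = 0.40,
                        atm_shape = cbind(c(1950, 1980, 2014), c(0, 1, 0.6)),
                        noise_cv = 0.11)),
    events = list(c(1910, 8), c(1963, 8), c(1995, 8)))
}

#' Look up a shipped scenario by name
#'
#' @param name `"remote-highland"` or `"peri-urban"`.
#' @return a [scenario()].
#' @export
scenario_preset <- function(name) {
  switch(name,
         "remote-highland" = scenario_remote_highland(),
         "peri-urban" = scenario_peri_urban(),
         stop("unknown preset '", name,
              "'; available: remote-highland, peri-urban"))
}

#' Write a synthetic core and its truth tables to files
#'
#' Writes `<prefix>_core.csv` (standard core-table format, readable by
#' [read_core_table()]) and `<prefix>_truth.csv` (per-layer, per-element
#' true components joined to the true chronology).
#'
#' @param sim a [build_synthetic_core()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "synthetic").
#' @return character vector of the two paths, invisibly.
#' @export
write_synthetic_core <- function(sim, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  core_path <- file.path(dir, paste0(prefix, "_core.csv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.csv"))
  write_core_table(sim$profile, core_path)
  tr <- merge(sim$truth$elements, sim$truth$layers, by = "layer_id")
  tr <- tr[order(tr$element, tr$layer_id), ]
  utils::write.csv(tr, truth_path, row.names = FALSE, na = "")
  invisible(c(core = core_path, truth = truth_path))
}
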