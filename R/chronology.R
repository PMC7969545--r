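# CRS (constant rate of supply) 210Pb chronology.
#
# Unit constants: activity Bq kg^-1, layer dry mass g cm^-2.
# 1 Bq kg^-1 * 1 g cm^-2 = 10 Bq m^-2, hence the factor 10 in inventories;
# lambda * I / A is in kg m^-2 yr^-1, hence the factor 1000 for MAR in
# g m^-2 yr^-1.
.INV_UNIT <- 10
.MAR_UNIT <- 1000

#' Default ²¹⁰Pb decay constant
#'
#' `ln(2) / 22.3` yr^-1 (half-life 22.3 yr).
#' @export
pb210_lambda <- function() log(2) / 22.3

#' Estimate supported ²¹⁰Pb
#'
#' Supported ²¹⁰Pb is produced in situ from ²²⁶Ra decay and does not date the
#' sediment; it must be subtracted from total ²¹⁰Pb before CRS modelling.
#' Two estimators are offered: the mean of the measured ²²⁶Ra activities
#' (`"ra226-mean"`, the default when ²²⁶Ra was measured), or the mean of the
#' deepest total ²¹⁰Pb values where the profile has reached equilibrium
#' (`"deep-asymptote"`).
#'
#' @param profile a [core_profile()].
#' @param method `"ra226-mean"` or `"deep-asymptote"`.
#' @param n_deep number of deepest ²¹⁰Pb values averaged by the asymptote
#'   method (>= 3).
#' @return positive scalar (Bq kg^-1) with attribute `method`. The asymptote
#'   method warns when the deep tail is still clearly above the asymptote
#'   (no equilibrium reached) but returns the estimate anyway.
#' @export
estimate_supported <- function(profile,
                               method = c("ra226-mean", "deep-asymptote"),
                               n_deep = 3) {
  method <- match.arg(method)
  if (method == "ra226-mean") {
    ra <- profile$ra226_bq_kg[!is.na(profile$ra226_bq_kg)]
    if (length(ra) == 0)
      stop("no 226Ra values: use method = 'deep-asymptote'")
    out <- mean(ra)
  } else {
    pb <- profile$pb210_bq_kg[!is.na(profile$pb210_bq_kg)]
    if (length(pb) < n_deep)
      stop("deep-asymptote needs >= ", n_deep, " 210Pb values")
    tail_pb <- utils::tail(pb, n_deep)
    out <- mean(tail_pb)
    # equilibrium check: tail should be flat, not still decaying
    if (length(pb) > n_deep) {
      above <- pb[seq_len(length(pb) - n_deep)]
      if (min(tail_pb) > 0 && (max(tail_pb) - min(tail_pb)) / out > 0.25)
        warning("deepest 210Pb values still decaying; ",
                "equilibrium may not be reached - asymptote estimate is rough")
    }
  }
  if (out <= 0) stop("supported 210Pb estimate is not positive")
  attr(out, "method") <- method
  out
}

#' Unsupported (excess) ²¹⁰Pb activity profile
#'
#' Subtracts the supported level from total ²¹⁰Pb and accumulates dry mass
#' down-core. Unsupported activity is clipped at 0 (flagged, never negative);
#' cumulative dry mass comes from per-layer dry mass ([layer_dry_mass()]).
#' Only the maximal run of layers from the surface with measured ²¹⁰Pb is
#' used -- deeper layers are left to age extrapolation.
#'
#' @param profile a [core_profile()].
#' @param supported supported ²¹⁰Pb (Bq kg^-1), e.g. from
#'   [estimate_supported()].
#' @return data.frame of class `activity_profile`: per dated layer
#'   `layer_id`, depths, `unsupported` and `unsupported_sd` (Bq kg^-1),
#'   per-layer dry mass `dm` and cumulative mass at layer top/mid/bottom
#'   (g cm^-2), and `clipped`.
#' @export
unsupported_profile <- function(profile, supported) {
  dm <- layer_dry_mass(profile)
  if (all(is.na(dm))) stop("no dry-mass information in profile")
  has_pb <- !is.na(profile$pb210_bq_kg)
  n_dated <- if (has_pb[1]) which.min(c(has_pb, FALSE)) - 1L else 0L
  if (n_dated < 2) stop("need >= 2 consecutive dated layers from the surface")
  i <- seq_len(n_dated)
  unsup <- profile$pb210_bq_kg[i] - supported
  clipped <- unsup < 0
  unsup[clipped] <- 0
  mass_bottom <- cumsum(dm[i])
  ap <- data.frame(
    layer_id = profile$layer_id[i],
    depth_top_cm = profile$depth_top_cm[i],
    depth_bottom_cm = profile$depth_bottom_cm[i],
    unsupported = unsup,
    unsupported_sd = profile$pb210_sd[i],
    dm = dm[i],
    mass_top = mass_bottom - dm[i],
    mass_mid = mass_bottom - dm[i] / 2,
    mass_bottom = mass_bottom,
    clipped = clipped)
  structure(ap, class = c("activity_profile", "data.frame"),
            supported = supported)
}

#' Cumulative residual ²¹⁰Pb inventory
#'
#' The inventory I(m) below each layer boundary, integrating layer-averaged
#' unsupported activity over cumulative dry mass (each layer contributes
#' activity x dry mass; the trapezoid of the piecewise-constant activity
#' step function). I is non-increasing with depth and reaches the appended
#' tail inventory (0 without a missing-inventory correction) at the core
#' bottom.
#'
#' @param ap an [unsupported_profile()], optionally carrying a
#'   `missing_inventory` attribute from [correct_missing_inventory()].
#' @return data.frame with one row per layer boundary (n layers + 1):
#'   `depth_cm`, cumulative `mass` (g cm^-2), `inventory` (Bq m^-2) and its
#'   1-sigma `inventory_sd` from counting errors.
#' @export
cumulative_residual_inventory <- function(ap) {
  n <- nrow(ap)
  if (n < 2) stop("need >= 2 layers to integrate an inventory")
  contrib <- .INV_UNIT * ap$unsupported * ap$dm
  tail_inv <- attr(ap, "missing_inventory")
  if (is.null(tail_inv)) tail_inv <- 0
  inv <- rev(cumsum(rev(c(contrib, tail_inv))))  # length n + 1
  var_contrib <- (.INV_UNIT * ifelse(is.na(ap$unsupported_sd), 0,
                                     ap$unsupported_sd) * ap$dm)^2
  inv_sd <- sqrt(rev(cumsum(rev(c(var_contrib, 0)))))
  if (all(is.na(ap$unsupported_sd))) inv_sd <- rep(NA_real_, n + 1)
  data.frame(depth_cm = c(ap$depth_top_cm[1], ap$depth_bottom_cm),
             mass = c(ap$mass_top[1], ap$mass_bottom),
             inventory = inv, inventory_sd = inv_sd)
}

#' Missing-inventory correction
#'
#' Cores truncated above the depth where unsupported ²¹⁰Pb reaches zero miss
#' part of the inventory, which biases CRS ages old near the core bottom.
#' The correction fits a log-linear regression of unsupported activity
#' against cumulative dry mass on the deepest `tail_k` positive layers and
#' adds the analytic integral of the fitted exponential from the core bottom
#' to infinity to the inventory at every boundary.
#'
#' @param ap an [unsupported_profile()].
#' @param tail_k number of deepest positive layers in the tail fit
#'   (default 4).
#' @param eq_tol equilibrium tolerance: when the deepest unsupported
#'   activity is below `eq_tol` times the surface activity the profile is
#'   considered complete and the correction is 0 (default 1e-4).
#' @return `ap` with attributes `missing_inventory` (Bq m^-2) and
#'   `tail_fit` (intercept/slope of log-activity vs mass, layer ids used).
#'   A non-decaying tail (slope >= 0) is an error: choose the tail
#'   manually. The regression tail is drawn from layers whose unsupported
#'   activity is significantly positive (> 2 counting sigma when
#'   uncertainties are given), so a noise-dominated deep tail cannot
#'   corrupt the fit.
#' @export
correct_missing_inventory <- function(ap, tail_k = 4, eq_tol = 1e-4) {
  floor_act <- pmax(0, ifelse(is.na(ap$unsupported_sd), 0,
                              2 * ap$unsupported_sd))
  pos <- which(ap$unsupported > floor_act)
  surface <- ap$unsupported[1]
  at_equilibrium <- length(pos) < 2 ||
    ap$unsupported[nrow(ap)] <= eq_tol * surface
  if (at_equilibrium) {
    # profile reaches equilibrium within the core: nothing is missing
    attr(ap, "missing_inventory") <- 0
    attr(ap, "tail_fit") <- NULL
    return(ap)
  }
  use <- utils::tail(pos, tail_k)
  if (length(use) < 2) stop("fewer than 2 positive layers for the tail fit")
  fit <- stats::lm(log(ap$unsupported[use]) ~ ap$mass_mid[use])
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b >= 0)
    stop("tail activity does not decay with mass (slope >= 0): ",
         "choose the regression tail manually")
  b_se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients[2, 2]),  # exact fits warn
    error = function(e) 0)
  if (is.finite(b_se) && b_se > 0 && abs(b) < 2 * b_se)
    stop("tail decay is not resolved by the data (slope within 2 SE of 0): ",
         "choose the regression tail manually")
  m_bot <- ap$mass_bottom[nrow(ap)]
  # integral of exp(a + b m) dm from m_bot to Inf = exp(a + b*m_bot)/(-b)
  missing <- .INV_UNIT * exp(a + b * m_bot) / (-b)
  measured <- .INV_UNIT * sum(ap$unsupported * ap$dm)
  if (missing > measured)
    stop("extrapolated tail inventory exceeds the measured inventory: ",
         "tail fit unreliable, choose the regression tail manually")
  attr(ap, "missing_inventory") <- missing
  attr(ap, "tail_fit") <- list(intercept = a, slope = b,
                               layer_id = ap$layer_id[use])
  ap
}

#' Fit the CRS age-depth model
#'
#' Constant-rate-of-supply model: the atmospheric supply of unsupported
#' ²¹⁰Pb to the sediment is assumed constant through time, so the age of a
#' layer boundary at cumulative mass m is `t(m) = log(I(0)/I(m)) / lambda`,
#' where I is the residual inventory below the boundary. The mass
#' accumulation rate of layer i is `MAR_i = lambda * I(m_i) / A_i` with A_i
#' the layer's unsupported activity and m_i its mass midpoint. Age
#' uncertainties are first-order propagation of the activity counting errors.
#'
#' Most users call [crs_date()], which chains the preparation steps and age
#' extrapolation; `crs_model()` is the bare model fit.
#'
#' @param ap an [unsupported_profile()], optionally after
#'   [correct_missing_inventory()].
#' @param coring_year calendar year of coring (age 0 at the sediment
#'   surface).
#' @param lambda ²¹⁰Pb decay constant (yr^-1); default [pb210_lambda()].
#' @return object of class `crs_fit`; see Details. Layers where the residual
#'   inventory or activity hits zero are left undated with a warning (model
#'   truncated).
#' @details A `crs_fit` holds `$layers` (per-layer `year`, `age`, `age_sd`,
#'   `mar`, `mar_sd`, `source_flag` in `{"crs", "clipped", "extrapolated",
#'   "undated"}` -- `clipped` layers have an age but no MAR because their
#'   unsupported activity was clipped at zero),
#'   `$boundaries` (boundary ages and inventories), and scalars `lambda`,
#'   `supported`, `total_inventory`, `missing_inventory`. Methods:
#'   [print.crs_fit()], [summary.crs_fit()], [plot.crs_fit()],
#'   [predict.crs_fit()], [coef.crs_fit()].
#' @export
crs_model <- function(ap, coring_year, lambda = pb210_lambda()) {
  bnd <- cumulative_residual_inventory(ap)
  I0 <- bnd$inventory[1]
  if (I0 <= 0) stop("surface inventory I(0) must be positive")
  n <- nrow(ap)
  ok_b <- bnd$inventory > 0
  age_b <- ifelse(ok_b, log(I0 / bnd$inventory) / lambda, NA_real_)
  age_b[1] <- 0
  # midpoint inventory: activity constant within a layer => linear in mass
  I_mid <- (bnd$inventory[-(n + 1)] + bnd$inventory[-1]) / 2
  has_age <- I_mid > 0
  # the dated range ends at the deepest layer whose unsupported activity is
  # significantly positive (> 2 counting sigma); deeper layers carry no
  # usable chronological signal and are left to age extrapolation
  sig <- ap$unsupported > pmax(0, ifelse(is.na(ap$unsupported_sd), 0,
                                         2 * ap$unsupported_sd))
  last_sig <- if (any(sig)) max(which(sig)) else 0L
  if (any(!has_age & seq_len(n) <= last_sig))
    warning("model truncated: zero residual inventory inside the dated ",
            "range leaves ", sum(!has_age & seq_len(n) <= last_sig),
            " layer(s) undated")
  has_age <- has_age & seq_len(n) <= last_sig
  datable <- has_age & ap$unsupported > 0
  age_mid <- ifelse(has_age, log(I0 / I_mid) / lambda, NA_real_)
  mar <- ifelse(datable, .MAR_UNIT * lambda * I_mid / ap$unsupported, NA_real_)
  mar_sd <- mar * ifelse(is.na(ap$unsupported_sd), NA_real_,
                         ap$unsupported_sd / ap$unsupported)
  # Var(log I0 - log Im) with nested sums (Im is a sub-sum of I0)
  sd0 <- bnd$inventory_sd[1]
  sd_mid <- sqrt(((bnd$inventory_sd[-(n + 1)]^2 + bnd$inventory_sd[-1]^2) / 2))
  age_sd <- if (is.na(sd0)) rep(NA_real_, n) else
    ifelse(datable, sqrt(pmax(0, sd0^2 / I0^2 + sd_mid^2 / I_mid^2 -
                                 2 * sd_mid^2 / (I0 * I_mid))) / lambda,
           NA_real_)
  layers <- data.frame(
    layer_id = ap$layer_id,
    depth_top_cm = ap$depth_top_cm,
    depth_bottom_cm = ap$depth_bottom_cm,
    depth_mid_cm = (ap$depth_top_cm + ap$depth_bottom_cm) / 2,
    mass_mid = ap$mass_mid,
    unsupported = ap$unsupported,
    age = age_mid, age_sd = age_sd,
    year = coring_year - age_mid,
    mar = mar, mar_sd = mar_sd,
    source_flag = ifelse(datable, "crs",
                         ifelse(has_age, "clipped", "undated")))
  bnd$age <- age_b
  bnd$year <- coring_year - age_b
  missing <- attr(ap, "missing_inventory")
  structure(list(layers = layers, boundaries = bnd, lambda = lambda,
                 coring_year = coring_year,
                 supported = as.numeric(attr(ap, "supported")),
                 supported_method = attr(attr(ap, "supported"), "method"),
                 total_inventory = I0,
                 missing_inventory = if (is.null(missing)) 0 else missing,
                 tail_fit = attr(ap, "tail_fit")),
            class = "crs_fit")
}

#' Extrapolate ages below the dated range
#'
#' Ordinary least squares of calendar year against midpoint depth on the
#' deepest `n_anchor` CRS-dated layers, applied to every deeper undated
#' layer. Extrapolated layers get the anchor-mean MAR and
#' `source_flag = "extrapolated"`; an extrapolated year is never younger
#' than the deepest dated layer.
#'
#' @param fit a [crs_model()] result.
#' @param profile the full [core_profile()] (supplies the undated deep
#'   layers).
#' @param n_anchor number of anchor layers (default 4).
#' @return the `crs_fit` with extrapolated layers appended.
#' @export
extrapolate_ages <- function(fit, profile, n_anchor = 4) {
  dated <- fit$layers[fit$layers$source_flag == "crs", ]
  if (nrow(dated) < n_anchor)
    stop("need >= ", n_anchor, " dated layers to extrapolate")
  anchors <- utils::tail(dated[order(dated$depth_mid_cm), ], n_anchor)
  ols <- stats::lm(year ~ depth_mid_cm, data = anchors)
  deepest_year <- min(dated$year)
  mid_all <- layer_mid(profile)
  deeper <- which(mid_all > max(dated$depth_mid_cm) &
                    !(profile$layer_id %in% dated$layer_id))
  if (length(deeper) == 0) return(fit)
  pred <- stats::predict(ols,
                         newdata = data.frame(depth_mid_cm = mid_all[deeper]))
  pred <- pmin(pred, deepest_year)
  dm <- layer_dry_mass(profile)
  extra <- data.frame(
    layer_id = profile$layer_id[deeper],
    depth_top_cm = profile$depth_top_cm[deeper],
    depth_bottom_cm = profile$depth_bottom_cm[deeper],
    depth_mid_cm = mid_all[deeper],
    mass_mid = NA_real_, unsupported = NA_real_,
    age = fit$coring_year - pred, age_sd = NA_real_,
    year = pred,
    mar = mean(anchors$mar), mar_sd = stats::sd(anchors$mar),
    source_flag = "extrapolated")
  keep <- fit$layers[!(fit$layers$layer_id %in% extra$layer_id), ]
  fit$layers <- rbind(keep, extra)
  fit$layers <- fit$layers[order(fit$layers$depth_top_cm), ]
  rownames(fit$layers) <- NULL
  fit$extrapolation <- list(n_anchor = n_anchor,
                            slope_yr_cm = unname(stats::coef(ols)[2]),
                            anchor_ids = anchors$layer_id)
  fit
}

#' Build a CRS chronology from a core profile
#'
#' One-call wrapper chaining [estimate_supported()],
#' [unsupported_profile()], [correct_missing_inventory()], [crs_model()]
#' and [extrapolate_ages()].
#'
#' @inheritParams estimate_supported
#' @inheritParams crs_model
#' @param supported optional known supported level (Bq kg^-1); overrides
#'   `method`.
#' @param correct_missing apply the missing-inventory correction
#'   (default TRUE).
#' @param tail_k tail length for the missing-inventory fit.
#' @param extrapolate extrapolate ages below the dated range (default TRUE).
#' @param n_anchor anchors for the extrapolation OLS.
#' @return a `crs_fit` (see [crs_model()]).
#' @examples
#' sim <- build_synthetic_core(scenario_remote_highland(), seed = 1)
#' fit <- crs_date(sim$profile, coring_year = 2014)
#' fit
#' @export
crs_date <- function(profile, coring_year,
                     method = c("ra226-mean", "deep-asymptote"),
                     supported = NULL, lambda = pb210_lambda(),
                     correct_missing = TRUE, tail_k = 4,
                     extrapolate = TRUE, n_anchor = 4) {
  if (is.null(supported)) supported <- estimate_supported(profile, method)
  ap <- unsupported_profile(profile, supported)
  if (correct_missing)
    ap <- tryCatch(correct_missing_inventory(ap, tail_k = tail_k),
                   error = function(e) {
                     warning("missing-inventory correction skipped: ",
                             conditionMessage(e))
                     attr(ap, "missing_inventory") <- 0
                     ap
                   })
  fit <- crs_model(ap, coring_year = coring_year, lambda = lambda)
  # extrapolation covers layers never dated AND deep layers the CRS model
  # could not resolve (clipped activity / exhausted inventory)
  if (extrapolate && sum(fit$layers$source_flag == "crs") >= n_anchor)
    fit <- extrapolate_ages(fit, profile, n_anchor = n_anchor)
  fit
}

#' @export
print.crs_fit <- function(x, ...) {
  n_crs <- sum(x$layers$source_flag == "crs")
  n_ex <- sum(x$layers$source_flag == "extrapolated")
  cat("CRS 210Pb age-depth model\n")
  cat(sprintf("  %d CRS-dated layer(s), %d extrapolated; coring year %d\n",
              n_crs, n_ex, x$coring_year))
  cat(sprintf("  supported 210Pb: %.2f Bq/kg (%s)\n", x$supported,
              if (is.null(x$supported_method)) "given" else x$supported_method))
  cat(sprintf("  inventory: %.1f Bq/m2 (missing-inventory term %.1f)\n",
              x$total_inventory, x$missing_inventory))
  rng <- range(x$layers$year, na.rm = TRUE)
  cat(sprintf("  years: %.0f-%.0f; MAR %.1f-%.1f g/m2/yr (dated layers)\n",
              rng[1], rng[2],
              min(x$layers$mar[x$layers$source_flag == "crs"], na.rm = TRUE),
              max(x$layers$mar[x$layers$source_flag == "crs"], na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.crs_fit <- function(object, ...) {
  print(object)
  cat("\nPer-layer chronology:\n")
  cols <- c("layer_id", "depth_mid_cm", "year", "age", "mar", "mar_sd",
            "source_flag")
  print(format(object$layers[, cols], digits = 4), row.names = FALSE)
  invisible(object$layers)
}

#' @export
coef.crs_fit <- function(object, ...) {
  c(supported_bq_kg = object$supported, lambda = object$lambda,
    total_inventory_bq_m2 = object$total_inventory,
    missing_inventory_bq_m2 = object$missing_inventory)
}

#' Predict calendar year at arbitrary depth
#'
#' Interpolates the fitted boundary ages within the dated range and uses the
#' extrapolation line (when fitted) below it.
#'
#' @param object a `crs_fit`.
#' @param depth numeric depths (cm below the sediment surface).
#' @param ... unused.
#' @return numeric calendar years (`NA` outside the model's range).
#' @export
predict.crs_fit <- function(object, depth, ...) {
  b <- object$boundaries[!is.na(object$boundaries$year), ]
  out <- stats::approx(b$depth_cm, b$year, xout = depth, rule = 1)$y
  if (!is.null(object$extrapolation)) {
    deeper <- which(depth > max(b$depth_cm))
    if (length(deeper) > 0) {
      sl <- object$extrapolation$slope_yr_cm
      y0 <- b$year[nrow(b)]
      out[deeper] <- pmin(y0 + sl * (depth[deeper] - max(b$depth_cm)), y0)
    }
  }
  out
}

#' @export
plot.crs_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  L <- x$layers
  crs <- L$source_flag == "crs"
  plot(L$year, L$depth_mid_cm, ylim = rev(range(L$depth_mid_cm)),
       xlab = "calendar year", ylab = "depth (cm)", type = "n",
       main = "CRS age-depth model", ...)
  graphics::lines(L$year[crs], L$depth_mid_cm[crs])
  graphics::points(L$year[crs], L$depth_mid_cm[crs], pch = 16, cex = 0.6)
  if (any(!crs))
    graphics::lines(L$year[!crs], L$depth_mid_cm[!crs], lty = 2)
  plot(L$year[crs], L$mar[crs], type = "s", xlab = "calendar year",
       ylab = "MAR (g m-2 yr-1)", main = "mass accumulation rate")
  invisible(x)
}

#' Export an age model as a delimited table
#'
#' Writes the per-layer chronology (layer_id, depth_mid_cm, year, age_yr,
#' mar_g_m2_yr, source_flag) preceded by `#`-prefixed provenance lines
#' (decay constant, supported level, inventories).
#'
#' @param fit a `crs_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_age_model <- function(fit, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# lambda_yr = %.8g", fit$lambda),
    sprintf("# supported_bq_kg = %.6g (%s)", fit$supported,
            if (is.null(fit$supported_method)) "given" else fit$supported_method),
    sprintf("# total_inventory_bq_m2 = %.6g", fit$total_inventory),
    sprintf("# missing_inventory_bq_m2 = %.6g", fit$missing_inventory),
    sprintf("# coring_year = %d", fit$coring_year)), con)
  out <- fit$layers[, c("layer_id", "depth_mid_cm", "year", "age", "mar",
                        "source_flag")]
  names(out) <- c("layer_id", "depth_mid_cm", "year", "age_yr",
                  "mar_g_m2_yr", "source_flag")
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}
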