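#' Construct a sediment core profile
#'
#' A `core_profile` is an ordered per-layer record of a short sediment core:
#' depth intervals, dry-mass information, radionuclide activities, element
#' concentrations and C/N/S content. It is the input object for the whole
#' pipeline ([crs_date()], [compute_fluxes()], ...).
#'
#' Layers are half-open depth intervals `[depth_top, depth_bottom)` in cm
#' below the sediment--water interface; the layer midpoint is used wherever a
#' single depth per layer is needed. Missing values are `NA`, never 0:
#' a zero concentration is a legal measurement.
#'
#' @param layers data.frame with at least `depth_top_cm` and `depth_bottom_cm`
#'   and one of `dbd_g_cm3` (dry bulk density, g cm^-3) or `dry_mass_g_cm2`
#'   (dry mass per area per layer). Optional columns: `layer_id`,
#'   `pb210_bq_kg`, `pb210_sd`, `ra226_bq_kg`, `ra226_sd`, element
#'   concentrations named `<el>_ug_g` (e.g. `hg_ug_g`), `c_pct`, `n_pct`,
#'   `s_pct`, and logical `event_layer`.
#' @param validate logical; run [validate_profile()] and stop on errors.
#'
#' @return A data.frame of class `core_profile`, sorted by `depth_top_cm`,
#'   with attribute `elements` (element names, capitalised) and a logical
#'   `below_lod` attribute matrix (layers x elements).
#' @seealso [read_core_table()], [validate_profile()]
#' @export
core_profile <- function(layers, validate = TRUE) {
  stopifnot(is.data.frame(layers))
  x <- as.data.frame(layers, stringsAsFactors = FALSE)
  need <- c("depth_top_cm", "depth_bottom_cm")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!any(c("dbd_g_cm3", "dry_mass_g_cm2") %in% names(x)))
    stop("need one of 'dbd_g_cm3' or 'dry_mass_g_cm2'")
  x <- x[order(x$depth_top_cm), , drop = FALSE]
  rownames(x) <- NULL
  if (is.null(x$layer_id)) x$layer_id <- seq_len(nrow(x))
  if (is.null(x$event_layer)) x$event_layer <- FALSE
  x$event_layer[is.na(x$event_layer)] <- FALSE
  for (col in c("dbd_g_cm3", "dry_mass_g_cm2", "pb210_bq_kg", "pb210_sd",
                "ra226_bq_kg", "ra226_sd", "c_pct", "n_pct", "s_pct"))
    if (is.null(x[[col]])) x[[col]] <- NA_real_
  els <- profile_elements(x)
  lod <- attr(layers, "below_lod")
  if (is.null(lod)) {
    lod <- matrix(FALSE, nrow(x), length(els), dimnames = list(NULL, els))
  }
  structure(x,
    class = c("core_profile", "data.frame"),
    elements = els, below_lod = lod) -> out
  if (validate) {
    f <- validate_profile(out)
    if (any(f$level == "error"))
      stop("invalid core profile:\n  ",
           paste(f$message[f$level == "error"], collapse = "\n  "))
  }
  out
}

profile_elements <- function(x) {
  nm <- grep("_ug_g$", names(x), value = TRUE)
  el <- sub("_ug_g$", "", nm)
  paste0(toupper(substring(el, 1, 1)), substring(el, 2))
}

#' Element concentration accessor
#'
#' @param profile a [core_profile()].
#' @param element element name as in `elements(profile)`, case-insensitive.
#' @return numeric vector of concentrations (ug g^-1), one per layer.
#' @export
concentration <- function(profile, element) {
  col <- paste0(tolower(element), "_ug_g")
  if (!col %in% names(profile))
    stop("no concentration column for element '", element, "'")
  profile[[col]]
}

#' @rdname concentration
#' @export
elements <- function(profile) attr(profile, "elements")

#' Layer midpoints, thicknesses and per-layer dry mass
#'
#' `layer_mid()` returns midpoint depths (cm); `layer_dry_mass()` the dry
#' mass per unit area of each layer (g cm^-2), taken from `dry_mass_g_cm2`
#' where present and otherwise computed as dry bulk density times thickness.
#'
#' @param profile a [core_profile()].
#' @return numeric vector, one value per layer.
#' @export
layer_mid <- function(profile) (profile$depth_top_cm + profile$depth_bottom_cm) / 2

#' @rdname layer_mid
#' @export
layer_dry_mass <- function(profile) {
  thick <- profile$depth_bottom_cm - profile$depth_top_cm
  dm <- profile$dry_mass_g_cm2
  use_dbd <- is.na(dm)
  dm[use_dbd] <- profile$dbd_g_cm3[use_dbd] * thick[use_dbd]
  dm
}

#' Validate a core profile
#'
#' Pure check of the `core_profile` invariants. Errors are invariant
#' violations (non-monotone or overlapping depths, negative activities or
#' concentrations, no dry-mass information); warnings flag conditions the
#' pipeline can work around (no ²²⁶Ra anywhere, below-LOD values, missing
#' ²¹⁰Pb at depth). The input is never modified.
#'
#' @param profile a `core_profile` (or plain data.frame with its columns).
#' @return data.frame of findings with columns `level` ("error"/"warning"),
#'   `layer_id` (NA for profile-wide findings) and `message`.
#' @export
validate_profile <- function(profile) {
  f <- list()
  add <- function(level, layer_id, message)
    f[[length(f) + 1]] <<- data.frame(level = level, layer_id = layer_id,
                                      message = message)
  top <- profile$depth_top_cm; bot <- profile$depth_bottom_cm
  id <- profile$layer_id
  bad <- which(!(top < bot))
  for (i in bad) add("error", id[i], sprintf(
    "layer %s: depth_top (%g) must be < depth_bottom (%g)", id[i], top[i], bot[i]))
  if (nrow(profile) > 1) {
    ov <- which(top[-1] < bot[-nrow(profile)] - 1e-9)
    for (i in ov) add("error", id[i + 1], sprintf(
      "layers %s and %s overlap or are out of order", id[i], id[i + 1]))
  }
  dm <- suppressWarnings(layer_dry_mass(profile))
  nb <- which(is.na(dm))
  for (i in nb) add("error", id[i], sprintf(
    "layer %s: neither dry bulk density nor areal dry mass given", id[i]))
  num_cols <- c("pb210_bq_kg", "ra226_bq_kg",
                grep("_ug_g$", names(profile), value = TRUE),
                "c_pct", "n_pct", "s_pct")
  for (col in intersect(num_cols, names(profile))) {
    neg <- which(!is.na(profile[[col]]) & profile[[col]] < 0)
    for (i in neg) add("error", id[i], sprintf(
      "layer %s: negative value in %s (%g)", id[i], col, profile[[col]][i]))
  }
  if (all(is.na(profile$ra226_bq_kg)))
    add("warning", NA, paste("no 226Ra activities: supported 210Pb must be",
                             "estimated by the deep-asymptote method"))
  if (any(is.na(profile$pb210_bq_kg)))
    add("warning", NA, sprintf("%d layer(s) without total 210Pb",
                               sum(is.na(profile$pb210_bq_kg))))
  lod <- attr(profile, "below_lod")
  if (!is.null(lod) && any(lod))
    add("warning", NA, sprintf("%d concentration value(s) below LOD", sum(lod)))
  if (length(f) == 0)
    return(data.frame(level = character(), layer_id = integer(),
                      message = character()))
  out <- do.call(rbind, f)
  rownames(out) <- NULL
  out
}

#' Default column-name schema for core tables
#'
#' Maps internal column names to file column names; pass a modified copy to
#' [read_core_table()] when a file uses different headers.
#' @return named character vector (internal name -> file column name).
#' @export
core_schema <- function() {
  c(depth_top_cm = "depth_top_cm", depth_bottom_cm = "depth_bottom_cm",
    dbd_g_cm3 = "dbd_g_cm3", dry_mass_g_cm2 = "dry_mass_g_cm2",
    pb210_bq_kg = "pb210_bq_kg", pb210_sd = "pb210_sd",
    ra226_bq_kg = "ra226_bq_kg", ra226_sd = "ra226_sd",
    c_pct = "c_pct", n_pct = "n_pct", s_pct = "s_pct",
    layer_id = "layer_id", event_layer = "event_layer")
}

#' Read / write a core table
#'
#' Core tables are comma-delimited UTF-8 text, one row per layer, with the
#' column names of [core_schema()] plus any number of `<el>_ug_g` element
#' columns. Empty cells are missing values; they are never read as zero.
#'
#' @param path file path.
#' @param schema optional named character vector mapping internal names to
#'   the file's column names (see [core_schema()]).
#' @return `read_core_table()`: a validated [core_profile()].
#' @export
read_core_table <- function(path, schema = core_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (internal in names(schema)) {
    filecol <- schema[[internal]]
    if (filecol %in% names(raw) && internal != filecol) {
      names(raw)[names(raw) == filecol] <- internal
    }
  }
  mandatory <- c("depth_top_cm", "depth_bottom_cm")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss) > 0)
    stop("core table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (!is.null(raw$event_layer)) raw$event_layer <- as.logical(raw$event_layer)
  # all-NA columns come back as logical; keep measurement columns numeric
  numcols <- c(setdiff(names(schema), c("layer_id", "event_layer")),
               grep("_ug_g$", names(raw), value = TRUE))
  for (col in intersect(numcols, names(raw)))
    raw[[col]] <- as.numeric(raw[[col]])
  core_profile(raw)
}

#' @rdname read_core_table
#' @param profile a [core_profile()].
#' @return `write_core_table()`: `path`, invisibly.
#' @export
write_core_table <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Lake metadata
#'
#' @param name lake name.
#' @param coring_year calendar year the core was retrieved.
#' @param lake_area_ha lake surface area (ha), > 0.
#' @param catchment_area_km2 catchment area (km^2), > 0.
#' @param elevation_m elevation (m a.s.l.), optional.
#' @param notes free text.
#' @return list of class `lake_metadata`.
#' @export
lake_metadata <- function(name, coring_year, lake_area_ha, catchment_area_km2,
                          elevation_m = NA_real_, notes = "") {
  stopifnot(lake_area_ha > 0, catchment_area_km2 > 0)
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  if (coring_year < 1900 || coring_year > this_year)
    stop("coring_year must lie in [1900, ", this_year, "]")
  structure(list(name = name, coring_year = coring_year,
                 lake_area_ha = lake_area_ha,
                 catchment_area_km2 = catchment_area_km2,
                 elevation_m = elevation_m, notes = notes),
            class = "lake_metadata")
}

#' Catchment-to-lake area ratio
#'
#' Dimensionless ratio of catchment area to lake surface area, a first-order
#' control on erosion-derived (lithogenic) input to the sediment record.
#'
#' @param md a [lake_metadata()] object.
#' @return numeric ratio (catchment km^2 x 100 / lake ha).
#' @export
catchment_lake_ratio <- function(md) {
  md$catchment_area_km2 * 100 / md$lake_area_ha
}

#' @export
print.lake_metadata <- function(x, ...) {
  cat("Lake:", x$name, "\n")
  cat(sprintf("  cored %d; %.1f ha; catchment %.2f km2 (ratio %.0f)\n",
              x$coring_year, x$lake_area_ha, x$catchment_area_km2,
              catchment_lake_ratio(x)))
  invisible(x)
}

#' Read a run configuration
#'
#' YAML file holding lake metadata and pipeline settings (background cutoff
#' year, period split year, decay constant, supported-Pb method, tail length
#' for the missing-inventory fit, extrapolation anchors, seed). Missing keys
#' get the defaults used throughout the package.
#'
#' @param path YAML file path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(cutoff_year = 1900, split_year = 1950,
                   lambda = log(2) / 22.3, supported_method = "ra226-mean",
                   tail_k = 4, n_anchor = 4, recovery_correct = FALSE,
                   exclude_layers = NULL, z_threshold = NULL, seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = c("run_config", "list"))
}
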