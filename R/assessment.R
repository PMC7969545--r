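# Contamination assessment against sediment-quality thresholds, between-lake
# comparison, element vs organic-matter correlation, and QA/QC utilities.

#' Exceedance factor
#'
#' Ratio of a concentration to a sediment-quality threshold. Values >= 1
#' mean the threshold is reached or exceeded.
#'
#' @param conc concentration (ug g^-1).
#' @param threshold threshold (ug g^-1), > 0; `NA` gives an `NA` factor
#'   (undefined, never 0).
#' @param digits optional rounding for display; the unrounded value is kept
#'   in `attr(, "raw")`.
#' @return numeric factor(s).
#' @export
exceedance_factor <- function(conc, threshold, digits = NULL) {
  if (any(!is.na(threshold) & threshold <= 0))
    stop("thresholds must be positive")
  raw <- conc / threshold
  out <- if (is.null(digits)) raw else round(raw, digits)
  attr(out, "raw") <- raw
  out
}

#' Classify period concentrations against sediment-quality thresholds
#'
#' Labels each element x period concentration against every available
#' threshold kind (LEL, ERL, TAS). "Exceeds" means strictly greater than
#' the threshold; an exact tie is classed as below and marked `boundary`.
#'
#' @param summary a [period_summary()] (or any data.frame with `element`,
#'   `conc_pre`, `conc_post`, `conc_recent`).
#' @param thresholds a [read_thresholds()] table; default the shipped one.
#' @return data.frame of class `exceedance_report`: `element`, `period`
#'   (pre/post/recent), `conc`, `kind`, `threshold`, `factor`, `exceeds`,
#'   `boundary`.
#' @export
sqg_classify <- function(summary, thresholds = default_thresholds()) {
  periods <- c(pre = "conc_pre", post = "conc_post", recent = "conc_recent")
  rows <- list()
  for (i in seq_len(nrow(summary))) {
    el <- summary$element[i]
    for (p in names(periods)) {
      conc <- summary[[periods[[p]]]][i]
      for (kind in c("lel", "erl", "tas")) {
        th <- threshold_lookup(thresholds, el, kind)
        if (is.na(th) || is.na(conc)) next
        fac <- conc / th
        rows[[length(rows) + 1]] <- data.frame(
          element = el, period = p, conc = conc, kind = toupper(kind),
          threshold = th, factor = fac, exceeds = conc > th,
          boundary = conc == th)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("exceedance_report", "data.frame"))
}

#' @export
print.exceedance_report <- function(x, ...) {
  ex <- x[x$exceeds, ]
  cat("Sediment-quality exceedance report:",
      nrow(ex), "of", nrow(x), "checks exceed a threshold\n")
  if (nrow(ex) > 0)
    print(format(as.data.frame(ex[, c("element", "period", "conc", "kind",
                                      "threshold", "factor")]), digits = 3),
          row.names = FALSE)
  invisible(x)
}

#' Between-lake ratio table
#'
#' Element-wise ratios (lake a over lake b) of period mean concentrations
#' and fluxes, sorted by the post-split flux ratio (descending).
#'
#' @param summary_a,summary_b [period_summary()] tables for the two lakes.
#' @return data.frame: `element`, `conc_pre`, `conc_post`, `flux_pre`,
#'   `flux_post` (each a ratio a/b). A zero denominator gives `NA` with a
#'   warning.
#' @export
between_lake_ratio <- function(summary_a, summary_b) {
  common <- intersect(summary_a$element, summary_b$element)
  if (length(common) == 0) stop("no common elements between summaries")
  a <- summary_a[match(common, summary_a$element), ]
  b <- summary_b[match(common, summary_b$element), ]
  rat <- function(x, y) {
    bad <- !is.na(y) & y == 0
    if (any(bad)) warning("zero-mean denominator; ratio set to NA")
    ifelse(bad, NA_real_, x / y)
  }
  out <- data.frame(element = common,
                    conc_pre = rat(a$conc_pre, b$conc_pre),
                    conc_post = rat(a$conc_post, b$conc_post),
                    flux_pre = rat(a$flux_pre, b$flux_pre),
                    flux_post = rat(a$flux_post, b$flux_post))
  out <- out[order(-out$flux_post), ]
  rownames(out) <- NULL
  out
}

#' Correlate element concentrations with organic-matter proxies
#'
#' Pearson correlations (with two-sided p-values) between element
#' concentrations and C, N, S contents down-core. Elements whose source or
#' cycling is tied to sedimentary organic matter (typically Hg, As) show
#' strong positive correlations. Complete-case pairs are used; a constant
#' series yields an `NA` coefficient flagged in the output.
#'
#' @param profile a [core_profile()] with `c_pct`/`n_pct`/`s_pct` columns.
#' @param targets element names; default all elements in the profile.
#' @param refs subset of `c("C", "N", "S")`.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()];
#'   default `"none"` (raw p-values, as conventional for this screening),
#'   `"holm"` available.
#' @return data.frame: `element`, `ref`, `r`, `p`, `n`, `constant`.
#' @export
correlate_elements <- function(profile, targets = NULL,
                               refs = c("C", "N", "S"), adjust = "none") {
  if (is.null(targets)) targets <- attr(profile, "elements")
  refcol <- c(C = "c_pct", N = "n_pct", S = "s_pct")
  rows <- list()
  for (el in targets) {
    x <- concentration(profile, el)
    for (rf in refs) {
      y <- profile[[refcol[[rf]]]]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n < 3) stop("fewer than 3 paired observations for ", el, " vs ", rf)
      const <- stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0
      if (const) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(element = el, ref = rf, r = r,
                                             p = p, n = n, constant = const)
    }
  }
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}

#' Recovery correction
#'
#' Scales a measured concentration by the certified-reference-material
#' recovery: `corrected = conc / (recovery / 100)`. The default pipeline
#' works on uncorrected values (a constant recovery changes no temporal
#' ratio); the correction is available behind this switch.
#'
#' @param conc measured concentration(s).
#' @param recovery recovery in percent (> 0).
#' @return corrected concentration(s).
#' @export
qa_recovery_correct <- function(conc, recovery) {
  if (any(recovery <= 0)) stop("recovery must be positive")
  conc / (recovery / 100)
}

#' Limit of detection from procedural blanks
#'
#' `LOD = mean(blanks) + k * sd(blanks)` (k = 3 by default). Works in
#' whatever domain the blanks are given in; convert digest-domain LODs to
#' sediment concentration units before flagging sample values.
#'
#' @param blanks numeric blank measurements (>= 2) for one element, or a
#'   named list of such vectors for several elements.
#' @param k multiplier on the blank standard deviation.
#' @return numeric LOD (or named vector for a list input).
#' @export
qa_lod <- function(blanks, k = 3) {
  if (is.list(blanks)) return(vapply(blanks, qa_lod, numeric(1), k = k))
  if (length(blanks) < 2) stop("need >= 2 blanks")
  mean(blanks) + k * stats::sd(blanks)
}

#' Flag below-LOD concentrations in a profile
#'
#' @param profile a [core_profile()].
#' @param lod named numeric vector of LODs in concentration units
#'   (ug g^-1), names matching elements.
#' @return the profile with its `below_lod` attribute matrix updated; the
#'   concentration values themselves are untouched (treatment of below-LOD
#'   values is left to the caller).
#' @export
flag_below_lod <- function(profile, lod) {
  m <- attr(profile, "below_lod")
  for (el in intersect(names(lod), colnames(m))) {
    v <- concentration(profile, el)
    m[, el] <- !is.na(v) & v < lod[[el]]
  }
  attr(profile, "below_lod") <- m
  profile
}

#' Replicate relative standard deviation
#'
#' RSD of each replicate set (`100 * sd / mean`, sample sd) and their mean:
#' the element-level reproducibility figure.
#'
#' @param sets list of numeric vectors (each a replicate set, >= 2 values).
#' @return list with `per_set` (numeric vector, `NA` for a zero-mean set,
#'   with a warning) and `mean_rsd`.
#' @export
qa_replicate_rsd <- function(sets) {
  if (!is.list(sets)) sets <- list(sets)
  per <- vapply(sets, function(s) {
    if (length(s) < 2) stop("each replicate set needs >= 2 values")
    m <- mean(s)
    if (m == 0) { warning("zero-mean replicate set: RSD undefined");
      return(NA_real_) }
    100 * stats::sd(s) / m
  }, numeric(1))
  list(per_set = per, mean_rsd = mean(per, na.rm = TRUE))
}
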