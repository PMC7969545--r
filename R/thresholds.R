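#' Sediment-quality threshold tables
#'
#' A `threshold_table` holds per-element concentration thresholds (ug g^-1
#' dry sediment): LEL (low effect level), ERL (effect range-low) and TAS
#' (threshold for agricultural soils). Any entry may be missing for an
#' element. LEL <= ERL is required where both are present, with Hg as the
#' one documented exception in the shipped defaults (LEL 0.2 > ERL 0.15).
#'
#' `default_thresholds()` returns the table shipped with the package
#' (V..Hg subset used for sediment-quality screening of lake cores).
#'
#' @param path delimited text file with columns `element`, `lel`, `erl`,
#'   `tas`; empty cells are missing thresholds.
#' @return data.frame of class `threshold_table`.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "lel", "erl", "tas")
  miss <- setdiff(need, names(tt))
  if (length(miss) > 0)
    stop("threshold table missing column(s): ", paste(miss, collapse = ", "))
  for (k in c("lel", "erl", "tas")) {
    tt[[k]] <- as.numeric(tt[[k]])
    if (any(!is.na(tt[[k]]) & tt[[k]] <= 0))
      stop("non-positive ", toupper(k), " threshold for element(s): ",
           paste(tt$element[!is.na(tt[[k]]) & tt[[k]] <= 0], collapse = ", "))
  }
  viol <- !is.na(tt$lel) & !is.na(tt$erl) & tt$lel > tt$erl &
    tt$element != "Hg"
  if (any(viol))
    warning("LEL > ERL for: ", paste(tt$element[viol], collapse = ", "))
  structure(tt, class = c("threshold_table", "data.frame"))
}

#' @rdname read_thresholds
#' @export
default_thresholds <- function() {
  read_thresholds(system.file("extdata", "sqg_thresholds.csv",
                              package = "limnotrace", mustWork = TRUE))
}

#' Look up one threshold
#'
#' @param thresholds a [read_thresholds()] table.
#' @param element element name (case-sensitive, e.g. "As").
#' @param kind one of "lel", "erl", "tas" (case-insensitive).
#' @return numeric threshold (ug g^-1), or `NA` when the element or value is
#'   absent from the table -- never 0.
#' @export
threshold_lookup <- function(thresholds, element, kind = c("lel", "erl", "tas")) {
  kind <- tolower(match.arg(kind))
  i <- match(element, thresholds$element)
  if (is.na(i)) return(NA_real_)
  thresholds[[kind]][i]
}
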