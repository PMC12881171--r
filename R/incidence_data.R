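#' Construct an age-bin table
#'
#' Age bins are closed-open intervals `[lower, upper)` in years.  The
#' regression abscissa used throughout the package is the bin midpoint
#' `(lower + upper) / 2`; open-ended bins (no upper bound) have no midpoint
#' and are excluded from fitting.
#'
#' @param breaks Strictly increasing numeric vector of bin edges in years;
#'   `n` edges define `n - 1` contiguous bins.
#' @return A data frame with columns `lower`, `upper`, `mid`.
#' @examples
#' age_bins(seq(25, 60, by = 5))
#' @export
age_bins <- function(breaks) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2L || any(diff(breaks) <= 0))
    stop("'breaks' must be a strictly increasing vector of at least 2 edges")
  data.frame(lower = breaks[-length(breaks)],
             upper = breaks[-1L],
             mid = (breaks[-length(breaks)] + breaks[-1L]) / 2)
}

series_columns <- c("registry", "age_lower", "age_upper", "age_mid",
                    "incidence", "cases", "person_years")

#' Build an incidence series
#'
#' An incidence series is the package's central container: one row per
#' registry x age-bin observation, holding the incidence rate per 100,000
#' person-years and, optionally, the case count and person-years it was
#' computed from.  A single data frame may hold several registries; most
#' fitting functions stack all rows, while hierarchical models use the
#' `registry` column as the grouping factor.
#'
#' @param registry Character vector of registry labels.
#' @param age_lower,age_upper Bin bounds in years; `NA` in `age_upper`
#'   marks an open-ended bin (no midpoint, excluded from fits).
#' @param incidence Incidence rate per 100,000 person-years; non-negative.
#' @param cases Optional non-negative case counts.
#' @param person_years Optional positive person-years at risk.  When both
#'   `cases` and `person_years` are given, `incidence` must equal
#'   `cases / person_years * 1e5` up to rounding.
#' @param provenance Free-text note stored as an attribute.
#' @return A data frame of class `"incidence_series"`, sorted by registry
#'   and bin midpoint, with columns `registry`, `age_lower`, `age_upper`,
#'   `age_mid`, `incidence`, `cases`, `person_years`.
#' @export
incidence_series <- function(registry, age_lower, age_upper, incidence,
                             cases = NA_real_, person_years = NA_real_,
                             provenance = "") {
  df <- data.frame(registry = as.character(registry),
                   age_lower = as.numeric(age_lower),
                   age_upper = as.numeric(age_upper),
                   incidence = as.numeric(incidence),
                   cases = as.numeric(cases),
                   person_years = as.numeric(person_years))
  df$age_mid <- ifelse(is.na(df$age_upper), NA_real_,
                       (df$age_lower + df$age_upper) / 2)
  df <- df[series_columns]
  validate_series(df)
  df <- df[order(df$registry, df$age_mid, df$age_lower), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("incidence_series", "data.frame"))
}

# Invariant checks shared by the constructor and the CSV reader.  `where`
# labels offending rows in error messages (e.g. file line numbers).
validate_series <- function(df, where = seq_len(nrow(df))) {
  bad <- function(cond, msg) {
    if (any(cond, na.rm = TRUE))
      stop(sprintf("%s (row %s)", msg,
                   paste(where[which(cond)], collapse = ", ")), call. = FALSE)
  }
  bad(!is.finite(df$age_lower), "non-numeric or missing lower age bound")
  bad(!is.na(df$age_upper) & df$age_upper <= df$age_lower,
      "age_upper must exceed age_lower for bounded bins")
  bad(is.na(df$incidence) | df$incidence < 0,
      "incidence must be a non-negative number")
  bad(!is.na(df$cases) & df$cases < 0, "cases must be non-negative")
  bad(!is.na(df$person_years) & df$person_years <= 0,
      "person_years must be positive")
  both <- !is.na(df$cases) & !is.na(df$person_years)
  if (any(both)) {
    implied <- df$cases[both] / df$person_years[both] * 1e5
    # rounding tolerance: printed rates are typically given to ~2 decimals
    off <- abs(implied - df$incidence[both]) >
      pmax(0.05, 0.01 * pmax(implied, df$incidence[both]))
    bad_rows <- where[both][off]
    if (length(bad_rows))
      stop(sprintf(
        "incidence inconsistent with cases/person_years x 100,000 (row %s)",
        paste(bad_rows, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read age-binned incidence data from CSV
#'
#' Expects a UTF-8, comma-separated file with a header and columns
#' `registry`, `age_lower`, `age_upper`, `incidence`, and optionally
#' `cases` and `person_years`.  An open upper age bound is encoded as an
#' empty field or `"+"`.  Malformed rows (negative incidence, non-numeric
#' fields, inverted bounds) raise an error naming the offending row.
#'
#' @param path Path to the CSV file.
#' @return An [incidence_series] data frame covering all registries in the
#'   file, sorted by registry and bin midpoint.
#' @seealso [write_incidence_csv()] for the inverse operation.
#' @export
read_incidence_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("registry", "age_lower", "age_upper", "incidence")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  num <- function(col, x) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    if (any(!is.na(x) & nzchar(x) & is.na(out)))
      stop(sprintf("non-numeric value in column '%s' (row %s)", col,
                   paste(which(!is.na(x) & nzchar(x) & is.na(out)),
                         collapse = ", ")), call. = FALSE)
    out
  }
  upper_raw <- trimws(raw$age_upper)
  open <- is.na(upper_raw) | upper_raw == "" | upper_raw == "+"
  upper <- rep(NA_real_, nrow(raw))
  upper[!open] <- num("age_upper", upper_raw[!open])
  incidence_series(
    registry = raw$registry,
    age_lower = num("age_lower", raw$age_lower),
    age_upper = upper,
    incidence = num("incidence", raw$incidence),
    cases = if ("cases" %in% names(raw)) num("cases", raw$cases) else NA_real_,
    person_years = if ("person_years" %in% names(raw))
      num("person_years", raw$person_years) else NA_real_,
    provenance = paste0("read from ", path))
}

#' Write an incidence series to CSV
#'
#' Emits the same dialect accepted by [read_incidence_csv()]; open-ended
#' bins are written with an empty `age_upper` field.  Round-tripping a
#' valid series reproduces all fields.
#'
#' @param series An [incidence_series].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_incidence_csv <- function(series, path) {
  df <- as.data.frame(series)[c("registry", "age_lower", "age_upper",
                                "incidence", "cases", "person_years")]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter incidence records for curve comparison
#'
#' Applies the standard inclusion rules before fitting: only adult age
#' ranges, only non-zero incidences (zeros, which arise from finite
#' sampling, become minus-infinity outliers on the log scale), and only
#' bounded bins (open-ended bins have no midpoint).  A bin straddling the
#' adult cutoff is dropped: the rule is `age_lower >= adult_age`.
#'
#' @param series An [incidence_series].
#' @param adult_only Drop bins with `age_lower < adult_age`.
#' @param drop_zero Drop records with zero incidence.
#' @param drop_unbounded Drop open-ended bins.
#' @param adult_age Adult cutoff in years (default 18).
#' @return A new filtered [incidence_series]; the input is untouched.
#'   Removing every record yields an empty series with a warning.
#' @export
filter_records <- function(series, adult_only = TRUE, drop_zero = TRUE,
                           drop_unbounded = TRUE, adult_age = 18) {
  stopifnot(inherits(series, "incidence_series"))
  keep <- rep(TRUE, nrow(series))
  if (adult_only) keep <- keep & series$age_lower >= adult_age
  if (drop_zero) keep <- keep & series$incidence > 0
  if (drop_unbounded) keep <- keep & !is.na(series$age_upper)
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("all records removed by filtering; returning an empty series")
  structure(out, provenance = attr(series, "provenance"),
            class = class(series))
}

#' Pool several registries onto a common age-bin grid
#'
#' Reconstructs an overall series by summing cases and person-years per
#' bin and recomputing incidence as `cases / person_years * 1e5`.  All
#' registries must share an identical bin grid.  When counts are absent,
#' two declared approximations are available: a person-years-weighted mean
#' of rates (if person-years are present), or a plain mean behind an
#' explicit override, flagged as approximate in the provenance.
#'
#' @param series A multi-registry [incidence_series].
#' @param fallback `"none"` (require counts; the default), `"person_years"`
#'   (weight rates by person-years), or `"mean"` (unweighted mean of rates).
#' @param pooled_id Registry label for the pooled pseudo-registry.
#' @return A single-registry [incidence_series].
#' @export
pool_registries <- function(series, fallback = c("none", "person_years", "mean"),
                            pooled_id = "pooled") {
  stopifnot(inherits(series, "incidence_series"))
  fallback <- match.arg(fallback)
  parts <- split(as.data.frame(series), series$registry)
  if (length(parts) == 1L) return(series)
  key <- function(df) paste(df$age_lower, df$age_upper, sep = "-",
                            collapse = ";")
  keys <- vapply(parts, function(df)
    key(df[order(df$age_lower), ]), character(1))
  if (length(unique(keys)) != 1L)
    stop("registries do not share an identical age-bin grid; cannot pool")
  grid <- parts[[1L]][order(parts[[1L]]$age_lower),
                      c("age_lower", "age_upper")]
  stack <- as.data.frame(series)
  k <- paste(stack$age_lower, stack$age_upper)
  gkey <- paste(grid$age_lower, grid$age_upper)
  have_counts <- all(!is.na(stack$cases)) && all(!is.na(stack$person_years))
  if (have_counts) {
    cases <- tapply(stack$cases, k, sum)[gkey]
    py <- tapply(stack$person_years, k, sum)[gkey]
    inc <- cases / py * 1e5
    note <- "pooled by summed cases and person-years"
  } else if (fallback == "person_years" && all(!is.na(stack$person_years))) {
    py <- tapply(stack$person_years, k, sum)[gkey]
    inc <- tapply(stack$incidence * stack$person_years, k, sum)[gkey] / py
    cases <- rep(NA_real_, nrow(grid))
    note <- "pooled by person-years-weighted mean of rates (approximate)"
  } else if (fallback == "mean") {
    inc <- tapply(stack$incidence, k, mean)[gkey]
    cases <- rep(NA_real_, nrow(grid))
    py <- rep(NA_real_, nrow(grid))
    note <- "pooled by unweighted mean of rates (approximate)"
  } else {
    stop("cases/person_years missing for some records and no fallback enabled")
  }
  incidence_series(registry = pooled_id,
                   age_lower = grid$age_lower, age_upper = grid$age_upper,
                   incidence = as.numeric(inc), cases = as.numeric(cases),
                   person_years = as.numeric(py),
                   provenance = note)
}

#' Number of registries in a series
#' @param series An [incidence_series].
#' @return Integer count of distinct registry labels.
#' @export
n_registries <- function(series) length(unique(series$registry))

#' @export
print.incidence_series <- function(x, ...) {
  cat(sprintf("<incidence_series> %d record(s), %d registr%s\n",
              nrow(x), n_registries(x),
              if (n_registries(x) == 1L) "y" else "ies"))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("provenance:", prov, "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
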