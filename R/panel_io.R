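#' @keywords internal
"_PACKAGE"

# Required panel columns, in canonical order. `state` is a 2-letter
# jurisdiction code (50 states + DC), `year` a calendar year.
PANEL_COLUMNS <- c(
  "state", "year", "total_cost", "q_inst", "q_hcbs",
  "hcbs_share", "waiver_share", "icfmr_share",
  "managed_care", "con", "population", "pc_income", "unemployment"
)

#' Jurisdiction universe: 50 US states plus the District of Columbia
#'
#' @return Character vector of 51 two-letter codes, sorted.
#' @export
state_codes <- function() {
  sort(c(
    "AL", "AK", "AZ", "AR", "CA", "CO", "CT", "DE", "DC", "FL", "GA", "HI",
    "ID", "IL", "IN", "IA", "KS", "KY", "LA", "ME", "MD", "MA", "MI", "MN",
    "MS", "MO", "MT", "NE", "NV", "NH", "NJ", "NM", "NY", "NC", "ND", "OH",
    "OK", "OR", "PA", "RI", "SC", "SD", "TN", "TX", "UT", "VT", "VA", "WA",
    "WV", "WI", "WY"
  ))
}

#' Construct a validated state-by-year LTSS panel
#'
#' The panel is the unit of analysis for the whole pipeline: one row per
#' state-year holding deflatable total LTSS expenditure, institutional and
#' HCBS participant counts (the two outputs of the cost frontier), policy
#' covariates and socioeconomic controls.
#'
#' Row-level invariants enforced: `total_cost > 0`, counts nonnegative with
#' `q_inst + q_hcbs > 0`, shares in \[0, 100\], binary policies in \{0, 1\},
#' `population > 0`, `pc_income > 0`, year inside `year_range`. Rows with
#' missing covariates are rejected (no imputation). Zero participant counts
#' are allowed at this stage but flagged, since the frontier design takes
#' logs of the counts.
#'
#' @param records data.frame with the columns in `PANEL_COLUMNS`.
#' @param base_year deflation base year, or `NA` if costs are still nominal.
#' @param provenance free-text source tags.
#' @param year_range allowed inclusive year range.
#' @return An object of class `ltss_panel`.
#' @export
ltss_panel <- function(records, base_year = NA_integer_,
                       provenance = character(),
                       year_range = c(1999L, 2007L)) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(PANEL_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("panel schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[, PANEL_COLUMNS]
  records$state <- as.character(records$state)
  records$year <- as.integer(records$year)
  num_cols <- setdiff(PANEL_COLUMNS, c("state", "year"))
  for (cc in num_cols) records[[cc]] <- as.numeric(records[[cc]])

  diag <- validate_panel_records(records, year_range)
  if (length(diag$errors) > 0) {
    stop("panel integrity error:\n  ",
         paste(diag$errors, collapse = "\n  "), call. = FALSE)
  }
  keep <- !diag$reject
  if (any(diag$reject)) {
    warning(sum(diag$reject), " row(s) rejected:\n  ",
            paste(diag$row_messages[diag$reject], collapse = "\n  "),
            call. = FALSE)
  }
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) stop("panel input error: no valid rows", call. = FALSE)
  if (length(diag$flags) > 0) {
    for (f in diag$flags) message("panel flag: ", f)
  }
  # states must contribute at least 2 years to be usable downstream
  records <- records[order(records$state, records$year), , drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(records = records,
         base_year = as.integer(base_year),
         provenance = provenance,
         year_range = as.integer(year_range)),
    class = "ltss_panel"
  )
}

# Per-row invariant checks. Returns per-row reject mask + messages, panel
# level errors (duplicates), and non-fatal flags (zero counts).
validate_panel_records <- function(records, year_range) {
  n <- nrow(records)
  reject <- logical(n)
  msgs <- character(n)
  errors <- character()
  flags <- character()

  key <- paste(records$state, records$year)
  dup <- duplicated(key)
  if (any(dup)) {
    errors <- c(errors, paste0("duplicate (state, year): ",
                               paste(unique(key[dup]), collapse = "; ")))
  }
  bad_state <- !(records$state %in% state_codes())
  num_cols <- setdiff(PANEL_COLUMNS, c("state", "year"))
  has_na <- rowSums(!is.finite(as.matrix(records[, num_cols, drop = FALSE]))) > 0 |
    is.na(records$year) | is.na(records$state)

  for (i in seq_len(n)) {
    probs <- character()
    if (bad_state[i]) probs <- c(probs, "unknown state code")
    if (has_na[i]) probs <- c(probs, "missing value (no imputation)")
    if (!has_na[i]) {
      r <- records[i, ]
      if (r$year < year_range[1] || r$year > year_range[2])
        probs <- c(probs, sprintf("year %d outside [%d, %d]",
                                  r$year, year_range[1], year_range[2]))
      if (r$total_cost <= 0) probs <- c(probs, "total_cost <= 0")
      if (r$q_inst < 0 || r$q_hcbs < 0) probs <- c(probs, "negative count")
      if (r$q_inst + r$q_hcbs <= 0) probs <- c(probs, "no LTSS participants")
      for (sh in c("hcbs_share", "waiver_share", "icfmr_share"))
        if (r[[sh]] < 0 || r[[sh]] > 100)
          probs <- c(probs, paste0(sh, " outside [0, 100]"))
      for (bv in c("managed_care", "con"))
        if (!r[[bv]] %in% c(0, 1)) probs <- c(probs, paste0(bv, " not binary"))
      if (r$population <= 0) probs <- c(probs, "population <= 0")
      if (r$pc_income <= 0) probs <- c(probs, "pc_income <= 0")
      if (length(probs) == 0 && (r$q_inst == 0 || r$q_hcbs == 0))
        flags <- c(flags, sprintf("%s %d: zero participant count (log-transform handled at design stage)",
                                  r$state, r$year))
    }
    if (length(probs) > 0) {
      reject[i] <- TRUE
      msgs[i] <- sprintf("row %d (%s %s): %s", i, records$state[i],
                         records$year[i], paste(probs, collapse = "; "))
    }
  }
  list(reject = reject, row_messages = msgs, errors = errors, flags = flags)
}

#' @export
print.ltss_panel <- function(x, ...) {
  cat(sprintf("ltss_panel: %d records, %d states, years %d-%d\n",
              nrow(x$records), length(unique(x$records$state)),
              min(x$records$year), max(x$records$year)))
  if (!is.na(x$base_year))
    cat(sprintf("  costs deflated to %d dollars\n", x$base_year))
  invisible(x)
}

#' @export
as.data.frame.ltss_panel <- function(x, ...) x$records

#' Number of records in a panel
#' @param x an `ltss_panel`.
#' @export
n_records <- function(x) nrow(x$records)

#' Read a state-by-year panel from CSV
#'
#' Expects a UTF-8 CSV with a header row and one row per state-year. Columns
#' may be renamed via `schema` (a named character vector mapping canonical
#' name -> file column name). Rows violating record invariants are rejected
#' with row-level diagnostics (as warnings); structural problems (missing
#' columns, duplicate keys, empty file) are errors.
#'
#' @param path CSV file path.
#' @param schema optional named character vector, e.g.
#'   `c(total_cost = "expenditure")`.
#' @param year_range allowed inclusive year range.
#' @return an `ltss_panel`.
#' @export
load_panel <- function(path, schema = NULL, year_range = c(1999L, 2007L)) {
  if (!file.exists(path)) stop("input error: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("input error: empty panel file: ", path, call. = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop("schema error: mapped column not found: ", src, call. = FALSE)
      names(df)[names(df) == src] <- canon
    }
  }
  ltss_panel(df, provenance = paste0("csv:", path), year_range = year_range)
}

#' Write a panel to CSV (inverse of [load_panel()])
#'
#' Floats are serialized at full precision so that
#' `load_panel(write_panel(x))` is the identity field-for-field.
#'
#' @param data an `ltss_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  stopifnot(inherits(data, "ltss_panel"))
  df <- data$records
  num_cols <- setdiff(PANEL_COLUMNS, c("state", "year"))
  out <- df
  for (cc in num_cols) out[[cc]] <- format(df[[cc]], digits = 17, trim = TRUE,
                                           scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default sample-construction exclusion rules
#'
#' Arizona is dropped entirely (capitated managed care only, no
#' service-level expenditure data); Vermont is dropped for 2006-2007
#' (transition to an 1115 global waiver). Applied to a complete 51
#' jurisdiction x 9 year grid these rules leave 448 state-year records.
#'
#' @return list of rules, each `list(state = , years = )` with `years = NULL`
#'   meaning all years.
#' @export
default_exclusions <- function() {
  list(
    list(state = "AZ", years = NULL),
    list(state = "VT", years = c(2006L, 2007L))
  )
}

#' Apply sample exclusion rules to a panel
#'
#' Idempotent and order-independent across rules; removal counts are logged
#' via `message()`.
#'
#' @param data an `ltss_panel`.
#' @param rules list of `list(state = , years = )` rules; default =
#'   [default_exclusions()].
#' @return the filtered `ltss_panel`.
#' @export
apply_exclusions <- function(data, rules = default_exclusions()) {
  stopifnot(inherits(data, "ltss_panel"))
  df <- data$records
  drop <- logical(nrow(df))
  for (rule in rules) {
    if (!rule$state %in% state_codes())
      stop("configuration error: unknown state code in exclusion rule: ",
           rule$state, call. = FALSE)
    hit <- df$state == rule$state
    if (!is.null(rule$years)) hit <- hit & df$year %in% rule$years
    message(sprintf("exclusion %s%s: %d record(s) removed", rule$state,
                    if (is.null(rule$years)) " (all years)"
                    else paste0(" {", paste(rule$years, collapse = ","), "}"),
                    sum(hit & !drop)))
    drop <- drop | hit
  }
  out <- data
  out$records <- df[!drop, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Construct a CPI series
#'
#' @param years integer years.
#' @param values positive index values, same length.
#' @return data.frame of class `cpi_series` with columns `year`, `cpi`.
#' @export
cpi_series <- function(years, values) {
  stopifnot(length(years) == length(values))
  if (any(!is.finite(values)) || any(values <= 0))
    stop("cpi values must be positive and finite", call. = FALSE)
  if (anyDuplicated(years)) stop("duplicate years in cpi series", call. = FALSE)
  structure(data.frame(year = as.integer(years), cpi = as.numeric(values)),
            class = c("cpi_series", "data.frame"))
}

#' Read a two-column `year,cpi` CSV
#'
#' A bundled synthetic default covering 1999-2007 (values in the vicinity
#' of the urban CPI of that era) ships at
#' `system.file("extdata", "cpi_synthetic.csv", package = "ltssfa")`; real
#' analyses should supply the actual deflator series.
#'
#' @param path CSV path.
#' @return a `cpi_series`.
#' @export
load_cpi <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "cpi") %in% names(df)))
    stop("schema error: cpi file needs columns year, cpi", call. = FALSE)
  cpi_series(df$year, df$cpi)
}

#' Deflate panel costs to a base year
#'
#' Each `total_cost` is multiplied by `cpi[base_year] / cpi[year]`, so
#' within-year cost ratios are preserved exactly and base-year costs are
#' unchanged. The base year is recorded on the panel.
#'
#' @param data an `ltss_panel`.
#' @param cpi a `cpi_series` covering every panel year and `base_year`.
#' @param base_year deflation target year (default 2005).
#' @return the deflated `ltss_panel`.
#' @export
deflate_costs <- function(data, cpi, base_year = 2005L) {
  stopifnot(inherits(data, "ltss_panel"), inherits(cpi, "cpi_series"))
  need <- sort(unique(c(data$records$year, base_year)))
  missing_years <- setdiff(need, cpi$year)
  if (length(missing_years) > 0)
    stop("coverage error: cpi missing year(s) ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  idx <- stats::setNames(cpi$cpi, cpi$year)
  out <- data
  out$records$total_cost <- data$records$total_cost *
    idx[[as.character(base_year)]] / idx[as.character(data$records$year)]
  names(out$records$total_cost) <- NULL
  out$base_year <- as.integer(base_year)
  out
}
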