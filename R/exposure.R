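#' Read a replicate-level exposure/mortality table
#'
#' Reads and validates the CSV layout used for raw assay data: one row per
#' experimental unit per census day, with the count of animals still alive.
#' Required columns: `species`, `population` (may be empty), `dose` (ppb; 0
#' for controls), `control_kind` (`"water"`, `"vehicle"` or `"none"`),
#' `replicate`, `block`, `day` (1-8), `alive`, `total`. A measured
#' concentration may accompany the nominal one as `dose_measured`.
#'
#' Validation enforces: counts are non-negative integers with
#' `alive <= total`; `dose` is 0 exactly when the row is a control; `alive`
#' never increases across days within a unit (animals do not resurrect).
#'
#' @param file path to the CSV.
#' @return a validated data frame.
#' @seealso [simulate_dose_response()] to generate such tables,
#'   [probit_lc()] to fit them.
#' @export
read_exposure_table <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_exposure_table(tab)
}

#' @rdname read_exposure_table
#' @param table a data frame to validate in place of a file.
#' @export
validate_exposure_table <- function(table) {
  required <- c("species", "population", "dose", "control_kind",
                "replicate", "block", "day", "alive", "total")
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop("exposure table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(table) == 0L) stop("exposure table has no rows")
  for (col in c("replicate", "block", "day", "alive", "total")) {
    v <- table[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != round(v)))
      stop("column '", col, "' must be integer-valued")
  }
  if (any(table$total <= 0)) stop("'total' must be positive")
  if (any(table$alive < 0)) stop("'alive' must be non-negative")
  if (any(table$alive > table$total)) stop("rows with alive > total")
  if (any(table$day < 1 | table$day > 8)) stop("'day' must be in 1..8")
  if (!is.numeric(table$dose) || anyNA(table$dose) || any(table$dose < 0))
    stop("'dose' must be numeric and >= 0")
  ctrl <- table$control_kind != "none"
  if (!all(table$control_kind %in% c("water", "vehicle", "none")))
    stop("'control_kind' must be water, vehicle or none")
  if (any(xor(table$dose == 0, ctrl)))
    stop("dose must be 0 exactly for control rows")
  unit <- interaction(table$species, table$population, table$dose,
                      table$control_kind, table$replicate, table$block,
                      drop = TRUE)
  for (u in split(seq_len(nrow(table)), unit)) {
    o <- u[order(table$day[u])]
    if (is.unsorted(rev(table$alive[o])))
      stop("'alive' increases over days within a replicate")
  }
  table
}
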