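#' Construct a validated case cohort
#'
#' A cohort is a data frame of case records (one row per death: `case_id`,
#' `diagnosis`, one column per coded risk factor) together with its factor
#' coding. Factor values are declared category labels, the literal
#' `"unknown"` (only where the coding allows it), or `NA` meaning
#' structurally not-applicable (only where the factor's applicability
#' predicate fails, e.g. co-sleeping for a non-sleep-related death).
#'
#' @param records Data frame with columns `case_id`, `diagnosis`, and one
#'   column per factor in `coding`. `diagnosis` may be `NA` for unlabeled
#'   prediction records.
#' @param coding Named list of [factor_definition()] objects
#'   (default: [default_factor_coding()]).
#' @return An object of class `"suid_cohort"`.
#' @export
new_cohort <- function(records, coding = default_factor_coding()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("case_id", "diagnosis", names(coding))
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  records <- records[required]
  for (col in required) records[[col]] <- as.character(records[[col]])
  if (anyDuplicated(records$case_id))
    stop("cohort validation error: duplicated case_id")
  obj <- structure(list(records = records, coding = coding),
                   class = "suid_cohort")
  validate_cohort(obj)
  obj
}

#' @rdname new_cohort
#' @param cohort A `"suid_cohort"` object.
#' @return `validate_cohort()`: the cohort, invisibly; errors name the first
#'   offending row and factor.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "suid_cohort"))
  rec <- cohort$records
  dx <- rec$diagnosis
  bad_dx <- which(!is.na(dx) & !(dx %in% diagnosis_levels()))
  if (length(bad_dx))
    stop("row ", bad_dx[1], ": invalid diagnosis '", dx[bad_dx[1]], "'")
  for (def in cohort$coding) {
    v <- rec[[def$name]]
    ok <- v %in% def$levels
    if (def$allows_unknown) ok <- ok | v == "unknown"
    if (!is.null(def$applicability)) {
      ctrl <- rec[[def$applicability$factor]]
      applicable <- !is.na(ctrl) & ctrl == def$applicability$level
      ok[is.na(v)] <- !applicable[is.na(v)]   # NA legal iff not applicable
      ok[!is.na(v) & !applicable] <- FALSE    # value given where undefined
    } else {
      ok[is.na(v)] <- FALSE
    }
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("row ", i, ", factor '", def$name, "': invalid value '",
           if (is.na(v[i])) "NA" else v[i], "'")
    }
  }
  invisible(cohort)
}

#' @export
print.suid_cohort <- function(x, ...) {
  n <- nrow(x$records)
  dx <- table(factor(x$records$diagnosis, levels = diagnosis_levels()))
  cat("<suid_cohort> ", n, " records (",
      paste(names(dx), dx, sep = "=", collapse = ", "), "), ",
      length(x$coding), " factors\n", sep = "")
  invisible(x)
}

#' Number of records in a cohort
#' @param x A `"suid_cohort"` object.
#' @export
n_cases <- function(x) nrow(x$records)

#' Read and write cohort CSV files
#'
#' The cohort CSV dialect is UTF-8, comma-separated, with a header row of
#' `case_id`, `diagnosis` and the snake_case factor identifiers. The literal
#' `"unknown"` encodes informational missingness; the literal `"NA"` encodes
#' structural not-applicability. An empty `diagnosis` field marks an
#' unlabeled prediction record.
#'
#' @param path Path to a cohort CSV file.
#' @param coding Named list of [factor_definition()] objects.
#' @return `load_cohort()`: a validated `"suid_cohort"`, row order preserved.
#' @export
load_cohort <- function(path, coding = default_factor_coding()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  rec <- utils::read.csv(path, colClasses = "character",
                         na.strings = "NA", check.names = FALSE)
  header <- names(rec)
  required <- c("case_id", "diagnosis", names(coding))
  missing_cols <- setdiff(required, header)
  if (length(missing_cols))
    stop("cohort schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(rec)) rec$diagnosis[rec$diagnosis == ""] <- NA_character_
  new_cohort(rec, coding)
}

#' @rdname load_cohort
#' @param cohort A `"suid_cohort"` object.
#' @return `write_cohort()`: `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "suid_cohort"))
  utils::write.csv(cohort$records, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Per-group level counts for every factor
#'
#' Tabulates, for each factor, the number of records at each level within
#' each group (diagnosis states or the levels of another factor), the way a
#' demographic characteristics table is laid out. Informational `"unknown"`
#' values are reported as their own row; structurally not-applicable records
#' (e.g. co-sleeping of non-sleep deaths) appear as a `"not_applicable"`
#' row, whose count equals that of the controlling factor's complementary
#' level, so every column partitions its group.
#'
#' @param cohort A `"suid_cohort"`.
#' @param group `"diagnosis"` (default) or the name of a coded factor.
#' @param collapse Logical; collapse the three diagnosis states to
#'   SIDS/non_SIDS before grouping (only when `group = "diagnosis"`).
#' @return A data frame with columns `factor`, `level`, `total`, and one
#'   count column per group level.
#' @export
summarize_by_group <- function(cohort, group = "diagnosis", collapse = FALSE) {
  stopifnot(inherits(cohort, "suid_cohort"))
  rec <- cohort$records
  if (group == "diagnosis") {
    g <- rec$diagnosis
    if (collapse) g <- collapse_diagnosis(g)
    glevels <- if (collapse) c("SIDS", "non_SIDS") else diagnosis_levels()
    if (anyNA(g)) stop("group variable 'diagnosis' missing on some records")
  } else if (group %in% names(cohort$coding)) {
    g <- rec[[group]]
    def <- cohort$coding[[group]]
    glevels <- c(def$levels, if (def$allows_unknown) "unknown")
    if (anyNA(g)) stop("group variable '", group,
                       "' not applicable on some records")
  } else stop("unknown group variable '", group, "'")
  g <- factor(g, levels = glevels)
  out <- list()
  for (def in cohort$coding) {
    v <- rec[[def$name]]
    vlevels <- c(def$levels, if (def$allows_unknown) "unknown",
                 if (!is.null(def$applicability)) "not_applicable")
    v[is.na(v)] <- "not_applicable"
    tab <- table(factor(v, levels = vlevels), g)
    out[[def$name]] <- data.frame(
      factor = def$name, level = vlevels,
      total = as.integer(rowSums(tab)),
      as.data.frame.matrix(tab), check.names = FALSE,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

extdata <- function(file) {
  p <- system.file("extdata", file, package = "suidbn", mustWork = FALSE)
  if (!nzchar(p)) {
    # during development (pkgload), fall back to the source tree
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("packaged data file not found: ", file)
  p
}

#' Packaged validation cases
#'
#' The eight validation cases (forensic autopsies from 2019-2020 used to
#' verify the trained diagnostic models): their sixteen coded risk-factor
#' values and the experts' consensus diagnoses (six SIDS, two other internal
#' causes). Shipped as a transcription fixture; the "lateral" sleeping
#' position of case 4 is coded as the `"other"` level and case ages are
#' banded with the standard 0-2 / 3-6 / 7-11 month coding.
#'
#' @return A `"suid_cohort"` of 8 labeled records.
#' @export
load_validation_cases <- function() {
  load_cohort(extdata("table4_cases.csv"))
}

#' Packaged marginal specification of the training cohort
#'
#' The published per-factor level counts of the 64-case training cohort
#' (41 SIDS, 23 other deaths, the latter split 11 internal / 12 external),
#' used by [generate_replicate_cohort()] to build marginal-exact synthetic
#' stand-ins for the non-deposited case-level data.
#'
#' @return A list with elements `group_sizes` (named integer vector over
#'   SIDS/internal/external), and `factor_counts`: per factor, per printed
#'   group (`SIDS`, `others`), named level counts.
#' @export
load_marginal_spec <- function() {
  spec <- jsonlite::read_json(extdata("table3_marginals.json"),
                              simplifyVector = TRUE)
  spec$group_sizes <- unlist(spec$group_sizes)
  spec
}
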