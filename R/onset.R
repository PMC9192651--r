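#' Derive the general-population SIDS incidence prior
#'
#' The annual SIDS incidence prior is the total SUID incidence rate
#' multiplied by the proportion of SUID deaths classified as SIDS, rounded
#' to one decimal (0.49/1000 x 0.64 = 0.3/1000 live births/year).
#'
#' @param suid_rate Total SUID incidence per 1000 live births per year.
#' @param sids_fraction Proportion of SUID classified as SIDS.
#' @return Rate per 1000 live births per year, rounded to 1 decimal.
#' @export
derive_prior <- function(suid_rate, sids_fraction) {
  stopifnot(suid_rate > 0, sids_fraction > 0)
  round(suid_rate * sids_fraction, 1)
}

#' Assemble the onset-predictive support model
#'
#' The model combines (i) a general-population annual SIDS incidence prior,
#' (ii) the age-band distribution of SIDS cases against the
#' uniform-by-month population age distribution, and (iii) per-factor
#' case-versus-population conditional proportions for the seven onset
#' factors (age, sex, gestational age, birth weight, co-sleeping,
#' breastfeeding, passive smoking). Co-sleeping and breastfeeding are
#' age-stratified; the remaining factors use a single stratum, mirroring
#' how the source control data are published. Informational unknowns are
#' excluded from case denominators (e.g. passive smoking yes = 21 of 30
#' known, not of 41).
#'
#' @param case_counts Data frame `factor, stratum, level, count` of SIDS
#'   case counts (default: the packaged published values).
#' @param controls Control proportions as from [default_control_tables()].
#' @param prior_rate Annual SIDS incidence per 1000 live births in the
#'   general population (default 0.3).
#' @param age_bands Age band labels, in order.
#' @return An object of class `"onset_model"`.
#' @export
onset_model <- function(case_counts = NULL,
                        controls = default_control_tables(),
                        prior_rate = 0.3,
                        age_bands = c("0-2", "3-6", "7-11")) {
  stopifnot(prior_rate > 0)
  if (is.null(case_counts))
    case_counts <- utils::read.csv(extdata("table5_cases.csv"),
                                   stringsAsFactors = FALSE)
  case_counts$level <- as.character(case_counts$level)
  controls$level <- as.character(controls$level)
  # per-(factor, stratum) case proportions, unknowns excluded
  cp <- case_counts
  cp <- cp[cp$level != "unknown", ]
  key <- paste(cp$factor, cp$stratum)
  cp$case_prop <- cp$count / stats::ave(cp$count, key, FUN = sum)
  tab <- merge(cp[c("factor", "stratum", "level", "count", "case_prop")],
               controls[c("factor", "stratum", "level", "proportion")],
               by = c("factor", "stratum", "level"), all.x = TRUE)
  names(tab)[names(tab) == "proportion"] <- "control_prop"
  names(tab)[names(tab) == "count"] <- "case_n"
  if (anyNA(tab$control_prop))
    stop("no control proportion for: ",
         paste(unique(tab$factor[is.na(tab$control_prop)]), collapse = ", "))
  age <- tab[tab$factor == "age_band", ]
  age <- age[match(age_bands, age$level), ]
  structure(list(
    prior_rate = prior_rate,
    age_bands = age_bands,
    case_age_dist = stats::setNames(age$case_prop, age_bands),
    population_age_dist = stats::setNames(age$control_prop, age_bands),
    factor_tables = tab[tab$factor != "age_band", ]
  ), class = "onset_model")
}

#' @export
print.onset_model <- function(x, ...) {
  cat("<onset_model> prior ", x$prior_rate, "/1000/year; factors: ",
      paste(unique(x$factor_tables$factor), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Age-band-specific prior incidence
#'
#' The general incidence prior reweighted by how SIDS cases distribute over
#' age bands relative to the (uniform-by-month) population:
#' `prior_rate * P(band | case) / P(band | population)`. The
#' population-weighted mean over bands equals `prior_rate`.
#'
#' @param model An `"onset_model"`.
#' @param band Age band label.
#' @return Rate per 1000 live births per year.
#' @export
age_prior <- function(model, band) {
  stopifnot(inherits(model, "onset_model"))
  if (!band %in% model$age_bands) stop("undeclared age band '", band, "'")
  unname(model$prior_rate * model$case_age_dist[[band]] /
           model$population_age_dist[[band]])
}

resolve_stratum <- function(model, factor, band) {
  strata <- unique(model$factor_tables$stratum[
    model$factor_tables$factor == factor])
  if (!length(strata)) stop("undeclared factor '", factor, "'")
  if ("all" %in% strata) "all" else {
    if (!band %in% strata)
      stop("factor '", factor, "' has no stratum for band '", band, "'")
    band
  }
}

#' Case-versus-population likelihood ratio of a factor level
#'
#' `P(level | SIDS case) / P(level | population)`, with the case proportion
#' taken over records with a known value, and the stratum resolved to the
#' age band for age-stratified factors (co-sleeping, breastfeeding) or to
#' the single `"all"` stratum otherwise.
#'
#' @param model An `"onset_model"`.
#' @param factor Factor name.
#' @param level Factor level.
#' @param band Age band (used only for age-stratified factors).
#' @return Positive ratio. A zero control proportion is an error (the ratio
#'   is undefined).
#' @export
likelihood_ratio <- function(model, factor, level, band = NULL) {
  stopifnot(inherits(model, "onset_model"))
  stratum <- resolve_stratum(model, factor,
                             if (is.null(band)) "all" else band)
  ft <- model$factor_tables
  row <- ft[ft$factor == factor & ft$stratum == stratum & ft$level == level, ]
  if (!nrow(row))
    stop("undeclared level '", level, "' for factor '", factor,
         "' (stratum ", stratum, ")")
  if (row$control_prop == 0)
    stop("likelihood ratio undefined: control proportion is 0 for ",
         factor, " = ", level)
  row$case_prop / row$control_prop
}

#' Predict annual SIDS incidence for a risk profile
#'
#' Multiplies the age-band prior by the likelihood ratio of every assigned
#' factor level; unassigned factors are neutral and contribute a ratio of 1.
#' The default `"lr"` form works in rate space (posterior-odds update under
#' a rare-event approximation); `"posterior"` applies full Bayes on
#' probabilities (odds form), treating the population as the non-case
#' reference. For annual rates below 5/1000 the two agree within 1%
#' relative.
#'
#' @param model An `"onset_model"`.
#' @param band Age band.
#' @param assignment Named character vector/list factor -> level (may be
#'   empty).
#' @param method `"lr"` (default, reproduces the published grid) or
#'   `"posterior"`.
#' @return Rate per 1000 live births per year (unrounded).
#' @export
predict_incidence <- function(model, band, assignment = NULL,
                              method = c("lr", "posterior")) {
  method <- match.arg(method)
  assignment <- unlist(assignment)
  prior <- age_prior(model, band)
  lr <- 1
  for (f in names(assignment))
    lr <- lr * likelihood_ratio(model, f, assignment[[f]], band)
  if (method == "lr") return(prior * lr)
  p0 <- prior / 1000
  odds <- p0 / (1 - p0) * lr
  1000 * odds / (1 + odds)
}

#' Display rounding for incidence rates
#'
#' Rates at or above 0.25/1000 are shown with 1 decimal, smaller rates with
#' 2 decimals, matching the printed precision pattern of the published grid
#' (so that e.g. the 0-2-month double-exposure / double-absence ratio is
#' 2.4 / 0.02 = 120.0).
#'
#' @param x Numeric vector of rates per 1000.
#' @return Rounded numeric vector.
#' @export
round_rate <- function(x) ifelse(x >= 0.25, round(x, 1), round(x, 2))

#' Incidence grid over age bands and the two modifiable exposures
#'
#' Builds the 3 x 4 grid of predicted annual SIDS incidence rates: rows are
#' the age bands and columns the exposure groups A (no passive smoking, no
#' co-sleeping), B (-/+), C (+/-) and D (+/+). Cells are displayed with
#' [round_rate()]; the ratio columns D/A and D over the general incidence
#' prior are computed from the rounded cells (matching the published
#' presentation).
#'
#' @param model An `"onset_model"`.
#' @param extra_assignment Optional named vector of additional fixed factor
#'   levels (e.g. `c(sex = "male", birth_weight = "<2500",
#'   breastfeeding = "no")` for the high-risk subgroup); must not assign
#'   passive smoking or co-sleeping.
#' @return Data frame with columns `age_band`, `A`, `B`, `C`, `D` (rounded
#'   rates), `d_over_a`, `d_over_general` (1 decimal); the unrounded cells
#'   are kept in the `"raw"` attribute.
#' @export
incidence_grid <- function(model, extra_assignment = NULL) {
  extra_assignment <- unlist(extra_assignment)
  if (any(c("passive_smoking", "co_sleeping") %in% names(extra_assignment)))
    stop("extra_assignment must not set passive smoking or co-sleeping")
  groups <- list(A = c(passive_smoking = "no", co_sleeping = "no"),
                 B = c(passive_smoking = "no", co_sleeping = "yes"),
                 C = c(passive_smoking = "yes", co_sleeping = "no"),
                 D = c(passive_smoking = "yes", co_sleeping = "yes"))
  raw <- sapply(groups, function(g)
    vapply(model$age_bands, function(band)
      predict_incidence(model, band, c(g, extra_assignment)), numeric(1)))
  raw <- matrix(raw, nrow = length(model$age_bands),
                dimnames = list(model$age_bands, names(groups)))
  cells <- round_rate(raw)
  out <- data.frame(age_band = model$age_bands,
                    cells,
                    d_over_a = round(cells[, "D"] / cells[, "A"], 1),
                    d_over_general = round(cells[, "D"] / model$prior_rate, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "raw") <- raw
  out
}
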