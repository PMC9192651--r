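#' Define a categorical risk factor
#'
#' A factor definition fixes the controlled vocabulary for one risk factor:
#' its ordered category levels, whether an informational \code{"unknown"}
#' value is permitted, and (for nested factors such as co-sleeping, which is
#' only defined for sleep-related deaths) an applicability predicate naming
#' the controlling factor and the level under which this factor is defined.
#'
#' @param name Factor identifier (snake_case).
#' @param levels Character vector of category labels, non-empty and unique.
#' @param allows_unknown Logical; may records carry the value \code{"unknown"}?
#' @param applicability \code{NULL}, or a list with elements \code{factor} and
#'   \code{level}: this factor is defined only for records where the
#'   controlling factor takes that level; elsewhere the value is
#'   not-applicable (written \code{NA} in memory, the literal \code{"NA"} in
#'   CSV).
#' @return An object of class \code{"factor_def"}.
#' @export
factor_definition <- function(name, levels, allows_unknown = FALSE,
                              applicability = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(levels) == 0L || anyDuplicated(levels))
    stop("factor '", name, "': levels must be non-empty and unique")
  if (allows_unknown && "unknown" %in% levels)
    stop("factor '", name, "': 'unknown' duplicated in levels while allows_unknown is set")
  if (!is.null(applicability))
    stopifnot(is.list(applicability),
              all(c("factor", "level") %in% names(applicability)))
  structure(
    list(name = name, levels = as.character(levels),
         allows_unknown = isTRUE(allows_unknown),
         applicability = applicability),
    class = "factor_def"
  )
}

#' @export
print.factor_def <- function(x, ...) {
  cat("<factor_def> ", x$name, ": ", paste(x$levels, collapse = ", "), sep = "")
  if (x$allows_unknown) cat(" (+unknown)")
  if (!is.null(x$applicability))
    cat(" [only when ", x$applicability$factor, " = ",
        x$applicability$level, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Default coding of the 16 SIDS-related risk factors
#'
#' The 16 risk factors recorded for each sudden-unexpected-infant-death case:
#' age band at death, sex, gestational age, birth weight, death during sleep,
#' co-sleeping and sleeping position (both defined only for sleep-related
#' deaths), maternal age, number of cohabiting siblings, family history of
#' SUID in siblings, breastfeeding, passive smoking, caregiver alcohol
#' influence, vaccination within one month of death, maltreatment, and
#' clinical signs of infection.
#'
#' Age is banded 0-2, 3-6 and 7-11 months; gestational age below/at-or-above
#' 37 weeks; birth weight below/at-or-above 2500 g; maternal age <19, 20-34,
#' >=35 years; siblings 0, 1, >=2. Sleeping position, breastfeeding, passive
#' smoking and vaccination admit an "unknown" value.
#'
#' @return A named list of [factor_definition()] objects, in canonical order.
#' @export
default_factor_coding <- function() {
  defs <- list(
    factor_definition("age_band", c("0-2", "3-6", "7-11")),
    factor_definition("sex", c("male", "female")),
    factor_definition("gestational_age", c("<37", ">=37")),
    factor_definition("birth_weight", c("<2500", ">=2500")),
    factor_definition("death_during_sleep", c("yes", "no")),
    factor_definition("co_sleeping", c("yes", "no"),
                      applicability = list(factor = "death_during_sleep",
                                           level = "yes")),
    factor_definition("sleep_position", c("supine", "prone", "other"),
                      allows_unknown = TRUE,
                      applicability = list(factor = "death_during_sleep",
                                           level = "yes")),
    factor_definition("maternal_age", c("<19", "20-34", ">=35")),
    factor_definition("siblings", c("0", "1", ">=2")),
    factor_definition("suid_history", c("yes", "no")),
    factor_definition("breastfeeding", c("yes", "no"), allows_unknown = TRUE),
    factor_definition("passive_smoking", c("yes", "no"), allows_unknown = TRUE),
    factor_definition("alcohol", c("yes", "no")),
    factor_definition("vaccination", c("yes", "no"), allows_unknown = TRUE),
    factor_definition("maltreatment", c("yes", "no")),
    factor_definition("infection_symptoms", c("yes", "no"))
  )
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  defs
}

#' Diagnosis label sets
#'
#' Consensus diagnoses take one of three states: SIDS, other internal causes
#' of death, or external causes. The two-outcome diagnostic models collapse
#' internal and external into a single non-SIDS state.
#'
#' @return Character vector of diagnosis states.
#' @export
diagnosis_levels <- function() c("SIDS", "internal", "external")

#' @rdname diagnosis_levels
#' @param x Character vector of three-state diagnosis labels.
#' @return `collapse_diagnosis()`: the labels mapped onto
#'   `c("SIDS", "non_SIDS")`.
#' @export
collapse_diagnosis <- function(x) {
  bad <- setdiff(unique(x[!is.na(x)]), c(diagnosis_levels(), "non_SIDS"))
  if (length(bad))
    stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "))
  ifelse(is.na(x), NA_character_, ifelse(x == "SIDS", "SIDS", "non_SIDS"))
}
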