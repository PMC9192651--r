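SUBCATEGORIES <- c("sids", "asphyxia", "unknown_cause")

check_regions <- function(records) {
  required <- c("region", "live_births", SUBCATEGORIES)
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("region table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(records) < 2) stop("at least 2 regions are required")
  if (any(records$live_births <= 0)) stop("live_births must be positive")
  if (any(records[SUBCATEGORIES] < 0)) stop("death counts must be >= 0")
  invisible(records)
}

#' Per-region SUID rates per 1000 live births
#'
#' Converts subcategory death counts (SIDS = ICD-10 R95; accidental
#' asphyxia = W75 + W78 + W79; unknown causes = R96 + R98 + R99) into rates
#' per 1000 live births, plus the total SUID rate (the sum of the three).
#'
#' @param records Data frame with columns `region`, `live_births`, `sids`,
#'   `asphyxia`, `unknown_cause` (e.g. from [generate_regions()]).
#' @return Data frame `region`, `sids`, `asphyxia`, `unknown_cause`, `suid`
#'   of rates per 1000.
#' @export
region_rates <- function(records) {
  check_regions(records)
  out <- data.frame(region = records$region, stringsAsFactors = FALSE)
  for (sub in SUBCATEGORIES)
    out[[sub]] <- records[[sub]] / records$live_births * 1000
  out$suid <- rowSums(out[SUBCATEGORIES])
  out
}

#' Coefficient of variation, in percent
#'
#' @param sd Standard deviation (or vector thereof).
#' @param mean Mean on the same scale; must be positive.
#' @return `sd / mean * 100`.
#' @export
cv_percent <- function(sd, mean) {
  if (any(mean <= 0)) stop("CV undefined for non-positive mean")
  sd / mean * 100
}

#' Inter-region variability of SUID subcategory rates
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' coefficient of variation of the per-region rates, per subcategory and
#' for total SUID. The CV, SD divided by the mean, indexes how consistently
#' regions apply a diagnostic subcategory: a heterogeneous label draws a
#' high CV even when the total SUID rate is stable.
#'
#' @param rates Output of [region_rates()].
#' @param digits Rounding for display: mean/SD to 2 decimals, CV to 1, as
#'   published; set `digits = NULL` to disable.
#' @return Data frame `subcategory`, `mean`, `sd`, `cv`.
#' @export
variability_table <- function(rates, digits = c(mean = 2, sd = 2, cv = 1)) {
  if (nrow(rates) < 2) stop("at least 2 regions are required")
  subs <- c(SUBCATEGORIES, "suid")
  m <- vapply(rates[subs], mean, numeric(1))
  s <- vapply(rates[subs], stats::sd, numeric(1))
  cv <- ifelse(m > 0, cv_percent(s, pmax(m, .Machine$double.eps)), NA_real_)
  out <- data.frame(subcategory = subs, mean = m, sd = s, cv = cv,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(digits)) {
    out$mean <- round(out$mean, digits[["mean"]])
    out$sd <- round(out$sd, digits[["sd"]])
    out$cv <- round(out$cv, digits[["cv"]])
  }
  out
}

#' Per-region subcategory proportions of total SUID
#'
#' @param records Region count table (see [region_rates()]).
#' @return Data frame `region`, `sids`, `asphyxia`, `unknown_cause` of
#'   proportions summing to 1 per region; regions with zero SUID deaths are
#'   reported with `NA` proportions (flagged, not propagated as NaN).
#' @export
subcategory_ratios <- function(records) {
  check_regions(records)
  tot <- rowSums(records[SUBCATEGORIES])
  out <- data.frame(region = records$region, stringsAsFactors = FALSE)
  for (sub in SUBCATEGORIES)
    out[[sub]] <- ifelse(tot > 0, records[[sub]] / tot, NA_real_)
  out$undefined <- tot == 0
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  check_count_table(table)
  stats::fisher.test(table)$p.value
}

check_count_table <- function(table) {
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
}

#' Freeman-Halton exact test for an R x C table
#'
#' Generalization of the Fisher exact test to arbitrary R x C contingency
#' tables: exact enumeration of all tables with the observed margins,
#' summing multivariate-hypergeometric probabilities not exceeding the
#' observed table's. Tables with a grand total above `max_total` must use
#' the seeded Monte-Carlo fallback (`mc = TRUE`), which simulates tables
#' with fixed margins.
#'
#' @param table Matrix of non-negative integer counts.
#' @param max_total Enumeration bound on the grand total (default 200).
#' @param mc Use Monte-Carlo estimation instead of full enumeration.
#' @param B Number of Monte-Carlo replicates.
#' @param seed Integer seed for the Monte-Carlo fallback.
#' @return Two-sided p-value in (0, 1].
#' @export
freeman_halton <- function(table, max_total = 200, mc = FALSE, B = 1e4,
                           seed = 1) {
  table <- as.matrix(table)
  check_count_table(table)
  # degenerate margins: only one table is possible
  if (sum(rowSums(table) > 0) <= 1L || sum(colSums(table) > 0) <= 1L)
    return(1)
  if (mc) {
    rng <- local_rng(seed)
    on.exit(rng$restore())
    return(stats::fisher.test(table, simulate.p.value = TRUE, B = B)$p.value)
  }
  if (sum(table) > max_total)
    stop("table total ", sum(table), " exceeds the enumeration bound ",
         max_total, "; call with mc = TRUE for a seeded Monte-Carlo estimate")
  stats::fisher.test(table, workspace = 2e7)$p.value
}
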