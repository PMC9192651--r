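#' Generate a marginal-exact replicate cohort
#'
#' Builds a synthetic cohort whose per-factor, per-group level counts equal
#' a marginal specification exactly, for every seed. Within each printed
#' diagnosis group (SIDS / others), each factor column is an independent
#' seeded permutation of the specified level counts; the only joint
#' structure honored is the structural nesting (co-sleeping and sleeping
#' position are assigned only to sleep-related deaths). The "others" group
#' is split into internal/external labels by a seeded permutation. Joint
#' dependence beyond these constraints is deliberately not modeled: the
#' published table prints marginals only.
#'
#' @param spec Marginal specification as returned by [load_marginal_spec()]
#'   (the packaged counts are the default).
#' @param seed Integer seed; counts are deterministic, arrangement is not.
#' @param coding Factor coding (defaults to the standard 16 factors).
#' @return A `"suid_cohort"`.
#' @export
generate_replicate_cohort <- function(spec = load_marginal_spec(), seed = 1,
                                      coding = default_factor_coding()) {
  sizes <- spec$group_sizes
  stopifnot(all(c("SIDS", "internal", "external") %in% names(sizes)))
  group_of <- list(SIDS = "SIDS",
                   others = c("internal", "external"))
  rng <- local_rng(seed)
  on.exit(rng$restore())
  out <- list()
  for (printed in names(group_of)) {
    n_g <- sum(sizes[group_of[[printed]]])
    cols <- list(diagnosis = rng$permute(rep(group_of[[printed]],
                                             sizes[group_of[[printed]]])))
    # nested factors are filled within the controlling level only
    for (def in coding) {
      counts <- unlist(spec$factor_counts[[def$name]][[printed]])
      bad <- setdiff(names(counts),
                     c(def$levels, if (def$allows_unknown) "unknown"))
      if (length(bad))
        stop("marginal spec, factor '", def$name,
             "': undeclared level(s) ", paste(bad, collapse = ", "))
      if (is.null(def$applicability)) {
        if (sum(counts) != n_g)
          stop("inconsistent marginal spec for factor '", def$name,
               "': counts sum to ", sum(counts), ", group size is ", n_g)
        cols[[def$name]] <- rng$permute(rep(names(counts), counts))
      } else {
        ctrl <- def$applicability
        n_app <- sum(cols[[ctrl$factor]] == ctrl$level)
        if (sum(counts) != n_app)
          stop("inconsistent marginal spec for factor '", def$name,
               "': counts sum to ", sum(counts), " but ", ctrl$factor,
               " = ", ctrl$level, " holds for ", n_app, " records")
        v <- rep(NA_character_, n_g)
        v[cols[[ctrl$factor]] == ctrl$level] <-
          rng$permute(rep(names(counts), counts))
        cols[[def$name]] <- v
      }
    }
    out[[printed]] <- as.data.frame(cols, stringsAsFactors = FALSE,
                                    check.names = FALSE)
  }
  rec <- do.call(rbind, out)
  rec <- data.frame(case_id = sprintf("sim-%03d", seq_len(nrow(rec))), rec,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(rec) <- NULL
  new_cohort(rec, coding)
}

# One seeded generator per call; restores the caller's RNG state on exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(
    permute = function(x) if (length(x) > 1L) sample(x) else x,
    runif = function(n) stats::runif(n),
    restore = function() {
      if (is.null(old)) suppressWarnings(
        rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    }
  )
}

#' Sample a cohort from a Bayesian network
#'
#' Ancestral (forward) sampling: nodes are visited in topological order and
#' each record's state is drawn from the node's CPT row selected by the
#' record's already-sampled parent states. If the network contains a
#' `cause_of_death` node it becomes the diagnosis column (only meaningful
#' when its states are the three diagnosis labels); every other node becomes
#' a factor column.
#'
#' @param net A `"bayesnet"`.
#' @param n Number of records, `>= 1`.
#' @param seed Integer seed; fixed seed gives identical cohorts.
#' @return A `"suid_cohort"` whose coding is derived from the node state
#'   sets (states named `"unknown"`/`"na"` map back onto the informational /
#'   structural missing codes).
#' @export
sample_cohort_from_bn <- function(net, n, seed = 1) {
  stopifnot(inherits(net, "bayesnet"), n >= 1)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  order <- topo_order_or_na(net$spec)
  cols <- list()
  for (node in order) {
    cpt <- net$cpts[[node]]
    k <- length(cpt$states)
    if (!length(cpt$parents)) {
      ri <- rep(1L, n)
    } else {
      obs <- as.data.frame(cols[cpt$parents], stringsAsFactors = FALSE,
                           check.names = FALSE)
      ri <- match(combo_key(obs),
                  combo_key(expand.grid(cpt$parent_states,
                                        KEEP.OUT.ATTRS = FALSE,
                                        stringsAsFactors = FALSE)))
    }
    u <- rng$runif(n)
    cum <- t(apply(cpt$prob, 1, cumsum))
    si <- rowSums(u > cum[ri, , drop = FALSE]) + 1L
    cols[[node]] <- cpt$states[si]
  }
  factor_nodes <- setdiff(names(net$spec$nodes), "cause_of_death")
  coding <- list()
  rec <- list(case_id = sprintf("bn-%05d", seq_len(n)))
  rec$diagnosis <- if ("cause_of_death" %in% names(net$spec$nodes))
    cols[["cause_of_death"]] else NA_character_
  for (node in factor_nodes) {
    states <- net$spec$nodes[[node]]
    levels <- setdiff(states, c("unknown", "na"))
    coding[[node]] <- factor_definition(
      node, levels, allows_unknown = "unknown" %in% states)
    v <- cols[[node]]
    v[v == "na"] <- NA_character_
    rec[[node]] <- v
  }
  rec <- as.data.frame(rec, stringsAsFactors = FALSE, check.names = FALSE)
  # bypass applicability validation: generic nets carry no nesting metadata
  structure(list(records = rec, coding = coding), class = "suid_cohort")
}

#' Specify a regional surveillance simulation
#'
#' Region-level SUID counts are modeled with a standard surveillance count
#' model: each region r draws a latent subcategory rate from a gamma
#' distribution with the stated mean (per 1000 live births per year) and
#' coefficient of variation (`dispersion`), and observed deaths are Poisson
#' with mean `live_births * rate / 1000`. Dispersion 0 makes all regional
#' rates identical.
#'
#' @param n_regions Number of regions, `>= 2` (47 prefectures by default).
#' @param live_birth_range Integer range of per-region live births over the
#'   observation window.
#' @param rates Named numeric vector of mean rates per 1000 live births for
#'   subcategories `sids`, `asphyxia`, `unknown_cause`.
#' @param dispersion Coefficient of variation of the latent regional rates
#'   (single value, recycled over subcategories).
#' @return An object of class `"region_sim_spec"`.
#' @export
region_sim_spec <- function(n_regions = 47,
                            live_birth_range = c(30000, 400000),
                            rates = c(sids = 0.11, asphyxia = 0.07,
                                      unknown_cause = 0.31),
                            dispersion = c(sids = 0.7, asphyxia = 0.7,
                                           unknown_cause = 0.3)) {
  stopifnot(n_regions >= 2, all(rates >= 0), all(dispersion >= 0),
            length(live_birth_range) == 2, live_birth_range[1] > 0)
  dispersion <- rep_len(dispersion, length(rates))
  names(dispersion) <- names(rates)
  structure(list(n_regions = as.integer(n_regions),
                 live_birth_range = as.integer(live_birth_range),
                 rates = rates, dispersion = dispersion),
            class = "region_sim_spec")
}

#' Generate region-level SUID count records
#'
#' @param spec A [region_sim_spec()].
#' @param seed Integer seed.
#' @return Data frame with columns `region`, `live_births`, and death counts
#'   `sids` (ICD-10 R95), `asphyxia` (W75/W78/W79) and `unknown_cause`
#'   (R96/R98/R99).
#' @export
generate_regions <- function(spec = region_sim_spec(), seed = 1) {
  stopifnot(inherits(spec, "region_sim_spec"))
  if (spec$n_regions < 2) stop("at least 2 regions are required")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  n <- spec$n_regions
  pool <- seq(spec$live_birth_range[1], spec$live_birth_range[2])
  births <- pool[sample.int(length(pool), n, replace = TRUE)]
  out <- data.frame(region = sprintf("region-%02d", seq_len(n)),
                    live_births = births, stringsAsFactors = FALSE)
  for (sub in names(spec$rates)) {
    mu <- spec$rates[[sub]]
    cv <- spec$dispersion[[sub]]
    lambda <- if (cv == 0 || mu == 0) rep(mu, n) else
      stats::rgamma(n, shape = 1 / cv^2, scale = mu * cv^2)
    out[[sub]] <- stats::rpois(n, births * lambda / 1000)
  }
  out
}

#' Packaged population control proportions
#'
#' The published control (general infant population) proportions used by the
#' onset model: age uniform by month over the 0-2 / 3-6 / 7-11 month bands
#' (3/12, 4/12, 5/12), sex, gestational age and birth weight from national
#' vital statistics, co-sleeping and breastfeeding age-stratified from
#' national surveys, and passive smoking prevalence 33.1% / 66.9%.
#' For sources published as counts the proportions are recomputed from the
#' counts; two factors (breastfeeding 7-11 months, passive smoking) are only
#' published as proportions.
#'
#' @return Data frame with columns `factor`, `stratum`, `level`, `count`
#'   (NA where only a proportion is published), `proportion` (normalized
#'   within each factor-stratum block), and `source_note`.
#' @export
default_control_tables <- function() {
  tab <- utils::read.csv(extdata("table5_controls.csv"),
                         stringsAsFactors = FALSE)
  names(tab)[names(tab) == "source"] <- "source_note"
  for (key in unique(paste(tab$factor, tab$stratum))) {
    idx <- paste(tab$factor, tab$stratum) == key
    if (all(!is.na(tab$count[idx]))) {
      tab$proportion[idx] <- tab$count[idx] / sum(tab$count[idx])
    } else {
      s <- sum(tab$proportion[idx])
      if (abs(s - 1) > 1e-9)
        stop("control proportions for ", key, " sum to ", s)
    }
  }
  tab
}
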