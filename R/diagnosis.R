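#' Configure a diagnostic support model
#'
#' Three diagnostic support models are shipped. Model 1 is causal (risk
#' factors upstream of the outcome, reflecting the pathway of factors
#' leading to death); Models 2 and 3 are retrospective (the cause of death
#' upstream of the factors, reflecting post-hoc estimation of case
#' characteristics from the diagnosis). Models 1 and 2 use the two-state
#' outcome SIDS / non_SIDS; Model 3 separates SIDS, other internal causes,
#' and external causes. The default network topologies are editable JSON
#' assets; every downstream operation is structure-agnostic.
#'
#' @param model_id 1, 2 or 3.
#' @param structure Optional path to a structure JSON overriding the shipped
#'   default for this model.
#' @param alpha Additive smoothing pseudo-count for CPT estimation
#'   (default 0: pure relative frequencies, which reproduce count-based
#'   tables but can yield hard 0/1 posteriors; set `alpha > 0` to
#'   regularize).
#' @param unknown_policy Passed to [estimate_cpts()]; the diagnostic models
#'   default to `"as_state"` because the training data reports "unknown" as
#'   a category of its own.
#' @return An object of class `"diag_config"`.
#' @export
diagnostic_model_config <- function(model_id, structure = NULL, alpha = 0,
                                    unknown_policy = "as_state") {
  stopifnot(model_id %in% 1:3, alpha >= 0)
  structure(list(model_id = as.integer(model_id), structure = structure,
                 alpha = alpha, unknown_policy = unknown_policy),
            class = "diag_config")
}

read_structure_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "suidbn-structure"))
    stop("not a suidbn structure document: ", path)
  nodes <- lapply(doc$nodes, unlist)
  edges <- do.call(rbind, lapply(doc$edges, function(e)
    c(from = e$from, to = e$to)))
  list(spec = network_spec(nodes, edges),
       outcome = doc$outcome, direction = doc$direction)
}

#' Build the network structure for a diagnostic model
#'
#' @param config A [diagnostic_model_config()].
#' @return A `"bn_spec"` with attributes `outcome` (outcome node name) and
#'   `direction` (`"causal"` or `"retrospective"`). Structural violations in
#'   an overriding JSON raise an error with the full validation report.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "diag_config"))
  path <- if (!is.null(config$structure)) config$structure else
    extdata(sprintf("model%d_structure.json", config$model_id))
  st <- read_structure_json(path)
  spec <- st$spec
  if (!st$outcome %in% names(spec$nodes))
    stop("outcome node '", st$outcome, "' not declared in structure")
  # orientation at the outcome must match the declared direction
  at_outcome_in <- sum(spec$edges[, "to"] == st$outcome)
  at_outcome_out <- sum(spec$edges[, "from"] == st$outcome)
  if (st$direction == "causal" && at_outcome_out > 0)
    stop("causal model must not have edges out of the outcome node")
  if (st$direction == "retrospective" && at_outcome_in > 0)
    stop("retrospective model must not have edges into the outcome node")
  attr(spec, "outcome") <- st$outcome
  attr(spec, "direction") <- st$direction
  spec
}

#' Train a diagnostic model on a labeled cohort
#'
#' Estimates all CPTs of the configured structure from the cohort with the
#' diagnostic defaults (unknown-as-state, smoothing `alpha` from the
#' config). The outcome node's marginal prior equals the diagnosis
#' frequencies of the training cohort (for Models 1-2 after collapsing to
#' SIDS / non_SIDS).
#'
#' @param config A [diagnostic_model_config()].
#' @param cohort A labeled `"suid_cohort"`.
#' @return A `"bayesnet"` with attribute `outcome`.
#' @export
train_diagnostic_model <- function(config, cohort) {
  spec <- build_model(config)
  if (anyNA(cohort$records$diagnosis))
    stop("training cohort must be fully labeled")
  net <- estimate_cpts(spec, cohort, alpha = config$alpha,
                       unknown_policy = config$unknown_policy)
  attr(net, "outcome") <- attr(spec, "outcome")
  net
}

case_evidence <- function(net, case, policy = c("as_state", "exclude")) {
  policy <- match.arg(policy)
  outcome <- attr(net, "outcome")
  if (is.null(outcome)) outcome <- "cause_of_death"
  ev <- character(0)
  for (node in setdiff(names(net$spec$nodes), outcome)) {
    if (!node %in% names(case)) next
    v <- case[[node]]
    if (is.na(v)) v <- "na"
    if (v == "unknown" && policy == "exclude") next  # neutral
    if (!v %in% net$spec$nodes[[node]]) next         # unrepresentable: neutral
    ev[[node]] <- v
  }
  ev
}

#' Posterior diagnosis for a single case
#'
#' Enters the case's factor values as evidence (not-applicable values as the
#' structural `"na"` state; informational unknowns as the `"unknown"` state
#' under the `as_state` policy, or as neutral under `exclude`) and computes
#' the exact outcome posterior by variable elimination. The predicted state
#' is the posterior argmax; ties are broken by declared state order and
#' flagged.
#'
#' @param net A trained `"bayesnet"` (see [train_diagnostic_model()]).
#' @param case A single-row cohort record (data frame row or named
#'   list/vector of factor values).
#' @param policy How informational unknowns enter the evidence.
#' @return A list with elements `posterior` (named numeric, sums to 1),
#'   `predicted` (state label), and `tie` (logical).
#' @export
diagnose_case <- function(net, case, policy = "as_state") {
  outcome <- attr(net, "outcome")
  if (is.null(outcome)) outcome <- "cause_of_death"
  if (is.data.frame(case)) {
    stopifnot(nrow(case) == 1L)
    case <- as.list(case)
  }
  post <- posterior_ve(net, outcome, case_evidence(net, case, policy))
  mx <- max(post)
  winners <- names(post)[post >= mx - 1e-12]
  list(posterior = post, predicted = winners[1],
       tie = length(winners) > 1L)
}

#' Validate diagnostic models against expert-labeled cases
#'
#' Runs each trained model over each validation case and reports the full
#' posterior, the argmax diagnosis, and whether it matches the expert
#' consensus label (for two-state models the three-state expert labels are
#' collapsed to SIDS / non_SIDS before comparison).
#'
#' @param nets Non-empty named list of trained `"bayesnet"` models.
#' @param cases A labeled `"suid_cohort"` of validation cases.
#' @param policy Passed to [diagnose_case()].
#' @return A data frame with one row per (model, case): `model`, `case_id`,
#'   `expert`, one `p_<state>` column per outcome state (NA where a state is
#'   not part of that model), `predicted`, `match`.
#' @export
validate_models <- function(nets, cases, policy = "as_state") {
  if (!length(nets)) stop("at least one model is required")
  stopifnot(inherits(cases, "suid_cohort"), nrow(cases$records) >= 1)
  if (is.null(names(nets)))
    names(nets) <- paste0("model", seq_along(nets))
  all_states <- unique(unlist(lapply(nets, function(net) {
    outcome <- attr(net, "outcome") %||% "cause_of_death"
    net$spec$nodes[[outcome]]
  })))
  rows <- list()
  for (m in names(nets)) {
    net <- nets[[m]]
    outcome <- attr(net, "outcome") %||% "cause_of_death"
    states <- net$spec$nodes[[outcome]]
    for (i in seq_len(nrow(cases$records))) {
      case <- cases$records[i, ]
      res <- diagnose_case(net, case, policy)
      expert <- case$diagnosis
      expert_cmp <- if (length(states) == 2L && !is.na(expert))
        collapse_diagnosis(expert) else expert
      p <- stats::setNames(rep(NA_real_, length(all_states)),
                           paste0("p_", all_states))
      p[paste0("p_", names(res$posterior))] <- res$posterior
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, case_id = case$case_id,
        expert = expert, as.list(p),
        predicted = res$predicted,
        match = if (is.na(expert)) NA else res$predicted == expert_cmp,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
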