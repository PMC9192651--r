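#' Specify a discrete Bayesian network structure
#'
#' A network specification is a DAG over categorical nodes: each node has an
#' ordered, unique state set, and edges are directed parent -> child pairs.
#'
#' @param nodes Named list: node name -> character vector of states.
#' @param edges Two-column character matrix or data frame (`from`, `to`);
#'   may have zero rows.
#' @return An object of class `"bn_spec"`.
#' @seealso [validate_network()] for a report-based check.
#' @export
network_spec <- function(nodes, edges = NULL) {
  stopifnot(is.list(nodes), length(nodes) >= 1L, !is.null(names(nodes)))
  if (is.null(edges)) {
    edges <- matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("from", "to")))
  } else {
    edges <- as.matrix(as.data.frame(edges, stringsAsFactors = FALSE))
    colnames(edges) <- c("from", "to")
    storage.mode(edges) <- "character"
  }
  spec <- structure(list(nodes = lapply(nodes, as.character), edges = edges),
                    class = "bn_spec")
  report <- validate_network(spec)
  if (length(report))
    stop("invalid network: ", paste(report, collapse = "; "))
  spec
}

#' Validate a network structure
#'
#' Report-based structural validation: undeclared edge endpoints, empty or
#' duplicated state sets, and cycles (detected by Kahn's algorithm). An empty
#' report means the structure is a valid DAG.
#'
#' @param spec A `"bn_spec"` or a list with elements `nodes` and `edges` in
#'   the same shape.
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_network <- function(spec) {
  report <- character(0)
  nn <- names(spec$nodes)
  if (anyDuplicated(nn)) report <- c(report, "duplicated node names")
  for (node in nn) {
    st <- spec$nodes[[node]]
    if (length(st) == 0L)
      report <- c(report, paste0("node '", node, "' has an empty state set"))
    if (anyDuplicated(st))
      report <- c(report, paste0("node '", node, "' has duplicated states"))
  }
  ed <- spec$edges
  undeclared <- setdiff(unique(c(ed)), nn)
  if (length(undeclared))
    report <- c(report, paste0("edge endpoint not a declared node: ",
                               paste(undeclared, collapse = ", ")))
  if (length(report)) return(report)
  if (!is.na(topo_order_or_na(spec)[1]) || length(nn) == 0L) return(report)
  c(report, "graph contains a cycle")
}

parents_of <- function(spec, node) {
  unname(spec$edges[spec$edges[, "to"] == node, "from"])
}

topo_order_or_na <- function(spec) {
  nn <- names(spec$nodes)
  indeg <- vapply(nn, function(v) sum(spec$edges[, "to"] == v), integer(1))
  out <- character(0)
  avail <- nn[indeg == 0L]
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    out <- c(out, v)
    for (w in unname(spec$edges[spec$edges[, "from"] == v, "to"])) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) avail <- c(avail, w)
    }
  }
  if (length(out) != length(nn)) return(NA_character_)
  out
}

parent_combos <- function(spec, node) {
  ps <- parents_of(spec, node)
  if (!length(ps)) return(data.frame(row.names = ""))
  g <- expand.grid(spec$nodes[ps], KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  names(g) <- ps
  g
}

combo_key <- function(df) {
  if (!ncol(df)) return(rep("", max(1L, nrow(df))))
  do.call(paste, c(unname(df), list(sep = "\r")))
}

#' Construct a conditional probability table
#'
#' @param node Node name.
#' @param parents Character vector of parent node names (may be empty).
#' @param states Ordered states of the node.
#' @param parent_states Named list of parent state vectors (in `parents`
#'   order).
#' @param prob Numeric matrix, one row per parent-state combination (parents
#'   in `expand.grid` order, first parent varying fastest), one column per
#'   node state; each row must sum to 1 within `1e-9`.
#' @return An object of class `"bn_cpt"`.
#' @export
new_cpt <- function(node, parents, states, parent_states, prob) {
  prob <- as.matrix(prob)
  n_rows <- if (length(parents)) prod(lengths(parent_states)) else 1L
  stopifnot(nrow(prob) == n_rows, ncol(prob) == length(states))
  if (any(prob < -1e-12 | prob > 1 + 1e-12))
    stop("CPT for '", node, "': probabilities outside [0, 1]")
  if (any(abs(rowSums(prob) - 1) > 1e-9))
    stop("CPT for '", node, "': a row does not sum to 1")
  colnames(prob) <- states
  structure(list(node = node, parents = parents, states = states,
                 parent_states = parent_states, prob = prob),
            class = "bn_cpt")
}

#' Assemble a Bayesian network from a structure and CPTs
#'
#' @param spec A `"bn_spec"`.
#' @param cpts Named list of `"bn_cpt"`, one per node; each CPT's parents
#'   must equal the node's graph parents.
#' @return An object of class `"bayesnet"`.
#' @export
bayesnet <- function(spec, cpts) {
  stopifnot(inherits(spec, "bn_spec"))
  missing_cpt <- setdiff(names(spec$nodes), names(cpts))
  if (length(missing_cpt))
    stop("missing CPT for node(s): ", paste(missing_cpt, collapse = ", "))
  for (node in names(spec$nodes)) {
    cpt <- cpts[[node]]
    if (!setequal(cpt$parents, parents_of(spec, node)))
      stop("CPT parents for '", node, "' do not match the graph")
    if (!identical(cpt$states, spec$nodes[[node]]))
      stop("CPT states for '", node, "' do not match the declared states")
  }
  structure(list(spec = spec, cpts = cpts[names(spec$nodes)]),
            class = "bayesnet")
}

#' @export
print.bayesnet <- function(x, ...) {
  cat("<bayesnet> ", length(x$spec$nodes), " nodes, ",
      nrow(x$spec$edges), " edges\n", sep = "")
  invisible(x)
}

#' Estimate conditional probability tables from a cohort
#'
#' Each CPT row is estimated by (count + alpha) / (row total + alpha * k)
#' over the k node states, counting records where the node and all its
#' parents are observed. The network's `cause_of_death` node (if present) is
#' read from the cohort's diagnosis column, collapsed to SIDS/non_SIDS when
#' the node is two-state; every other node must name a coded factor.
#' Structural not-applicability is its own state `"na"`.
#'
#' @param spec A `"bn_spec"` whose node names map onto cohort variables.
#' @param cohort A `"suid_cohort"` (or any object with `$records`).
#' @param alpha Additive smoothing pseudo-count, `>= 0`. With `alpha = 0`
#'   rows are pure relative frequencies; rows with zero total become uniform.
#' @param unknown_policy `"as_state"`: the value `"unknown"` is a category in
#'   its own right (the node must declare it). `"exclude"`: records with an
#'   unknown value at the node or any parent are dropped from that CPT.
#' @return A `"bayesnet"`.
#' @export
estimate_cpts <- function(spec, cohort, alpha = 0,
                          unknown_policy = c("as_state", "exclude")) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(alpha >= 0)
  rec <- cohort$records
  get_var <- function(node) {
    if (node == "cause_of_death") {
      v <- rec$diagnosis
      if (length(spec$nodes[[node]]) == 2L) v <- collapse_diagnosis(v)
      return(v)
    }
    if (!node %in% names(rec))
      stop("node '", node, "' has no cohort variable")
    v <- rec[[node]]
    v[is.na(v)] <- "na"
    v
  }
  cpts <- list()
  for (node in names(spec$nodes)) {
    states <- spec$nodes[[node]]
    ps <- parents_of(spec, node)
    cols <- c(list(get_var(node)), lapply(ps, get_var))
    keep <- !is.na(cols[[1]])
    if (unknown_policy == "exclude")
      for (v in cols) keep <- keep & !is.na(v) & v != "unknown"
    else
      for (v in cols[-1]) keep <- keep & !is.na(v)
    vals <- lapply(cols, `[`, keep)
    bad <- setdiff(unique(vals[[1]]), states)
    if (length(bad))
      stop("node '", node, "': cohort value(s) not in declared states: ",
           paste(bad, collapse = ", "))
    combos <- parent_combos(spec, node)
    keys <- combo_key(combos)
    obs_key <- if (length(ps)) {
      do.call(paste, c(vals[-1], list(sep = "\r")))
    } else rep("", length(vals[[1]]))
    counts <- table(factor(obs_key, levels = keys),
                    factor(vals[[1]], levels = states))
    prob <- (unclass(counts) + alpha)
    tot <- rowSums(prob)
    zero <- tot == 0
    prob[!zero, ] <- prob[!zero, , drop = FALSE] / tot[!zero]
    prob[zero, ] <- 1 / length(states)
    cpts[[node]] <- new_cpt(node, ps, states,
                            spec$nodes[ps], prob)
  }
  bayesnet(spec, cpts)
}

cpt_lookup <- function(cpt, node_states, parent_df) {
  keys <- combo_key(as.data.frame(parent_df, stringsAsFactors = FALSE))
  ri <- match(keys, combo_key(expand.grid(cpt$parent_states,
                                          KEEP.OUT.ATTRS = FALSE,
                                          stringsAsFactors = FALSE)))
  if (!length(cpt$parents)) ri <- rep(1L, length(node_states))
  ci <- match(node_states, cpt$states)
  cpt$prob[cbind(ri, ci)]
}

#' Joint probability of a full assignment
#'
#' Chain-rule factorization: the product over nodes of the CPT entry for the
#' node's state given its parents' states.
#'
#' @param net A `"bayesnet"`.
#' @param assignment Named character vector or list, one state per node.
#' @return A probability in `[0, 1]`.
#' @export
joint_probability <- function(net, assignment) {
  assignment <- unlist(assignment)
  missing_nodes <- setdiff(names(net$spec$nodes), names(assignment))
  if (length(missing_nodes))
    stop("assignment missing node(s): ", paste(missing_nodes, collapse = ", "))
  p <- 1
  for (node in names(net$spec$nodes)) {
    cpt <- net$cpts[[node]]
    st <- assignment[[node]]
    if (!st %in% cpt$states)
      stop("node '", node, "': '", st, "' is not a declared state")
    pv <- if (length(cpt$parents)) {
      as.data.frame(as.list(assignment[cpt$parents]),
                    stringsAsFactors = FALSE)
    } else data.frame(row.names = "")
    p <- p * cpt_lookup(cpt, st, pv)
  }
  unname(p)
}

check_evidence <- function(net, query, evidence) {
  if (!query %in% names(net$spec$nodes))
    stop("query node '", query, "' not in the network")
  evidence <- unlist(evidence)
  if (length(evidence)) {
    if (query %in% names(evidence))
      stop("query node '", query, "' cannot also be evidence")
    for (node in names(evidence)) {
      if (!node %in% names(net$spec$nodes))
        stop("evidence node '", node, "' not in the network")
      if (!evidence[[node]] %in% net$spec$nodes[[node]])
        stop("evidence '", evidence[[node]], "' is not a state of '",
             node, "'")
    }
  }
  evidence
}

#' Exact posterior by enumeration
#'
#' Conditional distribution of a query node given evidence, computed by
#' summing the joint over every completion of the unobserved (neutral)
#' nodes. Intended for small networks and as the reference oracle for
#' [posterior_ve()].
#'
#' @param net A `"bayesnet"`.
#' @param query Name of the query node (must not carry evidence).
#' @param evidence Named character vector/list node -> observed state;
#'   omitted nodes are neutral and are marginalized.
#' @return Named numeric vector over the query node's states, summing to 1.
#'   Evidence with probability zero is an error.
#' @export
posterior_enumeration <- function(net, query, evidence = NULL) {
  evidence <- check_evidence(net, query, evidence)
  spec <- net$spec
  state_sets <- spec$nodes
  for (node in names(evidence)) state_sets[[node]] <- evidence[[node]]
  n_rows <- prod(lengths(state_sets))
  if (n_rows > 2e6)
    stop("enumeration space too large (", n_rows, " assignments); use posterior_ve()")
  grid <- expand.grid(state_sets, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (node in names(spec$nodes)) {
    cpt <- net$cpts[[node]]
    p <- p * cpt_lookup(cpt, grid[[node]],
                        grid[cpt$parents])
  }
  post <- vapply(spec$nodes[[query]],
                 function(s) sum(p[grid[[query]] == s]), numeric(1))
  z <- sum(post)
  if (z <= 0) stop("impossible evidence: joint probability is zero")
  post / z
}

## ---- factor algebra for variable elimination ----

ve_factor <- function(vars, card, vals) list(vars = vars, card = card, vals = vals)

ve_from_cpt <- function(cpt) {
  vars <- c(cpt$parents, cpt$node)
  card <- c(lapply(cpt$parent_states, length), length(cpt$states))
  # prob matrix rows follow expand.grid over parents (first parent fastest);
  # vals laid out with vars in order (parents..., node): node varies slowest
  vals <- as.vector(cpt$prob)            # column-major: parents fastest
  ve_factor(vars, unlist(card), vals)
}

ve_state_index <- function(net, node, state) match(state, net$spec$nodes[[node]])

ve_restrict <- function(f, var, idx) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  a <- array(f$vals, dim = f$card)
  idxs <- rep(list(quote(expr = )), length(f$card))
  idxs[[k]] <- idx
  a <- do.call(`[`, c(list(a), idxs, list(drop = FALSE)))
  ve_factor(f$vars[-k], f$card[-k], as.vector(a))
}

ve_multiply <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  card <- integer(length(vars))
  card[match(f1$vars, vars)] <- f1$card
  card[match(f2$vars, vars)] <- f2$card
  n <- prod(c(card, 1))
  if (n == 0) stop("degenerate factor")
  idx_of <- function(f) {
    if (!length(f$vars)) return(rep(1L, n))
    pos <- match(f$vars, vars)
    strides_out <- cumprod(c(1L, card))[seq_along(vars)]
    strides_f <- cumprod(c(1L, f$card))[seq_along(f$vars)]
    full <- arrayInd(seq_len(n), .dim = pmax(card, 1L))
    1L + as.integer((full[, pos, drop = FALSE] - 1L) %*% strides_f)
  }
  v1 <- if (length(f1$vars)) f1$vals[idx_of(f1)] else rep(f1$vals, n)
  v2 <- if (length(f2$vars)) f2$vals[idx_of(f2)] else rep(f2$vals, n)
  ve_factor(vars, card, v1 * v2)
}

ve_sum_out <- function(f, var) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  a <- array(f$vals, dim = f$card)
  keep <- setdiff(seq_along(f$card), k)
  vals <- if (length(keep)) as.vector(apply(a, keep, sum)) else sum(a)
  ve_factor(f$vars[-k], f$card[-k], vals)
}

#' Exact posterior by variable elimination
#'
#' Scalable twin of [posterior_enumeration()]: evidence is absorbed by
#' restricting each CPT factor, hidden variables are summed out one at a
#' time (smallest intermediate factor first), and the remaining product is
#' normalized over the query states.
#'
#' @inheritParams posterior_enumeration
#' @return Named numeric vector over the query node's states, summing to 1.
#' @export
posterior_ve <- function(net, query, evidence = NULL) {
  evidence <- check_evidence(net, query, evidence)
  factors <- lapply(net$cpts, ve_from_cpt)
  for (node in names(evidence)) {
    idx <- ve_state_index(net, node, evidence[[node]])
    factors <- lapply(factors, ve_restrict, var = node, idx = idx)
  }
  hidden <- setdiff(names(net$spec$nodes), c(query, names(evidence)))
  while (length(hidden)) {
    # greedy: eliminate the variable whose product factor is smallest
    cost <- vapply(hidden, function(v) {
      involved <- factors[vapply(factors, function(f) v %in% f$vars, logical(1))]
      vars <- unique(unlist(lapply(involved, `[[`, "vars")))
      prod(vapply(vars, function(w) {
        for (f in involved) if (w %in% f$vars) return(f$card[match(w, f$vars)])
        1L
      }, integer(1)))
    }, numeric(1))
    v <- hidden[which.min(cost)]
    hidden <- setdiff(hidden, v)
    has_v <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prodf <- Reduce(ve_multiply, factors[has_v])
    factors <- c(factors[!has_v], list(ve_sum_out(prodf, v)))
  }
  res <- Reduce(ve_multiply, factors)
  stopifnot(identical(res$vars, query))
  post <- res$vals
  names(post) <- net$spec$nodes[[query]]
  z <- sum(post)
  if (z <= 0) stop("impossible evidence: joint probability is zero")
  post / z
}

## ---- JSON serialization ----

#' Serialize and deserialize a Bayesian network as JSON
#'
#' The document (schema version 1) stores node state sets, the edge list,
#' and per-node CPT probability rows keyed by parent-state combination.
#'
#' @param net A `"bayesnet"`.
#' @param path File path.
#' @return `bn_write_json()`: `path`, invisibly. `bn_read_json()`: a
#'   `"bayesnet"`.
#' @export
bn_write_json <- function(net, path) {
  doc <- list(
    schema = "suidbn-bayesnet", version = 1L,
    nodes = net$spec$nodes,
    edges = apply(net$spec$edges, 1, function(r)
      list(from = r[["from"]], to = r[["to"]])),
    cpts = lapply(net$cpts, function(cpt) list(
      node = cpt$node, parents = cpt$parents, states = cpt$states,
      prob = apply(cpt$prob, 1, as.numeric, simplify = FALSE)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname bn_write_json
#' @export
bn_read_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "suidbn-bayesnet"))
    stop("not a suidbn network document: ", path)
  nodes <- lapply(doc$nodes, function(s) unlist(s))
  edges <- if (length(doc$edges)) {
    do.call(rbind, lapply(doc$edges, function(e) c(from = e$from, to = e$to)))
  } else NULL
  spec <- network_spec(nodes, edges)
  cpts <- lapply(doc$cpts, function(x) {
    prob <- do.call(rbind, lapply(x$prob, unlist))
    new_cpt(x$node, unlist2char(x$parents), unlist2char(x$states),
            nodes[unlist2char(x$parents)], prob)
  })
  names(cpts) <- vapply(cpts, `[[`, character(1), "node")
  bayesnet(spec, cpts)
}

unlist2char <- function(x) if (length(x)) unlist(x) else character(0)
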