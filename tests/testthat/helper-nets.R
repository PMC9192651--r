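# Builders and independent oracles shared across the suite.

# Two-node net encoding the published diagnosis prior and the
# sleep-related-death conditional (41/41 for SIDS, 13/23 for others).
sleep_toy_net <- function() {
  spec <- network_spec(
    list(cause = c("SIDS", "other"), sleep = c("yes", "no")),
    rbind(c(from = "cause", to = "sleep")))
  bayesnet(spec, list(
    cause = new_cpt("cause", character(0), c("SIDS", "other"), list(),
                    matrix(c(41, 23) / 64, 1)),
    sleep = new_cpt("sleep", "cause", c("yes", "no"),
                    list(cause = c("SIDS", "other")),
                    rbind(c(1, 0), c(13 / 23, 10 / 23)))))
}

# Random DAG with random CPTs: <= max_nodes nodes, 2..max_states states.
random_net <- function(max_nodes = 8, max_states = 3) {
  n <- sample(2:max_nodes, 1)
  nodes <- paste0("n", seq_len(n))
  states <- lapply(seq_len(n), function(i)
    paste0("s", seq_len(sample(2:max_states, 1))))
  names(states) <- nodes
  edges <- NULL
  for (j in 2:n) for (i in 1:(j - 1))
    if (stats::runif(1) < 0.4)
      edges <- rbind(edges, c(from = nodes[i], to = nodes[j]))
  spec <- network_spec(states, edges)
  cpts <- lapply(nodes, function(v) {
    ps <- spec$edges[spec$edges[, "to"] == v, "from"]
    n_rows <- prod(c(1, lengths(states[ps])))
    prob <- matrix(stats::runif(n_rows * length(states[[v]]), 0.05, 1),
                   nrow = n_rows)
    prob <- prob / rowSums(prob)
    new_cpt(v, unname(ps), states[[v]], states[ps], prob)
  })
  names(cpts) <- nodes
  bayesnet(spec, cpts)
}

random_evidence <- function(net, query) {
  candidates <- setdiff(names(net$spec$nodes), query)
  picked <- candidates[stats::runif(length(candidates)) < 0.4]
  ev <- vapply(picked, function(v) sample(net$spec$nodes[[v]], 1),
               character(1))
  if (!length(ev)) NULL else ev
}

# Independent two-row exact-test oracle: enumerate every table with the
# observed margins, multivariate hypergeometric probability, sum those not
# exceeding the observed table's (point-probability rule).
two_row_exact_oracle <- function(tab) {
  stopifnot(nrow(tab) == 2)
  cs <- colSums(tab)
  r1 <- sum(tab[1, ])
  n <- sum(tab)
  rows <- expand.grid(lapply(cs, function(k) 0:k))
  rows <- rows[rowSums(rows) == r1, , drop = FALSE]
  logp <- apply(rows, 1, function(a)
    sum(lchoose(cs, unlist(a))) - lchoose(n, r1))
  p_obs <- sum(lchoose(cs, tab[1, ])) - lchoose(n, r1)
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# Probability mass of each parent-state combination (CPT row) of a node,
# computed by brute-force summation of the joint over all assignments.
marginal_row_mass <- function(net, node) {
  cpt <- net$cpts[[node]]
  if (!length(cpt$parents)) return(1)
  grid <- expand.grid(net$spec$nodes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  joint <- apply(grid, 1, function(row)
    joint_probability(net, as.list(row)))
  key <- do.call(paste, c(grid[cpt$parents], list(sep = "\r")))
  combos <- expand.grid(cpt$parent_states, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  ck <- do.call(paste, c(combos, list(sep = "\r")))
  vapply(ck, function(k) sum(joint[key == k]), numeric(1))
}

# Random contingency table with the given shape and a total <= max_total.
random_count_table <- function(nr, nc, max_total = 40) {
  repeat {
    tab <- matrix(sample(0:10, nr * nc, replace = TRUE), nr, nc)
    if (sum(tab) <= max_total && sum(tab) > 0) return(tab)
  }
}
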