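test_that("structural validation reports cycles and undeclared endpoints", {
  ok <- list(nodes = list(A = c("y", "n"), B = c("y", "n"), C = c("y", "n")),
             edges = rbind(c(from = "A", to = "B"), c(from = "B", to = "C")))
  expect_length(validate_network(ok), 0)
  cyc <- ok
  cyc$edges <- rbind(c(from = "A", to = "B"), c(from = "B", to = "A"))
  expect_match(validate_network(cyc), "cycle")
  und <- ok
  und$edges <- rbind(c(from = "A", to = "Z"))
  expect_match(validate_network(und), "Z")
  empty_states <- list(nodes = list(A = character(0)),
                       edges = ok$edges[0, , drop = FALSE])
  expect_match(validate_network(empty_states), "empty state set")
  expect_error(network_spec(cyc$nodes, cyc$edges), "cycle")
})

test_that("CPT estimation reproduces count arithmetic, smoothing and zero-row rules", {
  cohort <- generate_replicate_cohort(seed = 1)
  spec <- network_spec(
    list(cause_of_death = c("SIDS", "non_SIDS"),
         death_during_sleep = c("yes", "no")),
    rbind(c(from = "cause_of_death", to = "death_during_sleep")))
  net <- estimate_cpts(spec, cohort, alpha = 0)
  expect_equal(unname(net$cpts$cause_of_death$prob[1, ]), c(41, 23) / 64)
  # sleep-related death is deterministic for SIDS (41/41)
  expect_equal(unname(net$cpts$death_during_sleep$prob[1, ]), c(1, 0))
  expect_equal(unname(net$cpts$death_during_sleep$prob[2, ]),
               c(13, 10) / 23)
  # alpha = 1 on a row with zero counts gives the uniform over k states
  tiny <- new_cohort(data.frame(
    case_id = "a", diagnosis = "SIDS",
    generate_replicate_cohort(seed = 1)$records[1, -(1:2)],
    stringsAsFactors = FALSE))
  net1 <- estimate_cpts(spec, tiny, alpha = 1)
  expect_equal(unname(net1$cpts$death_during_sleep$prob[2, ]), c(0.5, 0.5))
  # unmapped node
  bad <- network_spec(list(not_a_factor = c("y", "n")))
  expect_error(estimate_cpts(bad, cohort), "no cohort variable")
})

test_that("unknown_policy switches between category and exclusion counting", {
  cohort <- generate_replicate_cohort(seed = 1)
  spec <- network_spec(
    list(cause_of_death = c("SIDS", "non_SIDS"),
         passive_smoking = c("yes", "no", "unknown")),
    rbind(c(from = "cause_of_death", to = "passive_smoking")))
  as_state <- estimate_cpts(spec, cohort, unknown_policy = "as_state")
  expect_equal(unname(as_state$cpts$passive_smoking$prob[1, ]),
               c(21, 9, 11) / 41)
  spec2 <- network_spec(
    list(cause_of_death = c("SIDS", "non_SIDS"),
         passive_smoking = c("yes", "no")),
    rbind(c(from = "cause_of_death", to = "passive_smoking")))
  excl <- estimate_cpts(spec2, cohort, unknown_policy = "exclude")
  # the 21/30 = 0.7 proportion used by the onset model
  expect_equal(unname(excl$cpts$passive_smoking$prob[1, ]), c(0.7, 0.3))
})

test_that("joint probabilities factorize and normalize", {
  net <- sleep_toy_net()
  expect_equal(joint_probability(net, c(cause = "SIDS", sleep = "yes")),
               41 / 64)
  # two independent fair coins
  coins <- bayesnet(
    network_spec(list(a = c("h", "t"), b = c("h", "t"))),
    list(a = new_cpt("a", character(0), c("h", "t"), list(),
                     matrix(0.5, 1, 2)),
         b = new_cpt("b", character(0), c("h", "t"), list(),
                     matrix(0.5, 1, 2))))
  expect_equal(joint_probability(coins, c(a = "h", b = "t")), 0.25)
  # sum over all full assignments is 1 (random net)
  set.seed(101)
  net2 <- random_net(5)
  grid <- expand.grid(net2$spec$nodes, stringsAsFactors = FALSE)
  total <- sum(apply(grid, 1, function(row)
    joint_probability(net2, as.list(row))))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("enumeration posterior matches hand-computed Bayes updates", {
  net <- sleep_toy_net()
  post <- posterior_enumeration(net, "cause", c(sleep = "yes"))
  expect_equal(unname(post["SIDS"]), 0.759, tolerance = 5e-4)
  expect_equal(sum(post), 1)
  # no evidence: posterior equals the marginal prior
  expect_equal(unname(posterior_enumeration(net, "cause")),
               c(41, 23) / 64)
  # impossible evidence fails loudly
  net0 <- bayesnet(
    network_spec(list(a = c("x", "y"), b = c("u", "v")),
                 rbind(c(from = "a", to = "b"))),
    list(a = new_cpt("a", character(0), c("x", "y"), list(),
                     matrix(c(1, 0), 1)),
         b = new_cpt("b", "a", c("u", "v"), list(a = c("x", "y")),
                     rbind(c(1, 0), c(0, 1)))))
  expect_error(posterior_enumeration(net0, "a", c(b = "v")),
               "impossible evidence")
  expect_error(posterior_ve(net0, "a", c(b = "v")), "impossible evidence")
})

test_that("with full evidence the posterior matches joint-probability ratios", {
  set.seed(77)
  for (rep in 1:10) {
    net <- random_net(5)
    nodes <- names(net$spec$nodes)
    query <- sample(nodes, 1)
    ev <- vapply(setdiff(nodes, query),
                 function(v) sample(net$spec$nodes[[v]], 1), character(1))
    joints <- vapply(net$spec$nodes[[query]], function(s)
      joint_probability(net, c(ev, stats::setNames(s, query))), numeric(1))
    expect_equal(unname(posterior_enumeration(net, query, ev)),
                 unname(joints / sum(joints)), tolerance = 1e-12)
  }
})

test_that("variable elimination equals enumeration on random networks", {
  set.seed(2024)
  worst <- 0
  for (rep in 1:200) {
    net <- random_net(8, 3)
    query <- sample(names(net$spec$nodes), 1)
    ev <- random_evidence(net, query)
    p_enum <- posterior_enumeration(net, query, ev)
    p_ve <- posterior_ve(net, query, ev)
    expect_equal(sum(p_ve), 1, tolerance = 1e-12)
    worst <- max(worst, max(abs(p_enum - p_ve)))
  }
  expect_lt(worst, 1e-9)
})

test_that("variable elimination matches the closed-form chain inversion", {
  # A -> B -> C with known CPTs; posterior of A given C by two-step Bayes
  pA <- c(0.3, 0.7)
  pBgA <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  pCgB <- rbind(c(0.6, 0.4), c(0.25, 0.75))
  spec <- network_spec(list(A = c("a1", "a2"), B = c("b1", "b2"),
                            C = c("c1", "c2")),
                       rbind(c(from = "A", to = "B"),
                             c(from = "B", to = "C")))
  net <- bayesnet(spec, list(
    A = new_cpt("A", character(0), c("a1", "a2"), list(), matrix(pA, 1)),
    B = new_cpt("B", "A", c("b1", "b2"), list(A = c("a1", "a2")), pBgA),
    C = new_cpt("C", "B", c("c1", "c2"), list(B = c("b1", "b2")), pCgB)))
  # closed form: P(A=a | C=c1) over joint sum
  lik <- pBgA %*% pCgB[, 1]          # P(C=c1 | A)
  expected <- pA * as.vector(lik)
  expected <- expected / sum(expected)
  expect_equal(unname(posterior_ve(net, "A", c(C = "c1"))), expected,
               tolerance = 1e-12)
})

test_that("posteriors are invariant to node declaration order", {
  net <- sleep_toy_net()
  spec_rev <- network_spec(
    list(sleep = c("yes", "no"), cause = c("SIDS", "other")),
    rbind(c(from = "cause", to = "sleep")))
  net_rev <- bayesnet(spec_rev, net$cpts)
  expect_equal(posterior_ve(net_rev, "cause", c(sleep = "yes")),
               posterior_ve(net, "cause", c(sleep = "yes")))
})

test_that("estimation recovers generating CPTs from 10,000 sampled records", {
  set.seed(31)
  net <- random_net(5, 3)
  cohort <- sample_cohort_from_bn(net, n = 10000, seed = 13)
  fit <- estimate_cpts(net$spec, cohort, alpha = 0)
  worst <- 0
  for (v in names(net$cpts)) {
    # only well-visited parent rows can be recovered to +-0.02; rows
    # with mass below 10% are left out of the comparison
    reach <- marginal_row_mass(net, v)
    keep <- reach > 0.1
    if (!any(keep)) next
    worst <- max(worst, max(abs(net$cpts[[v]]$prob[keep, , drop = FALSE] -
                                  fit$cpts[[v]]$prob[keep, , drop = FALSE])))
  }
  expect_lt(worst, 0.02)
})

test_that("favorable single-factor evidence strictly raises the favored posterior", {
  set.seed(55)
  for (rep in 1:20) {
    prior <- stats::runif(1, 0.2, 0.8)
    l1 <- stats::runif(1, 0.1, 0.9)
    l2 <- stats::runif(1, 0.1, 0.9)
    if (l1 <= l2) next  # want likelihood ratio > 1 for state q1
    spec <- network_spec(list(q = c("q1", "q2"), e = c("pos", "neg")),
                         rbind(c(from = "q", to = "e")))
    net <- bayesnet(spec, list(
      q = new_cpt("q", character(0), c("q1", "q2"), list(),
                  matrix(c(prior, 1 - prior), 1)),
      e = new_cpt("e", "q", c("pos", "neg"), list(q = c("q1", "q2")),
                  rbind(c(l1, 1 - l1), c(l2, 1 - l2)))))
    post <- posterior_ve(net, "q", c(e = "pos"))
    expect_gt(post[["q1"]], prior)
  }
})

test_that("network JSON serialization round-trips inference exactly", {
  set.seed(8)
  net <- random_net(6)
  path <- withr::local_tempfile(fileext = ".json")
  bn_write_json(net, path)
  back <- bn_read_json(path)
  query <- names(net$spec$nodes)[1]
  expect_equal(posterior_ve(back, query), posterior_ve(net, query))
  expect_equal(back$cpts[[query]]$prob, net$cpts[[query]]$prob)
})
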