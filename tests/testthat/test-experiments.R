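test_that("concentration plans define the published grids", {
  p1 <- concentration_plan("exp1")
  expect_identical(length(p1$psi_values) * length(p1$group_values), 5151L)
  p2 <- concentration_plan("exp2")
  expect_identical(length(p2$psi_values), 101L)
  expect_identical(length(p2$group_values), 50L)
  expect_identical(range(p2$group_values), c(151L, 200L))
  p3 <- concentration_plan("exp3")
  expect_identical(length(p3$psi_values) * length(p3$group_values), 5151L)
  expect_identical(range(p3$group_a$values), c(151L, 200L))
  expect_identical(range(p3$group_b$values), c(100L, 150L))
  # sigma and varsigma partition the roster
  model <- test_model()
  g <- pheronet:::plan_groups(model$net, p3, model$roster)
  expect_length(g$a, 14L)
  expect_length(g$b, 27L)
  expect_length(intersect(g$a, g$b), 0L)
})

test_that("initial markings set group concentrations together", {
  model <- test_model()
  config <- generate_network(model, 5L)
  plan <- concentration_plan("exp1")
  m <- initial_marking(config, plan, 300L, c(lambda = 100L),
                       roster = model$roster)
  psi <- pheronet:::tagged_places(config$net, "psi")
  add <- pheronet:::tagged_places(config$net, "additional")
  expect_true(all(m[psi] == 300L))
  expect_identical(length(unique(m[psi])), 1L)
  expect_true(all(m[add] == 100L))
  # technical-presence places keep their shipped tokens
  expect_identical(unname(m["p5"]), unname(model$m0["p5"]))
  # the split plan drives sigma and varsigma separately
  p3 <- concentration_plan("exp3")
  m3 <- initial_marking(config, p3, 350L, c(sigma = 151L, varsigma = 100L),
                        roster = model$roster)
  g <- pheronet:::plan_groups(config$net, p3, model$roster)
  expect_true(all(m3[g$a] == 151L))
  expect_true(all(m3[g$b] == 100L))
  expect_error(initial_marking(config, plan, 299L, c(lambda = 100L),
                               roster = model$roster), "range")
  expect_error(initial_marking(config, plan, 300L, c(lambda = 99L),
                               roster = model$roster), "range")
})

test_that("an all-ones configuration responds once thresholds are trivial", {
  config <- uniform_config(1L)
  model <- test_model()
  plan <- concentration_plan("exp1")
  m <- initial_marking(config, plan, 400L, c(lambda = 150L),
                       roster = model$roster)
  pol <- firing_policy(max_steps = 1000000L)
  res <- simulate_response(config, m, policy = pol)
  expect_true(res)
  expect_false(attr(res, "budget"))
  expect_identical(simulate_response(config, m, policy = pol),
                   simulate_response(config, m, policy = pol))
})

test_that("an unattainable threshold on the critical chain blanks the grid", {
  # the Ste11-phosphorylation pool is the sole route to activated Fus3, so
  # a threshold far above any attainable pool content blocks the response
  # everywhere (the receptor arm itself is bypassable under pooling; see
  # the methods vignette)
  config <- uniform_config(1L, overrides = c(s17TOt17 = 900000L))
  model <- test_model()
  plan <- concentration_plan("exp1")
  sw <- sweep(config, plan, policy = firing_policy(max_steps = 100000L),
              roster = model$roster)
  expect_identical(dim(sw$fired), c(101L, 51L))
  expect_false(any(sw$fired))
  expect_identical(classify_profile(sw)$kind, "negative")
})

test_that("profiles classify thresholds from the literal grid", {
  plan <- concentration_plan("exp1")
  blank <- matrix(FALSE, 101, 51, dimnames = list(plan$psi_values,
                                                  plan$group_values))
  mk <- function(f) structure(list(fired = f, budget = blank,
                                   psi_values = plan$psi_values,
                                   group_values = plan$group_values,
                                   plan = plan), class = "sweep_result")
  # positive for all psi >= 374 at the group minimum: core-driven (type a)
  g <- blank; g[as.character(374:400), ] <- TRUE
  p <- classify_profile(mk(g))
  expect_identical(p$kind, "type_a")
  expect_identical(p$x, 374L)
  expect_identical(p$y, 100L)
  expect_true(p$monotone)
  # positive only when psi >= 374 and the group exceeds 105: type b
  g <- blank; g[as.character(374:400), as.character(105:150)] <- TRUE
  p <- classify_profile(mk(g))
  expect_identical(p$kind, "type_b")
  expect_identical(c(p$x, p$y), c(374L, 105L))
  # all-false grid
  expect_identical(classify_profile(mk(blank))$kind, "negative")
  # non-monotone grid is flagged
  g <- blank; g["380", "120"] <- TRUE
  g["390", "120"] <- FALSE; g["380", "130"] <- TRUE; g["381", "120"] <- TRUE
  g["382", "120"] <- TRUE
  expect_false(classify_profile(mk(g))$monotone)
})

test_that("outcomes are invariant to a common scale on weights and tokens", {
  model <- test_model()
  cfg <- generate_network(model, 404L)
  scale <- 3L
  w2 <- cfg$weights * scale
  cfg2 <- set_weights(model$net, w2)
  cfg2$m0 <- marking(model$net,
                     setNames(as.integer(model$m0 * scale)[model$m0 > 0],
                              names(model$m0)[model$m0 > 0]))
  plan <- concentration_plan("exp1")
  for (cell in list(c(300L, 100L), c(350L, 125L), c(400L, 150L))) {
    m1 <- initial_marking(cfg, plan, cell[1], c(lambda = cell[2]),
                          roster = model$roster)
    m2 <- m1 * scale
    class(m2) <- "marking"
    r1 <- run(cfg$net, m1, firing_policy(), "t23")
    r2 <- run(cfg2$net, m2, firing_policy(), "t23")
    expect_identical(r1$fired, r2$fired)
    expect_identical(r1$termination_reason, r2$termination_reason)
  }
})

test_that("small ensembles partition, persist, and replay bit-identically", {
  model <- test_model()
  plan <- concentration_plan("exp1")
  r1 <- experiment1(6L, 77L, plan, model)
  expect_identical(nrow(r1$profiles), 6L)
  expect_identical(sort(c(positives(r1), negatives(r1))),
                   sort(r1$profiles$network_id))
  expect_identical(dim(r1$weights),
                   c(6L, sum(!model$net$arcs$read)))
  r1b <- experiment1(6L, 77L, plan, model)
  expect_identical(r1$profiles, r1b$profiles)
  expect_identical(r1$weights, r1b$weights)
  # different master seed, different weights
  expect_false(identical(experiment1(2L, 78L, plan, model)$weights[1, ],
                         r1$weights[1, ]))
})

test_that("raising the additional-protein range can rescue a negative network", {
  # construct a configuration whose Ste11-phosphorylation pool threshold
  # sits just above the supply available at the base additional-protein
  # range: with all-ones weights the pool's intake grows with the group
  # value, so the elevated range crosses the threshold
  model <- test_model()
  pol <- firing_policy(max_steps = 300000L)
  probe <- uniform_config(1L, overrides = c(s17TOt17 = 900000L))
  plan1 <- concentration_plan("exp1")
  plan2 <- concentration_plan("exp2")
  m150 <- initial_marking(probe, plan1, 400L, c(lambda = 150L),
                          roster = model$roster)
  supply150 <- run(probe$net, m150, pol)$final_marking[["s17"]]
  m200 <- initial_marking(probe, plan2, 400L, c(lambda = 200L),
                          roster = model$roster)
  supply200 <- run(probe$net, m200, pol)$final_marking[["s17"]]
  expect_gt(supply200, supply150)
  thr <- supply150 + 1L
  config <- uniform_config(1L, overrides = c(s17TOt17 = thr))
  sw1 <- sweep(config, plan1, policy = pol, roster = model$roster)
  expect_false(any(sw1$fired))
  sw2 <- sweep(config, plan2, policy = pol, roster = model$roster)
  expect_true(any(sw2$fired))
  # and the experiment-2 driver moves it from neg to pos
  prof <- classify_profile(sw1)
  report1 <- pheronet:::new_report(
    "exp1",
    pheronet:::profile_row("net00001", NA_integer_, prof),
    matrix(config$weights, nrow = 1,
           dimnames = list("net00001", names(config$weights))),
    plan1, "t23", pol, 1L, model)
  report2 <- experiment2(report1, plan2, policy = pol)
  expect_identical(positives(report2), "net00001")
  # an empty negative set produces an empty, well-formed report
  report1$profiles$kind <- "type_a"
  report1$profiles$positive <- TRUE
  expect_identical(nrow(experiment2(report1, plan2, policy = pol)$profiles),
                   0L)
})

test_that("the split-range experiment classes CS, CD and CN are exhaustive", {
  model <- test_model()
  plan1 <- concentration_plan("exp1")
  r1 <- experiment1(8L, 1234L, plan1, model)
  r2 <- experiment2(r1)
  r3 <- experiment3(r2)
  expect_identical(nrow(r3$profiles), length(positives(r2)))
  if (nrow(r3$profiles) > 0L) {
    expect_true(all(r3$profiles$class %in% c("CS", "CD", "CN")))
    expect_identical(r3$profiles$class == "CN", !r3$profiles$positive)
    cs <- r3$profiles[r3$profiles$class == "CS", ]
    for (id in cs$network_id) {
      old <- r2$profiles[r2$profiles$network_id == id, ]
      expect_identical(cs[cs$network_id == id, c("x", "y")],
                       old[, c("x", "y")], ignore_attr = TRUE)
    }
  }
  # replay determinism across the chain
  r3b <- experiment3(experiment2(experiment1(8L, 1234L, plan1, model)))
  expect_identical(r3$profiles, r3b$profiles)
})
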