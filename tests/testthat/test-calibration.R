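test_that("build_scenarios reproduces the worked prevalence grid", {
  scen <- build_scenarios(ref_theta0)
  theta1 <- t(vapply(scen, `[[`, ref_theta0, "theta1"))
  # Scenario C IVH: 1.5 x 0.15 = 0.225 rounds to 0.22; the reference table
  # prints 0.23 while also printing 0.58 for the tie 1.5 x 0.39 = 0.585,
  # so no rounding rule reproduces both (the source control rates carried
  # more decimals). The formula value is asserted here.
  expected <- rbind(
    A = c(0.39, 0.15, 0.06, 0.04),
    B = c(0.26, 0.10, 0.04, 0.03),
    C = c(0.58, 0.22, 0.09, 0.06),
    D = c(0.78, 0.30, 0.12, 0.08),
    E = c(1.00, 0.45, 0.18, 0.12))
  expect_equal(unname(theta1), unname(expected))
  expect_equal(scen[[1]]$theta1, scen[[1]]$theta0)  # multiplier 1
  # default truth labels: death/IVH unacceptable from C, NEC/ret from D
  expect_equal(unname(scen[[3]]$truth),
               c("Unacceptable", "Unacceptable", "Acceptable", "Acceptable"))
  expect_equal(unname(scen[[4]]$truth), rep("Unacceptable", 4))
  expect_equal(unname(scen[[2]]$truth), rep("Acceptable", 4))
  expect_error(build_scenarios(c(a = 0.2, b = 0.3)), "unacceptable_from")
})

test_that("max_class_b applies the severity-weighted cap", {
  expect_equal(max_class_b(ref_weights),
               c(death = 0.10, ivh = 0.16, nec = 0.25, ret = 0.30))
  expect_equal(max_class_b(0), 0.60)
  expect_error(max_class_b(120), "\\[0, 100\\]")
})

test_that("misclassification_rates counts the contingency table", {
  mt <- misclassification_rates(
    conclusions = c("Unacceptable", "Acceptable", "Acceptable",
                    "Unacceptable"),
    truth = c("Acceptable", "Acceptable", "Unacceptable", "Unacceptable"))
  expect_equal(c(mt$A, mt$B, mt$C, mt$D), c(1, 1, 1, 1))
  expect_equal(mt$rate_a, 0.5); expect_equal(mt$rate_b, 0.5)
  perfect <- misclassification_rates(rep(FALSE, 10), rep(FALSE, 10))
  expect_equal(perfect$rate_a, 0)
  expect_true(is.na(perfect$rate_b))  # no truly-unacceptable trials
  ten <- misclassification_rates(c(TRUE, rep(FALSE, 9)), rep(FALSE, 10))
  expect_equal(ten$rate_a, 0.1)
  expect_error(misclassification_rates(TRUE, c(TRUE, FALSE)), "aligned")
})

test_that("rate identities hold for random conclusion sets", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    cu <- stats::runif(n) < 0.4; tu <- stats::runif(n) < 0.5
    mt <- misclassification_rates(cu, tu)
    expect_equal(mt$A + mt$B + mt$C + mt$D, n)
    if (any(!tu)) expect_equal(mt$rate_a, sum(cu & !tu) / sum(!tu))
    if (any(tu)) expect_equal(mt$rate_b, sum(!cu & tu) / sum(tu))
  }
})

test_that("simulate_trials is deterministic and hits the two limits", {
  cfg <- sim_config(n_per_arm = 60, L = 4, n_trials = 60,
                    mc_samples = 2000, seed = 11)
  sched <- list(e1 = solve_schedule("uniform", 4, 0.95, 0.8))
  # wide margin: essentially no unacceptable conclusions under the null
  null_scen <- list(scenario_id = "A", index = 1, multiplier = 1,
                    theta0 = c(e1 = 0.39), theta1 = c(e1 = 0.39),
                    truth = c(e1 = "Acceptable"))
  s1 <- simulate_trials(null_scen, cfg, prior_pair(1, 1, 1, 1),
                        point_margin(0.6), schedule = sched)
  expect_lt(mean(s1$conclusions[, "e1"]), 0.01)
  # extreme excess against a small margin: almost always flagged
  alt_scen <- list(scenario_id = "E", index = 5, multiplier = 3,
                   theta0 = c(e1 = 0.39), theta1 = c(e1 = 1.0),
                   truth = c(e1 = "Unacceptable"))
  s2 <- simulate_trials(alt_scen, cfg, prior_pair(1, 1, 1, 1),
                        point_margin(0.25), schedule = sched)
  expect_gt(mean(s2$conclusions[, "e1"]), 0.95)
  # same seed, same conclusions
  s1b <- simulate_trials(null_scen, cfg, prior_pair(1, 1, 1, 1),
                         point_margin(0.6), schedule = sched)
  expect_identical(s1$conclusions, s1b$conclusions)
  expect_identical(s1$probabilities, s1b$probabilities)
})

test_that("count data are shared across priors (sensitivity contract)", {
  cfg <- sim_config(n_per_arm = 40, L = 4, n_trials = 20,
                    mc_samples = 2000, seed = 21)
  scen <- build_scenarios(c(e1 = 0.2, e2 = 0.1),
                          unacceptable_from = c(3, 4))[[1]]
  m <- point_margin(0.1)
  pA <- simulate_trials(scen, cfg, prior_pair(1, 1, 1, 1), m,
                        analyses = "final")
  pB <- simulate_trials(scen, cfg, prior_pair(2, 8, 2, 8), m,
                        analyses = "final")
  # identical data streams: probabilities correlate strongly across priors
  expect_gt(stats::cor(pA$probabilities[, 1, "e1"],
                       pB$probabilities[, 1, "e1"]), 0.9)
})

test_that("calibrate_final_thresholds: rates are monotone in the threshold", {
  cfg <- sim_config(n_per_arm = 60, L = 3, n_trials = 40,
                    mc_samples = 2000, seed = 31)
  scen <- build_scenarios(c(e1 = 0.3, e2 = 0.1),
                          unacceptable_from = c(3, 4))
  margins <- list(e1 = point_margin(0.15), e2 = point_margin(0.1))
  grid <- seq(0.55, 0.95, by = 0.05)
  cal <- calibrate_final_thresholds(scen, cfg,
                                    build_prior_grid(0.3, 0.05)[c(1, 9)],
                                    margins, threshold_grid = grid)
  expect_error(calibrate_final_thresholds(scen, cfg,
                                          build_prior_grid(0.3, 0.05)[1],
                                          margins, threshold_grid = c(0.4)),
               "0.5")
  for (pl in unique(cal$prior_label)) for (ev in c("e1", "e2")) {
    sub <- cal[cal$prior_label == pl & cal$event_id == ev, ]
    sub <- sub[order(sub$tau_final), ]
    expect_true(all(diff(sub$rate_a) <= 1e-12))
    expect_true(all(diff(sub$rate_b) >= -1e-12))
  }
})

test_that("thresholding a fixture of probabilities matches hand counts", {
  set.seed(41)
  p <- stats::runif(100)
  labels <- rep(c(TRUE, FALSE), 50)
  mt <- misclassification_rates(p >= 0.8, labels)
  # brute-force enumeration
  A <- 0L; B <- 0L; C <- 0L; D <- 0L
  for (i in 1:100) {
    concl_u <- p[i] >= 0.8
    if (concl_u && !labels[i]) A <- A + 1L
    if (!concl_u && labels[i]) B <- B + 1L
    if (!concl_u && !labels[i]) C <- C + 1L
    if (concl_u && labels[i]) D <- D + 1L
  }
  expect_equal(c(mt$A, mt$B, mt$C, mt$D), c(A, B, C, D))
  expect_equal(mt$rate_a, A / (A + C))
  expect_equal(mt$rate_b, B / (B + D))
})

test_that("select_rule honours constraints, tie-breaks and infeasibility", {
  fix <- expand.grid(prior_label = c(1L, 2L), event_id = c("e1", "e2"),
                     tau_final = c(0.6, 0.8), stringsAsFactors = FALSE)
  # prior 1 violates the class-a cap for e1 at every threshold
  fix$rate_a <- ifelse(fix$prior_label == 1 & fix$event_id == "e1", 0.4,
                       ifelse(fix$tau_final == 0.6, 0.08, 0.02))
  fix$rate_b <- ifelse(fix$tau_final == 0.6, 0.05, 0.20)
  cons <- constraint_spec(0.10, c(e1 = 0.25, e2 = 0.25))
  rule <- select_rule(fix, cons)
  expect_true(rule$admissible)
  expect_equal(rule$prior_label, 2L)
  # smallest admissible threshold retained per event
  expect_equal(unname(rule$tau_final[c("e1", "e2")]), c(0.6, 0.6))
  # vacuous constraints: everything admissible, lowest label wins
  rule_v <- select_rule(fix, constraint_spec(1, c(e1 = 1, e2 = 1)))
  expect_true(rule_v$admissible)
  expect_equal(rule_v$prior_label, 1L)
  # infeasible constraints: explicit no-admissible-rule result
  rule_0 <- select_rule(fix, constraint_spec(0, c(e1 = 0, e2 = 0)))
  expect_false(rule_0$admissible)
  expect_s3_class(rule_0$nearest_miss, "data.frame")
  expect_true(all(rule_0$nearest_miss$constraint_excess > 0))
})

test_that("select_rule picks the family that meets the constraints", {
  fix <- data.frame(prior_label = 9L, event_id = c("e1", "e2"),
                    tau_final = 0.8, rate_a = 0.05, rate_b = 0.1)
  cons <- constraint_spec(0.10, c(e1 = 0.25, e2 = 0.25))
  fam <- data.frame(
    family = rep(c("uniform", "exponential"), each = 2),
    event_id = rep(c("e1", "e2"), 2),
    rate_a = c(0.30, 0.25, 0.08, 0.05),
    rate_b = c(0.01, 0.02, 0.10, 0.12))
  rule <- select_rule(fix, cons, family_rates = fam)
  expect_equal(rule$family, "exponential")
  expect_equal(rule$family_detail$admissible, c(FALSE, TRUE))
})

test_that("sim_config validates accrual", {
  expect_equal(sim_config(n_per_arm = 162, L = 11)$accrual[11], 162L)
  expect_error(sim_config(accrual = c(10, 5, 162), L = 3, n_per_arm = 162),
               "increasing")
  expect_error(sim_config(accrual = c(10, 20), L = 2, n_per_arm = 162),
               "equal n_per_arm")
})
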