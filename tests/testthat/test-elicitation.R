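answers_df <- function(h, event = "ivh") {
  # paste0 with recycle0 = FALSE would yield "E" on empty input
  data.frame(expert_id = as.character(seq_along(h)),
             event_id = rep(event, length(h)),
             acceptable_rate = h,
             severity_weight = rep(80, length(h)))
}

test_that("compute_differences subtracts, clamps and preserves order", {
  expect_equal(compute_differences(answers_df(0.20), 0.15)$differences, 0.05)
  # zero difference is clamped: zero is not an admissible margin
  expect_equal(compute_differences(answers_df(0.15), 0.15)$differences, 1e-3)
  d <- compute_differences(answers_df(c(0.18, 0.25, 0.16)), 0.15)
  expect_equal(d$differences, c(0.03, 0.10, 0.01))
  expect_equal(d$n_experts, 3L)
  expect_error(compute_differences(answers_df(numeric(0)), 0.15),
               "no elicitation data")
  expect_error(compute_differences(answers_df(1.2), 0.15), "\\[0, 1\\]")
  expect_error(
    compute_differences(rbind(answers_df(0.2, "a"), answers_df(0.2, "b")),
                        0.15),
    "multiple events")
})

test_that("clamping keeps every difference strictly inside (0, 1)", {
  set.seed(11)
  for (i in 1:50) {
    h <- stats::runif(20)
    f <- stats::runif(1, 0.01, 0.99)
    d <- compute_differences(answers_df(h), f)$differences
    expect_true(all(d > 0 & d < 1))
  }
})

test_that("fit_beta_ml recovers known shapes and respects symmetry", {
  set.seed(21)
  x <- stats::rbeta(5000, 2, 5)
  f <- fit_beta_ml(x)
  expect_lt(abs(f$shape1 - 2) / 2, 0.1)
  expect_lt(abs(f$shape2 - 5) / 5, 0.1)
  # symmetric data give a = b
  fs <- fit_beta_ml(c(0.3, 0.7, 0.4, 0.6))
  expect_lt(abs(fs$shape1 - fs$shape2), 1e-6)
})

test_that("fit_beta_ml agrees with a dense grid search on two points", {
  f <- fit_beta_ml(c(0.2, 0.4))
  oracle <- grid_beta_ml(c(0.2, 0.4))
  expect_lt(abs(f$shape1 - oracle["a"]), 0.06)
  expect_lt(abs(f$shape2 - oracle["b"]), 0.06)
  ss <- safenim:::beta_suffstats(c(0.2, 0.4))
  expect_gte(safenim:::beta_loglik_suff(f$shape1, f$shape2, ss),
             oracle["loglik"] - 1e-6)
})

test_that("fit_beta_ml falls back to a spike on identical values", {
  expect_warning(f <- fit_beta_ml(rep(0.2, 5)), "degenerate")
  expect_true(f$degenerate)
  expect_equal(f$shape1 / (f$shape1 + f$shape2), 0.2, tolerance = 1e-8)
  expect_equal(f$shape1 + f$shape2, 1000)
})

test_that("single-component EM reduces to the plain ML fit", {
  set.seed(31)
  x <- stats::rbeta(300, 3, 20)
  em <- fit_mixture_em(x, 1, test_elicit_config())
  ml <- fit_beta_ml(x)
  expect_equal(em$mixture$weights, 1)
  expect_equal(em$mixture$shape1, ml$shape1, tolerance = 1e-6)
  expect_equal(em$mixture$shape2, ml$shape2, tolerance = 1e-6)
})

test_that("EM recovers a two-component mixture and ascends monotonically", {
  set.seed(41)
  x <- c(stats::rbeta(1200, 2, 40), stats::rbeta(800, 10, 30))
  f <- fit_mixture_em(x, 2, test_elicit_config())
  expect_equal(f$diagnostics$k_selected, 2L)
  w <- sort(f$mixture$weights, decreasing = TRUE)
  expect_lt(abs(w[1] - 0.6), 0.05)
  means <- f$mixture$shape1 / (f$mixture$shape1 + f$mixture$shape2)
  expect_lt(abs(min(means) - 2 / 42), 0.02)
  expect_lt(abs(max(means) - 10 / 40), 0.02)
  expect_true(all(diff(f$diagnostics$loglik_trace) >= -1e-10))
})

test_that("EM ascent holds across seeds and component counts", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- c(stats::rbeta(150, 1.5, 60), stats::rbeta(100, 8, 25))
    cfg <- test_elicit_config(seed = seed)
    f <- suppressWarnings(fit_mixture_em(x, sample(2:3, 1), cfg))
    expect_true(all(diff(f$diagnostics$loglik_trace) >= -1e-10))
  }
})

test_that("manual two-component search separates clear clusters", {
  set.seed(51)
  x <- c(stats::rbeta(500, 2, 200), stats::rbeta(500, 20, 80))
  f <- fit_manual_two_component(x, test_elicit_config())
  # the chosen cut sits between the clusters
  xs <- sort(x)
  cut_value <- xs[f$diagnostics$chosen_cut]
  expect_gt(cut_value, 0.03)
  expect_lt(cut_value, 0.15)
  expect_lt(abs(f$diagnostics$chosen_weight - 0.5), 0.1)
  expect_equal(f$mixture$k, 2L)
})

test_that("the manual weight grid is 0, 0.05, ..., 1", {
  g <- elicit_config()$weight_grid
  expect_length(g, 21L)
  expect_equal(g, seq(0, 1, by = 0.05))
})

test_that("boundary weight w1 = 1 reduces to the left-side beta", {
  set.seed(61)
  x <- c(stats::rbeta(30, 2, 50), stats::rbeta(10, 10, 20))
  cfg <- test_elicit_config(weight_grid = 1)
  f <- fit_manual_two_component(x, cfg)
  expect_equal(f$mixture$k, 1L)
  expect_equal(f$diagnostics$chosen_weight, 1)
  sides <- safenim:::fit_cut_sides(sort(x), f$diagnostics$chosen_cut,
                                   cfg$shape_bounds)
  expect_equal(f$mixture$shape1, sides$left$shape1)
  expect_equal(f$mixture$shape2, sides$left$shape2)
})

test_that("hybrid fit rescales EM weights by 1 - w1 and normalises", {
  set.seed(71)
  x <- c(stats::rbeta(400, 2, 200),      # cluster near 0.01
         stats::rbeta(300, 16, 184),     # cluster near 0.08
         stats::rbeta(300, 20, 80))      # cluster near 0.2
  f <- fit_hybrid(x, test_elicit_config())
  expect_equal(sum(f$mixture$weights), 1, tolerance = 1e-9)
  w1 <- f$diagnostics$chosen_weight
  if (f$mixture$k == 3L) {
    expect_equal(f$mixture$weights[1], w1, tolerance = 1e-9)
    means <- f$mixture$shape1 / (f$mixture$shape1 + f$mixture$shape2)
    expect_true(!is.unsorted(means))
    expect_lt(abs(means[1] - 0.01), 0.03)
    expect_lt(abs(means[2] - 0.08), 0.03)
    expect_lt(abs(means[3] - 0.20), 0.03)
  } else fail("hybrid fit did not produce three components")
})

test_that("hybrid weight arithmetic: (0.5, 0.5) EM split of 1 - w1", {
  # direct check of the composition rule on a constructed example
  w1 <- 0.6; v <- c(0.5, 0.5)
  expect_equal(c(w1, (1 - w1) * v), c(0.6, 0.2, 0.2))
})

test_that("select_margin_fit prefers one component for unimodal data", {
  set.seed(81)
  x <- stats::rbeta(120, 3, 60)
  f <- suppressWarnings(select_margin_fit(x, test_elicit_config()))
  expect_equal(f$diagnostics$method_id, "em_mixture")
  expect_equal(f$mixture$k, 1L)
  # comparison lists a criterion value for every competing method
  expect_true(all(c("em_mixture", "manual_two_component", "hybrid") %in%
                    f$diagnostics$comparison$method))
  expect_true(all(is.finite(f$diagnostics$comparison$criterion)))
  win <- f$diagnostics$criterion_values[[f$diagnostics$criterion_used]]
  expect_equal(win, min(f$diagnostics$comparison$criterion))
})

test_that("mixture recovery invariant on separated clusters (reduced scale)", {
  # scaled down from 50 replicates of >= 2000 draws to 12 of 600 to fit
  # the CPU budget; the full-size EM recovery runs in the acceptance suite
  ok <- 0L
  reps <- 12L
  for (seed in seq_len(reps)) {
    set.seed(1000 + seed)
    x <- c(stats::rbeta(360, 2, 40), stats::rbeta(240, 10, 30))
    f <- suppressWarnings(
      select_margin_fit(x, test_elicit_config(seed = seed)))
    w <- sort(f$mixture$weights, decreasing = TRUE)
    if (f$mixture$k == 2L && abs(w[1] - 0.6) <= 0.05) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.9)
})

test_that("median_weight matches the worked configuration and medians", {
  expect_equal(median_weight(70), 70)
  expect_equal(median_weight(c(60, 80)), 70)
  w <- data.frame(severity_weight = c(100, 100, 100))
  expect_equal(median_weight(w), 100)
  expect_error(median_weight(150), "\\[0, 100\\]")
  expect_error(median_weight(numeric(0)), "no severity weights")
})
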