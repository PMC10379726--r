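test_that("age binning rounds half-up with a 30.4375-day month", {
  expect_equal(assign_age_group(0), 0L)
  expect_equal(assign_age_group(44), 1L)   # 44 / 30.4375 = 1.45
  expect_equal(assign_age_group(75), 2L)   # 75 / 30.4375 = 2.46
  expect_equal(assign_age_group(c(15.3, 45.7)), c(1L, 2L))
  expect_error(assign_age_group(-1), "negative")
})

test_that("transition graph applies the self-loop and skip rules", {
  meta <- data.frame(
    sample_id = c("i1_a", "i1_b", "i2_a", "i2_b", "i3_a"),
    infant_id = c("i1", "i1", "i2", "i2", "i3"),
    age = c(60, 120, 50, 70, 60))
  assignment <- data.frame(sample_id = meta$sample_id,
                           fct = c(1L, 2L, 2L, 2L, 1L))
  g <- build_transition_graph(assignment, meta)

  # i1: month 2 -> month 4, progression (a skipped month bin is allowed)
  e1 <- g$edges[g$edges$from_fct == 1L, ]
  expect_equal(e1$from_month, 2L)
  expect_equal(e1$to_month, 4L)
  expect_equal(e1$category, "progression")

  # i2: both samples in month 2 -> self-loop, no_change
  e2 <- g$edges[g$edges$from_fct == 2L, ]
  expect_equal(e2$from_month, e2$to_month)
  expect_equal(e2$category, "no_change")

  # i3 has one sample: contributes a node but no edge
  expect_equal(sum(g$edges$n), 2L)
  # occupancy columns sum to 1
  occ <- tapply(g$nodes$occupancy, g$nodes$month, sum)
  expect_equal(as.numeric(occ), rep(1, length(occ)))
})

test_that("edges at or below the display threshold are hidden, not removed", {
  # 1 transition of one kind vs 32 of another: fraction 1/33 = 0.03
  meta <- data.frame(
    sample_id = c(sprintf("a%02d_1", 1:33), sprintf("a%02d_2", 1:33)),
    infant_id = rep(sprintf("a%02d", 1:33), 2),
    age = rep(c(40, 100), each = 33))
  assignment <- data.frame(
    sample_id = meta$sample_id,
    fct = c(rep(1L, 32), 2L, rep(2L, 32), 3L))
  g <- build_transition_graph(assignment, meta, display_threshold = 0.04)
  rare <- g$edges[g$edges$from_fct == 2L & g$edges$to_fct == 3L, ]
  expect_equal(rare$fraction, 1 / 33)
  expect_true(rare$hidden)
  common <- g$edges[g$edges$from_fct == 1L & g$edges$to_fct == 2L, ]
  expect_false(common$hidden)
  # occupancies are unaffected by the threshold
  g2 <- build_transition_graph(assignment, meta, display_threshold = 0)
  expect_equal(g$nodes, g2$nodes)
})

test_that("event times follow the earliest-visit-at-or-beyond rule", {
  meta <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    infant_id = c("i1", "i1", "i1", "i2", "i2", "i2", "i3", "i3"),
    age = c(60, 120, 240, 60, 120, 240, 90, 150),
    arm = "control")
  assignment <- data.frame(
    sample_id = meta$sample_id,
    fct = c(1L, 2L, 4L, 1L, 2L, 2L, 3L, 3L))
  tab <- fct_event_table(assignment, meta, target_fct = 3L)
  expect_equal(tab$event[tab$infant_id == "i1"], 1L)
  expect_equal(tab$time[tab$infant_id == "i1"], 240)   # FCT4 >= FCT3
  expect_equal(tab$event[tab$infant_id == "i2"], 0L)
  expect_equal(tab$time[tab$infant_id == "i2"], 240)   # censored at last visit
  expect_equal(tab$time[tab$infant_id == "i3"], 90)    # event at first visit
})

test_that("single-sample infants are excluded from survival records", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     infant_id = c("i1", "i2", "i2"),
                     age = c(365, 30, 90), arm = "test")
  assignment <- data.frame(sample_id = meta$sample_id, fct = c(5L, 1L, 1L))
  expect_message(tab <- fct_event_table(assignment, meta, 3L), "excluded")
  expect_equal(tab$infant_id, "i2")
})

test_that("the product-limit estimator matches hand calculation", {
  rec <- data.frame(time = c(1, 2, 3), event = 1L)
  km <- km_curve(rec)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  all_cens <- data.frame(time = c(1, 2, 3), event = 0L)
  expect_true(all(km_curve(all_cens)$surv == 1))
  set.seed(4)
  rec2 <- data.frame(time = rexp(40), event = rbinom(40, 1, 0.7))
  s <- km_curve(rec2)$surv
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("Cox score test equals the classical log-rank statistic", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 30
    rec <- data.frame(time = round(rexp(n), 6),  # continuous, tie-free
                      event = rbinom(n, 1, 0.8),
                      arm = sample(c("control", "test"), n, TRUE))
    if (sum(rec$event) == 0 || length(unique(rec$arm)) < 2) next
    cx <- cox_binary(rec)
    expect_equal(cx$score_chi2,
                 oracle_logrank_chi2(rec$time, rec$event, rec$arm),
                 tolerance = 1e-6)
  }
})

test_that("Cox HR is symmetric and consistent", {
  # identical event-time multisets in both groups -> HR 1, score 0
  rec <- data.frame(time = rep(c(1, 2, 5, 7), 2), event = 1L,
                    arm = rep(c("control", "test"), each = 4))
  cx <- cox_binary(rec)
  expect_equal(cx$hazard_ratio, 1)
  expect_equal(cx$score_chi2, 0, tolerance = 1e-12)

  # large-sample consistency at true HR 0.5
  set.seed(23)
  n <- 500
  rec2 <- data.frame(time = c(rexp(n, 1), rexp(n, 0.5)), event = 1L,
                     arm = rep(c("control", "test"), each = n))
  cx2 <- cox_binary(rec2)
  expect_gt(cx2$hazard_ratio, 0.4)
  expect_lt(cx2$hazard_ratio, 0.62)
  expect_true(cx2$ci_low <= cx2$hazard_ratio &&
              cx2$hazard_ratio <= cx2$ci_high)
  expect_error(cox_binary(data.frame(time = 1:4, event = 0L,
                                     arm = c("a", "a", "b", "b"))),
               "no events")
})

test_that("log-rank type-I error is calibrated under the null", {
  set.seed(31)
  rejections <- 0L
  n_rep <- 1000L
  for (b in seq_len(n_rep)) {
    rec <- data.frame(time = rexp(100), event = rbinom(100, 1, 0.8),
                      arm = rep(c("control", "test"), each = 50))
    if (sum(rec$event) == 0) next
    p <- cox_binary(rec)$score_p
    if (p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  ci_half <- 2.58 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rate, 0.05 - ci_half)
  expect_lt(rate, 0.05 + ci_half)
})
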