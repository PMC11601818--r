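test_that("the earliest qualifying visit defines the event", {
  # MoCA 25, 23, 20 at months 0, 6, 12 -> event at 12 via MoCA < 21
  v <- toyVisits(c(0, 6, 12), moca = c(25, 23, 20))
  ev <- detectMilestones(v)
  expect_equal(ev$time, 12)
  expect_true(ev$event)
  expect_equal(ev$first_milestone_type, "moca_lt_cutoff")
  expect_false(ev$baseline_event)

  # nothing ever crosses a cutoff -> censored at the last visit
  calm <- toyVisits(c(0, 6, 12, 18), moca = 25, i11 = 2, i12 = 1)
  cens <- detectMilestones(calm)
  expect_false(cens$event)
  expect_equal(cens$time, 18)
  expect_equal(cens$first_milestone_type, "none")

  # hallucinations at 6 beat a later MoCA event at 12 (earliest wins);
  # verified against an exhaustive scan over the visit rows
  v2 <- toyVisits(c(0, 6, 12), moca = c(25, 24, 19), i12 = c(0, 3, 3))
  ev2 <- detectMilestones(v2)
  crit <- function(r) r["moca"] < 21 || r["updrs_1_1"] >= 3 ||
    r["updrs_1_2"] >= 3 || r["updrs_1_5"] >= 3
  firstHit <- min(which(apply(v2[, c("moca", "updrs_1_1", "updrs_1_2",
                                     "updrs_1_5")], 1, crit)))
  expect_equal(ev2$time, v2$visit_month[firstHit])
  expect_equal(ev2$time, 6)
  expect_equal(ev2$first_milestone_type, "hallucinations")

  # baseline events are kept at time 0 and flagged
  base <- detectMilestones(toyVisits(c(0, 6), moca = c(19, 25)))
  expect_equal(base$time, 0)
  expect_true(base$baseline_event)

  expect_error(detectMilestones(toyVisits(numeric(0))), "empty")
  expect_error(detectMilestones(toyVisits(c(0, 12, 6))),
               "strictly increasing")
})

test_that("milestone detection is monotone in the cutoffs", {
  set.seed(31)
  for (r in 1:25) {
    v <- toyVisits(seq(0, 36, 6),
                   moca = sample(18:28, 7, replace = TRUE),
                   i11 = sample(0:4, 7, replace = TRUE),
                   i12 = sample(0:4, 7, replace = TRUE),
                   i15 = sample(0:4, 7, replace = TRUE))
    tight <- detectMilestones(v, milestoneCriteria())
    loose <- detectMilestones(v, milestoneCriteria(
      moca_cutoff = 24, updrs_1_1_cutoff = 2, updrs_1_2_cutoff = 2,
      updrs_1_5_cutoff = 2))
    if (tight$event) {
      expect_true(loose$event)
      expect_lte(loose$time, tight$time)
    }
  }
})

test_that("the cohort-level event builder agrees with per-subject detection", {
  sim <- generatePDMCICohort(simulationConfig(seed = 15, nPD = 60L))
  ev <- buildMilestoneEvents(sim$visits)
  for (id in sample(unique(sim$visits$subject_id), 10)) {
    one <- detectMilestones(
      sim$visits[sim$visits$subject_id == id, , drop = FALSE])
    row <- ev[ev$subject_id == id, ]
    expect_equal(row$time, one$time)
    expect_equal(row$event, one$event)
    expect_equal(row$first_milestone_type, one$first_milestone_type)
  }
})

test_that("Kaplan-Meier matches the product-limit definition", {
  # no censoring: empirical survival, S(t) = 2/3 on [1, 2)
  km <- kmEstimate(data.frame(time = c(1, 2, 3), event = TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring before the first event leaves S at 1 until that event
  km2 <- kmEstimate(data.frame(time = c(5, 7), event = c(FALSE, TRUE)))
  expect_equal(km2$surv[km2$time == 7], 0)
  expect_true(all(km2$surv[km2$time < 7] == 1))
  # mixed toy: events 2, 4; censored 3 -> S(4) = (1 - 1/3)(1 - 1/1) = 0
  km3 <- kmEstimate(data.frame(time = c(2, 3, 4),
                               event = c(TRUE, FALSE, TRUE)))
  expect_equal(km3$surv[km3$time == 2], 2 / 3)
  expect_equal(km3$surv[km3$time == 4], 0)
  # hand product-limit oracle on a random set
  set.seed(8)
  ev <- data.frame(time = sample(1:20, 30, replace = TRUE),
                   event = runif(30) < 0.7)
  km4 <- kmEstimate(ev)
  orc <- kmOracle(ev$time, ev$event)
  got <- km4[km4$n_event > 0, c("time", "surv")]
  expect_equal(got$surv, orc$surv, tolerance = 1e-12)
  # invariants: S starts at 1 and never increases; at-risk decreasing
  expect_true(all(diff(km4$surv) <= 0))
  expect_true(all(km4$surv <= 1))
  expect_true(all(diff(km4$n_risk) < 0))
  expect_error(kmEstimate(data.frame(time = -1, event = TRUE)), "negative")
})

test_that("log-rank test matches a brute-force O-E tabulation", {
  # identical event lists in both groups -> chi2 = 0, p = 1
  same <- data.frame(time = rep(c(3, 6, 9), 2), event = TRUE,
                     group = rep(c("a", "b"), each = 3))
  lr0 <- logrankTest(same)
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # tiny instances against the hand-coded O-E/V oracle
  set.seed(17)
  for (r in 1:10) {
    ev <- data.frame(time = sample(1:8, 6, replace = TRUE),
                     event = runif(6) < 0.8,
                     group = rep(c("a", "b"), 3))
    if (sum(ev$event) < 2) next
    got <- logrankTest(ev)
    orc <- logrankOE(ev$time, ev$event, ev$group)
    expect_equal(got$chi2, orc$chi2, tolerance = 1e-8)
    expect_equal(got$p_value, orc$p, tolerance = 1e-8)
  }
  expect_error(logrankTest(data.frame(time = 1, event = TRUE,
                                      group = "a")), "two non-empty")
})

test_that("log-rank keeps its nominal size under the null", {
  # a clean null also zeroes the clinical shifts: a shifted MoCA would
  # otherwise reach the hazard through the b_moca pathway
  sv0 <- c(lambda0 = 0.008, logHR_low = 0, b_age = 0.02, b_sex = 0.1,
           b_moca = -0.15, visit_interval = 6, max_followup = 96,
           dropout_rate = 0.002)
  sh0 <- c(updrs1 = 0, updrs2 = 0, updrs3 = 0, scopa_aut = 0, rbdsq = 0,
           upsit = 0, moca = 0)
  rej <- vapply(1:1000, function(r) {
    sim <- generatePDMCICohort(simulationConfig(seed = 60000 + r,
                                                survivalTruth = sv0,
                                                clinicalShifts = sh0,
                                                gmdShiftLow = 0))
    ev <- buildMilestoneEvents(sim$visits)
    ev <- merge(ev, sim$truth$subjects[c("subject_id", "latent_low_ch4")],
                by = "subject_id")
    ev$group <- ev$latent_low_ch4
    logrankTest(ev)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("Cox fit matches grid-search partial-likelihood maximization", {
  # 4 subjects, one binary covariate, no ties, finite MLE
  time <- c(1, 2, 3, 4)
  event <- c(TRUE, TRUE, TRUE, TRUE)
  x <- c(1, 0, 1, 0)
  ev <- data.frame(subject_id = letters[1:4], time = time, event = event)
  cv <- data.frame(subject_id = letters[1:4], x = x)
  fit <- coxMilestones(ev, cv, formula_rhs = "x")
  beta <- coxGridSearch(time, event, x)
  expect_equal(fit$coefficients$coef, beta, tolerance = 1e-3)

  # a second toy with censoring
  time2 <- c(2, 3, 5, 7, 8, 9)
  event2 <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  x2 <- c(1, 1, 0, 1, 0, 0)
  ev2 <- data.frame(subject_id = letters[1:6], time = time2, event = event2)
  cv2 <- data.frame(subject_id = letters[1:6], x = x2)
  fit2 <- coxMilestones(ev2, cv2, formula_rhs = "x")
  expect_equal(fit2$coefficients$coef, coxGridSearch(time2, event2, x2),
               tolerance = 1e-3)

  # degenerate design: constant covariate is unidentifiable
  cvConst <- data.frame(subject_id = letters[1:4], x = 1)
  expect_error(coxMilestones(ev, cvConst, formula_rhs = "x"),
               "unidentifiable")
})

test_that("Cox estimates rescale exactly under affine covariate changes", {
  sim <- generatePDMCICohort(simulationConfig(seed = 77, nPD = 300L))
  ev <- buildMilestoneEvents(sim$visits)
  cv <- merge(sim$cohort[c("subject_id", "age", "sex", "moca")],
              sim$truth$subjects[c("subject_id", "latent_low_ch4")],
              by = "subject_id")
  names(cv)[names(cv) == "latent_low_ch4"] <- "low_ch4"
  f1 <- coxMilestones(ev, cv)
  cv10 <- cv; cv10$age <- cv10$age / 10 + 100
  f2 <- coxMilestones(ev, cv10)
  c1 <- f1$coefficients; c2 <- f2$coefficients
  expect_equal(c2$coef[c2$term == "age"], 10 * c1$coef[c1$term == "age"],
               tolerance = 1e-6)
  expect_equal(c2$coef[c2$term == "low_ch4"],
               c1$coef[c1$term == "low_ch4"], tolerance = 1e-6)
  expect_true(all(c1$ci_low <= c1$hr & c1$hr <= c1$ci_high))
  # Breslow tie handling is available and close on this grid
  fb <- coxMilestones(ev, cv, ties = "breslow")
  expect_equal(fb$ties, "breslow")
})
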