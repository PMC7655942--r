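# small incident analysis_set built directly (bypasses the preprocessing
# pipeline) for matching and evaluation unit tests
make_incident_set <- function(n, seed = 1, n_lipids = 4, beta = NULL) {
  withr::with_seed(seed, {
    age <- runif(n, 65, 85)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    sp <- matrix(rnorm(n * n_lipids), n,
                 dimnames = list(NULL, paste0("L", seq_len(n_lipids))))
    lp <- if (is.null(beta)) rep(0, n) else drop(sp %*% beta)
    t_ev <- rexp(n, 0.05 * exp(lp))
    cens <- runif(n, 2, 8)
    event <- t_ev <= cens
    fu <- pmin(t_ev, cens)
    cov <- data.frame(age = age, sex = factor(sex), bmi = rnorm(n, 26, 4),
                      total_cholesterol = rnorm(n, 5, 1),
                      hdl_c = rnorm(n, 1.5, 0.4),
                      triglycerides = rlnorm(n, 0.3, 0.4),
                      apoe4_count = sample(0:2, n, TRUE, c(.6, .3, .1)),
                      statin = FALSE, omega3 = FALSE)
    structure(list(role = "incident", species = sp,
                   classes = sp[, 1, drop = FALSE],
                   covariates = cov,
                   outcome = data.frame(entry_age = age,
                                        exit_age = age + fu, event = event,
                                        followup_years = fu, mci = FALSE),
                   participant_id = paste0("P", seq_len(n)),
                   sample_id = paste0("S", seq_len(n))),
              class = "analysis_set")
  })
}

make_prevalent_set <- function(n, seed = 1, n_lipids = 4, beta = NULL) {
  withr::with_seed(seed, {
    sp <- matrix(rnorm(n * n_lipids), n,
                 dimnames = list(NULL, paste0("L", seq_len(n_lipids))))
    lp <- -0.8 + if (is.null(beta)) rep(0, n) else drop(sp %*% beta)
    ad <- runif(n) < plogis(lp)
    cov <- data.frame(age = runif(n, 65, 85),
                      sex = factor(sample(c("F", "M"), n, TRUE)),
                      bmi = rnorm(n, 26, 4),
                      total_cholesterol = rnorm(n, 5, 1),
                      hdl_c = rnorm(n, 1.5, 0.4),
                      triglycerides = rlnorm(n, 0.3, 0.4),
                      apoe4_count = sample(0:2, n, TRUE, c(.6, .3, .1)),
                      statin = FALSE, omega3 = FALSE)
    structure(list(role = "prevalent", species = sp,
                   classes = sp[, 1, drop = FALSE], covariates = cov,
                   outcome = data.frame(ad = ad),
                   participant_id = paste0("P", seq_len(n)),
                   sample_id = paste0("S", seq_len(n))),
              class = "analysis_set")
  })
}

test_that("age-sex matching selects the nearest same-sex controls", {
  set <- make_incident_set(60, seed = 11)
  # force a clean scenario: 3 cases with exact-age duplicate controls
  set$outcome$event[] <- FALSE
  cases <- 1:3
  set$outcome$event[cases] <- TRUE
  set$covariates$sex[] <- "F"
  set$covariates$sex <- factor(set$covariates$sex)
  set$covariates$age[cases] <- c(70, 75, 80)
  set$covariates$age[4:9] <- c(70, 70, 75, 75, 80, 80)
  set$covariates$age[10:60] <- 60  # far away
  m <- match_discovery_subset(set, ratio = 2)
  expect_equal(nrow(m$species), 9)
  expect_setequal(m$participant_id[m$outcome$event], paste0("P", 1:3))
  expect_setequal(sort(m$covariates$age[!m$outcome$event]),
                  c(70, 70, 75, 75, 80, 80))
})

test_that("matching matches a brute-force greedy oracle and errors on shortfall", {
  set <- make_incident_set(40, seed = 5)
  set$outcome$event[] <- FALSE
  set$outcome$event[1:3] <- TRUE
  m <- match_discovery_subset(set, ratio = 2)
  expect_equal(nrow(m$species), 9)  # ratio 2, 3 cases -> 3 + 6 rows

  # oracle: same greedy rule written independently
  age <- set$covariates$age; sex <- as.character(set$covariates$sex)
  cases <- which(set$outcome$event)
  avail <- setdiff(seq_len(40), cases)
  picked <- integer(0)
  for (i in cases[order(-age[cases])]) {
    pool <- avail[sex[avail] == sex[i]]
    sel <- pool[order(abs(age[pool] - age[i]))][1:2]
    picked <- c(picked, sel)
    avail <- setdiff(avail, sel)
  }
  expect_setequal(m$participant_id,
                  paste0("P", sort(c(cases, picked))))

  # insufficient same-sex pool
  small <- make_incident_set(10, seed = 6)
  small$outcome$event[] <- FALSE
  small$outcome$event[1:4] <- TRUE
  small$covariates$sex[] <- "M"
  small$covariates$sex <- factor(small$covariates$sex)
  small$covariates$sex[5:10] <- "M"
  small$outcome$event[5:8] <- TRUE   # 8 cases, 2 controls
  expect_error(match_discovery_subset(small, ratio = 2), "shortfall")
})

test_that("stepwise selection honours max_k and finds a dominant signal", {
  set <- make_prevalent_set(500, seed = 31, n_lipids = 21,
                            beta = c(1, rep(0, 20)))
  # max_k = 0: no selection, all frequencies zero
  r0 <- cv_stepwise_select(set, max_k = 0, n_folds = 5, n_repeats = 1)
  expect_true(all(r0$frequencies == 0))
  expect_equal(r0$n_fits, 5)

  r <- cv_stepwise_select(set, max_k = 3, n_folds = 10, n_repeats = 1,
                          seed = 2)
  expect_equal(unname(r$frequencies["L1"]), 10)  # planted lipid in every fit
  expect_equal(unname(r$selection_order["L1"]), 1)  # always entered first
})

test_that("AIC stopping selects fewer than max_k under the null", {
  mean_selected <- vapply(1:10, function(s) {
    set <- make_prevalent_set(200, seed = 700 + s, n_lipids = 10)
    r <- cv_stepwise_select(set, max_k = 5, n_folds = 5, n_repeats = 1,
                            seed = s)
    sum(r$frequencies) / r$n_fits
  }, numeric(1))
  expect_lt(mean(mean_selected), 5)
})

test_that("feature finalisation pools split incorporations by cluster", {
  # two perfectly correlated planted lipids split their incorporations
  labels <- c(L1 = 1L, L2 = 1L, L3 = 0L, L4 = 0L)
  asg <- structure(list(labels = labels, n_clusters = 1L, params = list()),
                   class = "cluster_assignment")
  stepwise <- list(frequencies = c(L1 = 6, L2 = 4, L3 = 3, L4 = 0),
                   selection_order = c(L1 = 1, L2 = 1, L3 = 2, L4 = NA),
                   n_fits = 10, max_k = 2, n_folds = 10, n_repeats = 1,
                   seed = 1)
  sel <- finalize_features(stepwise, asg, max_k = 2)
  expect_s3_class(sel, "selection_result")
  # one representative for the correlated pair (frequency 10), not two
  expect_equal(sel$features, c("L1", "L3"))
  expect_equal(sel$ranking$total_frequency[1], 10)

  # zero frequencies -> empty feature list
  stepwise0 <- stepwise
  stepwise0$frequencies[] <- 0
  expect_message(sel0 <- finalize_features(stepwise0, asg, max_k = 2),
                 "0 cluster")
  expect_length(sel0$features, 0)

  # 12 nonzero singleton clusters, cap 10 -> top 10 by frequency
  lab12 <- setNames(rep(0L, 12), paste0("M", 1:12))
  asg12 <- structure(list(labels = lab12, n_clusters = 0L, params = list()),
                     class = "cluster_assignment")
  st12 <- list(frequencies = setNames(12:1, paste0("M", 1:12)),
               selection_order = setNames(rep(1, 12), paste0("M", 1:12)),
               n_fits = 10, max_k = 10, n_folds = 10, n_repeats = 1,
               seed = 1)
  sel12 <- finalize_features(st12, asg12, max_k = 10)
  expect_length(sel12$features, 10)
  expect_equal(sel12$features, paste0("M", 1:10))
})

test_that("binary concordance equals brute-force pair counting", {
  expect_equal(c_statistic(c(0.1, 0.4, 0.35, 0.8),
                           outcome = c(FALSE, FALSE, TRUE, TRUE)), 0.75)
  # perfect separation and pure ties
  expect_equal(c_statistic(c(1, 2, 3, 4), outcome = c(F, F, T, T)), 1)
  expect_equal(c_statistic(rep(1, 6), outcome = rep(c(TRUE, FALSE), 3)), 0.5)
  set.seed(8)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    s <- round(rnorm(n), 1)  # coarse scores force ties
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) next
    expect_equal(c_statistic(s, outcome = y), oracle_auc(s, y))
    # monotone transform invariance
    expect_equal(c_statistic(exp(s), outcome = y),
                 c_statistic(s, outcome = y))
  }
})

test_that("binary concordance agrees with an independent AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  s <- rnorm(80); y <- runif(80) < 0.4
  expect_equal(c_statistic(s, outcome = y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("survival concordance matches oracles under truncation and ties", {
  set.seed(19)
  for (i in 1:5) {
    n <- 60
    s <- round(rnorm(n), 1)
    time <- round(rexp(n, 0.3), 2) + 0.01
    event <- runif(n) < 0.6
    expect_equal(c_statistic(s, time = time, event = event),
                 oracle_harrell(s, time, event))
    entry <- runif(n, 0, 0.3)
    time2 <- entry + time
    expect_equal(c_statistic(s, time = time2, event = event, entry = entry),
                 oracle_harrell(s, time2, event, entry))
  }
  # cross-check against survival::concordance (no truncation, no tied times)
  n <- 100
  s <- rnorm(n); time <- rexp(n) + 0.01; event <- runif(n) < 0.5
  ours <- c_statistic(s, time = time, event = event)
  ref <- survival::concordance(survival::Surv(time, event) ~ s,
                               reverse = TRUE)$concordance
  expect_equal(ours, unname(ref), tolerance = 1e-10)

  expect_error(c_statistic(c(1, 2), time = c(1, 2),
                           event = c(FALSE, FALSE)), "comparable")
})

test_that("category-free NRI satisfies its identities", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  # no change
  expect_equal(unname(nri_continuous(1:4, 1:4, y)), c(0, 0, 0))
  # events up, nonevents down -> (2, 1, 1)
  expect_equal(unname(nri_continuous(c(1, 1, 1, 1), c(2, 2, 0, 0), y)),
               c(2, 1, 1))
  # events one up one down, nonevents both down -> (1, 0, 1)
  expect_equal(unname(nri_continuous(c(1, 1, 1, 1), c(2, 0, 0, 0), y)),
               c(1, 0, 1))
  set.seed(33)
  for (i in 1:10) {
    n <- 40
    b <- rnorm(n); nw <- b + round(rnorm(n), 1); yy <- runif(n) < 0.5
    if (!any(yy) || all(yy)) next
    r <- nri_continuous(b, nw, yy)
    expect_equal(unname(r), unname(oracle_nri(b, nw, yy)))
    expect_equal(r[["total"]], r[["event"]] + r[["nonevent"]])
    # swapping labels swaps and negates the components
    r2 <- nri_continuous(b, nw, !yy)
    expect_equal(r2[["event"]], -r[["nonevent"]])
    expect_equal(r2[["nonevent"]], -r[["event"]])
  }
})

test_that("replication evaluation reports percentile CIs over repeats", {
  set <- make_prevalent_set(300, seed = 41, n_lipids = 6,
                            beta = c(0.8, 0.8, 0, 0, 0, 0))
  ev <- replicate_evaluate(set, c("L1", "L2"), n_folds = 5, n_repeats = 20,
                           seed = 9)
  expect_s3_class(ev, "model_evaluation")
  expect_gte(ev$c_full$estimate, ev$c_base$estimate)
  expect_true(ev$c_full$ci[1] <= ev$c_full$estimate &&
                ev$c_full$estimate <= ev$c_full$ci[2])
  # single repeat: CI collapses to the estimate
  ev1 <- replicate_evaluate(set, c("L1", "L2"), n_folds = 5, n_repeats = 1,
                            seed = 9)
  expect_equal(unname(ev1$c_full$ci), rep(ev1$c_full$estimate, 2))
  # deterministic under a fixed seed
  ev2 <- replicate_evaluate(set, c("L1", "L2"), n_folds = 5, n_repeats = 20,
                            seed = 9)
  expect_identical(ev$per_repeat, ev2$per_repeat)

  expect_error(replicate_evaluate(set, c("L1", "NOPE")), "NOPE")
})

test_that("cox replication evaluation runs and respects signal direction", {
  set <- make_incident_set(250, seed = 51, n_lipids = 5,
                           beta = c(0.7, 0, 0, 0, 0))
  ev <- replicate_evaluate(set, "L1", n_folds = 5, n_repeats = 10, seed = 3)
  expect_gt(ev$c_full$estimate, ev$c_base$estimate)
  expect_true(all(ev$per_repeat$c_full >= 0 & ev$per_repeat$c_full <= 1))
})
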