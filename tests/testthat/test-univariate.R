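test_that("logistic fit recovers the closed-form 2x2 log odds ratio", {
  # balanced null: symmetric table -> beta 0
  y <- rep(c(1, 0), each = 10)
  x <- rep(c(0, 1, 0, 1), each = 5)
  r0 <- fit_logistic(y, x)
  expect_equal(r0$beta, 0, tolerance = 1e-8)

  # counts (x=1,y=1)=20, (x=1,y=0)=10, (x=0,y=1)=10, (x=0,y=0)=20
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  x <- c(rep(1, 30), rep(0, 30))
  r <- fit_logistic(y, x)
  expect_equal(r$beta, log(4), tolerance = 1e-6)
  expect_equal(r$se, sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20),
               tolerance = 1e-6)
  expect_equal(r$n_cases, 30)
  expect_equal(r$n_total, 60)
})

test_that("logistic fit flags separation and rejects rank deficiency", {
  y <- c(rep(0, 10), rep(1, 10))
  x <- c(rnorm(10, -3), rnorm(10, 3))
  r <- fit_logistic(y, x)
  expect_equal(r$flag, "separated")
  expect_true(is.na(r$p))

  cov <- data.frame(a = rnorm(20))
  cov$b <- 2 * cov$a
  expect_error(fit_logistic(y, rnorm(20), cov), "collinear.*b")
  expect_error(fit_logistic(rep(1, 20), rnorm(20)), "both classes")
})

test_that("cox fit maximises the written partial likelihood", {
  # independent oracle: grid-search maximisation of the partial likelihood
  # for 3 subjects, x = (0,1,0), event ages (1,2,3), all events
  pl <- function(b) {
    # risk sets {1,2,3}, {2,3}, {3}; events in that order
    log(1 / (2 + exp(b))) + log(exp(b) / (exp(b) + 1)) + 0
  }
  grid <- seq(-2, 2, by = 1e-4)
  b_star <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_equal(b_star, log(sqrt(2)), tolerance = 1e-3)

  r <- fit_cox(entry_age = c(0, 0, 0), exit_age = c(1, 2, 3),
               event = c(TRUE, TRUE, TRUE), lipid = c(0, 1, 0))
  expect_equal(r$beta, b_star, tolerance = 1e-3)
  expect_equal(r$model, "cox")

  expect_error(fit_cox(c(0, 0, 0), c(1, 2, 3), c(TRUE, TRUE, TRUE),
                       lipid = c(1, 1, 1)), "zero variance")
  expect_error(fit_cox(c(2, 0), c(1, 3), c(TRUE, TRUE), c(0, 1)),
               "exit_age")
})

test_that("cox fit respects left truncation on the age scale", {
  # delayed entry changes risk sets; survival::coxph is the implementation,
  # so check against a hand-written partial likelihood with truncation
  entry <- c(0, 0, 2.5)
  exit <- c(2, 3, 4)
  event <- c(TRUE, TRUE, TRUE)
  x <- c(1, 0, 1)
  # risk sets: t=2 -> {1,2} (3 enters at 2.5); t=3 -> {2,3}; t=4 -> {3}
  pl <- function(b) {
    log(exp(b) / (exp(b) + 1)) + log(1 / (1 + exp(b)))
  }
  grid <- seq(-3, 3, by = 1e-4)
  b_star <- grid[which.max(vapply(grid, pl, numeric(1)))]
  r <- fit_cox(entry, exit, event, x)
  expect_equal(r$beta, b_star, tolerance = 1e-3)
})

test_that("effect scale: rescaling the lipid rescales beta exactly", {
  set.seed(21)
  n <- 300
  x <- rnorm(n)
  cov <- data.frame(a = rnorm(n))
  y <- rbinom(n, 1, plogis(0.3 * x + 0.2 * cov$a))
  r1 <- fit_logistic(y, x, cov)
  r2 <- fit_logistic(y, x / 2, cov)
  expect_equal(r2$beta, 2 * r1$beta, tolerance = 1e-6)
  expect_equal(r2$p, r1$p, tolerance = 1e-8)

  entry <- rep(0, n); exit <- rexp(n) + 0.01
  ev <- rbinom(n, 1, 0.5) == 1
  ev[1:2] <- TRUE
  r3 <- fit_cox(entry, exit, ev, x, cov)
  r4 <- fit_cox(entry, exit, ev, x * 4, cov)
  expect_equal(r4$beta, r3$beta / 4, tolerance = 1e-6)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(1)
  for (i in 1:10) {
    p <- runif(25)^2
    expect_equal(bh_fdr(p), oracle_bh(p))
    m <- length(p) + sample(0:10, 1)
    expect_equal(bh_fdr(p, m), oracle_bh(p, m))
    # monotone in input ranks
    q <- bh_fdr(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(bh_fdr(runif(5), family_size = 3), "family_size")
})

test_that("summary-statistic ANOVA reproduces published group comparisons", {
  # equal means -> F = 0, p = 1
  r0 <- two_group_anova_summary(10, 5, 1, 12, 5, 2)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)

  # cohort age comparison: (696, 75.27, 6.53) vs (268, 81.40, 7.91)
  r_age <- two_group_anova_summary(696, 75.27, 6.53, 268, 81.40, 7.91)
  expect_lt(abs(log10(r_age$p) - log10(2.96e-32)), 0.15)
  # triglycerides: (696, 1.26, 0.63) vs (268, 1.50, 0.78)
  r_tg <- two_group_anova_summary(696, 1.26, 0.63, 268, 1.50, 0.78)
  expect_lt(abs(log10(r_tg$p) - log10(9.42e-7)), 0.15)

  # F equals the squared pooled two-sample t statistic
  t2 <- function(n1, m1, s1, n2, m2, s2) {
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    ((m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2)))^2
  }
  expect_equal(r_age$F, t2(696, 75.27, 6.53, 268, 81.40, 7.91))

  # degenerate: zero pooled variance, unequal means
  rd <- two_group_anova_summary(5, 1, 0, 5, 2, 0)
  expect_true(rd$degenerate)
  expect_equal(rd$p, 0)
})

test_that("chi-square test reproduces published allele-count tables", {
  # proportional rows -> chi2 = 0
  r0 <- chisq_independence(rbind(c(10, 20), c(20, 40)))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # 3x2 allele tables
  r1 <- chisq_independence(rbind(c(523, 99), c(163, 131), c(10, 38)))
  expect_equal(r1$df, 2)
  expect_equal(r1$p, 7.31e-33, tolerance = 0.01)
  r2 <- chisq_independence(rbind(c(257, 58), c(118, 83), c(22, 25)))
  expect_equal(r2$p, 1.91e-10, tolerance = 0.01)

  # df = 2: p = exp(-chi2/2) exactly
  expect_equal(r1$p, exp(-r1$chi2 / 2))
  # invariant to row/column permutation
  m <- rbind(c(5, 9), c(11, 3), c(7, 7))
  r <- chisq_independence(m)
  expect_equal(chisq_independence(m[c(3, 1, 2), c(2, 1)])$chi2, r$chi2)

  expect_error(chisq_independence(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("panel scan applies per-family FDR and survives flagged fits", {
  panel <- default_panel(2, 6)
  cfg <- sim_config(n_participants = 150, panel = panel, seed = 8,
                    beta_prevalent = planted_effects(panel, 1, 1.2))
  co <- generate_cohort(cfg)
  set <- select_prevalent(co, panel)
  res <- scan_panel(set, panel)
  expect_equal(nrow(res), 12 + 2)
  expect_setequal(unique(res$family), c("species", "class"))
  # q within each family equals bh_fdr of that family's p-values
  for (fam in c("species", "class")) {
    sub <- res[res$family == fam & !is.na(res$p), ]
    expect_equal(sub$q, bh_fdr(sub$p))
  }
  expect_true(all(res$q >= res$p - 1e-12, na.rm = TRUE))
  # class column annotated from the registry
  expect_equal(res$class[res$lipid == panel$species$species_name[1]],
               panel$species$class_code[1])
  # single-species family: q = p
  one <- res[res$family == "class", ]
  expect_equal(one$q, bh_fdr(one$p))
})
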