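# Per-lipid association models (logistic for prevalent disease, Cox with
# age as timescale for incident disease), BH FDR control, and the
# summary-statistic group-comparison tests used for cohort tables.

# expand a covariate data.frame to a numeric design matrix (no intercept
# column; factors become indicator columns)
.design_matrix <- function(covariates, n_rows = NULL) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(matrix(numeric(0),
                  nrow = if (!is.null(n_rows)) n_rows
                         else if (is.null(covariates)) 0
                         else nrow(covariates),
                  ncol = 0))
  df <- as.data.frame(covariates)
  mm <- stats::model.matrix(~., data = df)
  mm[, -1, drop = FALSE]
}

.check_full_rank <- function(X, context) {
  if (ncol(X) == 0) return(invisible())
  q <- qr(cbind(1, X))
  if (q$rank < ncol(X) + 1) {
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)) + 1L,
                                   q$pivot[seq_len(q$rank)]) - 1L]
    stop(sprintf("rank-deficient design in %s; collinear column(s): %s",
                 context, paste(dropped, collapse = ", ")))
  }
  invisible()
}

.assoc_row <- function(lipid_id, model, beta, se, p, n_cases, n_total,
                       flag = "") {
  data.frame(lipid = lipid_id, model = model, beta = unname(beta),
             se = unname(se), p = unname(p), q = NA_real_,
             n_cases = n_cases, n_total = n_total,
             flag = flag, stringsAsFactors = FALSE, row.names = NULL)
}

#' Logistic association of one lipid with prevalent disease
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' standardized lipid plus covariates; the reported effect is the lipid
#' coefficient (log odds ratio per SD of log10 concentration) with its Wald
#' standard error and two-sided p-value.
#'
#' Complete or quasi-complete separation is flagged (\code{flag =
#' "separated"}, \code{p = NA}) rather than reported as a spuriously extreme
#' effect; flagged lipids are excluded from the FDR family by
#' [scan_panel()].
#'
#' @param outcome Logical/0-1 vector (both classes must be present).
#' @param lipid Numeric vector (standardized log10 concentration).
#' @param covariates Optional data.frame of adjustment covariates.
#' @param lipid_id Label for the output row.
#' @return One-row data.frame: \code{lipid}, \code{model}, \code{beta},
#'   \code{se}, \code{p}, \code{q} (NA until FDR adjustment),
#'   \code{n_cases}, \code{n_total}, \code{flag}.
#' @export
fit_logistic <- function(outcome, lipid, covariates = NULL,
                         lipid_id = "lipid") {
  y <- as.integer(as.logical(outcome))
  stopifnot(length(y) == length(lipid))
  if (length(unique(y)) < 2)
    stop("outcome must contain both classes")
  X <- .design_matrix(covariates, n_rows = length(y))
  if (ncol(X) && nrow(X) != length(y))
    stop("covariates and outcome lengths differ")
  full <- cbind(lipid = lipid, X)
  .check_full_rank(full, "logistic model")

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, full), y,
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- fit$coefficients
  # observed-information covariance
  se <- tryCatch({
    Xw <- cbind(1, full) * sqrt(fit$weights)
    sqrt(diag(chol2inv(chol(crossprod(Xw)))))
  }, error = function(e) rep(NA_real_, length(cf)))
  beta <- cf["lipid"]
  se_l <- se[2L]
  separated <- sep_warn && (abs(beta) > 10 || !is.finite(se_l) || se_l > 50)
  if (!fit$converged || separated || !is.finite(se_l)) {
    return(.assoc_row(lipid_id, "logistic",
                      beta = if (separated) sign(beta) * Inf else beta,
                      se = NA_real_, p = NA_real_,
                      n_cases = sum(y), n_total = length(y),
                      flag = if (separated) "separated" else "nonconverged"))
  }
  z <- beta / se_l
  .assoc_row(lipid_id, "logistic", beta = unname(beta), se = unname(se_l),
             p = 2 * stats::pnorm(-abs(z)),
             n_cases = sum(y), n_total = length(y))
}

#' Cox association of one lipid with incident disease (age as timescale)
#'
#' Partial-likelihood estimation with left truncation at the entry age and
#' Efron handling of tied event times; the reported effect is the lipid
#' log hazard ratio per SD of log10 concentration with Wald standard error
#' and two-sided p-value.  Age acts only as the timescale, not as a
#' covariate.
#'
#' @param entry_age,exit_age Numeric vectors (years); \code{exit_age} must
#'   exceed \code{entry_age} row-wise.
#' @param event Logical conversion indicator (at least 2 events required).
#' @param lipid Numeric vector (standardized; must not be constant).
#' @param covariates Optional data.frame of adjustment covariates.
#' @param lipid_id Label for the output row.
#' @return One-row data.frame as in [fit_logistic()] with
#'   \code{model = "cox"}.
#' @export
fit_cox <- function(entry_age, exit_age, event, lipid, covariates = NULL,
                    lipid_id = "lipid") {
  event <- as.logical(event)
  stopifnot(length(entry_age) == length(exit_age),
            length(event) == length(lipid),
            length(lipid) == length(entry_age))
  if (any(exit_age <= entry_age))
    stop("exit_age must exceed entry_age for every row")
  if (sum(event) < 2) stop("need at least 2 events")
  if (stats::sd(lipid) == 0)
    stop(sprintf("lipid '%s' has zero variance", lipid_id))
  X <- .design_matrix(covariates, n_rows = length(lipid))
  full <- cbind(lipid = lipid, X)
  .check_full_rank(full, "cox model")
  dat <- data.frame(full, check.names = FALSE)
  dat$.entry <- entry_age; dat$.exit <- exit_age; dat$.event <- event

  mono_warn <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.entry, .exit, .event) ~ . - .entry -
                      .exit - .event,
                    data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        mono_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)["lipid"]
  se_l <- sqrt(diag(stats::vcov(fit)))["lipid"]
  if (mono_warn || !is.finite(beta) || !is.finite(se_l) || se_l > 50) {
    return(.assoc_row(lipid_id, "cox",
                      beta = if (is.finite(beta)) beta else sign(beta) * Inf,
                      se = NA_real_, p = NA_real_,
                      n_cases = sum(event), n_total = length(event),
                      flag = "nonconverged"))
  }
  z <- beta / se_l
  .assoc_row(lipid_id, "cox", beta = unname(beta), se = unname(se_l),
             p = 2 * stats::pnorm(-abs(z)),
             n_cases = sum(event), n_total = length(event))
}

#' Benjamini-Hochberg FDR adjustment within a stated family
#'
#' Step-up adjustment \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j} capped at
#' 1, with the family size \code{m} allowed to exceed the number of supplied
#' p-values (tests flagged as non-converged shrink the vector but not
#' necessarily the family).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param family_size Family size \code{m}; defaults to
#'   \code{length(p_values)} and must be at least that.
#' @return Adjusted p-values, order-preserving.
#' @export
bh_fdr <- function(p_values, family_size = length(p_values)) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  if (family_size < length(p_values))
    stop("family_size must be at least length(p_values)")
  stats::p.adjust(p_values, method = "BH", n = family_size)
}

#' Two-group one-way ANOVA from summary statistics
#'
#' Pooled-variance one-way ANOVA with two groups reconstructed from each
#' group's size, mean and SD (the form used to compare cohort
#' characteristics when only summaries are published):
#' \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)},
#' \eqn{F = (\bar x_1 - \bar x_2)^2 / (s_p^2 (1/n_1 + 1/n_2))}, with
#' \eqn{p} from \eqn{F(1, n_1+n_2-2)}.  Equivalent to the squared pooled
#' two-sample t statistic.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 Group summaries (\code{n >= 2},
#'   \code{sd >= 0}).
#' @return List with \code{F}, \code{p}, \code{df2} and a
#'   \code{degenerate} flag (zero pooled variance with unequal means).
#' @examples
#' two_group_anova_summary(696, 75.27, 6.53, 268, 81.40, 7.91)$p
#' @export
two_group_anova_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df2 <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df2
  if (sp2 == 0) {
    if (mean1 != mean2)
      return(list(F = Inf, p = 0, df2 = df2, degenerate = TRUE))
    return(list(F = 0, p = 1, df2 = df2, degenerate = TRUE))
  }
  Fstat <- (mean1 - mean2)^2 / (sp2 * (1 / n1 + 1 / n2))
  list(F = Fstat, p = stats::pf(Fstat, 1, df2, lower.tail = FALSE),
       df2 = df2, degenerate = FALSE)
}

#' Pearson chi-square test of independence on an r x c count table
#'
#' Pearson chi-square without continuity correction, df = (r-1)(c-1),
#' upper-tail p (the form used for allele-count and categorical cohort
#' comparisons).
#'
#' @param counts Integer matrix of non-negative counts, at least 2 rows and
#'   2 columns, with strictly positive margins.
#' @return List with \code{chi2}, \code{df}, \code{p}.
#' @examples
#' chisq_independence(matrix(c(523, 99, 163, 131, 10, 38), 3, byrow = TRUE))
#' @export
chisq_independence <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2 x 2 table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Panel-wide per-lipid association scan
#'
#' Fits the analysis set's model family (logistic for prevalent, Cox with
#' age as timescale for incident) to every species column and every class
#' total, then applies BH FDR within the species family and the class
#' family separately.  Lipids whose fits are flagged (separation,
#' non-convergence) are reported with \code{p = NA} and reduce the FDR
#' family instead of aborting the scan.
#'
#' @param analysis_set An \code{"analysis_set"} from [select_prevalent()]
#'   or [select_incident()].
#' @param registry Optional \code{"panel_registry"}; adds a \code{class}
#'   column for species rows.
#' @param adjust_mci For incident sets: also adjust for the MCI indicator
#'   (sensitivity analysis).
#' @return data.frame with one row per species and per class total:
#'   \code{lipid}, \code{family} ("species"/"class"), \code{class},
#'   \code{model}, \code{beta}, \code{se}, \code{p}, \code{q},
#'   \code{n_cases}, \code{n_total}, \code{flag}.
#' @export
scan_panel <- function(analysis_set, registry = NULL, adjust_mci = FALSE) {
  set <- analysis_set
  stopifnot(inherits(set, "analysis_set"))
  cov <- set$covariates
  if (adjust_mci) {
    if (set$role != "incident")
      stop("adjust_mci applies to incident analysis sets only")
    cov <- cbind(cov, mci = set$outcome$mci)
  }
  fit_one <- function(x, id) {
    if (set$role == "prevalent")
      fit_logistic(set$outcome$ad, x, cov, lipid_id = id)
    else
      fit_cox(set$outcome$entry_age, set$outcome$exit_age,
              set$outcome$event, x, cov, lipid_id = id)
  }
  scan_family <- function(mat, family) {
    rows <- lapply(colnames(mat), function(id) {
      r <- tryCatch(fit_one(mat[, id], id),
                    error = function(e)
                      .assoc_row(id, if (set$role == "prevalent") "logistic"
                                 else "cox",
                                 NA_real_, NA_real_, NA_real_,
                                 NA_integer_, NA_integer_,
                                 flag = paste0("error: ",
                                               conditionMessage(e))))
      r$family <- family
      r
    })
    do.call(rbind, rows)
  }
  out <- rbind(scan_family(set$species, "species"),
               scan_family(set$classes, "class"))
  out$class <- NA_character_
  if (!is.null(registry)) {
    sp <- out$family == "species"
    out$class[sp] <- unname(registry$class_of[out$lipid[sp]])
  }
  out$class[out$family == "class"] <- out$lipid[out$family == "class"]
  for (fam in c("species", "class")) {
    sel <- out$family == fam & !is.na(out$p)
    if (sum(out$family == fam & is.na(out$p)))
      message(sum(out$family == fam & is.na(out$p)),
              " flagged fit(s) excluded from the ", fam, " FDR family")
    if (any(sel)) out$q[sel] <- bh_fdr(out$p[sel], family_size = sum(sel))
  }
  out[, c("lipid", "family", "class", "model", "beta", "se", "p", "q",
          "n_cases", "n_total", "flag")]
}
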