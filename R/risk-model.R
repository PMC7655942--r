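# Multivariate risk models: age-sex matching, cluster-aware cross-validated
# forward stepwise selection on a discovery cohort, and retrained
# cross-validated evaluation on a replication cohort (C-statistic and
# category-free NRI).

# row-subset of an analysis_set
.subset_set <- function(set, idx) {
  structure(list(role = set$role,
                 species = set$species[idx, , drop = FALSE],
                 classes = set$classes[idx, , drop = FALSE],
                 covariates = set$covariates[idx, , drop = FALSE],
                 outcome = set$outcome[idx, , drop = FALSE],
                 participant_id = set$participant_id[idx],
                 sample_id = set$sample_id[idx]),
            class = "analysis_set")
}

# base risk-model design: age, sex, BMI, APOE e4 count
.base_design <- function(set) {
  cov <- set$covariates
  cbind(age = cov$age,
        sexM = as.numeric(cov$sex == "M"),
        bmi = cov$bmi,
        apoe4 = cov$apoe4_count)
}

.risk_outcome <- function(set) {
  if (set$role == "prevalent") {
    list(family = "logistic", y = as.integer(set$outcome$ad),
         case = set$outcome$ad)
  } else {
    list(family = "cox",
         surv = survival::Surv(set$outcome$followup_years,
                               set$outcome$event),
         case = set$outcome$event)
  }
}

#' Age- and sex-matched discovery subset for incident models
#'
#' For cohorts where converters are few and much older than non-converters,
#' selects a \code{ratio}:1 matched subset: cases are processed in
#' descending age and each receives its \code{ratio} nearest-age
#' non-converters of the same sex, chosen greedily without replacement.
#'
#' @param set An incident \code{"analysis_set"}.
#' @param ratio Controls per case (default 2).
#' @return The matched \code{"analysis_set"} (cases plus matched controls).
#' @export
match_discovery_subset <- function(set, ratio = 2) {
  stopifnot(inherits(set, "analysis_set"), set$role == "incident")
  case <- which(set$outcome$event)
  ctrl <- which(!set$outcome$event)
  age <- set$covariates$age
  sex <- as.character(set$covariates$sex)
  for (s in unique(sex[case])) {
    need <- ratio * sum(sex[case] == s)
    have <- sum(sex[ctrl] == s)
    if (have < need)
      stop(sprintf(paste0("insufficient same-sex control pool for sex '%s':",
                          " need %d, have %d (shortfall %d)"),
                   s, need, have, need - have))
  }
  avail <- rep(TRUE, length(ctrl))
  picked <- integer(0)
  for (i in case[order(-age[case])]) {
    pool <- which(avail & sex[ctrl] == sex[i])
    sel <- pool[order(abs(age[ctrl[pool]] - age[i]))][seq_len(ratio)]
    avail[sel] <- FALSE
    picked <- c(picked, ctrl[sel])
  }
  .subset_set(set, sort(c(case, picked)))
}

# stratified folds: cases and controls split separately, as equally as
# possible; returns integer fold id per row
.stratified_folds <- function(case, n_folds) {
  fold <- integer(length(case))
  for (grp in list(which(case), which(!case))) {
    if (!length(grp)) next
    fold[grp[sample.int(length(grp))]] <-
      rep_len(seq_len(n_folds), length(grp))
  }
  fold
}

# AIC of a logistic or Cox fit on design X (no intercept column for cox);
# returns NA on non-convergence
.model_aic <- function(X, out) {
  if (out$family == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), out$y, family = stats::binomial()))
    if (!fit$converged) return(NA_real_)
    return(fit$aic)
  }
  fit <- tryCatch(
    survival::coxph.fit(X, out$surv, strata = NULL,
                        offset = rep(0, nrow(X)),
                        init = rep(0, ncol(X)),
                        control = survival::coxph.control(),
                        weights = rep(1, nrow(X)), method = "efron",
                        rownames = NULL),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients))) return(NA_real_)
  2 * ncol(X) - 2 * fit$loglik[2]
}

#' Cross-validated forward stepwise lipid selection
#'
#' Within each training portion of stratified \code{n_folds}-fold
#' cross-validation (repeated \code{n_repeats} times), lipids are added one
#' at a time to the fixed base covariates (age, sex, BMI, APOE
#' \eqn{\epsilon}4 count), at each step choosing the candidate giving the
#' largest decrease of the Akaike Information Criterion (partial-likelihood
#' AIC for Cox models), and stopping after \code{max_k} lipids or when no
#' candidate decreases the AIC.  The result is each lipid's incorporation
#' frequency: the number of training fits (out of
#' \code{n_folds * n_repeats}) that included it.
#'
#' @param set Discovery \code{"analysis_set"} (prevalent sets are modelled
#'   with logistic regression, incident sets with Cox regression on the
#'   follow-up time axis).
#' @param max_k Maximum lipids per model (10 for logistic diagnosis models,
#'   5 for Cox incidence models).
#' @param n_folds Folds (default 10).
#' @param n_repeats CV repeats (default 10, so frequencies are out of 100
#'   training fits).
#' @param seed Seed for the fold randomisation.
#' @return List: \code{frequencies} (named counts), \code{selection_order}
#'   (mean step at which each lipid entered, for tie-breaking; NA if never
#'   selected), \code{n_fits}, \code{max_k}, \code{n_folds},
#'   \code{n_repeats}, \code{seed}.
#' @export
cv_stepwise_select <- function(set, max_k, n_folds = 10, n_repeats = 10,
                               seed = 1L) {
  stopifnot(inherits(set, "analysis_set"), max_k >= 0)
  out <- .risk_outcome(set)
  Xb <- .base_design(set)
  sp <- set$species
  lipids <- colnames(sp)
  freq <- stats::setNames(numeric(length(lipids)), lipids)
  order_sum <- stats::setNames(numeric(length(lipids)), lipids)
  n_fits <- 0L
  n_skipped <- 0L

  withr::with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      fold <- .stratified_folds(out$case, n_folds)
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        out_tr <- if (out$family == "logistic")
          list(family = "logistic", y = out$y[tr])
        else list(family = "cox", surv = out$surv[tr, ])
        Xtr <- Xb[tr, , drop = FALSE]
        sptr <- sp[tr, , drop = FALSE]
        n_fits <- n_fits + 1L
        if (max_k == 0) next
        chosen <- character(0)
        current_aic <- .model_aic(Xtr, out_tr)
        candidates <- lipids
        while (length(chosen) < max_k && length(candidates)) {
          aics <- vapply(candidates, function(l) {
            .model_aic(cbind(Xtr, sptr[, c(chosen, l), drop = FALSE]),
                       out_tr)
          }, numeric(1))
          if (any(is.na(aics))) {
            n_skipped <- n_skipped + sum(is.na(aics))
            candidates <- candidates[!is.na(aics)]
            aics <- aics[!is.na(aics)]
            if (!length(candidates)) break
          }
          best <- which.min(aics)
          if (aics[best] >= current_aic) break
          current_aic <- aics[best]
          lip <- candidates[best]
          chosen <- c(chosen, lip)
          freq[lip] <- freq[lip] + 1
          order_sum[lip] <- order_sum[lip] + length(chosen)
          candidates <- candidates[-best]
        }
      }
    }
  })
  if (n_skipped)
    message(n_skipped, " non-converged candidate fit(s) skipped")
  sel_order <- ifelse(freq > 0, order_sum / pmax(freq, 1), NA_real_)
  list(frequencies = freq, selection_order = sel_order, n_fits = n_fits,
       max_k = max_k, n_folds = n_folds, n_repeats = n_repeats, seed = seed)
}

#' Finalise the cluster-aware feature list
#'
#' Applies [representative_ranking()] to the incorporation frequencies so
#' that correlated lipids, which split their incorporations across CV
#' training fits, are pooled at the cluster level; then keeps the top
#' \code{max_k} cluster representatives with positive pooled frequency.
#'
#' @param stepwise Result of [cv_stepwise_select()].
#' @param assignment A \code{"cluster_assignment"} for the same panel.
#' @param max_k Feature cap (10 logistic / 5 Cox).
#' @return Object of class \code{"selection_result"}: list with
#'   \code{features} (character), \code{ranking} (full cluster ranking),
#'   \code{frequencies}, \code{max_k}, \code{n_folds}, \code{n_repeats},
#'   \code{seed}.
#' @export
finalize_features <- function(stepwise, assignment, max_k) {
  ranking <- representative_ranking(stepwise$frequencies, assignment,
                                    aic_rank = stepwise$selection_order)
  features <- utils::head(ranking$representative, max_k)
  if (length(features) < max_k)
    message("only ", length(features),
            " cluster(s) with positive frequency (cap ", max_k, ")")
  structure(list(features = features, ranking = ranking,
                 frequencies = stepwise$frequencies, max_k = max_k,
                 n_folds = stepwise$n_folds,
                 n_repeats = stepwise$n_repeats, seed = stepwise$seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d feature(s) (cap %d):\n",
              length(x$features), x$max_k))
  for (f in x$features)
    cat(sprintf("  %-28s freq %g\n", f, x$frequencies[f]))
  invisible(x)
}

#' Concordance statistic (AUC / Harrell's C)
#'
#' Binary outcomes: the probability that a randomly chosen case outscores a
#' randomly chosen control, ties counted 1/2 (identical to the area under
#' the ROC curve).  Survival outcomes: Harrell's C over comparable pairs --
#' a pair is comparable when the earlier event time falls strictly inside
#' the other subject's at-risk interval (left truncation respected via
#' \code{entry}); the pair is concordant when the earlier event carries the
#' higher score, ties 1/2.
#'
#' @param scores Numeric risk scores (higher = riskier).
#' @param outcome Logical case indicator (binary mode); omit for survival.
#' @param time Event/censoring times (survival mode).
#' @param event Logical event indicator (survival mode).
#' @param entry Optional left-truncation entry times (survival mode;
#'   default 0).
#' @return Concordance in [0, 1].
#' @examples
#' c_statistic(c(0.1, 0.4, 0.35, 0.8), outcome = c(FALSE, FALSE, TRUE, TRUE))
#' @export
c_statistic <- function(scores, outcome = NULL, time = NULL, event = NULL,
                        entry = NULL) {
  if (!is.null(outcome)) {
    y <- as.logical(outcome)
    stopifnot(length(scores) == length(y))
    if (!any(y) || all(y)) stop("need at least 1 case and 1 control")
    d <- outer(scores[y], scores[!y], `-`)
    return((sum(d > 0) + 0.5 * sum(d == 0)) / length(d))
  }
  stopifnot(!is.null(time), !is.null(event),
            length(scores) == length(time), length(time) == length(event))
  event <- as.logical(event)
  if (is.null(entry)) entry <- rep(0, length(time))
  conc <- 0; comp <- 0
  ev <- which(event)
  for (i in ev) {
    # subjects still at risk when i fails, observed longer than t_i
    at_risk <- which(time > time[i] & entry < time[i])
    if (!length(at_risk)) next
    comp <- comp + length(at_risk)
    conc <- conc + sum(scores[i] > scores[at_risk]) +
      0.5 * sum(scores[i] == scores[at_risk])
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

#' Category-free Net Reclassification Index
#'
#' Continuous (category-free) NRI of a new risk score against a base score:
#' \code{event = P(new > base | event) - P(new < base | event)},
#' \code{nonevent = P(new < base | nonevent) - P(new > base | nonevent)},
#' \code{total = event + nonevent}; exact ties contribute zero.
#'
#' @param base_scores,new_scores Numeric vectors of equal length.
#' @param outcome Logical event indicator (at least one event and one
#'   nonevent).
#' @return Named numeric: \code{total}, \code{event}, \code{nonevent}.
#' @export
nri_continuous <- function(base_scores, new_scores, outcome) {
  y <- as.logical(outcome)
  stopifnot(length(base_scores) == length(new_scores),
            length(new_scores) == length(y))
  if (!any(y) || all(y)) stop("need at least 1 event and 1 nonevent")
  s <- sign(new_scores - base_scores)
  ev <- mean(s[y])
  ne <- -mean(s[!y])
  c(total = ev + ne, event = ev, nonevent = ne)
}

# fit base/full risk model on training rows, return linear predictors for
# test rows; NULL on failure
.fit_predict <- function(out, X_tr, X_te, surv_tr = NULL, y_tr = NULL) {
  if (out == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X_tr), y_tr, family = stats::binomial()))
    if (!fit$converged) return(NULL)
    return(drop(cbind(1, X_te) %*% fit$coefficients))
  }
  fit <- tryCatch(
    survival::coxph.fit(X_tr, surv_tr, strata = NULL,
                        offset = rep(0, nrow(X_tr)),
                        init = rep(0, ncol(X_tr)),
                        control = survival::coxph.control(),
                        weights = rep(1, nrow(X_tr)), method = "efron",
                        rownames = NULL),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients))) return(NULL)
  ctr <- colMeans(X_tr)
  drop(sweep(X_te, 2, ctr) %*% fit$coefficients)
}

#' Cross-validated replication of a selected lipid model
#'
#' Retrains both the base model (age, sex, BMI, APOE \eqn{\epsilon}4 count)
#' and the base+lipids model on the replication cohort within stratified
#' \code{n_folds}-fold cross-validation, re-randomised \code{n_repeats}
#' times.  Per repeat, out-of-fold linear predictors are pooled and the
#' C-statistic of both models and the category-free NRI (base vs
#' base+lipids) are computed; point estimates are means over repeats and
#' 95% intervals are 2.5/97.5 percentiles over repeats.
#'
#' @param set Replication \code{"analysis_set"}.
#' @param selection A \code{"selection_result"} (or character vector of
#'   feature names) from the discovery cohort.
#' @param n_folds Folds (default 10).
#' @param n_repeats Repeats (default 200).
#' @param seed Seed for the fold randomisation.
#' @return Object of class \code{"model_evaluation"}: list with
#'   \code{c_full}, \code{c_base}, \code{nri_total}, \code{nri_event},
#'   \code{nri_nonevent} (each \code{estimate} + \code{ci}),
#'   \code{per_repeat} (data.frame), \code{n_repeats}, \code{features}.
#' @export
replicate_evaluate <- function(set, selection, n_folds = 10,
                               n_repeats = 200, seed = 1L) {
  stopifnot(inherits(set, "analysis_set"))
  features <- if (inherits(selection, "selection_result"))
    selection$features else as.character(selection)
  missing_f <- setdiff(features, colnames(set$species))
  if (length(missing_f))
    stop("feature(s) missing from the replication panel: ",
         paste(missing_f, collapse = ", "))
  out <- .risk_outcome(set)
  Xb <- .base_design(set)
  Xf <- cbind(Xb, set$species[, features, drop = FALSE])
  n <- nrow(Xb)

  res <- matrix(NA_real_, n_repeats, 5,
                dimnames = list(NULL, c("c_base", "c_full", "nri_total",
                                        "nri_event", "nri_nonevent")))
  withr::with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      fold <- .stratified_folds(out$case, n_folds)
      lp_base <- rep(NA_real_, n)
      lp_full <- rep(NA_real_, n)
      for (f in seq_len(n_folds)) {
        te <- fold == f; tr <- !te
        if (out$family == "logistic") {
          lp_base[te] <- .fit_predict("logistic", Xb[tr, , drop = FALSE],
                                      Xb[te, , drop = FALSE],
                                      y_tr = out$y[tr])
          lp_full[te] <- .fit_predict("logistic", Xf[tr, , drop = FALSE],
                                      Xf[te, , drop = FALSE],
                                      y_tr = out$y[tr])
        } else {
          lp_base[te] <- .fit_predict("cox", Xb[tr, , drop = FALSE],
                                      Xb[te, , drop = FALSE],
                                      surv_tr = out$surv[tr, ])
          lp_full[te] <- .fit_predict("cox", Xf[tr, , drop = FALSE],
                                      Xf[te, , drop = FALSE],
                                      surv_tr = out$surv[tr, ])
        }
      }
      if (anyNA(lp_base) || anyNA(lp_full)) next
      if (out$family == "logistic") {
        res[r, "c_base"] <- c_statistic(lp_base, outcome = out$case)
        res[r, "c_full"] <- c_statistic(lp_full, outcome = out$case)
      } else {
        res[r, "c_base"] <- c_statistic(lp_base,
                                        time = set$outcome$followup_years,
                                        event = out$case)
        res[r, "c_full"] <- c_statistic(lp_full,
                                        time = set$outcome$followup_years,
                                        event = out$case)
      }
      nri <- nri_continuous(lp_base, lp_full, out$case)
      res[r, c("nri_total", "nri_event", "nri_nonevent")] <- nri
    }
  })
  ok <- stats::complete.cases(res)
  if (!any(ok)) stop("no successful evaluation repeats")
  if (any(!ok))
    message(sum(!ok), " repeat(s) dropped for non-converged fold fits")
  res <- res[ok, , drop = FALSE]
  summ <- function(col) {
    v <- res[, col]
    list(estimate = mean(v),
         ci = unname(stats::quantile(v, c(0.025, 0.975))))
  }
  structure(list(c_full = summ("c_full"), c_base = summ("c_base"),
                 nri_total = summ("nri_total"),
                 nri_event = summ("nri_event"),
                 nri_nonevent = summ("nri_nonevent"),
                 per_repeat = as.data.frame(res),
                 n_repeats = nrow(res), features = features),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  fmt <- function(s) sprintf("%.3f (%.3f-%.3f)", s$estimate,
                             s$ci[1], s$ci[2])
  cat("<model_evaluation>\n")
  cat("  C-statistic base:        ", fmt(x$c_base), "\n")
  cat("  C-statistic base+lipids: ", fmt(x$c_full), "\n")
  cat("  NRI total:               ", fmt(x$nri_total), "\n")
  cat("  NRI event:               ", fmt(x$nri_event), "\n")
  cat("  NRI nonevent:            ", fmt(x$nri_nonevent), "\n")
  cat("  repeats:                 ", x$n_repeats, "\n")
  invisible(x)
}

#' Discovery-to-replication risk-model pipeline
#'
#' Runs the full multivariate workflow: (optional 2:1 age-sex matching of
#' an incident discovery set), per-cohort lipid clustering, cross-validated
#' forward stepwise selection on the discovery cohort, cluster-aware
#' feature finalisation, and retrained cross-validated evaluation on the
#' replication cohort.
#'
#' @param discovery,replication \code{"analysis_set"}s of the same role.
#' @param max_k Feature cap; default 10 for prevalent (logistic), 5 for
#'   incident (Cox).
#' @param match_ratio 2:1 matching ratio applied to incident discovery
#'   sets; \code{NULL} disables matching.
#' @param n_folds Folds for both stages.
#' @param discovery_repeats,replication_repeats CV repeats for selection
#'   and evaluation.
#' @param seed Master seed (selection uses \code{seed}, evaluation
#'   \code{seed + 1}).
#' @param ... Passed to [dynamic_hybrid_cut()] via [cluster_lipids()].
#' @return List: \code{selection} (\code{"selection_result"}),
#'   \code{evaluation} (\code{"model_evaluation"}), \code{clusters}.
#' @export
run_risk_model <- function(discovery, replication,
                           max_k = if (discovery$role == "prevalent") 10 else 5,
                           match_ratio = 2, n_folds = 10,
                           discovery_repeats = 10,
                           replication_repeats = 200, seed = 1L, ...) {
  stopifnot(inherits(discovery, "analysis_set"),
            inherits(replication, "analysis_set"),
            discovery$role == replication$role)
  disc <- discovery
  if (disc$role == "incident" && !is.null(match_ratio))
    disc <- match_discovery_subset(disc, ratio = match_ratio)
  clusters <- cluster_lipids(disc$species, ...)
  stepwise <- cv_stepwise_select(disc, max_k = max_k, n_folds = n_folds,
                                 n_repeats = discovery_repeats, seed = seed)
  selection <- finalize_features(stepwise, clusters, max_k = max_k)
  evaluation <- replicate_evaluate(replication, selection,
                                   n_folds = n_folds,
                                   n_repeats = replication_repeats,
                                   seed = seed + 1L)
  list(selection = selection, evaluation = evaluation, clusters = clusters)
}
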