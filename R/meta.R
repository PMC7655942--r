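# Inverse-variance fixed-effects meta-analysis of per-lipid cohort results.

#' Inverse-variance fixed-effects pooling for one lipid
#'
#' Pools per-study effects with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\beta = \sum w_i \beta_i / \sum w_i},
#' \eqn{se = (\sum w_i)^{-1/2}}, \eqn{z = \beta/se},
#' \eqn{p = 2\Phi(-|z|)} (standard-normal reference, the convention for
#' inverse-variance meta-analysis).  Studies with non-finite effects or
#' non-positive standard errors (flagged fits) are dropped before pooling.
#'
#' @param betas Numeric vector of per-study effects.
#' @param ses Numeric vector of per-study standard errors.
#' @param lipid_id Label for the output.
#' @return One-row data.frame: \code{lipid}, \code{beta_meta},
#'   \code{se_meta}, \code{z}, \code{p}, \code{q} (NA), \code{n_studies},
#'   \code{flag} plus a \code{"studies"} attribute holding the per-study
#'   (beta, se, weight) table.
#' @examples
#' fixed_effect_meta(c(0.5, 0.3), c(0.2, 0.1))
#' @export
fixed_effect_meta <- function(betas, ses, lipid_id = "lipid") {
  stopifnot(length(betas) == length(ses))
  ok <- is.finite(betas) & is.finite(ses) & ses > 0
  betas <- betas[ok]; ses <- ses[ok]
  if (!length(betas))
    stop(sprintf("no usable studies for lipid '%s'", lipid_id))
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  out <- data.frame(lipid = lipid_id, beta_meta = beta, se_meta = se,
                    z = z, p = 2 * stats::pnorm(-abs(z)), q = NA_real_,
                    n_studies = length(betas),
                    flag = if (length(betas) == 1L) "single_study" else "",
                    stringsAsFactors = FALSE)
  attr(out, "studies") <- data.frame(beta = betas, se = ses, weight = w)
  out
}

#' Meta-analyse per-lipid scans across cohorts
#'
#' Joins the per-cohort [scan_panel()] result tables by lipid and family,
#' pools each lipid with [fixed_effect_meta()], and applies BH FDR within
#' the species family and the class family separately.  Lipids flagged in a
#' cohort contribute nothing from that cohort; a lipid usable in only one
#' cohort is reported flagged \code{"single_study"}.
#'
#' @param cohort_results List of data.frames from [scan_panel()] (one per
#'   cohort).
#' @return data.frame with one row per lipid: \code{lipid}, \code{family},
#'   \code{class}, \code{beta_meta}, \code{se_meta}, \code{z}, \code{p},
#'   \code{q}, \code{n_studies}, \code{flag}.
#' @export
meta_scan <- function(cohort_results) {
  stopifnot(is.list(cohort_results), length(cohort_results) >= 1)
  all_res <- do.call(rbind, lapply(seq_along(cohort_results), function(i) {
    r <- cohort_results[[i]]
    r$study <- i
    r
  }))
  keys <- unique(all_res[, c("lipid", "family")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- all_res[all_res$lipid == keys$lipid[k] &
                     all_res$family == keys$family[k], , drop = FALSE]
    usable <- sub[is.na(sub$flag) | sub$flag == "", , drop = FALSE]
    usable <- usable[is.finite(usable$beta) & is.finite(usable$se) &
                       usable$se > 0, , drop = FALSE]
    if (!nrow(usable)) {
      return(data.frame(lipid = keys$lipid[k], family = keys$family[k],
                        class = sub$class[1], beta_meta = NA_real_,
                        se_meta = NA_real_, z = NA_real_, p = NA_real_,
                        q = NA_real_, n_studies = 0L, flag = "no_studies",
                        stringsAsFactors = FALSE))
    }
    m <- fixed_effect_meta(usable$beta, usable$se, keys$lipid[k])
    data.frame(lipid = m$lipid, family = keys$family[k], class = sub$class[1],
               beta_meta = m$beta_meta, se_meta = m$se_meta, z = m$z,
               p = m$p, q = NA_real_, n_studies = m$n_studies,
               flag = m$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (fam in unique(out$family)) {
    sel <- out$family == fam & !is.na(out$p)
    if (any(sel)) out$q[sel] <- bh_fdr(out$p[sel], family_size = sum(sel))
  }
  out
}
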