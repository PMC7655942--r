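# Batch alignment, transformation, standardisation and analysis-set
# selection for the prevalent (logistic) and incident (Cox) analyses.

#' Align analytical batches on QC medians
#'
#' Removes multiplicative technical batch variation: each lipid in each
#' batch is multiplied by (global QC median for that lipid) / (that batch's
#' QC median), so that after alignment the per-batch QC medians agree across
#' batches for every lipid.  Operating multiplicatively on raw
#' concentrations is equivalent to an additive correction in log space and
#' preserves scale.
#'
#' @param concentrations Numeric matrix/data.frame (samples x lipids).
#' @param batch_ids Vector of batch labels, one per row.
#' @param qc_flags Logical vector, one per row; \code{TRUE} marks a pooled
#'   QC sample.
#' @return Numeric matrix of aligned concentrations, same shape and
#'   dimnames as the input.
#' @export
align_batches <- function(concentrations, batch_ids, qc_flags) {
  m <- as.matrix(concentrations)
  storage.mode(m) <- "double"
  stopifnot(length(batch_ids) == nrow(m), length(qc_flags) == nrow(m),
            is.logical(qc_flags))
  batches <- unique(batch_ids)
  no_qc <- batches[!batches %in% unique(batch_ids[qc_flags])]
  if (length(no_qc))
    stop("batch(es) without any QC sample: ", paste(no_qc, collapse = ", "))
  qc <- m[qc_flags, , drop = FALSE]
  qc_batch <- batch_ids[qc_flags]
  global_med <- apply(qc, 2, stats::median)
  out <- m
  for (b in batches) {
    bmed <- apply(qc[qc_batch == b, , drop = FALSE], 2, stats::median)
    zero <- bmed == 0
    if (any(zero))
      stop(sprintf("QC median of zero for lipid '%s' in batch '%s'",
                   colnames(m)[which(zero)[1]], b))
    out[batch_ids == b, ] <- sweep(m[batch_ids == b, , drop = FALSE], 2,
                                   global_med / bmed, `*`)
  }
  out
}

#' Log10-transform and standardise a concentration matrix
#'
#' Each column is log10-transformed, then centred and scaled using the mean
#' and standard deviation computed over the included rows only; only the
#' included rows are returned.  Effects are therefore per standard deviation
#' of log10 concentration within the analysis set.
#'
#' @param concentrations Numeric matrix (samples x lipids), strictly
#'   positive on the included rows.
#' @param include Row index (logical or integer); default all rows.
#' @return Standardised numeric matrix over the included rows (column means
#'   0, SDs 1).
#' @export
log10_standardize <- function(concentrations, include = NULL) {
  m <- as.matrix(concentrations)
  storage.mode(m) <- "double"
  if (!is.null(include)) m <- m[include, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 included rows to standardise")
  bad <- which(!(m > 0), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive concentration at sample '%s', lipid '%s'",
                 if (is.null(rownames(m))) as.character(bad[1, 1])
                 else rownames(m)[bad[1, 1]],
                 if (is.null(colnames(m))) as.character(bad[1, 2])
                 else colnames(m)[bad[1, 2]]))
  lg <- log10(m)
  mu <- colMeans(lg)
  sd <- apply(lg, 2, stats::sd)
  zero <- sd == 0
  if (any(zero))
    stop("zero standard deviation in column(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  scale(lg, center = mu, scale = sd)[, , drop = FALSE]
}

.cohort_parts <- function(cohort) {
  stopifnot(is.list(cohort),
            all(c("concentrations", "metadata") %in% names(cohort)))
  conc <- cohort$concentrations
  meta <- cohort$metadata
  fixed <- c("sample_id", "batch_id", "is_qc")
  stopifnot(all(fixed %in% names(conc)))
  species <- setdiff(names(conc), fixed)
  list(conc = conc, meta = meta, species = species)
}

# covariate design data.frame for an analysis set; drops all-NA optional
# columns, keeps factors as factors (model.matrix expands them later)
.build_covariates <- function(meta, timepoint_factor = FALSE) {
  cov <- data.frame(age = meta$age,
                    sex = factor(meta$sex),
                    bmi = meta$bmi,
                    total_cholesterol = meta$total_cholesterol,
                    hdl_c = meta$hdl_c,
                    triglycerides = meta$triglycerides,
                    apoe4_count = meta$apoe4_count,
                    statin = as.logical(meta$statin),
                    omega3 = as.logical(meta$omega3))
  if (!all(is.na(meta$site)) && length(unique(stats::na.omit(meta$site))) > 1)
    cov$site <- factor(meta$site)
  if (!all(is.na(meta$fasting)))
    cov$fasting <- as.logical(meta$fasting)
  if (timepoint_factor && length(unique(meta$timepoint)) > 1)
    cov$timepoint <- factor(meta$timepoint)
  cov
}

.new_analysis_set <- function(role, species, classes, covariates, outcome,
                              meta) {
  structure(list(role = role, species = species, classes = classes,
                 covariates = covariates, outcome = outcome,
                 participant_id = meta$participant_id,
                 sample_id = meta$sample_id),
            class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cat(sprintf("<analysis_set> role=%s  n=%d  species=%d  classes=%d\n",
              x$role, nrow(x$species), ncol(x$species), ncol(x$classes)))
  invisible(x)
}

# batch-align a cohort and return aligned species matrix + class totals for
# the non-QC rows, keyed by sample id
.aligned_study_matrices <- function(cohort, registry) {
  parts <- .cohort_parts(cohort)
  m <- as.matrix(parts$conc[, parts$species, drop = FALSE])
  rownames(m) <- parts$conc$sample_id
  aligned <- align_batches(m, parts$conc$batch_id, parts$conc$is_qc)
  study <- aligned[!parts$conc$is_qc, , drop = FALSE]
  totals <- class_totals(study, registry)
  list(species = study, totals = totals, meta = parts$meta)
}

# complete-case filter over the columns actually used; logs dropped count
.complete_cases <- function(meta, cov) {
  keep <- stats::complete.cases(cov) & !is.na(meta$diagnosis)
  if (any(!keep))
    message(sum(!keep), " sample(s) dropped for missing covariates")
  keep
}

#' Select the prevalent-disease analysis set
#'
#' One row per participant, using the last acquired sample (maximum
#' timepoint); MCI participants are excluded so the contrast is AD versus
#' cognitively normal.  Batch alignment is applied first; class totals are
#' computed on the aligned raw scale; species and class totals are then
#' log10-standardised over the selected rows only.  When more than one
#' timepoint survives selection, timepoint enters the covariates as a
#' categorical indicator.
#'
#' @param cohort List with \code{concentrations} and \code{metadata} as
#'   produced by [generate_cohort()] (or read from delimited files with the
#'   same columns).
#' @param registry A \code{"panel_registry"} covering the panel.
#' @return An \code{"analysis_set"} with \code{role = "prevalent"}:
#'   standardized \code{species} and \code{classes} matrices, a
#'   \code{covariates} data.frame and \code{outcome} data.frame with column
#'   \code{ad} (logical).
#' @export
select_prevalent <- function(cohort, registry) {
  am <- .aligned_study_matrices(cohort, registry)
  meta <- am$meta

  # last acquired sample per participant, ties broken by first-read row
  complete_lipids <- stats::complete.cases(am$species[meta$sample_id, ,
                                                      drop = FALSE])
  meta <- meta[complete_lipids, , drop = FALSE]
  ord <- order(meta$participant_id, -meta$timepoint)
  meta <- meta[ord, , drop = FALSE]
  dup_tp <- duplicated(meta[, c("participant_id", "timepoint")])
  if (any(dup_tp)) {
    warning("duplicate rows at a participant's latest timepoint; keeping the",
            " first-read row")
  }
  meta <- meta[!duplicated(meta$participant_id), , drop = FALSE]

  meta <- meta[meta$diagnosis != "MCI", , drop = FALSE]
  cov <- .build_covariates(meta, timepoint_factor = TRUE)
  keep <- .complete_cases(meta, cov)
  meta <- meta[keep, , drop = FALSE]
  cov <- droplevels(cov[keep, , drop = FALSE])

  sp <- log10_standardize(am$species[meta$sample_id, , drop = FALSE])
  cl <- log10_standardize(am$totals[meta$sample_id, , drop = FALSE])
  outcome <- data.frame(ad = meta$diagnosis == "AD")
  .new_analysis_set("prevalent", sp, cl, cov, outcome, meta)
}

#' Select the incident-disease analysis set
#'
#' Baseline samples only; participants already diagnosed with AD at
#' baseline are excluded; cognitively normal and MCI participants are
#' retained (an \code{mci} indicator is carried in the outcome table as an
#' optional sensitivity covariate).  The survival outcome is left-truncated
#' on the age axis: entry at baseline age, exit at baseline age plus
#' follow-up, with the conversion flag as the event.
#'
#' @inheritParams select_prevalent
#' @return An \code{"analysis_set"} with \code{role = "incident"} and
#'   \code{outcome} columns \code{entry_age}, \code{exit_age},
#'   \code{event}, \code{followup_years}, \code{mci}.
#' @export
select_incident <- function(cohort, registry) {
  am <- .aligned_study_matrices(cohort, registry)
  meta <- am$meta[am$meta$timepoint == 0, , drop = FALSE]
  complete_lipids <- stats::complete.cases(am$species[meta$sample_id, ,
                                                      drop = FALSE])
  meta <- meta[complete_lipids, , drop = FALSE]
  meta <- meta[meta$diagnosis != "AD", , drop = FALSE]
  bad <- meta$converted & meta$followup_years <= 0
  if (any(bad))
    stop("converter(s) with non-positive follow-up time: ",
         paste(meta$participant_id[bad], collapse = ", "))
  meta <- meta[meta$followup_years > 0, , drop = FALSE]

  cov <- .build_covariates(meta, timepoint_factor = FALSE)
  keep <- .complete_cases(meta, cov)
  meta <- meta[keep, , drop = FALSE]
  cov <- droplevels(cov[keep, , drop = FALSE])

  sp <- log10_standardize(am$species[meta$sample_id, , drop = FALSE])
  cl <- log10_standardize(am$totals[meta$sample_id, , drop = FALSE])
  outcome <- data.frame(entry_age = meta$age,
                        exit_age = meta$age + meta$followup_years,
                        event = meta$converted,
                        followup_years = meta$followup_years,
                        mci = meta$diagnosis == "MCI")
  .new_analysis_set("incident", sp, cl, cov, outcome, meta)
}
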