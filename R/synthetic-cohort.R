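# Synthetic two-cohort generator: block-correlated log-normal lipid panels,
# batch structure with embedded QC samples, clinical covariates, prevalent
# diagnosis from a logistic model and incident conversion from a
# proportional-hazards model on the age scale.

.panel_class_specs <- list(
  PC      = list(template = "PC(%d:%d)",          carbons = seq(30, 40, 2), db = 0:5),
  PE      = list(template = "PE(%d:%d)",          carbons = seq(32, 42, 2), db = 0:5),
  SM      = list(template = "SM(d18:1/%d:%d)",    carbons = seq(14, 24, 2), db = 0:5),
  Cer     = list(template = "Cer(d18:1/%d:%d)",   carbons = seq(16, 26, 2), db = 0:5),
  TG      = list(template = "TG(%d:%d)",          carbons = seq(46, 56, 2), db = 0:5),
  CE      = list(template = "CE(%d:%d)",          carbons = seq(14, 24, 2), db = 0:5),
  LPC     = list(template = "LPC(%d:%d)",         carbons = seq(14, 24, 2), db = 0:5),
  GM3     = list(template = "GM3(d18:1/%d:%d)",   carbons = seq(16, 26, 2), db = 0:5),
  `PC(O)` = list(template = "PC(O-%d:%d)",        carbons = seq(30, 40, 2), db = 0:5),
  `PC(P)` = list(template = "PC(P-%d:%d)",        carbons = seq(30, 40, 2), db = 0:5),
  `PE(O)` = list(template = "PE(O-%d:%d)",        carbons = seq(32, 42, 2), db = 0:5),
  `PE(P)` = list(template = "PE(P-%d:%d)",        carbons = seq(32, 42, 2), db = 0:5),
  `TG(O)` = list(template = "TG(O-%d:%d)",        carbons = seq(46, 56, 2), db = 0:5),
  dhCer   = list(template = "dhCer(d18:0/%d:%d)", carbons = seq(16, 26, 2), db = 0:5),
  HexCer  = list(template = "HexCer(d18:1/%d:%d)", carbons = seq(16, 26, 2), db = 0:5),
  Hex2Cer = list(template = "Hex2Cer(d18:1/%d:%d)", carbons = seq(16, 26, 2), db = 0:5),
  Hex3Cer = list(template = "Hex3Cer(d18:1/%d:%d)", carbons = seq(16, 26, 2), db = 0:5),
  GM1     = list(template = "GM1(d18:1/%d:%d)",   carbons = seq(16, 26, 2), db = 0:5),
  DG      = list(template = "DG(%d:%d)",          carbons = seq(30, 40, 2), db = 0:5),
  DE      = list(template = "DE(%d:%d)",          carbons = seq(14, 24, 2), db = 0:5),
  PS      = list(template = "PS(%d:%d)",          carbons = seq(32, 42, 2), db = 0:5),
  PI      = list(template = "PI(%d:%d)",          carbons = seq(32, 42, 2), db = 0:5),
  PG      = list(template = "PG(%d:%d)",          carbons = seq(32, 42, 2), db = 0:5),
  LPE     = list(template = "LPE(%d:%d)",         carbons = seq(14, 24, 2), db = 0:5),
  AC      = list(template = "AC(%d:%d)",          carbons = seq(10, 20, 2), db = 0:5)
)

#' Construct a synthetic lipid panel registry
#'
#' Builds a panel of realistic, parseable species names spread over up to 25
#' lipid classes and subclasses (diacyl and ether glycerophospholipids,
#' sphingolipids including gangliosides, glycerolipids, sterol esters,
#' lysophospholipids and acylcarnitines).  The default desk-scale panel is 8
#' classes x 25 species = 200 species; larger panels approaching the size of
#' a full targeted plasma lipidomics assay are available by raising both
#' arguments.
#'
#' @param n_classes Number of classes (1..25).
#' @param species_per_class Species per class (each class template offers 36
#'   carbon/double-bond combinations).
#' @return A \code{"panel_registry"}.
#' @export
default_panel <- function(n_classes = 8, species_per_class = 25) {
  stopifnot(n_classes >= 1, n_classes <= length(.panel_class_specs))
  specs <- .panel_class_specs[seq_len(n_classes)]
  rows <- lapply(names(specs), function(cl) {
    sp <- specs[[cl]]
    grid <- expand.grid(carbons = sp$carbons, db = sp$db,
                        KEEP.OUT.ATTRS = FALSE)
    if (species_per_class > nrow(grid))
      stop(sprintf("class %s supports at most %d species", cl, nrow(grid)))
    grid <- grid[seq_len(species_per_class), , drop = FALSE]
    data.frame(species_name = sprintf(sp$template, grid$carbons, grid$db),
               class_code = cl, stringsAsFactors = FALSE)
  })
  lipid_registry(do.call(rbind, rows))
}

#' Configuration for the synthetic cohort generator
#'
#' Collects every tunable of [generate_cohort()] with defaults emulating an
#' ageing memory-clinic cohort: participants aged ~75 (SD 7), diagnosis mix
#' 70/10/20 CN/MCI/AD, APOE \eqn{\epsilon}4 allele counts 0/1/2 with
#' probabilities 0.60/0.32/0.08, block-correlated log-normal lipid
#' concentrations with within-class Spearman correlation ~0.5, analytical
#' batches with embedded pooled-plasma QC samples and multiplicative
#' per-lipid batch factors (SD 0.1 on the log10 scale), and administrative
#' censoring drawn uniformly on 2.4--9.9 years (mean 6.15, SD 2.17 years of
#' follow-up among non-converters).
#'
#' @param cohort_id Cohort label (also used in sample ids).
#' @param n_participants Number of participants.
#' @param n_timepoints Visits per participant, 18 months apart (visit 0 is
#'   baseline; later visits have 85% retention).
#' @param diagnosis_weights Named weights for CN/MCI/AD; must sum to 1.  The
#'   AD weight sets the logistic intercept; the MCI weight sets the MCI rate
#'   among non-AD participants.
#' @param panel A \code{"panel_registry"}; default [default_panel()].
#' @param rho_within,rho_between Within-class and cross-class correlation of
#'   log10 concentrations; require \code{0 <= rho_between <= rho_within < 1}
#'   for a positive semi-definite block structure.
#' @param samples_per_batch,qc_per_batch Analytical batch size and number of
#'   embedded QC samples per batch.
#' @param batch_sd SD of the per-lipid, per-batch multiplicative factor on
#'   the log10 scale.
#' @param age_mean,age_sd,age_min Baseline age distribution (years; normal
#'   truncated below at \code{age_min}).
#' @param female_frac Fraction of female participants.
#' @param bmi_mean,bmi_sd BMI (kg/m^2).
#' @param chol_mean,chol_sd,hdl_mean,hdl_sd Total and HDL cholesterol
#'   (mmol/l).
#' @param trig_meanlog,trig_sdlog Clinical triglycerides (mmol/l),
#'   log-normal.
#' @param apoe4_probs Probabilities of 0/1/2 APOE \eqn{\epsilon}4 alleles.
#' @param statin_prob,omega3_prob Medication/supplement probabilities.
#' @param site_prob Probability of the first collection site (two-site
#'   cohort); \code{NULL} for single-site cohorts.
#' @param fasting_prob Probability a sample is fasted; \code{NULL} when
#'   fasting status is not recorded.
#' @param beta_prevalent,beta_incident Named numeric vectors of planted
#'   per-SD effects (log-odds / log-hazard) for species on the panel.
#' @param cov_effects_prevalent,cov_effects_incident Named effects of
#'   centred covariates (\code{age}, \code{sexM}, \code{bmi}, \code{apoe4})
#'   on the outcome linear predictors.
#' @param baseline_hazard Exponential baseline conversion hazard per year
#'   on the age scale.
#' @param censor_range Administrative censoring horizon, years; drawn
#'   uniformly per participant.
#' @param mci_gamma Slope linking the centred incident linear predictor to
#'   the log-odds of MCI among non-AD participants, so MCI enriches among
#'   high-risk individuals.
#' @param mci_boost Additional MCI log-odds for participants who convert
#'   within follow-up (prodromal enrichment: baseline MCI is far more
#'   common among future converters in memory-clinic cohorts).
#' @param visit_noise_sd SD of visit-to-visit measurement noise added to the
#'   person-level latent log10 abundance.
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(cohort_id = "COHORT_A",
                       n_participants = 400,
                       n_timepoints = 1,
                       diagnosis_weights = c(CN = 0.70, MCI = 0.10, AD = 0.20),
                       panel = default_panel(),
                       rho_within = 0.5,
                       rho_between = 0.05,
                       samples_per_batch = 120,
                       qc_per_batch = 8,
                       batch_sd = 0.1,
                       age_mean = 75, age_sd = 7, age_min = 60,
                       female_frac = 0.55,
                       bmi_mean = 26, bmi_sd = 4,
                       chol_mean = 5.2, chol_sd = 1.1,
                       hdl_mean = 1.5, hdl_sd = 0.45,
                       trig_meanlog = log(1.3), trig_sdlog = 0.4,
                       apoe4_probs = c(0.60, 0.32, 0.08),
                       statin_prob = 0.30, omega3_prob = 0.20,
                       site_prob = NULL,
                       fasting_prob = NULL,
                       beta_prevalent = numeric(0),
                       beta_incident = numeric(0),
                       cov_effects_prevalent = c(age = 0.06, sexM = 0.05,
                                                 bmi = -0.02, apoe4 = 0.9),
                       cov_effects_incident = c(sexM = 0.05, bmi = -0.02,
                                                apoe4 = 0.7),
                       baseline_hazard = 0.02,
                       censor_range = c(2.4, 9.9),
                       mci_gamma = 1.0,
                       mci_boost = 2.5,
                       visit_noise_sd = 0.2,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(inherits(panel, "panel_registry"),
            n_participants >= 1, n_timepoints >= 1,
            length(diagnosis_weights) == 3,
            abs(sum(diagnosis_weights) - 1) < 1e-8,
            all(diagnosis_weights >= 0),
            length(apoe4_probs) == 3, abs(sum(apoe4_probs) - 1) < 1e-8,
            samples_per_batch >= 1, qc_per_batch >= 1, batch_sd >= 0,
            length(censor_range) == 2, censor_range[1] > 0,
            censor_range[2] >= censor_range[1])
  if (is.null(names(diagnosis_weights)))
    names(cfg$diagnosis_weights) <- c("CN", "MCI", "AD")
  if (rho_within < 0 || rho_within >= 1 || rho_between < 0 ||
      rho_between > rho_within)
    stop(sprintf(paste0("correlation block (rho_within=%.3f, rho_between=%.3f)",
                        " is not positive semi-definite: require ",
                        "0 <= rho_between <= rho_within < 1"),
                 rho_within, rho_between))
  bad <- setdiff(c(names(beta_prevalent), names(beta_incident)),
                 panel$species$species_name)
  if (length(bad))
    stop("planted species not on the panel: ", paste(bad, collapse = ", "))
  class(cfg) <- "sim_config"
  cfg
}

# Draw the block-correlated latent matrix (rows = units, cols = species),
# standard normal margins, corr rho_within inside a class, rho_between
# across classes.
.draw_block_normal <- function(n, classes, rho_within, rho_between) {
  p <- length(classes)
  g <- stats::rnorm(n)
  u <- matrix(stats::rnorm(n * length(unique(classes))), n)
  colnames(u) <- unique(classes)
  e <- matrix(stats::rnorm(n * p), n, p)
  sqrt(rho_between) * g +
    sqrt(rho_within - rho_between) * u[, classes, drop = FALSE] +
    sqrt(1 - rho_within) * e
}

.rtruncnorm_lower <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate one synthetic cohort
#'
#' Log10 concentrations are multivariate normal with a within-class /
#' cross-class block correlation structure; raw concentrations are strictly
#' positive.  Prevalent diagnosis is drawn from a logistic model on the
#' standardized planted species plus centred covariates; incident conversion
#' is drawn from a proportional-hazards model on the age scale (exponential
#' baseline hazard, entry at baseline age, administrative censoring).  MCI is
#' assigned among non-AD participants with log-odds increasing in the
#' incident linear predictor, so MCI enriches among future converters.
#' Samples are laid out in analytical batches with embedded QC samples
#' (draws centred on the panel pool mean); all rows of a batch are then
#' multiplied by that batch's per-lipid factor.
#'
#' Identical configurations (including the seed) produce identical output.
#'
#' @param config A \code{"sim_config"}.
#' @return List with components
#'   \describe{
#'     \item{concentrations}{data.frame: \code{sample_id}, \code{batch_id},
#'       \code{is_qc}, then one column per species (raw concentrations,
#'       pmol/ml scale).}
#'     \item{metadata}{data.frame of sample records (one row per non-QC
#'       sample): participant id, cohort id, timepoint, age at visit, sex,
#'       BMI, cholesterol, HDL-C, triglycerides, APOE \eqn{\epsilon}4 count,
#'       statin, omega-3, site, fasting, diagnosis, follow-up years,
#'       conversion flag.}
#'     \item{truth}{list: planted effect vectors, class/block membership,
#'       per-batch factors, per-participant latent linear predictors
#'       (\code{lp_prevalent}, \code{lp_incident}), conversion times.}
#'   }
#' @examples
#' cfg <- sim_config(n_participants = 50, panel = default_panel(2, 5),
#'                   seed = 7)
#' cohort <- generate_cohort(cfg)
#' dim(cohort$concentrations)
#' table(cohort$metadata$diagnosis)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  reg <- cfg$panel
  species <- reg$species$species_name
  classes <- reg$class_of[species]
  p <- length(species)
  n <- cfg$n_participants

  # per-species abundance scale on the log10 concentration axis
  mu <- stats::runif(p, 1, 3)
  sigma <- stats::runif(p, 0.15, 0.30)
  names(mu) <- names(sigma) <- species

  # participant covariates
  age <- .rtruncnorm_lower(n, cfg$age_mean, cfg$age_sd, cfg$age_min)
  sex <- ifelse(stats::runif(n) < cfg$female_frac, "F", "M")
  bmi <- .rtruncnorm_lower(n, cfg$bmi_mean, cfg$bmi_sd, 15)
  chol <- .rtruncnorm_lower(n, cfg$chol_mean, cfg$chol_sd, 2)
  hdl <- .rtruncnorm_lower(n, cfg$hdl_mean, cfg$hdl_sd, 0.5)
  trig <- stats::rlnorm(n, cfg$trig_meanlog, cfg$trig_sdlog)
  apoe4 <- sample(0:2, n, replace = TRUE, prob = cfg$apoe4_probs)
  statin <- stats::runif(n) < cfg$statin_prob
  omega3 <- stats::runif(n) < cfg$omega3_prob
  site <- if (!is.null(cfg$site_prob))
    ifelse(stats::runif(n) < cfg$site_prob, "site1", "site2") else NA_character_
  fasting <- if (!is.null(cfg$fasting_prob))
    stats::runif(n) < cfg$fasting_prob else NA

  # person-level latent lipid abundances (standard normal, block correlated)
  z <- .draw_block_normal(n, classes, cfg$rho_within, cfg$rho_between)
  colnames(z) <- species

  # centred covariate contributions
  cov_lp <- function(effects) {
    lp <- numeric(n)
    if ("age" %in% names(effects)) lp <- lp + effects["age"] * (age - cfg$age_mean)
    if ("sexM" %in% names(effects)) lp <- lp + effects["sexM"] * (sex == "M")
    if ("bmi" %in% names(effects)) lp <- lp + effects["bmi"] * (bmi - cfg$bmi_mean)
    if ("apoe4" %in% names(effects))
      lp <- lp + effects["apoe4"] * (apoe4 - sum(cfg$apoe4_probs * 0:2))
    unname(lp)
  }
  planted_lp <- function(betas) {
    if (!length(betas)) return(numeric(n))
    as.vector(z[, names(betas), drop = FALSE] %*% betas)
  }

  w <- cfg$diagnosis_weights
  lp_prev <- stats::qlogis(max(w[["AD"]], 1e-8)) +
    planted_lp(cfg$beta_prevalent) + cov_lp(cfg$cov_effects_prevalent)
  prevalent_ad <- stats::runif(n) < stats::plogis(lp_prev)

  lp_inc <- planted_lp(cfg$beta_incident) + cov_lp(cfg$cov_effects_incident)
  rate <- cfg$baseline_hazard * exp(lp_inc)
  conv_time <- stats::rexp(n, rate)            # years after baseline entry
  censor <- stats::runif(n, cfg$censor_range[1], cfg$censor_range[2])
  converted <- !prevalent_ad & (conv_time <= censor)
  followup <- ifelse(prevalent_ad, 0, pmin(conv_time, censor))

  # MCI among non-AD: an intermediate latent-risk band plus a prodromal
  # boost for participants who will convert within the follow-up horizon,
  # emulating the strong baseline-MCI enrichment seen among converters in
  # memory-clinic cohorts
  p_mci_base <- w[["MCI"]] / max(1 - w[["AD"]], 1e-8)
  p_mci_base <- min(max(p_mci_base, 1e-8), 1 - 1e-8)
  lp_mci <- stats::qlogis(p_mci_base) +
    cfg$mci_gamma * (lp_inc - mean(lp_inc)) +
    cfg$mci_boost * converted
  mci <- !prevalent_ad & (stats::runif(n) < stats::plogis(lp_mci))

  # visit schedule: baseline always present, later visits 85% retention
  tp_list <- lapply(seq_len(n), function(i) {
    tps <- 0L
    if (cfg$n_timepoints > 1L) {
      extra <- seq_len(cfg$n_timepoints - 1L)
      keep <- stats::runif(length(extra)) < 0.85
      tps <- c(0L, extra[keep])
    }
    tps
  })
  idx <- rep(seq_len(n), lengths(tp_list))
  tp <- unlist(tp_list)
  visit_years <- 1.5 * tp
  n_rows <- length(idx)

  # diagnosis at each visit: prevalent AD persists; converters become AD
  # once the conversion time has passed; otherwise MCI/CN status holds
  diag_at <- ifelse(prevalent_ad[idx] |
                      (converted[idx] & conv_time[idx] <= visit_years), "AD",
                    ifelse(mci[idx], "MCI", "CN"))

  log_conc <- matrix(mu, n_rows, p, byrow = TRUE) +
    matrix(sigma, n_rows, p, byrow = TRUE) *
    (z[idx, , drop = FALSE] +
       cfg$visit_noise_sd * matrix(stats::rnorm(n_rows * p), n_rows, p))
  sample_id <- sprintf("%s_P%04d_T%d", cfg$cohort_id, idx, tp)

  # batch layout: shuffle study samples, chunk into batches, add QC rows
  ord <- sample.int(n_rows)
  batch_of <- integer(n_rows)
  batch_of[ord] <- (seq_len(n_rows) - 1L) %/% cfg$samples_per_batch + 1L
  n_batches <- max(batch_of)
  qc_n <- n_batches * cfg$qc_per_batch
  qc_batch <- rep(seq_len(n_batches), each = cfg$qc_per_batch)
  qc_log <- matrix(mu, qc_n, p, byrow = TRUE) +
    0.05 * matrix(stats::rnorm(qc_n * p), qc_n, p)
  qc_id <- sprintf("%s_QC_B%02d_%02d", cfg$cohort_id, qc_batch,
                   stats::ave(seq_len(qc_n), qc_batch, FUN = seq_along))

  all_log <- rbind(log_conc, qc_log)
  all_batch <- c(batch_of, qc_batch)
  all_qc <- c(rep(FALSE, n_rows), rep(TRUE, qc_n))
  all_id <- c(sample_id, qc_id)

  batch_factors <- matrix(stats::rnorm(n_batches * p, 0, cfg$batch_sd),
                          n_batches, p, dimnames = list(NULL, species))
  conc <- 10^(all_log + batch_factors[all_batch, , drop = FALSE])
  colnames(conc) <- species

  concentrations <- data.frame(sample_id = all_id,
                               batch_id = sprintf("B%02d", all_batch),
                               is_qc = all_qc,
                               stringsAsFactors = FALSE,
                               check.names = FALSE)
  concentrations <- cbind(concentrations, as.data.frame(conc))
  rownames(concentrations) <- NULL

  metadata <- data.frame(
    sample_id = sample_id,
    participant_id = sprintf("%s_P%04d", cfg$cohort_id, idx),
    cohort_id = cfg$cohort_id,
    timepoint = tp,
    age = age[idx] + visit_years,
    sex = sex[idx],
    bmi = bmi[idx],
    total_cholesterol = chol[idx],
    hdl_c = hdl[idx],
    triglycerides = trig[idx],
    apoe4_count = apoe4[idx],
    statin = statin[idx],
    omega3 = omega3[idx],
    site = site[idx],
    fasting = fasting[idx],
    diagnosis = diag_at,
    followup_years = followup[idx],
    converted = converted[idx],
    stringsAsFactors = FALSE
  )

  truth <- list(
    beta_prevalent = cfg$beta_prevalent,
    beta_incident = cfg$beta_incident,
    block_of = classes,
    mu = mu, sigma = sigma,
    batch_factors = batch_factors,
    lp_prevalent = lp_prev,
    lp_incident = lp_inc,
    prevalent_ad = prevalent_ad,
    conversion_time = conv_time,
    censor_time = censor,
    baseline_age = age
  )
  list(concentrations = concentrations, metadata = metadata, truth = truth)
}

#' Generate a pair of linked synthetic cohorts
#'
#' Convenience wrapper producing a two-site / fasting-status pair of cohorts
#' (different sizes, diagnosis mixes and batch layouts) that share the same
#' lipid panel and the same planted species effects, so cross-cohort
#' meta-analysis and discovery/replication modelling are exercised with
#' transferable signal.
#'
#' @param seed Master seed; the two cohorts use \code{seed} and
#'   \code{seed + 1}.
#' @param n_a,n_b Participants per cohort.
#' @param panel Shared \code{"panel_registry"}.
#' @param beta_prevalent,beta_incident Shared planted effect vectors.
#' @param n_timepoints_a Visits in the first (longitudinal) cohort.
#' @param ... Further arguments passed to both [sim_config()] calls.
#' @return List with elements \code{cohort_a}, \code{cohort_b} (each as
#'   returned by [generate_cohort()]) and \code{panel}.
#' @export
sim_two_cohorts <- function(seed = 1L, n_a = 500, n_b = 400,
                            panel = default_panel(),
                            beta_prevalent = numeric(0),
                            beta_incident = numeric(0),
                            n_timepoints_a = 1, ...) {
  a <- sim_config(cohort_id = "STUDY_A", n_participants = n_a,
                  n_timepoints = n_timepoints_a, panel = panel,
                  site_prob = 0.55,
                  diagnosis_weights = c(CN = 0.70, MCI = 0.10, AD = 0.20),
                  beta_prevalent = beta_prevalent,
                  beta_incident = beta_incident, seed = seed, ...)
  b <- sim_config(cohort_id = "STUDY_B", n_participants = n_b,
                  panel = panel, fasting_prob = 0.92,
                  diagnosis_weights = c(CN = 0.35, MCI = 0.40, AD = 0.25),
                  beta_prevalent = beta_prevalent,
                  beta_incident = beta_incident, seed = seed + 1L, ...)
  list(cohort_a = generate_cohort(a), cohort_b = generate_cohort(b),
       panel = panel)
}

#' Pick a default set of planted species
#'
#' Deterministically selects \code{n} species spread across classes (the
#' first species of each of the first \code{n} classes, wrapping around if
#' needed) and attaches a common effect size.
#'
#' @param registry A \code{"panel_registry"}.
#' @param n Number of planted species.
#' @param beta Per-SD effect size attached to every planted species.
#' @return Named numeric vector of planted effects.
#' @export
planted_effects <- function(registry, n = 5, beta = 0.4) {
  stopifnot(inherits(registry, "panel_registry"))
  df <- registry$species
  classes <- unique(df$class_code)
  picks <- character(n)
  for (i in seq_len(n)) {
    cl <- classes[((i - 1L) %% length(classes)) + 1L]
    members <- df$species_name[df$class_code == cl]
    picks[i] <- members[min(((i - 1L) %/% length(classes)) + 1L,
                            length(members))]
  }
  stats::setNames(rep(beta, n), picks)
}
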