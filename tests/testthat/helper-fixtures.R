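# Shared fixtures: tiny registries, hand-built cohorts, and independent
# brute-force oracles used across the test files.

tiny_registry <- function() {
  lipid_registry(c("CE(16:0)", "CE(18:1)", "AC(12:0)", "AC(14:1)"),
                 c("CE", "CE", "AC", "AC"))
}

# brute-force per-class sums, written independently of class_totals()
oracle_class_totals <- function(m, registry) {
  cls <- registry$class_of[colnames(m)]
  out <- sapply(unique(cls), function(cl) {
    sub <- m[, cls == cl, drop = FALSE]
    apply(sub, 1, sum)
  })
  colnames(out) <- unique(cls)
  out
}

# brute-force BH step-up: q_(i) = min_{j >= i} m p_(j) / j, capped at 1
oracle_bh <- function(p, m = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  k <- length(p)
  q <- numeric(k)
  for (i in seq_len(k)) {
    q[i] <- min(1, min(m * ps[i:k] / (i:k)))
  }
  out <- numeric(k)
  out[ord] <- q
  out
}

# brute-force all-pairs AUC with ties 1/2
oracle_auc <- function(scores, y) {
  y <- as.logical(y)
  num <- 0; den <- 0
  for (i in which(y)) for (j in which(!y)) {
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  num / den
}

# brute-force Harrell C with left truncation, ties 1/2
oracle_harrell <- function(scores, time, event, entry = rep(0, length(time))) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !event[i]) next
    if (time[j] > time[i] && entry[j] < time[i]) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# direct-count category-free NRI
oracle_nri <- function(base, new, y) {
  y <- as.logical(y)
  up <- new > base; down <- new < base
  ev <- (sum(up & y) - sum(down & y)) / sum(y)
  ne <- (sum(down & !y) - sum(up & !y)) / sum(!y)
  c(total = ev + ne, event = ev, nonevent = ne)
}

# hand-built cohort: 2 batches, 1 QC row per batch, species from
# tiny_registry(), one row per (participant, timepoint) in `meta_rows`
toy_cohort <- function(meta_rows, batch_of = NULL, conc_seed = 99) {
  reg <- tiny_registry()
  species <- reg$species$species_name
  n <- nrow(meta_rows)
  if (is.null(batch_of)) batch_of <- rep("B1", n)
  set.seed(conc_seed)
  conc_vals <- matrix(10^runif(n * length(species), 1, 2), n,
                      dimnames = list(NULL, species))
  qc <- NULL
  for (b in unique(batch_of)) {
    row <- as.data.frame(matrix(10^1.5, 1, length(species),
                                dimnames = list(NULL, species)))
    qc <- rbind(qc, cbind(data.frame(sample_id = paste0("QC_", b),
                                     batch_id = b, is_qc = TRUE), row))
  }
  conc <- rbind(
    cbind(data.frame(sample_id = meta_rows$sample_id, batch_id = batch_of,
                     is_qc = FALSE), as.data.frame(conc_vals)),
    qc)
  defaults <- data.frame(
    cohort_id = "TOY", age = 75, sex = "F", bmi = 26,
    total_cholesterol = 5, hdl_c = 1.5, triglycerides = 1.3,
    apoe4_count = 0, statin = FALSE, omega3 = FALSE,
    site = NA_character_, fasting = NA, followup_years = 0,
    converted = FALSE, stringsAsFactors = FALSE)
  meta <- cbind(meta_rows,
                defaults[rep(1, n), setdiff(names(defaults),
                                            names(meta_rows)),
                         drop = FALSE])
  rownames(meta) <- NULL
  list(concentrations = conc, metadata = meta, registry = reg)
}

# block-correlated gaussian sample matrix for clustering tests
block_sample <- function(n, block_sizes, rho_in, rho_out = 0, seed = 1) {
  withr::with_seed(seed, {
    blocks <- rep(seq_along(block_sizes), block_sizes)
    p <- length(blocks)
    g <- rnorm(n)
    u <- matrix(rnorm(n * length(block_sizes)), n)
    e <- matrix(rnorm(n * p), n, p)
    x <- sqrt(rho_out) * g + sqrt(rho_in - rho_out) * u[, blocks] +
      sqrt(1 - rho_in) * e
    colnames(x) <- paste0("V", seq_len(p))
    list(x = x, blocks = blocks)
  })
}
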