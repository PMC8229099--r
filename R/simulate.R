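#' Configuration for the synthetic 450k AML cohort generator
#'
#' Defaults mirror the diagnostic cohort structure of a Nordic pediatric
#' AML series: eight cytogenetic subtypes with sizes 30/25/19/12/5/4/3/1,
#' 24 cytogenetically undefined diagnostic samples and 19 relapse samples.
#' The CpG background is a bimodal beta mixture (low mode ~0.06, high mode
#' ~0.89) as on methylation arrays; each subtype owns a planted signature
#' of CpGs shifted by `effect_delta`, half hyper- and half hypomethylated.
#' A hidden binary methylation group with its own CpG signature drives the
#' survival outcome through a proportional-hazards effect.
#'
#' @param n_cpgs Number of CpG sites (desk scale; the real array retains
#'   ~406,830 autosomal sites).
#' @param subtype_sizes Named integer vector, diagnostic samples per
#'   cytogenetic subtype.
#' @param n_signature_cpgs Planted signature CpGs per subtype.
#' @param effect_delta Beta-scale mean shift at signature CpGs, in \[0, 1\].
#' @param background_mix List with `p_low` (weight of the unmethylated
#'   component) and `low_shape`/`high_shape` (Beta shape pairs).
#' @param noise_sd Per-entry Gaussian noise SD on the beta scale (clipped
#'   to \[0, 1\] afterwards).
#' @param missing_rate Fraction of entries set missing.
#' @param detection_fail_rate Fraction of entries whose detection p-value
#'   is drawn >= 0.05.
#' @param n_undefined Diagnostic samples whose true subtype is hidden
#'   (reported as "undefined").
#' @param n_relapse Relapse samples, generated as noisy copies of their
#'   diagnostic pair.
#' @param relapse_noise_sd Extra beta-scale noise between a diagnostic
#'   sample and its relapse copy.
#' @param n_outcome_cpgs Planted CpGs separating the hidden outcome group.
#' @param outcome List with `baseline_hazard` (events/month),
#'   `hazard_ratio` for the planted high-risk methylation group, and
#'   `censor_rate` (expected censored fraction).
#' @param seed Integer seed; same config + seed gives identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cpgs = 10000,
                              subtype_sizes = c("NK" = 30, "MLL" = 25,
                                                "t(8;21)" = 19, "inv(16)" = 12,
                                                "mono7" = 5, "t(15;17)" = 4,
                                                "sole+8" = 3, "3q21q26" = 1),
                              n_signature_cpgs = 50,
                              effect_delta = 0.4,
                              background_mix = list(p_low = 0.5,
                                                    low_shape = c(2, 18),
                                                    high_shape = c(17, 3)),
                              noise_sd = 0.05,
                              missing_rate = 0.05,
                              detection_fail_rate = 0.01,
                              n_undefined = 24,
                              n_relapse = 19,
                              relapse_noise_sd = 0.02,
                              n_outcome_cpgs = 50,
                              outcome = list(baseline_hazard = 0.02,
                                             hazard_ratio = 4,
                                             censor_rate = 0.3),
                              seed = 1L) {
  cfg <- list(n_cpgs = as.integer(n_cpgs), subtype_sizes = subtype_sizes,
              n_signature_cpgs = as.integer(n_signature_cpgs),
              effect_delta = effect_delta, background_mix = background_mix,
              noise_sd = noise_sd, missing_rate = missing_rate,
              detection_fail_rate = detection_fail_rate,
              n_undefined = as.integer(n_undefined),
              n_relapse = as.integer(n_relapse),
              relapse_noise_sd = relapse_noise_sd,
              n_outcome_cpgs = as.integer(n_outcome_cpgs),
              outcome = outcome, seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_cpgs > 0, cfg$n_signature_cpgs >= 0, cfg$n_outcome_cpgs >= 0)
  if (is.null(names(cfg$subtype_sizes)) || any(names(cfg$subtype_sizes) == "")) {
    stop("subtype_sizes must be a named vector")
  }
  if (any(cfg$subtype_sizes < 0)) stop("subtype_sizes must be >= 0")
  rates <- c(cfg$missing_rate, cfg$detection_fail_rate,
             cfg$outcome$censor_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$effect_delta < 0 || cfg$effect_delta > 1) {
    stop("effect_delta must lie in [0, 1]")
  }
  if (any(cfg$subtype_sizes > 0) && cfg$n_signature_cpgs > cfg$n_cpgs) {
    stop("n_signature_cpgs exceeds n_cpgs")
  }
  n_needed <- cfg$n_signature_cpgs * sum(cfg$subtype_sizes > 0) +
    cfg$n_outcome_cpgs
  if (n_needed > cfg$n_cpgs) {
    stop("not enough CpGs for disjoint planted signatures (need ",
         n_needed, ", have ", cfg$n_cpgs, ")")
  }
  if (cfg$outcome$hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  invisible(cfg)
}

#' Simulate a methylation cohort with planted subtype signatures
#'
#' Generates a beta matrix, a sample sheet with demographics, mutation
#' flags and survival outcomes, a detection p-value matrix, and the ground
#' truth of every planted signal. Subtype signatures are disjoint CpG sets;
#' within each, half the CpGs are hypermethylated and half hypomethylated
#' by `effect_delta` in the owning subtype (means kept inside \[0, 1\] by
#' drawing hyper CpGs from the unmethylated background mode and vice
#' versa). Undefined samples carry a hidden true subtype drawn with
#' probability proportional to the subtype sizes; relapse samples are
#' noisy copies of a diagnostic sample from the same patient.
#'
#' @param config A [simulation_config()].
#' @return List with elements `beta` (with missingness injected),
#'   `detection_p`, `beta_complete` (pre-missingness), `sheet`, and
#'   `truth` (list: `signatures` subtype -> CpG IDs, `directions`,
#'   `outcome_cpgs`, `outcome_group` named 0/1 per patient).
#' @export
simulate_cohort <- function(config) {
  cfg <- if (inherits(config, "simulation_config")) config else
    do.call(simulation_config, config)
  validate_simulation_config(cfg)
  set.seed(cfg$seed)

  cpg_ids <- sprintf("cg%08d", seq_len(cfg$n_cpgs))
  mix <- cfg$background_mix
  is_low <- stats::runif(cfg$n_cpgs) < mix$p_low
  baseline <- numeric(cfg$n_cpgs)
  baseline[is_low] <- stats::rbeta(sum(is_low), mix$low_shape[1], mix$low_shape[2])
  baseline[!is_low] <- stats::rbeta(sum(!is_low), mix$high_shape[1], mix$high_shape[2])

  ## diagnostic samples: defined subtypes, then undefined with hidden truth
  subtypes <- names(cfg$subtype_sizes)
  true_subtype <- rep(subtypes, times = cfg$subtype_sizes)
  reported <- true_subtype
  if (cfg$n_undefined > 0) {
    hidden <- sample(subtypes, cfg$n_undefined, replace = TRUE,
                     prob = pmax(cfg$subtype_sizes, 0.5))
    true_subtype <- c(true_subtype, hidden)
    reported <- c(reported, rep("undefined", cfg$n_undefined))
  }
  n_diag <- length(true_subtype)
  patient_ids <- sprintf("AML%03d", seq_len(n_diag))

  ## planted signature CpGs: disjoint, direction-aware pools
  margin <- 2 * cfg$noise_sd
  hyper_pool <- which(baseline <= 1 - cfg$effect_delta - margin)
  hypo_pool <- which(baseline >= cfg$effect_delta + margin)
  owners <- subtypes[cfg$subtype_sizes > 0]
  n_hyper <- ceiling(cfg$n_signature_cpgs / 2)
  n_hypo <- cfg$n_signature_cpgs - n_hyper
  need_hyper <- n_hyper * length(owners) + ceiling(cfg$n_outcome_cpgs / 2)
  need_hypo <- n_hypo * length(owners) + floor(cfg$n_outcome_cpgs / 2)
  if (length(hyper_pool) < need_hyper || length(hypo_pool) < need_hypo) {
    stop("background pools too small for the requested signatures; ",
         "reduce effect_delta or n_signature_cpgs, or increase n_cpgs")
  }
  hyper_pick <- sample(hyper_pool, need_hyper)
  hypo_pick <- sample(setdiff(hypo_pool, hyper_pick), need_hypo)
  signatures <- list()
  directions <- list()
  hi <- 0; lo <- 0
  for (s in owners) {
    hy <- hyper_pick[hi + seq_len(n_hyper)]; hi <- hi + n_hyper
    ho <- hypo_pick[lo + seq_len(n_hypo)]; lo <- lo + n_hypo
    signatures[[s]] <- cpg_ids[c(hy, ho)]
    directions[[s]] <- c(rep(1, n_hyper), rep(-1, n_hypo))
  }
  out_hyper <- hyper_pick[hi + seq_len(ceiling(cfg$n_outcome_cpgs / 2))]
  out_hypo <- hypo_pick[lo + seq_len(floor(cfg$n_outcome_cpgs / 2))]
  outcome_idx <- c(out_hyper, out_hypo)
  outcome_dir <- c(rep(1, length(out_hyper)), rep(-1, length(out_hypo)))

  ## hidden outcome (risk) group, one per patient
  outcome_group <- stats::rbinom(n_diag, 1, 0.5)
  names(outcome_group) <- patient_ids

  ## mean structure for diagnostic samples
  mu <- matrix(baseline, cfg$n_cpgs, n_diag)
  for (s in owners) {
    cols <- which(true_subtype == s)
    if (!length(cols)) next
    rows <- match(signatures[[s]], cpg_ids)
    mu[rows, cols] <- mu[rows, cols] + directions[[s]] * cfg$effect_delta
  }
  if (length(outcome_idx)) {
    cols <- which(outcome_group == 1)
    mu[outcome_idx, cols] <- mu[outcome_idx, cols] +
      outcome_dir * cfg$effect_delta
  }

  values <- mu + stats::rnorm(length(mu), sd = cfg$noise_sd)

  ## relapse samples: noisy copies of sampled diagnostic columns
  relapse_of <- integer(0)
  if (cfg$n_relapse > 0) {
    relapse_of <- sample(n_diag, cfg$n_relapse,
                         replace = cfg$n_relapse > n_diag)
    rel <- values[, relapse_of, drop = FALSE] +
      stats::rnorm(cfg$n_cpgs * cfg$n_relapse, sd = cfg$relapse_noise_sd)
    values <- cbind(values, rel)
  }
  values <- pmin(pmax(values, 0), 1)

  sample_ids <- c(patient_ids,
                  if (cfg$n_relapse > 0) paste0(patient_ids[relapse_of], "_r"))
  dimnames(values) <- list(cpg_ids, sample_ids)

  ## sample sheet (per sample; relapse rows inherit patient covariates)
  pat_row <- c(seq_len(n_diag), relapse_of)
  age <- round(stats::runif(n_diag, 0, 18), 1)
  sex <- sample(c("F", "M"), n_diag, replace = TRUE)
  mut <- function() {
    f <- stats::runif(n_diag) < 0.15
    f[stats::runif(n_diag) < 0.27] <- NA   # incomplete mutation panel
    f
  }
  sheet <- data.frame(
    sample_id = sample_ids,
    patient_id = patient_ids[pat_row],
    true_subtype = true_subtype[pat_row],
    reported_subtype = reported[pat_row],
    timepoint = c(rep("diagnosis", n_diag),
                  rep("relapse", length(relapse_of))),
    age = age[pat_row], sex = sex[pat_row],
    CEBPA = mut()[pat_row], FLT3 = mut()[pat_row],
    NPM1 = mut()[pat_row], WT1 = mut()[pat_row],
    stringsAsFactors = FALSE
  )
  sheet <- simulate_outcomes(sheet, outcome_group[pat_row],
                             hazard_ratio = cfg$outcome$hazard_ratio,
                             baseline_hazard = cfg$outcome$baseline_hazard,
                             censor_rate = cfg$outcome$censor_rate,
                             seed = cfg$seed + 1L)
  ## relapse rows duplicate the diagnostic outcome of the same patient
  if (length(relapse_of)) {
    oc <- c("rfs_time", "rfs_event", "os_time", "os_event")
    sheet[n_diag + seq_along(relapse_of), oc] <- sheet[relapse_of, oc]
  }
  validate_sample_sheet(sheet)

  beta_complete <- beta_matrix(values)
  inj <- inject_missingness(beta_complete, cfg$missing_rate,
                            cfg$detection_fail_rate, seed = cfg$seed + 2L)
  list(beta = inj$beta, detection_p = inj$detection_p,
       beta_complete = beta_complete, sheet = sheet,
       truth = list(signatures = signatures, directions = directions,
                    outcome_cpgs = cpg_ids[outcome_idx],
                    outcome_group = outcome_group))
}

#' Draw survival outcomes with a planted proportional-hazards group effect
#'
#' Event times are exponential with hazard `baseline_hazard *
#' hazard_ratio^group`; censoring is administrative (independent of the
#' risk group), with an exponential rate calibrated so the baseline group
#' is censored at `censor_rate` (the high-risk group is censored less
#' often, as in real follow-up).
#' Relapse-free survival uses the given hazard; overall survival uses a
#' 0.6x baseline hazard with the same group effect (death is rarer than
#' relapse but tracks the same planted risk group).
#'
#' @param sheet Sample sheet to populate (one row per sample).
#' @param group_labels Binary (0/1 or logical) per-sample risk group.
#' @param hazard_ratio Hazard ratio of group 1 vs group 0; must be > 0.
#' @param baseline_hazard Events per month in group 0.
#' @param censor_rate Expected fraction of censored observations in \[0, 1\].
#' @param seed Optional integer seed.
#' @return `sheet` with `rfs_time`, `rfs_event`, `os_time`, `os_event`.
#' @export
simulate_outcomes <- function(sheet, group_labels, hazard_ratio,
                              baseline_hazard = 0.02, censor_rate = 0.3,
                              seed = NULL) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  g <- as.integer(group_labels)
  if (length(g) != nrow(sheet) || !all(g %in% c(0L, 1L))) {
    stop("group_labels must be binary, one per sample")
  }
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(h0) {
    h <- h0 * hazard_ratio^g
    t_event <- stats::rexp(length(g), h)
    if (censor_rate == 0) {
      list(time = t_event, event = rep(1L, length(g)))
    } else {
      ## administrative censoring, independent of group risk; the rate is
      ## calibrated so the baseline group is censored at censor_rate
      hc <- h0 * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(length(g), hc)
      list(time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens))
    }
  }
  rfs <- draw(baseline_hazard)
  os <- draw(baseline_hazard * 0.6)
  sheet$rfs_time <- round(rfs$time, 2)
  sheet$rfs_event <- rfs$event
  sheet$os_time <- round(pmax(os$time, rfs$time * 0.5), 2)
  sheet$os_event <- os$event
  sheet
}

#' Inject missing values and detection p-value failures
#'
#' Entries fail detection (p drawn uniformly in \[0.05, 1\]) at rate
#' `detection_fail_rate`; all other p-values are drawn uniformly in
#' [0, 0.05). Independently, entries are set missing (`NA`) at rate
#' `missing_rate`. Detection failures are *not* pre-masked here; masking
#' is the job of [mask_low_confidence()].
#'
#' @param beta Beta matrix.
#' @param missing_rate Fraction of entries set to `NA`.
#' @param detection_fail_rate Fraction of entries with detection p >= 0.05.
#' @param seed Optional integer seed.
#' @return List with `beta` (missingness applied) and `detection_p`.
#' @export
inject_missingness <- function(beta, missing_rate, detection_fail_rate,
                               seed = NULL) {
  if (missing_rate < 0 || missing_rate > 1 ||
      detection_fail_rate < 0 || detection_fail_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(beta)
  n <- length(m)
  fail <- stats::runif(n) < detection_fail_rate
  p <- stats::runif(n, 0, 0.05 - 1e-12)
  p[fail] <- stats::runif(sum(fail), 0.05, 1)
  detection_p <- matrix(p, nrow(m), ncol(m), dimnames = dimnames(m))
  m[stats::runif(n) < missing_rate] <- NA_real_
  list(beta = beta_matrix(m), detection_p = detection_p)
}

#' Write the planted-truth signature map as two-column TSV
#' @param truth Truth list from [simulate_cohort()].
#' @param path Output file path.
#' @export
write_truth_map <- function(truth, path) {
  df <- data.frame(
    subtype = rep(names(truth$signatures), lengths(truth$signatures)),
    cpg_id = unlist(truth$signatures, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (length(truth$outcome_cpgs)) {
    df <- rbind(df, data.frame(subtype = "outcome_group",
                               cpg_id = truth$outcome_cpgs))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
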