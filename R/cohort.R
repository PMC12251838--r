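#' Synthetic cohorts of swimmers
#'
#' Builds sets of synthetic subjects from phenotype specifications (each
#' phenotype a distribution over kinematic-template settings), computes
#' every subject's swimming-parameter vector from their ground-truth
#' kinematics, and keeps the phenotype labels as planted truth for
#' validating the clustering stage.
#'
#' @name cohort
NULL

#' Built-in phenotype presets
#'
#' Three phenotypes: `healthy` (no impairment), `cluster1` (mild range
#' deficit, low variability, moderate speed loss) and `cluster2` (strong
#' ankle/knee range deficit, high phase-shift and stroke-duration
#' variability, pronounced asymmetry, slow). Deficit directions follow
#' the clinical pattern of impaired breaststroke: distal joints most
#' affected, timing more variable.
#'
#' @return named list of phenotype specifications.
#' @export
phenotype_presets <- function() {
  list(
    healthy = list(
      velocity = c(0.50, 0.05), duration = c(2.0, 0.15),
      duration_cv = c(0.04, 0.01),
      rom = list(knee = c(1.00, 0.05), hip = c(1.00, 0.05),
                 hip_abd = c(1.00, 0.05), ankle = c(1.00, 0.05)),
      impaired_leg_scale = 1.0,
      lag_between = 1.0, lag_jitter = 1.0, cycle_jitter = 2.0),
    cluster1 = list(
      velocity = c(0.35, 0.05), duration = c(2.2, 0.2),
      duration_cv = c(0.05, 0.01),
      rom = list(knee = c(0.85, 0.05), hip = c(0.95, 0.05),
                 hip_abd = c(0.95, 0.05), ankle = c(0.85, 0.05)),
      impaired_leg_scale = 0.95,
      lag_between = 2.0, lag_jitter = 2.0, cycle_jitter = 3.0),
    cluster2 = list(
      velocity = c(0.18, 0.04), duration = c(2.6, 0.3),
      duration_cv = c(0.13, 0.02),
      rom = list(knee = c(0.65, 0.07), hip = c(0.85, 0.07),
                 hip_abd = c(0.90, 0.07), ankle = c(0.55, 0.07)),
      impaired_leg_scale = 0.85,
      lag_between = 6.0, lag_jitter = 8.0, cycle_jitter = 6.0))
}

# draw one subject's template from a phenotype specification
draw_subject_template <- function(ph) {
  rn <- function(ms) ms[1] + ms[2] * stats::rnorm(1)
  joints <- c("knee", "hip", "hip_abd", "ankle")
  scale_R <- vapply(joints, function(j) max(0.05, rn(ph$rom[[j]])), numeric(1))
  scale_L <- scale_R * ph$impaired_leg_scale   # more-impaired leg: left
  tmpl <- breaststroke_template(
    stroke_duration = max(0.8, rn(ph$duration)),
    rom_scale = list(L = scale_L, R = scale_R),
    phase_lag = max(-45, min(45, ph$lag_between * stats::rnorm(1))),
    phase_lag_jitter = ph$lag_jitter,
    duration_cv = max(0, rn(ph$duration_cv)),
    cycle_jitter = ph$cycle_jitter)
  list(template = tmpl, velocity = max(0.05, rn(ph$velocity)))
}

#' Swimming parameters of one synthetic subject
#'
#' Computes the full parameter vector from a subject's ground-truth
#' kinematics (exact events, noiseless angles) via the parameters
#' module. This is the fast cohort path; the IMU forward simulation and
#' estimation pipeline are validated separately.
#'
#' @param kin a [generate_kinematics()] result.
#' @param reference centered reference cyclograms
#'   ([reference_cyclograms()]); default unimpaired template.
#' @return named numeric parameter vector.
#' @export
subject_parameters <- function(kin, reference = reference_cyclograms()) {
  sp <- swim_parameter_set(kin$angles, kin$events, lap = kin$lap,
                           reference = reference)
  sp$params
}

#' Generate a synthetic cohort
#'
#' @param scenario named list `phenotype_name = n_subjects`, using
#'   phenotypes from [phenotype_presets()] (or a custom list passed via
#'   `presets`).
#' @param seed integer RNG seed; every subject is reproducible from
#'   (scenario, seed).
#' @param n_strokes strokes per subject (default 12).
#' @param rate kinematics sampling rate, Hz (default 50; parameters are
#'   computed from 100-point normalized cycles, so the full 200 Hz is
#'   not needed here).
#' @param presets phenotype specifications (default
#'   [phenotype_presets()]).
#' @return list: `params` (subjects x parameters matrix), `labels`
#'   (phenotype per subject), `subjects` (templates and velocities).
#' @export
cohort_scenarios <- function(scenario, seed = 1, n_strokes = 12, rate = 50,
                             presets = phenotype_presets()) {
  stopifnot(all(names(scenario) %in% names(presets)))
  set.seed(seed)
  ref <- reference_cyclograms()
  subjects <- list()
  labels <- character(0)
  rows <- list()
  for (ph_name in names(scenario)) {
    ph <- presets[[ph_name]]
    for (s in seq_len(scenario[[ph_name]])) {
      sub <- draw_subject_template(ph)
      kin <- generate_kinematics(sub$template, n_strokes = n_strokes,
                                 seed = sample.int(.Machine$integer.max, 1),
                                 rate = rate, velocity = sub$velocity)
      rows[[length(rows) + 1L]] <- subject_parameters(kin, reference = ref)
      labels <- c(labels, ph_name)
      subjects[[length(subjects) + 1L]] <- sub
    }
  }
  params <- do.call(rbind, rows)
  rownames(params) <- sprintf("S%02d", seq_len(nrow(params)))
  list(params = params, labels = labels, subjects = subjects)
}

#' Phenotype clustering of a cohort parameter matrix
#'
#' Convenience chain: standardize parameters, PCA to the target
#' cumulative explained variance, k-means with diagnostics.
#'
#' @param params subjects x parameters matrix.
#' @param target_variance cumulative explained-variance target
#'   (default 0.70).
#' @param k_range candidate cluster counts (default 2:6).
#' @param seed RNG seed.
#' @return list `pca`, `clustering`, `scaled`.
#' @export
cluster_cohort <- function(params, target_variance = 0.70, k_range = 2:6,
                           seed = 1) {
  keep <- apply(params, 2, function(x) !any(is.na(x)) && stats::sd(x) > 0)
  scaled <- scale(params[, keep, drop = FALSE])
  pca <- pca_reduce(scaled, target_variance = target_variance)
  cl <- kmeans_select(pca$scores, k_range = k_range, seed = seed)
  list(pca = pca, clustering = cl, scaled = scaled)
}
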