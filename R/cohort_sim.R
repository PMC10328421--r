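#' Parameters for cohort simulation
#'
#' Defaults encode the covariate structure and effect sizes of the
#' case-control cohort the analysis targets: 64 ASD vs 72 non-ASD
#' neuropsychiatric controls, male fractions 0.672 / 0.556, severity levels
#' distributed 10/18/36, a lognormal baseline WM-PVS volume anchored at the
#' female median (425 voxels, log-sd 0.6 from the printed IQR), and
#' multiplicative volume effects for male sex (1.4), young age within ASD
#' (1.9 below 4 years), severity (1.25 per level above 1) and insomnia.
#'
#' @param n_asd,n_control group sizes (>= 0, not both 0).
#' @param male_fraction named fractions for `asd` and `control`.
#' @param age_range years, uniform sampling range.
#' @param severity_distribution probabilities over severity levels 1-3
#'   (ASD only).
#' @param baseline_log_volume_mean,baseline_log_volume_sd lognormal
#'   parameters of the reference (female, older, level-1, no insomnia)
#'   WM-PVS voxel-count volume.
#' @param effect_male,effect_young_asd,effect_severity_per_level,effect_insomnia
#'   multiplicative volume factors (> 0). `effect_young_asd` applies to ASD
#'   subjects younger than 4 years.
#' @param comorbidity_rates list of per-group rates (`asd`, `control`) for
#'   `adhd`, `epilepsy`, `insomnia`, `id`.
#' @param count_per_volume latent max-slice count per voxel of volume.
#' @param grade_noise_sd lognormal sd of the latent count around its
#'   volume-proportional mean (chosen so adjacent-grade confusion is about
#'   15%).
#' @param seed integer RNG seed.
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_asd = 64, n_control = 72,
                              male_fraction = c(asd = 0.672, control = 0.556),
                              age_range = c(1, 10),
                              severity_distribution = c(10, 18, 36) / 64,
                              baseline_log_volume_mean = log(425),
                              baseline_log_volume_sd = 0.6,
                              effect_male = 1.4,
                              effect_young_asd = 1.9,
                              effect_severity_per_level = 1.25,
                              effect_insomnia = 1.3,
                              comorbidity_rates = list(
                                adhd = c(asd = 10 / 64, control = 3 / 72),
                                epilepsy = c(asd = 9 / 64, control = 8 / 72),
                                insomnia = c(asd = 24 / 64, control = 0),
                                id = c(asd = 0.40, control = 0.19)),
                              count_per_volume = 1 / 20,
                              grade_noise_sd = 0.25,
                              seed = 1L) {
  if (n_asd < 0 || n_control < 0) stop("group sizes must be >= 0", call. = FALSE)
  if (n_asd + n_control == 0)
    stop("at least one group must be non-empty", call. = FALSE)
  stopifnot(all(male_fraction >= 0 & male_fraction <= 1),
            all(severity_distribution >= 0),
            baseline_log_volume_sd >= 0)
  effects <- c(effect_male, effect_young_asd, effect_severity_per_level,
               effect_insomnia)
  if (any(effects <= 0))
    stop("multiplicative effects must be > 0", call. = FALSE)
  severity_distribution <- severity_distribution / sum(severity_distribution)
  structure(list(n_asd = as.integer(n_asd), n_control = as.integer(n_control),
                 male_fraction = male_fraction, age_range = age_range,
                 severity_distribution = severity_distribution,
                 baseline_log_volume_mean = baseline_log_volume_mean,
                 baseline_log_volume_sd = baseline_log_volume_sd,
                 effect_male = effect_male,
                 effect_young_asd = effect_young_asd,
                 effect_severity_per_level = effect_severity_per_level,
                 effect_insomnia = effect_insomnia,
                 comorbidity_rates = comorbidity_rates,
                 count_per_volume = count_per_volume,
                 grade_noise_sd = grade_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_sim_params")
}

#' Simulate a subject-level cohort table
#'
#' Each record carries group, sex, age, severity (ASD only), comorbidity
#' flags, a WM-PVS voxel-count volume drawn log-normally with the configured
#' multiplicative effects, and a max-slice count / grade derived from the
#' volume by a monotone map with lognormal noise, so grade and volume are
#' positively correlated by construction.
#'
#' @param params a [cohort_sim_params()].
#' @return A data.frame with one row per subject: `id`, `group`, `sex`,
#'   `age_years`, `asd_type`, `severity`, `adhd`, `epilepsy`, `insomnia`,
#'   `id_flag`, `pvs_volume_voxels`, `max_slice_count`, `pvs_grade`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  with_seed(params$seed, {
    n <- params$n_asd + params$n_control
    group <- c(rep("ASD", params$n_asd), rep("NP-non-ASD", params$n_control))
    is_asd <- group == "ASD"
    sex <- ifelse(stats::runif(n) < ifelse(is_asd,
                                           params$male_fraction["asd"],
                                           params$male_fraction["control"]),
                  "M", "F")
    age <- stats::runif(n, params$age_range[1], params$age_range[2])
    severity <- rep(NA_integer_, n)
    if (params$n_asd > 0)
      severity[is_asd] <- sample.int(3, params$n_asd, replace = TRUE,
                                     prob = params$severity_distribution)
    asd_type <- ifelse(is_asd,
                       ifelse(stats::runif(n) < 0.844, "complex", "essential"),
                       "none")
    flag <- function(name) {
      r <- params$comorbidity_rates[[name]]
      stats::runif(n) < ifelse(is_asd, r["asd"], r["control"])
    }
    adhd <- flag("adhd"); epilepsy <- flag("epilepsy")
    insomnia <- flag("insomnia"); id_flag <- flag("id")

    lmu <- params$baseline_log_volume_mean +
      log(params$effect_male) * (sex == "M") +
      log(params$effect_young_asd) * (is_asd & age < 4) +
      log(params$effect_severity_per_level) *
        ifelse(is.na(severity), 0, severity - 1) +
      log(params$effect_insomnia) * insomnia
    volume <- round(exp(stats::rnorm(n, lmu, params$baseline_log_volume_sd)))
    volume <- pmax(volume, 1)

    latent <- params$count_per_volume * volume *
      exp(stats::rnorm(n, 0, params$grade_noise_sd))
    max_count <- pmax(round(latent), 0)
    grade <- vapply(max_count, grade_from_max_count, integer(1))

    data.frame(id = sprintf("S%03d", seq_len(n)),
               group = group, sex = sex,
               age_years = round(age, 1),
               asd_type = asd_type, severity = severity,
               adhd = adhd, epilepsy = epilepsy, insomnia = insomnia,
               id_flag = id_flag,
               pvs_volume_voxels = volume,
               max_slice_count = max_count,
               pvs_grade = grade,
               stringsAsFactors = FALSE)
  })
}

#' Write a cohort table as CSV
#' @param cohort data.frame from [generate_cohort()] (or compatible).
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#' @param path CSV with the column dictionary of [generate_cohort()].
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(tab$id)) stop("duplicate subject ids", call. = FALSE)
  if (any(is.na(tab$group)) || any(is.na(tab$sex)))
    stop("missing group/sex entries", call. = FALSE)
  tab
}
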