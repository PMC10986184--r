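#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of [generate_cohort()] with defaults that emulate the
#' study conditions the pipeline was designed for: six clinical phenotypes
#' with sizes 45/41/32/17/10/8, a 152-region parcellation split into two
#' hemispheric blocks, sparse symmetric GFA matrices whose retained tracts
#' are present in roughly 80.5% of participants (between-tract SD 11.9%),
#' phenotype-specific white-matter degeneration, linear age and sex
#' effects, grey-matter volumes positively coupled to incident-tract GFA
#' with group-dependent slopes, and group-shifted global FA/MD/ISO.
#'
#' @param n_per_phenotype Named integer vector of participants per
#'   phenotype (`CN`, `aAD`, `lvPPA`, `PCA`, `bvAD`, `CBS`).
#' @param region_count Number of parcellation regions (>= 4).
#' @param effect_spec List of effect entries; each entry is a list with
#'   `phenotype` (a phenotype code or the group shorthand `"amnestic"` /
#'   `"non-amnestic"`), `shift` (mean GFA shift in control-SD units, i.e.
#'   multiples of `noise_sd`), and a tract selector: either `tracts`
#'   (explicit tract identifiers) or `n` plus `offset` selecting tracts
#'   ranked by presence probability (descending), positions
#'   `offset + 1 ... offset + n`. Shifts on the same tract accumulate.
#'   `NULL` selects the default degeneration pattern; `list()` disables
#'   all effects.
#' @param presence_mean,presence_sd Mean and SD of the per-tract presence
#'   probability (Beta-distributed across tracts).
#' @param gm_coupling_slopes Named numeric vector (per group) of slopes
#'   coupling grey-matter volume to the participant's mean incident-tract
#'   GFA deviation (in control-SD units of GFA; volume units via
#'   `gm_scale`).
#' @param age_effect GFA change per year of age (applied around age 65).
#' @param sex_effect GFA shift for male relative to female participants.
#' @param noise_sd Residual SD of tract GFA in GFA units (>= 0). Also the
#'   unit in which `effect_spec` shifts are expressed.
#' @param severity_effect Relative scaling of a patient's injected tract
#'   shifts per SD of latent disease severity (mean shift preserved);
#'   couples degeneration to within-group severity.
#' @param mmse_severity_slope MMSE points lost per SD of latent severity
#'   within patient phenotypes, so the MMSE covariate carries real
#'   within-group disease-progression signal.
#' @param p_within,p_between Probability that a within-block /
#'   between-block region pair belongs to the tract universe.
#' @param low_coverage_regions Number of regions whose incident-tract
#'   presence is suppressed so that they frequently occur as islands
#'   (emulating regions excluded by quality control); the last
#'   `low_coverage_regions / 2` regions of each hemispheric block are used.
#' @param island_spec Named integer vector: region label -> number of
#'   scans in which the region is forced to be an island (all incident
#'   tracts missing).
#' @param presence_group_coupling Additive shift of presence probability
#'   for patient groups (stress-test switch; default 0 keeps missingness
#'   independent of group).
#' @param missing_mmse,missing_duration,missing_apoe Named integer vectors
#'   (per phenotype) of participants with missing MMSE / disease duration /
#'   APOE genotype.
#' @param unconfirmed_biomarkers Named integer vector (per phenotype) of
#'   patients without biomarker confirmation (used by subset analyses).
#' @param micro_means List with numeric vectors `fa`, `md`, `iso`, each
#'   named by group: generating means of the global white-matter
#'   microstructure metrics.
#' @param micro_sds Numeric vector with elements `fa`, `md`, `iso`.
#' @param gm_scale SD of regional grey-matter volume noise (mm^3).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_per_phenotype = c(
                            CN = 45L, aAD = 41L, lvPPA = 32L,
                            PCA = 17L, bvAD = 10L, CBS = 8L
                          ),
                          region_count = 152L,
                          effect_spec = NULL,
                          presence_mean = 0.805,
                          presence_sd = 0.119,
                          gm_coupling_slopes = c(
                            CN = 0.03, amnestic = 0.08, `non-amnestic` = 0.08
                          ),
                          age_effect = -0.0012,
                          sex_effect = 0.008,
                          noise_sd = 0.05,
                          severity_effect = 0.35,
                          mmse_severity_slope = 2.0,
                          p_within = 0.10,
                          p_between = 0.008,
                          low_coverage_regions = 4L,
                          island_spec = NULL,
                          presence_group_coupling = 0,
                          missing_mmse = c(CN = 4L, aAD = 2L),
                          missing_duration = c(lvPPA = 1L),
                          missing_apoe = c(
                            CN = 33L, aAD = 11L, lvPPA = 1L, CBS = 4L
                          ),
                          unconfirmed_biomarkers = c(aAD = 11L, lvPPA = 3L),
                          micro_means = list(
                            fa = c(CN = 0.425, amnestic = 0.415, `non-amnestic` = 0.395),
                            md = c(CN = 7.0e-4, amnestic = 7.2e-4, `non-amnestic` = 7.6e-4),
                            iso = c(CN = 0.150, amnestic = 0.160, `non-amnestic` = 0.175)
                          ),
                          micro_sds = c(fa = 0.015, md = 4e-5, iso = 0.012),
                          gm_scale = 800,
                          seed = 1L) {
  if (is.null(effect_spec)) effect_spec <- default_effect_spec()
  cfg <- list(
    n_per_phenotype = n_per_phenotype, region_count = as.integer(region_count),
    effect_spec = effect_spec, presence_mean = presence_mean,
    presence_sd = presence_sd, gm_coupling_slopes = gm_coupling_slopes,
    age_effect = age_effect, sex_effect = sex_effect, noise_sd = noise_sd,
    severity_effect = severity_effect, mmse_severity_slope = mmse_severity_slope,
    p_within = p_within, p_between = p_between,
    low_coverage_regions = as.integer(low_coverage_regions),
    island_spec = island_spec,
    presence_group_coupling = presence_group_coupling,
    missing_mmse = missing_mmse, missing_duration = missing_duration,
    missing_apoe = missing_apoe,
    unconfirmed_biomarkers = unconfirmed_biomarkers,
    micro_means = micro_means, micro_sds = micro_sds, gm_scale = gm_scale,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

# Default degeneration pattern: a shared non-amnestic set, an amnestic
# set, and phenotype-specific sets, all selected by presence rank so the
# affected tracts survive the coverage filter.
default_effect_spec <- function() {
  c(
    list(list(phenotype = "non-amnestic", n = 60L, offset = 0L, shift = -0.9)),
    list(list(phenotype = "aAD", n = 40L, offset = 140L, shift = -0.7)),
    list(
      list(phenotype = "lvPPA", n = 25L, offset = 60L, shift = -0.8),
      list(phenotype = "PCA", n = 25L, offset = 80L, shift = -0.8),
      list(phenotype = "bvAD", n = 20L, offset = 105L, shift = -0.8),
      list(phenotype = "CBS", n = 15L, offset = 125L, shift = -0.8)
    )
  )
}

validate_cohort_config <- function(cfg) {
  n <- cfg$n_per_phenotype
  if (is.null(names(n)) || !all(names(n) %in% PHENOTYPE_LEVELS)) {
    stop("n_per_phenotype must be named with phenotype codes")
  }
  if (any(n < 0)) stop("phenotype counts must be >= 0")
  if (cfg$region_count < 4L) stop("region_count must be >= 4")
  if (cfg$presence_mean <= 0 || cfg$presence_mean > 1) {
    stop("presence_mean must lie in (0, 1]")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  ok_names <- c(PHENOTYPE_LEVELS, "amnestic", "non-amnestic")
  for (eff in cfg$effect_spec) {
    if (!is.list(eff) || is.null(eff$phenotype) || is.null(eff$shift)) {
      stop("each effect_spec entry needs 'phenotype' and 'shift'")
    }
    if (!eff$phenotype %in% ok_names) {
      stop("invalid phenotype name in effect_spec: ", eff$phenotype)
    }
    if (is.null(eff$tracts) && is.null(eff$n)) {
      stop("effect_spec entry needs a tract selector ('tracts' or 'n')")
    }
  }
  invisible(cfg)
}
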