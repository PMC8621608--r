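#' Simulation configuration for a synthetic trio cohort
#'
#' Bundles every knob of the synthetic-cohort generator: the genome model,
#' the two probe tiers, the dye-swap noise level, per-group de novo CNV
#' rates, the CNV size distribution, inherited (founder) CNV load, and the
#' Weibull lifespan model with multiplicative hazards.
#'
#' Defaults emulate the study conditions the package is designed around:
#' two F1 groups of 156 (non-irradiated) and 142 (irradiated) mice, a
#' first-tier probe every 2 kb and a second-tier (confirmation) probe every
#' 0.1 kb, de novo CNV rates calibrated so that roughly 7% of control and
#' 20% of irradiated F1 mice carry at least one de novo deletion, CNV sizes
#' log-uniform between 150 bp and 2 Mb, and lifespans with a reference-group
#' (male, non-irradiated, CNV-free) mean of 914 days, shorter for females,
#' irradiated mice and CNV carriers.
#'
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   identical cohort, signals and plates.
#' @param n_f1_per_group Named integer vector, F1 mice per exposure group
#'   (`non_irradiated`, `irradiated`).
#' @param n_f1_per_family Number of F1 offspring per sire x dam family.
#' @param n_chromosomes,chromosome_length Synthetic genome: number of
#'   chromosomes and length of each in bp.
#' @param first_tier_spacing,second_tier_spacing Probe spacing in bp of the
#'   genome-wide screening tier and the dense confirmation tier.
#' @param noise_sd Standard deviation of the additive Gaussian noise on each
#'   log2 ratio, independently per probe and per hybridization.
#' @param denovo_rate_non_irradiated,denovo_rate_irradiated Expected number
#'   of de novo CNVs per F1 mouse (Poisson), by group.
#' @param duplication_fraction Probability that a planted CNV is a
#'   single-copy duplication rather than a hemizygous deletion.
#' @param size_log10_range Length-2 numeric, log10 bounds (bp) of the
#'   log-uniform CNV size distribution.
#' @param inherited_cnv_rate Expected number of standing CNVs per founder
#'   (sire or dam), each transmitted to each offspring with probability 1/2.
#' @param min_cnv_separation Minimum bp separation enforced between planted
#'   CNV intervals within one family (inherited copies of a founder CNV
#'   excepted, as they share its locus by descent). Real germline CNVs
#'   virtually never coincide within a family except by descent; keeping
#'   the default above the family-analysis matching window preserves that
#'   property on the small synthetic genome.
#' @param lifespan_shape,lifespan_scale Weibull shape and scale (days) of the
#'   baseline (reference stratum) lifespan distribution.
#' @param hazard_ratios Named positive numeric vector of multiplicative
#'   hazards applied to the coded-1 level of each factor: `sex` (female),
#'   `irradiation` (irradiated), `cnv` (carries at least one de novo CNV).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes = 2, chromosome_length = 5e6)
#' cfg$first_tier_spacing
#' @export
sim_config <- function(seed = 1L,
                       n_f1_per_group = c(non_irradiated = 156L, irradiated = 142L),
                       n_f1_per_family = 4L,
                       n_chromosomes = 5L,
                       chromosome_length = 2e7,
                       first_tier_spacing = 2000,
                       second_tier_spacing = 100,
                       noise_sd = 0.15,
                       denovo_rate_non_irradiated = 0.074,
                       denovo_rate_irradiated = 0.23,
                       duplication_fraction = 0.1,
                       size_log10_range = c(log10(150), log10(2e6)),
                       inherited_cnv_rate = 1,
                       min_cnv_separation = 20000,
                       lifespan_shape = 7,
                       lifespan_scale = 914 / gamma(1 + 1 / 7),
                       hazard_ratios = c(sex = 1.972, irradiation = 1.175, cnv = 1.435)) {
  if (length(n_f1_per_group) != 2L) {
    abort("`n_f1_per_group` must have two entries: non_irradiated and irradiated.")
  }
  if (is.null(names(n_f1_per_group))) {
    names(n_f1_per_group) <- c("non_irradiated", "irradiated")
  }
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    all(n_f1_per_group >= 0), n_f1_per_family >= 1,
    n_chromosomes >= 1, chromosome_length > 0
  )
  if (first_tier_spacing <= 0 || second_tier_spacing <= 0) {
    abort("Probe spacings must be positive.")
  }
  if (second_tier_spacing >= first_tier_spacing) {
    abort("`second_tier_spacing` must be smaller than `first_tier_spacing`.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (denovo_rate_non_irradiated < 0 || denovo_rate_irradiated < 0 ||
      inherited_cnv_rate < 0) {
    abort("CNV rates must be non-negative.")
  }
  if (duplication_fraction < 0 || duplication_fraction > 1) {
    abort("`duplication_fraction` must lie in [0, 1].")
  }
  if (length(size_log10_range) != 2L || diff(size_log10_range) < 0) {
    abort("`size_log10_range` must be an increasing length-2 numeric.")
  }
  if (min_cnv_separation < 0) {
    abort("`min_cnv_separation` must be non-negative.")
  }
  if (lifespan_shape <= 0 || lifespan_scale <= 0) {
    abort("Lifespan Weibull parameters must be positive.")
  }
  required_hr <- c("sex", "irradiation", "cnv")
  if (!all(required_hr %in% names(hazard_ratios)) || any(hazard_ratios <= 0)) {
    abort("`hazard_ratios` must be positive and named sex, irradiation, cnv.")
  }

  structure(
    list(
      seed = as.integer(seed),
      n_f1_per_group = setNames(as.integer(n_f1_per_group),
                                c("non_irradiated", "irradiated")),
      n_f1_per_family = as.integer(n_f1_per_family),
      n_chromosomes = as.integer(n_chromosomes),
      chromosome_length = chromosome_length,
      first_tier_spacing = first_tier_spacing,
      second_tier_spacing = second_tier_spacing,
      noise_sd = noise_sd,
      denovo_rate_non_irradiated = denovo_rate_non_irradiated,
      denovo_rate_irradiated = denovo_rate_irradiated,
      duplication_fraction = duplication_fraction,
      size_log10_range = size_log10_range,
      inherited_cnv_rate = inherited_cnv_rate,
      min_cnv_separation = min_cnv_separation,
      lifespan_shape = lifespan_shape,
      lifespan_scale = lifespan_scale,
      hazard_ratios = hazard_ratios[required_hr]
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp\n",
              x$n_chromosomes, format(x$chromosome_length, big.mark = ",")))
  cat(sprintf("  probe tiers: %s bp / %s bp spacing\n",
              format(x$first_tier_spacing), format(x$second_tier_spacing)))
  cat(sprintf("  F1 mice: %d non-irradiated + %d irradiated (families of %d)\n",
              x$n_f1_per_group[["non_irradiated"]],
              x$n_f1_per_group[["irradiated"]], x$n_f1_per_family))
  cat(sprintf("  de novo rates: %.3f / %.3f per F1; duplication fraction %.2f\n",
              x$denovo_rate_non_irradiated, x$denovo_rate_irradiated,
              x$duplication_fraction))
  cat(sprintf("  noise sd: %.3f log2 units; seed %d\n", x$noise_sd, x$seed))
  invisible(x)
}

chromosome_names <- function(config) {
  paste0("chr", seq_len(config$n_chromosomes))
}
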