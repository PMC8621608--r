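#' Lay out the probe map for one tier of the array design
#'
#' Probes are placed deterministically on a regular grid: every
#' `first_tier_spacing` bp for the genome-wide screening tier, every
#' `second_tier_spacing` bp for the dense confirmation tier. Positions are
#' 1-based; the first probe of a chromosome sits at one spacing from the
#' start, so a 10 Mb chromosome at 2 kb spacing carries exactly 5000 probes.
#'
#' @param config A [sim_config()].
#' @param tier `"first"` or `"second"`.
#' @param regions Optional tibble (`chrom`, `start`, `end`) restricting the
#'   dense tier to windows of interest; mainly used by [run_cnv_pipeline()]
#'   to avoid materialising the full confirmation grid.
#' @return A probe-map tibble with columns `probe_id`, `chrom`, `pos`,
#'   `tier`, sorted by chromosome and position.
#' @examples
#' map <- simulate_probe_map(sim_config(n_chromosomes = 1,
#'                                      chromosome_length = 1e6))
#' nrow(map) # 500 probes at 2 kb spacing
#' @export
simulate_probe_map <- function(config, tier = c("first", "second"),
                               regions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tier <- match.arg(tier)
  spacing <- if (tier == "first") config$first_tier_spacing else config$second_tier_spacing
  if (spacing > config$chromosome_length) {
    abort("Probe spacing exceeds the chromosome length; no probes can be placed.")
  }
  chroms <- chromosome_names(config)
  map <- purrr::map_dfr(chroms, function(ch) {
    pos <- seq(spacing, config$chromosome_length, by = spacing)
    tibble(chrom = ch, pos = pos)
  })
  if (!is.null(regions)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
    keep <- rep(FALSE, nrow(map))
    for (i in seq_len(nrow(regions))) {
      keep <- keep | (map$chrom == regions$chrom[i] &
                        map$pos >= regions$start[i] &
                        map$pos <= regions$end[i])
    }
    map <- map[keep, ]
  }
  prefix <- if (tier == "first") "p1" else "p2"
  map %>%
    mutate(
      probe_id = sprintf("%s_%s_%010d", prefix, .data$chrom, .data$pos),
      tier = tier
    ) %>%
    select("probe_id", "chrom", "pos", "tier") %>%
    arrange(.data$chrom, .data$pos)
}

#' Simulate a trio cohort with planted inherited and de novo CNVs
#'
#' Builds sire x dam families per exposure group, plants standing (founder)
#' CNVs that are transmitted to each offspring with probability 1/2, draws
#' per-F1 de novo CNV counts from a Poisson with the group rate, and draws
#' lifespans from a Weibull baseline with multiplicative hazards for sex,
#' irradiation and de novo CNV carriage.
#'
#' CNV sizes are log-uniform within `config$size_log10_range`; the interval
#' convention is 1-based with size `end - start`. A hemizygous deletion has
#' copy number 1, a duplication copy number 3, on a diploid background.
#'
#' @param config A [sim_config()].
#' @return An object of class `cnv_cohort`: a list with
#'   * `mice`: tibble (`family`, `mouse_id`, `role`, `sex`, `group`,
#'     `lifespan_days`),
#'   * `cnvs`: ground-truth tibble (`mouse_id`, `chrom`, `start`, `end`,
#'     `size`, `kind`, `origin`, `copy_number`),
#'   * `config`: the configuration used.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 7,
#'                                      n_f1_per_group = c(8, 8),
#'                                      n_chromosomes = 2,
#'                                      chromosome_length = 5e6))
#' dplyr::count(cohort$mice, role)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    mice <- build_pedigree(config)
    cnvs <- plant_cnvs(mice, config)
    mice <- draw_lifespans(mice, cnvs, config)
    structure(list(mice = mice, cnvs = cnvs, config = config),
              class = "cnv_cohort")
  })
}

#' @export
print.cnv_cohort <- function(x, ...) {
  n_f1 <- sum(x$mice$role == "f1")
  cat(sprintf("<cnv_cohort> %d mice (%d F1) in %d families; %d planted CNVs (%d de novo)\n",
              nrow(x$mice), n_f1, length(unique(x$mice$family)), nrow(x$cnvs),
              sum(x$cnvs$origin == "de_novo")))
  invisible(x)
}

build_pedigree <- function(config) {
  purrr::map_dfr(names(config$n_f1_per_group), function(group) {
    n_f1 <- config$n_f1_per_group[[group]]
    if (n_f1 == 0L) return(tibble())
    n_fam <- ceiling(n_f1 / config$n_f1_per_family)
    fam_sizes <- rep(config$n_f1_per_family, n_fam)
    fam_sizes[n_fam] <- n_f1 - config$n_f1_per_family * (n_fam - 1L)
    gtag <- if (group == "irradiated") "irr" else "ctl"
    purrr::map_dfr(seq_len(n_fam), function(i) {
      fam <- sprintf("%s_fam%03d", gtag, i)
      bind_rows(
        tibble(family = fam, mouse_id = paste0(fam, "_sire"),
               role = "sire", sex = "M", group = group),
        tibble(family = fam, mouse_id = paste0(fam, "_dam"),
               role = "dam", sex = "F", group = group),
        tibble(family = fam,
               mouse_id = sprintf("%s_f1_%02d", fam, seq_len(fam_sizes[i])),
               role = "f1",
               sex = sample(c("M", "F"), fam_sizes[i], replace = TRUE),
               group = group)
      )
    })
  })
}

random_intervals <- function(n, config) {
  if (n == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  size = numeric(), kind = character(), copy_number = integer()))
  }
  size <- round(10 ^ runif(n, config$size_log10_range[1], config$size_log10_range[2]))
  size <- pmin(size, config$chromosome_length - 2)
  chrom <- sample(chromosome_names(config), n, replace = TRUE)
  start <- floor(runif(n, min = 1, max = config$chromosome_length - size))
  kind <- if_else(runif(n) < config$duplication_fraction, "duplication", "deletion")
  tibble(
    chrom = chrom, start = start, end = start + size, size = size,
    kind = kind, copy_number = if_else(kind == "deletion", 1L, 3L)
  )
}

# Redraw intervals until no two planted CNVs of the same family lie within
# `min_cnv_separation` bp of one another. Inherited copies are created from
# the final founder coordinates afterwards, so descent-sharing is untouched.
separate_family_cnvs <- function(cnvs, config) {
  gap <- config$min_cnv_separation
  if (nrow(cnvs) < 2) return(cnvs)
  for (iter in 1:100) {
    ord <- order(cnvs$family, cnvs$chrom, cnvs$start)
    o <- cnvs[ord, ]
    clash <- c(FALSE, o$family[-1] == o$family[-nrow(o)] &
                 o$chrom[-1] == o$chrom[-nrow(o)] &
                 o$start[-1] <= o$end[-nrow(o)] + gap)
    if (!any(clash)) return(cnvs)
    redraw_idx <- ord[clash]
    fresh <- random_intervals(length(redraw_idx), config)
    cnvs[redraw_idx, c("chrom", "start", "end", "size", "kind", "copy_number")] <-
      fresh[, c("chrom", "start", "end", "size", "kind", "copy_number")]
  }
  abort("Could not place the requested CNVs with the configured separation; the genome is too small for the CNV load.")
}

plant_cnvs <- function(mice, config) {
  founders <- mice %>% filter(.data$role %in% c("sire", "dam"))
  founder_counts <- rpois(nrow(founders), config$inherited_cnv_rate)
  founder_cnvs <- random_intervals(sum(founder_counts), config) %>%
    mutate(
      mouse_id = rep(founders$mouse_id, founder_counts),
      family = rep(founders$family, founder_counts),
      role = rep(founders$role, founder_counts),
      origin = "founder"
    )

  f1 <- mice %>% filter(.data$role == "f1")

  rate <- if_else(f1$group == "irradiated",
                  config$denovo_rate_irradiated,
                  config$denovo_rate_non_irradiated)
  denovo_counts <- rpois(nrow(f1), rate)
  denovo <- random_intervals(sum(denovo_counts), config) %>%
    mutate(mouse_id = rep(f1$mouse_id, denovo_counts),
           family = rep(f1$family, denovo_counts),
           origin = "de_novo")

  # enforce within-family separation jointly over founder and de novo events
  combined <- separate_family_cnvs(bind_rows(founder_cnvs, denovo), config)
  founder_cnvs <- filter(combined, .data$origin == "founder")
  denovo <- filter(combined, .data$origin == "de_novo")

  # transmission: each founder CNV passes to each offspring with prob 1/2
  inherited <- purrr::map_dfr(seq_len(nrow(founder_cnvs)), function(i) {
    cnv <- founder_cnvs[i, ]
    kids <- f1$mouse_id[f1$family == cnv$family]
    transmitted <- kids[runif(length(kids)) < 0.5]
    if (length(transmitted) == 0L) return(tibble())
    tibble(
      mouse_id = transmitted, chrom = cnv$chrom, start = cnv$start,
      end = cnv$end, size = cnv$size, kind = cnv$kind,
      origin = if (cnv$role == "sire") "inherited_sire" else "inherited_dam",
      copy_number = cnv$copy_number
    )
  })

  cols <- c("mouse_id", "chrom", "start", "end", "size", "kind", "origin",
            "copy_number")
  bind_rows(
    founder_cnvs %>% select(all_of(cols)),
    inherited %>% select(any_of(cols)),
    denovo %>% select(all_of(cols))
  ) %>%
    arrange(.data$mouse_id, .data$chrom, .data$start)
}

draw_lifespans <- function(mice, cnvs, config) {
  carriers <- unique(cnvs$mouse_id[cnvs$origin == "de_novo"])
  hr <- config$hazard_ratios
  hazard <- hr[["sex"]] ^ (mice$sex == "F") *
    hr[["irradiation"]] ^ (mice$group == "irradiated") *
    hr[["cnv"]] ^ (mice$mouse_id %in% carriers)
  # proportional hazards on a Weibull baseline: scale each draw by h^(-1/shape)
  scale <- config$lifespan_scale * hazard ^ (-1 / config$lifespan_shape)
  mice$lifespan_days <- round(rweibull(nrow(mice), config$lifespan_shape, scale), 1)
  mice
}
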