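#' Simulate dye-swap log2-ratio signals for a set of mice
#'
#' Each mouse is hybridised twice against the common reference with the dyes
#' exchanged. For every probe the true shift is `log2(copy_number / 2)` when
#' the probe lies strictly inside a CNV carried by that mouse (so -1 for a
#' hemizygous deletion, about +0.585 for a single-copy duplication) and 0
#' elsewhere; each hybridisation adds independent Gaussian noise with
#' standard deviation `config$noise_sd`.
#'
#' By default both columns are stored in sample-over-reference orientation
#' (the swapped experiment is sign-normalised at generation). With
#' `raw_orientation = TRUE` the second experiment keeps its native
#' reference-over-sample sign, as scanner output would.
#'
#' @param mice Tibble with at least `mouse_id`; typically `cohort$mice` or a
#'   subset of it.
#' @param cnvs Ground-truth CNV tibble (`mouse_id`, `chrom`, `start`, `end`,
#'   `copy_number`); CNVs of mice absent from `mice` are an error.
#' @param probe_map Probe map from [simulate_probe_map()].
#' @param config A [sim_config()]; supplies `noise_sd`.
#' @param seed Integer seed for the noise draws (defaults to
#'   `config$seed + 1`, so signals are reproducible independently of how
#'   often the cohort generator consumed the stream).
#' @param raw_orientation Keep experiment B in reference-over-sample sign.
#' @return Tibble (`mouse_id`, `probe_id`, `log2_a`, `log2_b`), one row per
#'   mouse x probe.
#' @examples
#' cfg <- sim_config(noise_sd = 0, n_chromosomes = 1, chromosome_length = 1e5)
#' map <- simulate_probe_map(cfg)
#' mice <- tibble::tibble(mouse_id = "m1")
#' del <- tibble::tibble(mouse_id = "m1", chrom = "chr1",
#'                       start = 10100, end = 30100, copy_number = 1)
#' sig <- simulate_signals(mice, del, map, cfg)
#' range(sig$log2_a)
#' @export
simulate_signals <- function(mice, cnvs, probe_map, config,
                             seed = config$seed + 1L,
                             raw_orientation = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(all(c("mouse_id") %in% names(mice)))
  if (nrow(cnvs) > 0 && !all(cnvs$mouse_id %in% mice$mouse_id)) {
    bad <- setdiff(unique(cnvs$mouse_id), mice$mouse_id)
    abort(paste0("CNVs planted for unknown mouse id(s): ",
                 paste(head(bad, 3), collapse = ", ")))
  }
  if (nrow(cnvs) > 0 &&
      (any(cnvs$start < 1) || any(cnvs$end > config$chromosome_length))) {
    abort("Planted CNVs must lie within the genome.")
  }

  n_probe <- nrow(probe_map)
  shift_for_mouse <- function(id) {
    shift <- numeric(n_probe)
    mc <- cnvs[cnvs$mouse_id == id, , drop = FALSE]
    for (i in seq_len(nrow(mc))) {
      inside <- probe_map$chrom == mc$chrom[i] &
        probe_map$pos > mc$start[i] & probe_map$pos < mc$end[i]
      shift[inside] <- log2(mc$copy_number[i] / 2)
    }
    shift
  }

  withr::with_seed(seed, {
    out <- purrr::map_dfr(mice$mouse_id, function(id) {
      shift <- shift_for_mouse(id)
      tibble(
        mouse_id = id,
        probe_id = probe_map$probe_id,
        log2_a = shift + rnorm(n_probe, 0, config$noise_sd),
        log2_b = shift + rnorm(n_probe, 0, config$noise_sd)
      )
    })
  })
  if (raw_orientation) out$log2_b <- -out$log2_b
  out
}

#' Simulate a duplex qPCR dilution plate for one locus
#'
#' Emulates a TaqMan-style copy-number assay run in duplex (target plus a
#' two-copy reference gene) over a genomic-DNA dilution series, in
#' triplicate. Each well's Ct follows the standard log-linear chemistry
#' `Ct = intercept + slope * log10(input_mass * copy / 2)` plus Gaussian
#' cycle noise; the reference assay always sees copy 2, the target assay the
#' local copy number of the queried mouse at `locus` (2 unless a planted CNV
#' of that mouse covers the position).
#'
#' @param mouse_id Mouse to assay.
#' @param locus Length-2 list or tibble row with `chrom` and `pos`.
#' @param cnvs Ground-truth CNV tibble as in [simulate_signals()]; pass a
#'   zero-row tibble for a calibrator (diploid) plate.
#' @param masses Input masses in ng (at least 3 distinct, all positive).
#' @param n_replicates Wells per assay and mass.
#' @param slope,intercept_target,intercept_ref Standard-curve chemistry; the
#'   default slope -log10(2)^-1 = -3.3219 corresponds to 100% efficiency.
#' @param ct_noise_sd Gaussian noise on each Ct, in cycles.
#' @param seed Integer seed.
#' @return Plate tibble (`mouse_id`, `chrom`, `pos`, `assay`, `mass_ng`,
#'   `replicate`, `ct`).
#' @examples
#' plate <- simulate_qpcr_plate("m1", list(chrom = "chr1", pos = 5e4),
#'                              cnvs = tibble::tibble(), ct_noise_sd = 0)
#' dplyr::count(plate, assay, mass_ng)
#' @export
simulate_qpcr_plate <- function(mouse_id, locus, cnvs,
                                masses = c(1.25, 2.5, 5),
                                n_replicates = 3,
                                slope = -1 / log10(2),
                                intercept_target = 30,
                                intercept_ref = 29,
                                ct_noise_sd = 0,
                                seed = NULL) {
  if (any(masses <= 0)) abort("Input masses must be positive.")
  if (length(unique(masses)) < 3) abort("The dilution series needs at least 3 distinct masses.")
  if (n_replicates < 1) abort("At least one replicate per level is required.")
  locus <- as.list(locus)

  copy <- 2L
  if (nrow(cnvs) > 0) {
    hit <- cnvs$mouse_id == mouse_id & cnvs$chrom == locus$chrom &
      cnvs$start <= locus$pos & cnvs$end >= locus$pos
    if (any(hit)) copy <- cnvs$copy_number[which(hit)[1]]
  }

  grid <- tidyr::expand_grid(
    assay = c("target", "reference"),
    mass_ng = masses,
    replicate = seq_len(n_replicates)
  )
  q <- if_else(grid$assay == "target",
               grid$mass_ng * copy / 2,
               grid$mass_ng)
  intercept <- if_else(grid$assay == "target", intercept_target, intercept_ref)
  ct_true <- intercept + slope * log10(q)
  noise <- if (is.null(seed)) {
    rnorm(nrow(grid), 0, ct_noise_sd)
  } else {
    withr::with_seed(seed, rnorm(nrow(grid), 0, ct_noise_sd))
  }
  tibble(
    mouse_id = mouse_id,
    chrom = locus$chrom,
    pos = locus$pos,
    assay = grid$assay,
    mass_ng = grid$mass_ng,
    replicate = grid$replicate,
    ct = ct_true + noise
  )
}
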