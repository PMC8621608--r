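#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct against log10(input mass) over the dilution
#' series of one assay. Amplification efficiency is `10^(-1/slope) - 1`, so
#' perfect doubling chemistry (slope -3.3219) gives efficiency 1.
#'
#' @param plate Plate tibble with columns `mass_ng` and `ct`, usually one
#'   assay's wells of a [simulate_qpcr_plate()] or [read_qpcr_plate()]
#'   table.
#' @return An object of class `qpcr_curve` wrapping the linear fit, with
#'   [tidy()] and [glance()] methods.
#' @examples
#' plate <- simulate_qpcr_plate("ref", list(chrom = "chr1", pos = 1000),
#'                              cnvs = tibble::tibble())
#' curve <- fit_standard_curve(dplyr::filter(plate, assay == "reference"))
#' glance(curve)$efficiency
#' @export
fit_standard_curve <- function(plate) {
  stopifnot(all(c("mass_ng", "ct") %in% names(plate)))
  if (length(unique(plate$mass_ng)) < 3) {
    abort("A standard curve needs at least 3 distinct input masses.")
  }
  if (any(plate$mass_ng <= 0)) abort("Input masses must be positive.")
  fit <- lm(ct ~ log10(mass_ng), data = plate)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-8) {
    abort("Ct does not vary with input mass; the amplification efficiency is undefined.")
  }
  structure(
    list(fit = fit, slope = slope, intercept = unname(coef(fit)[1]),
         efficiency = 10 ^ (-1 / slope) - 1, n = nrow(plate)),
    class = "qpcr_curve"
  )
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat(sprintf("<qpcr_curve> Ct = %.3f %+.4f * log10(mass); efficiency %.3f (n = %d)\n",
              x$intercept, x$slope, x$efficiency, x$n))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `qpcr_curve`.
#' @param ... Unused.
#' @export
tidy.qpcr_curve <- function(x, ...) {
  # noiseless calibration plates fit perfectly; the lm summary warning about
  # that is expected here
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = s[, "Std. Error"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname fit_standard_curve
#' @export
glance.qpcr_curve <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, efficiency = x$efficiency,
    r.squared = suppressWarnings(summary(x$fit))$r.squared, n_wells = x$n
  )
}

#' Relative-standard-curve copy-number confirmation
#'
#' Standard curves for the target and the reference assay are fitted on the
#' calibrator plate (reference DNA, two copies everywhere). Every well of
#' the sample plate is interpolated to a quantity, the target/reference
#' quantity ratio is averaged per plate, and the sample ratio is normalised
#' by the calibrator ratio. A diploid locus yields 1, a hemizygous deletion
#' 0.5, a single-copy duplication 1.5; the verdict thresholds default to the
#' midpoints (0.75, 1.25).
#'
#' @param plate Sample plate (columns `assay`, `mass_ng`, `ct`; carries
#'   `mouse_id`, `chrom`, `pos` into the result when present).
#' @param calibrator Calibrator plate with the same assay pair and design.
#' @param thresholds Length-2 numeric `(low, high)`: relative quantity below
#'   `low` confirms a deletion, above `high` a duplication.
#' @return One-row tibble: identifiers, `relative_quantity`, `verdict`
#'   (`confirmed_deletion`, `confirmed_duplication`, `not_confirmed`).
#' @examples
#' del <- tibble::tibble(mouse_id = "m1", chrom = "chr1", start = 1,
#'                       end = 1e5, copy_number = 1)
#' locus <- list(chrom = "chr1", pos = 5e4)
#' sample <- simulate_qpcr_plate("m1", locus, del)
#' calib <- simulate_qpcr_plate("ref", locus, del[0, ])
#' confirm_copy_number(sample, calib)
#' @export
confirm_copy_number <- function(plate, calibrator, thresholds = c(0.75, 1.25)) {
  if (length(thresholds) != 2 || thresholds[1] <= 0 ||
      thresholds[1] >= thresholds[2]) {
    abort("`thresholds` must be positive with low < high.")
  }
  for (tb in list(plate, calibrator)) {
    stopifnot(all(c("assay", "mass_ng", "ct") %in% names(tb)))
    if (!all(c("target", "reference") %in% tb$assay)) {
      abort("Both plates must carry the target and the reference assay.")
    }
  }
  curves <- list(
    target = fit_standard_curve(filter(calibrator, .data$assay == "target")),
    reference = fit_standard_curve(filter(calibrator, .data$assay == "reference"))
  )
  quantity <- function(tb) {
    q <- purrr::map_dbl(seq_len(nrow(tb)), function(i) {
      cv <- curves[[tb$assay[i]]]
      10 ^ ((tb$ct[i] - cv$intercept) / cv$slope)
    })
    tb %>%
      mutate(q = q) %>%
      group_by(.data$assay) %>%
      summarise(q = mean(.data$q), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "assay", values_from = "q")
  }
  qs <- quantity(plate)
  qc <- quantity(calibrator)
  rel <- (qs$target / qs$reference) / (qc$target / qc$reference)
  if (!is.finite(rel) || rel <= 0) {
    abort("The relative quantity is non-positive; the plates are inconsistent.")
  }
  verdict <- case_when(
    rel < thresholds[1] ~ "confirmed_deletion",
    rel > thresholds[2] ~ "confirmed_duplication",
    TRUE ~ "not_confirmed"
  )
  ids <- plate %>%
    select(any_of(c("mouse_id", "chrom", "pos"))) %>%
    distinct() %>%
    head(1)
  bind_cols(ids, tibble(relative_quantity = rel, verdict = verdict))
}
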