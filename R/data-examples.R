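#' Example cohort data: confirmed de novo CNVs
#'
#' A table of confirmed de novo CNVs from a published two-generation mouse
#' cohort in which sires were chronically exposed to low dose-rate gamma
#' radiation (20 mGy/day for 400 days, total 8 Gy) and compared with
#' non-irradiated controls. Coordinates are GRCm38, 1-based, with size
#' `end - start`. One irradiated deletion is included with its size
#' reconstructed from the published group geometric mean and is flagged
#' `reconstructed = TRUE` (it has no coordinates); all other rows are as
#' published.
#'
#' @return Tibble with columns `group`, `kind`, `mouse_id`, `sex`,
#'   `n_pos_first`, `n_pos_second` (display string, e.g. `">50"`),
#'   `size_bp`, `chrom`, `start`, `end`, `reconstructed`.
#' @examples
#' calls <- example_cnv_calls()
#' dplyr::count(calls, group, kind)
#' @export
example_cnv_calls <- function() {
  path <- system.file("extdata", "example_cnv_calls.tsv", package = "cnvtrio",
                      mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    n_pos_first = readr::col_integer(),
                    n_pos_second = readr::col_character(),
                    size_bp = readr::col_double(),
                    start = readr::col_double(),
                    end = readr::col_double(),
                    reconstructed = readr::col_logical(),
                    .default = readr::col_character()
                  ))
}

#' Example cohort data: mice-with-CNV tallies
#'
#' Per-stratum counts of F1 mice carrying at least one confirmed de novo
#' CNV from the same published cohort as [example_cnv_calls()], with the
#' published Fisher p-values and the test sidedness under which each printed
#' value reproduces on recomputation (the published table mixed one- and
#' two-sided tests; see the methods vignette).
#'
#' @return Tibble with columns `sex`, `cnv_type`, `kind`,
#'   `n_non_irradiated`, `total_non_irradiated`, `n_irradiated`,
#'   `total_irradiated`, `printed_p`, `printed_alternative`.
#' @examples
#' tallies <- example_cnv_tallies()
#' dplyr::filter(tallies, kind == "deletion", sex == "all")
#' @export
example_cnv_tallies <- function() {
  path <- system.file("extdata", "example_cnv_tallies.tsv", package = "cnvtrio",
                      mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    printed_p = readr::col_double(),
                    printed_alternative = readr::col_character(),
                    sex = readr::col_character(),
                    cnv_type = readr::col_character(),
                    kind = readr::col_character(),
                    .default = readr::col_integer()
                  ))
}
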