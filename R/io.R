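#' @noRd
write_table_with_header <- function(x, path, hash = NULL, delim = "\t") {
  lines <- character()
  if (!is.null(hash)) lines <- c(lines, paste0("# config_hash: ", hash))
  writeLines(lines, path)
  readr::write_delim(x, path, delim = delim, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @noRd
read_table_checked <- function(path, required, delim = "\t") {
  tb <- readr::read_delim(path, delim = delim, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(tb))
  if (length(missing_cols) > 0) {
    abort(sprintf("File %s is malformed: missing column(s) %s.",
                  path, paste(missing_cols, collapse = ", ")))
  }
  tb
}

#' Read and write the probe-map TSV
#'
#' Tab-separated with a `#`-comment metadata header; columns `probe_id`,
#' `chrom`, `pos`, `tier`. Reading validates that probe ids are unique and
#' positions strictly increasing within chromosome and tier.
#'
#' @param path File path (gzip transparently supported).
#' @param map Probe-map tibble.
#' @param hash Optional configuration hash written as a header comment.
#' @return The tibble (readers) or the path, invisibly (writers).
#' @export
read_probe_map <- function(path) {
  tb <- read_table_checked(path, c("probe_id", "chrom", "pos", "tier"))
  if (anyDuplicated(tb$probe_id)) {
    abort(sprintf("File %s contains duplicate probe ids.", path))
  }
  sorted <- tb %>%
    group_by(.data$chrom, .data$tier) %>%
    summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(sorted$ok)) {
    abort(sprintf("File %s has non-increasing probe positions within a chromosome.", path))
  }
  tb
}

#' @rdname read_probe_map
#' @export
write_probe_map <- function(map, path, hash = NULL) {
  write_table_with_header(map, path, hash)
}

#' Read and write the per-mouse dye-swap signal TSV
#'
#' Columns `mouse_id`, `probe_id`, `log2_a`, `log2_b`.
#'
#' @inheritParams read_probe_map
#' @param signals Signal tibble.
#' @export
read_signals <- function(path) {
  read_table_checked(path, c("mouse_id", "probe_id", "log2_a", "log2_b"))
}

#' @rdname read_signals
#' @export
write_signals <- function(signals, path, hash = NULL) {
  write_table_with_header(signals, path, hash)
}

#' Read and write the pedigree/cohort TSV
#'
#' Columns `family`, `mouse_id`, `role` (sire/dam/f1), `sex`, `group`,
#' `lifespan_days`.
#'
#' @inheritParams read_probe_map
#' @param mice Pedigree tibble.
#' @export
read_pedigree <- function(path) {
  read_table_checked(path, c("family", "mouse_id", "role", "sex", "group",
                             "lifespan_days"))
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(mice, path, hash = NULL) {
  write_table_with_header(mice, path, hash)
}

#' Read and write qPCR plate CSV
#'
#' Columns `mouse_id`, `chrom`, `pos`, `assay`, `mass_ng`, `replicate`,
#' `ct`.
#'
#' @inheritParams read_probe_map
#' @param plate Plate tibble.
#' @export
read_qpcr_plate <- function(path) {
  read_table_checked(path, c("mouse_id", "assay", "mass_ng", "replicate", "ct"),
                     delim = ",")
}

#' @rdname read_qpcr_plate
#' @export
write_qpcr_plate <- function(plate, path, hash = NULL) {
  write_table_with_header(plate, path, hash, delim = ",")
}

#' Write and read CNV calls as BED
#'
#' Internal coordinates are 1-based closed with size `end - start`; on
#' write they are converted to BED's 0-based half-open convention
#' (`bed_start = start - 1`, `bed_end = end`), and back on read, so a call
#' at 7,323,388-7,323,541 round-trips through a BED line with start
#' 7,323,387. The BED name field packs `mouse_id:kind:cnv_type`.
#'
#' @param calls Call tibble with `mouse_id`, `chrom`, `start`, `end`,
#'   `kind`, `cnv_type`.
#' @param path File path.
#' @return `write_calls_bed()` the path invisibly; `read_calls_bed()` a
#'   call tibble.
#' @export
write_calls_bed <- function(calls, path) {
  gr <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$start, calls$end),
    name = paste(calls$mouse_id, calls$kind, calls$cnv_type, sep = ":")
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
read_calls_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  parts <- strsplit(gr$name, ":", fixed = TRUE)
  tibble(
    mouse_id = purrr::map_chr(parts, 1),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    kind = purrr::map_chr(parts, 2),
    cnv_type = purrr::map_chr(parts, 3)
  )
}

#' Read a gene-annotation BED as 1-based closed intervals
#'
#' @param path BED file path.
#' @return Tibble (`chrom`, `start`, `end`, `name`).
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_
  )
}

#' Load a run configuration from YAML
#'
#' The YAML file may carry any [sim_config()] argument under `simulate:`,
#' any [screen_thresholds()] argument under `thresholds:`, plus top-level
#' `family_window`, `qpcr_thresholds` (two numbers) and `k_neighbors`.
#'
#' @param path YAML file path.
#' @return A list with elements `config`, `thresholds`, `family_window`,
#'   `qpcr_thresholds`, `k_neighbors` ready for [run_cnv_pipeline()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulate %||% list()
  if (!is.null(sim_args$n_f1_per_group)) {
    sim_args$n_f1_per_group <- unlist(sim_args$n_f1_per_group)
  }
  if (!is.null(sim_args$size_log10_range)) {
    sim_args$size_log10_range <- unlist(sim_args$size_log10_range)
  }
  if (!is.null(sim_args$hazard_ratios)) {
    sim_args$hazard_ratios <- unlist(sim_args$hazard_ratios)
  }
  list(
    config = do.call(sim_config, sim_args),
    thresholds = do.call(screen_thresholds, y$thresholds %||% list()),
    family_window = y$family_window %||% 10000,
    qpcr_thresholds = unlist(y$qpcr_thresholds %||% c(0.75, 1.25)),
    k_neighbors = y$k_neighbors %||% 10L
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
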