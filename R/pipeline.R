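#' Run the full simulate-screen-call-confirm-summarise pipeline
#'
#' End-to-end orchestration over a synthetic cohort: simulate the cohort and
#' its first-tier dye-swap signals, run the first screen on every mouse,
#' select dense confirmation probes around each F1 positive, simulate and
#' score the second screen, remove inherited positives by family analysis,
#' aggregate de novo positives into candidates with estimated intervals and
#' Type S/L classes, confirm each candidate by simulated duplex qPCR, and
#' compute the cohort statistics.
#'
#' @param config A [sim_config()]; drives every stochastic stage through its
#'   seed.
#' @param thresholds A [screen_thresholds()].
#' @param family_window Parental matching tolerance in bp, see
#'   [family_filter()].
#' @param k_neighbors Dense probes selected per positive, see
#'   [select_second_tier_probes()].
#' @param qpcr_thresholds Length-2 `(low, high)` relative-quantity bounds,
#'   see [confirm_copy_number()].
#' @param qpcr_ct_noise_sd Ct noise (cycles) of the simulated plates.
#' @param out_dir If non-`NULL`, per-stage TSV/CSV/BED artifacts are written
#'   here, each tagged with the configuration hash in a `#` header comment.
#' @param verbose Log stage progress and record counts.
#' @return A `cnv_pipeline_result` list: `config`, `mice`, `planted`,
#'   `first_positives`, `confirmations`, `calls` (with `status`
#'   confirmed/rejected and intervals), `summary` (a
#'   [cohort_stats()] result) and `hash`.
#' @examples
#' \donttest{
#' cfg <- sim_config(seed = 42, n_f1_per_group = c(10, 10),
#'                   n_chromosomes = 2, chromosome_length = 2e6)
#' res <- run_cnv_pipeline(cfg, verbose = FALSE)
#' res$summary$tallies
#' }
#' @export
run_cnv_pipeline <- function(config = sim_config(),
                             thresholds = screen_thresholds(),
                             family_window = 10000,
                             k_neighbors = 10L,
                             qpcr_thresholds = c(0.75, 1.25),
                             qpcr_ct_noise_sd = 0.1,
                             out_dir = NULL,
                             verbose = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  hash <- rlang::hash(unclass(config))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  cohort <- simulate_cohort(config)
  mice <- cohort$mice
  planted <- cohort$cnvs
  say("simulate: %d mice, %d planted CNVs [%s]", nrow(mice), nrow(planted),
      format(Sys.time() - t0, digits = 2))

  map1 <- simulate_probe_map(config, "first")
  signals1 <- simulate_signals(mice, planted, map1, config,
                               seed = config$seed + 1L)
  pos1 <- first_screen(signals1, map1, thresholds)
  say("screen1: %d positive probes across %d mice", nrow(pos1),
      length(unique(pos1$mouse_id)))

  f1_ids <- mice$mouse_id[mice$role == "f1"]
  f1_pos <- filter(pos1, .data$mouse_id %in% f1_ids)

  confirmations <- empty_confirmations()
  denovo_pos <- f1_pos[0, ]
  if (nrow(f1_pos) > 0) {
    pad <- 2 * k_neighbors * config$second_tier_spacing
    regions <- f1_pos %>%
      mutate(start = pmax(1, .data$pos - pad),
             end = pmin(config$chromosome_length, .data$pos + pad)) %>%
      select("chrom", "start", "end") %>%
      distinct()
    dense_map <- simulate_probe_map(config, "second", regions = regions)

    second_map <- select_second_tier_probes(f1_pos, dense_map, k = k_neighbors)
    confirmations <- purrr::map_dfr(unique(f1_pos$mouse_id), function(id) {
      m_map <- second_map %>%
        filter(.data$mouse_id == id) %>%
        select("probe_id", "chrom", "pos", "tier") %>%
        distinct()
      m_sig <- simulate_signals(
        tibble(mouse_id = id), filter(planted, .data$mouse_id == id),
        m_map, config,
        seed = config$seed + 1000L + match(id, mice$mouse_id)
      )
      second_screen(filter(f1_pos, .data$mouse_id == id), m_sig,
                    filter(second_map, .data$mouse_id == id), thresholds)
    })
    say("screen2: %d of %d F1 positives confirmed",
        sum(confirmations$confirmed), nrow(confirmations))

    confirmed_pos <- f1_pos %>%
      semi_join(filter(confirmations, .data$confirmed),
                by = c("mouse_id", "probe_id" = "origin_probe_id"))

    fams <- mice %>% select("family", "mouse_id", "role")
    denovo_pos <- purrr::map_dfr(unique(confirmed_pos$mouse_id), function(id) {
      fam <- fams$family[fams$mouse_id == id]
      sire <- fams$mouse_id[fams$family == fam & fams$role == "sire"]
      dam <- fams$mouse_id[fams$family == fam & fams$role == "dam"]
      family_filter(
        filter(confirmed_pos, .data$mouse_id == id),
        filter(pos1, .data$mouse_id %in% sire),
        filter(pos1, .data$mouse_id %in% dam),
        window = family_window
      )
    })
    say("family analysis: %d de novo positives retained", nrow(denovo_pos))
  }

  calls <- empty_calls()
  if (nrow(denovo_pos) > 0) {
    candidates <- call_candidates(denovo_pos, map1)
    support <- confirmations %>%
      filter(.data$confirmed) %>%
      select("mouse_id", "origin_probe_id", "support") %>%
      tidyr::unnest("support")
    candidates <- estimate_interval(candidates, support)

    verdicts <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
      cand <- candidates[i, ]
      locus <- list(chrom = cand$chrom,
                    pos = floor((cand$start + cand$end) / 2))
      sample_plate <- simulate_qpcr_plate(
        cand$mouse_id, locus, planted, ct_noise_sd = qpcr_ct_noise_sd,
        seed = config$seed + 5000L + 2L * i)
      calibrator <- simulate_qpcr_plate(
        "reference", locus, planted[0, ], ct_noise_sd = qpcr_ct_noise_sd,
        seed = config$seed + 5000L + 2L * i + 1L)
      confirm_copy_number(sample_plate, calibrator, qpcr_thresholds) %>%
        select("relative_quantity", "verdict")
    })
    calls <- bind_cols(candidates, verdicts) %>%
      mutate(status = if_else(
        (.data$kind == "deletion" & .data$verdict == "confirmed_deletion") |
          (.data$kind == "duplication" & .data$verdict == "confirmed_duplication"),
        "confirmed", "rejected"))
    say("qPCR: %d of %d candidates confirmed",
        sum(calls$status == "confirmed"), nrow(calls))
  }

  summary <- cohort_stats(mice, calls)
  say("pipeline done [%s]", format(Sys.time() - t0, digits = 2))

  result <- structure(
    list(config = config, thresholds = thresholds, mice = mice,
         planted = planted, first_positives = pos1,
         confirmations = confirmations, calls = calls,
         summary = summary, hash = hash),
    class = "cnv_pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, map1, signals1, out_dir)
  result
}

empty_confirmations <- function() {
  tibble(mouse_id = character(), origin_probe_id = character(),
         direction = character(), confirmed = logical(),
         n_support = integer(), support = list())
}

empty_calls <- function() {
  tibble(mouse_id = character(), chrom = character(), kind = character(),
         n_pos_first = integer(), cnv_type = character(),
         first_pos = numeric(), last_pos = numeric(), status = character(),
         probe_ids = list(), start = numeric(), end = numeric(),
         size = numeric(), relative_quantity = numeric(),
         verdict = character())
}

write_pipeline_artifacts <- function(result, map1, signals1, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- result$hash
  write_probe_map(map1, file.path(out_dir, "probe_map.tsv"), hash = h)
  write_signals(signals1, file.path(out_dir, "signals_first_tier.tsv"), hash = h)
  write_pedigree(result$mice, file.path(out_dir, "pedigree.tsv"), hash = h)
  calls_flat <- result$calls %>% select(-any_of("probe_ids"))
  write_table_with_header(calls_flat, file.path(out_dir, "calls.tsv"), hash = h)
  if (nrow(result$calls) > 0) {
    write_calls_bed(filter(result$calls, .data$status == "confirmed"),
                    file.path(out_dir, "calls_confirmed.bed"))
  }
  truth_bed <- result$planted %>%
    mutate(name = paste(.data$mouse_id, .data$kind, .data$origin, sep = ":"))
  gr <- GenomicRanges::GRanges(truth_bed$chrom,
                               IRanges::IRanges(truth_bed$start, truth_bed$end),
                               name = truth_bed$name)
  rtracklayer::export(gr, file.path(out_dir, "planted_truth.bed"), format = "BED")
  write_table_with_header(result$summary$tallies,
                          file.path(out_dir, "report_tallies.tsv"), hash = h)
  invisible(out_dir)
}

#' @export
print.cnv_pipeline_result <- function(x, ...) {
  cat(sprintf("<cnv_pipeline_result> %d mice; %d planted CNVs; %d calls (%d confirmed)\n",
              nrow(x$mice), nrow(x$planted), nrow(x$calls),
              sum(x$calls$status == "confirmed")))
  cat(sprintf("  config hash %s\n", x$hash))
  invisible(x)
}
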