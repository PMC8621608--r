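#' Family analysis: remove inherited positive probes
#'
#' An F1 positive probe is kept as de novo only if neither parent shows a
#' same-direction positive probe within `window` bp on the same chromosome.
#' Parent and offspring were screened on the same probe map, but boundary
#' jitter under noise makes an exact-coordinate match too brittle, hence the
#' tolerance window.
#'
#' @param f1_positives Positive-probe tibble for one F1 mouse (needs
#'   `chrom`, `pos`, `direction`).
#' @param sire_positives,dam_positives Positive-probe tibbles of the two
#'   parents (zero-row tibbles are valid: a clean parent); `NULL` is an
#'   error, since missing parental data cannot be distinguished from a clean
#'   screen.
#' @param window Matching tolerance in bp (default 10 kb, five first-tier
#'   probe spacings).
#' @return The rows of `f1_positives` that survive as de novo.
#' @examples
#' f1 <- tibble::tibble(probe_id = "p", chrom = "chr1", pos = 5e6,
#'                      direction = "loss")
#' clean <- f1[0, ]
#' family_filter(f1, clean, clean)          # retained: parents flat
#' family_filter(f1, f1, clean)             # removed: inherited from sire
#' @export
family_filter <- function(f1_positives, sire_positives, dam_positives,
                          window = 10000) {
  if (is.null(sire_positives) || is.null(dam_positives)) {
    abort("Both parental screening results are required (pass a zero-row tibble for a clean parent).")
  }
  needed <- c("chrom", "pos", "direction")
  stopifnot(all(needed %in% names(f1_positives)))
  parents <- bind_rows(
    sire_positives %>% select(any_of(needed)),
    dam_positives %>% select(any_of(needed))
  )
  if (nrow(f1_positives) == 0L || nrow(parents) == 0L) return(f1_positives)
  inherited <- purrr::map_lgl(seq_len(nrow(f1_positives)), function(i) {
    any(parents$chrom == f1_positives$chrom[i] &
          parents$direction == f1_positives$direction[i] &
          abs(parents$pos - f1_positives$pos[i]) <= window)
  })
  f1_positives[!inherited, , drop = FALSE]
}

#' Aggregate de novo positive probes into CNV candidates
#'
#' Maximal runs of same-direction positive probes that are consecutive on
#' the first-tier map (gap tolerance 0 probes) become one candidate each.
#' Every run length is emitted, down to a single probe: the visual review
#' that small candidates traditionally receive is replaced by the same
#' programmatic run-calling, with the second screen and qPCR providing the
#' downstream filtering.
#'
#' @param de_novo_positives Surviving positives from [family_filter()]
#'   (needs `probe_id`, `chrom`, `pos`, `direction`; `mouse_id` optional).
#' @param probe_map The first-tier probe map defining adjacency.
#' @param gap_tolerance Number of non-positive probes allowed inside a run
#'   (default 0: strictly consecutive).
#' @return Candidate tibble: `mouse_id` (if supplied), `chrom`, `kind`
#'   (`deletion`/`duplication`), `n_pos_first`, `cnv_type` (`S` for a single
#'   positive probe, `L` for two or more), `first_pos`, `last_pos`, `status`
#'   (`candidate`) and a `probe_ids` list-column.
#' @export
call_candidates <- function(de_novo_positives, probe_map, gap_tolerance = 0L) {
  empty <- tibble(
    mouse_id = character(), chrom = character(), kind = character(),
    n_pos_first = integer(), cnv_type = character(),
    first_pos = numeric(), last_pos = numeric(), status = character(),
    probe_ids = list()
  )
  if (nrow(de_novo_positives) == 0L) return(empty)
  has_mouse <- "mouse_id" %in% names(de_novo_positives)
  pos <- de_novo_positives
  if (!has_mouse) pos$mouse_id <- "sample"

  map_idx <- probe_map %>%
    arrange(.data$chrom, .data$pos) %>%
    group_by(.data$chrom) %>%
    mutate(.idx = row_number()) %>%
    ungroup() %>%
    select("probe_id", ".idx")

  runs <- pos %>%
    inner_join(map_idx, by = "probe_id") %>%
    arrange(.data$mouse_id, .data$chrom, .data$pos) %>%
    group_by(.data$mouse_id, .data$chrom, .data$direction) %>%
    mutate(
      new_run = .data$.idx - lag(.data$.idx, default = -1e9) > gap_tolerance + 1L,
      run = cumsum(.data$new_run)
    ) %>%
    group_by(.data$mouse_id, .data$chrom, .data$direction, .data$run) %>%
    summarise(
      n_pos_first = dplyr::n(),
      first_pos = min(.data$pos),
      last_pos = max(.data$pos),
      probe_ids = list(.data$probe_id),
      .groups = "drop"
    ) %>%
    mutate(
      kind = if_else(.data$direction == "loss", "deletion", "duplication"),
      cnv_type = classify_cnv_type(.data$n_pos_first),
      status = "candidate"
    ) %>%
    select("mouse_id", "chrom", "kind", "n_pos_first", "cnv_type",
           "first_pos", "last_pos", "status", "probe_ids")
  if (!has_mouse) runs$mouse_id <- NULL
  runs
}

#' Classify CNV candidates by first-screen probe support
#'
#' Type S: exactly one positive probe in the genome-wide screen;
#' Type L: two or more.
#'
#' @param n_pos_first Integer vector of first-screen positive-probe counts.
#' @return Character vector of `"S"`/`"L"`.
#' @examples
#' classify_cnv_type(c(1, 2, 575))
#' @export
classify_cnv_type <- function(n_pos_first) {
  stopifnot(all(n_pos_first >= 1))
  if_else(n_pos_first == 1L, "S", "L")
}

#' Estimate candidate intervals from the supporting positive probes
#'
#' The reported interval runs from the outermost supporting positive probe
#' on the left to the outermost on the right, pooling first-screen positives
#' of the run with every second-screen probe that passed confirmation
#' thresholds for one of the run's probes. Size is `end - start` (1-based
#' coordinates), matching the convention that a 153-bp event spans e.g.
#' 7,323,388-7,323,541.
#'
#' @param candidates Output of [call_candidates()].
#' @param support Second-screen support probes: tibble with
#'   `origin_probe_id`, `pos` (and `mouse_id` when candidates carry one),
#'   e.g. the unnested `support` column of [second_screen()].
#' @return `candidates` with `start`, `end` and `size` columns added.
#' @export
estimate_interval <- function(candidates, support = NULL) {
  if (nrow(candidates) == 0L) {
    return(mutate(candidates, start = numeric(), end = numeric(), size = numeric()))
  }
  has_mouse <- "mouse_id" %in% names(candidates)
  out <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    pts <- c(cand$first_pos, cand$last_pos)
    if (!is.null(support) && nrow(support) > 0) {
      sup <- support[support$origin_probe_id %in% cand$probe_ids[[1]], , drop = FALSE]
      if (has_mouse && "mouse_id" %in% names(support)) {
        sup <- sup[sup$mouse_id == cand$mouse_id, , drop = FALSE]
      }
      pts <- c(pts, sup$pos)
    }
    start <- min(pts)
    end <- max(pts)
    if (end <= start) {
      abort(sprintf(
        "Candidate at %s:%s has a single supporting probe; its extent cannot be sized.",
        cand$chrom, format(start, big.mark = ",")))
    }
    mutate(cand, start = start, end = end, size = end - start)
  })
  out
}

#' Count annotation intervals overlapped by each call
#'
#' Closed-interval overlap on both sides with a minimum of 1 bp: a gene
#' starting at `end + 1` does not count.
#'
#' @param calls Call tibble with `chrom`, `start`, `end`.
#' @param genes Annotation tibble with `chrom`, `start`, `end` (1-based
#'   closed), e.g. from [read_genes_bed()].
#' @return `calls` with a `gene_count` column.
#' @export
annotate_genes <- function(calls, genes) {
  if (nrow(calls) == 0L) return(mutate(calls, gene_count = integer()))
  if (is.null(genes) || nrow(genes) == 0L) {
    return(mutate(calls, gene_count = 0L))
  }
  call_gr <- GenomicRanges::GRanges(calls$chrom,
                                    IRanges::IRanges(calls$start, calls$end))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  mutate(calls, gene_count = GenomicRanges::countOverlaps(call_gr, gene_gr))
}

#' Tally mice carrying at least one qualifying confirmed call
#'
#' The unit of comparison is the mouse, not the CNV: a mouse counts once no
#' matter how many qualifying calls it carries. Mice with
#' `multi_cnv_threshold` (default 4) or more confirmed calls of any kind are
#' excluded from numerator and denominator alike, so that animals with
#' many events -- plausibly a different mutational process -- do not drive
#' the group comparison. Type-stratified tallies may count the same mouse
#' under both S and L.
#'
#' @param mice Cohort tibble with `mouse_id`, `sex`, `group` and (if
#'   present) `role`; only `role == "f1"` rows are tallied.
#' @param calls Call tibble with `mouse_id`, `kind`, `cnv_type`, `status`.
#' @param kind Restrict qualifying calls to `"deletion"` or
#'   `"duplication"` (`NULL`: any).
#' @param cnv_type Restrict to `"S"` or `"L"` (`NULL`: any).
#' @param sex Restrict the tallied mice to `"M"` or `"F"` (`NULL`: both).
#' @param multi_cnv_threshold Confirmed-call count at which a mouse is
#'   excluded entirely.
#' @return One row per group: `group`, `n_with`, `n_total`, `pct`.
#' @export
tally_mice <- function(mice, calls, kind = NULL, cnv_type = NULL, sex = NULL,
                       multi_cnv_threshold = 4L) {
  if (!is.null(kind) && !kind %in% c("deletion", "duplication")) {
    abort("`kind` must be \"deletion\" or \"duplication\".")
  }
  if (!is.null(cnv_type) && !cnv_type %in% c("S", "L")) {
    abort("`cnv_type` must be \"S\" or \"L\".")
  }
  if (!is.null(sex) && !sex %in% c("M", "F")) {
    abort("`sex` must be \"M\" or \"F\".")
  }
  if ("role" %in% names(mice)) mice <- filter(mice, .data$role == "f1")
  confirmed <- filter(calls, .data$status == "confirmed")

  counts <- confirmed %>% dplyr::count(.data$mouse_id, name = "n_calls")
  multi <- counts$mouse_id[counts$n_calls >= multi_cnv_threshold]
  mice <- filter(mice, !.data$mouse_id %in% multi)
  if (!is.null(sex)) mice <- filter(mice, .data$sex == .env$sex)

  qual <- confirmed %>% filter(!.data$mouse_id %in% multi)
  if (!is.null(kind)) qual <- filter(qual, .data$kind == .env$kind)
  if (!is.null(cnv_type)) qual <- filter(qual, .data$cnv_type == .env$cnv_type)

  mice %>%
    group_by(.data$group) %>%
    summarise(
      n_with = dplyr::n_distinct(.data$mouse_id[.data$mouse_id %in% qual$mouse_id]),
      n_total = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(pct = round(100 * .data$n_with / .data$n_total, 1))
}
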