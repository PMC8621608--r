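#' Thresholds for the two-screen probe positivity rules
#'
#' @param t_single Single-probe threshold on both dye-swap |log2 ratios| in
#'   the first screen (strict inequality).
#' @param t_pair Adjacent-pair threshold: two consecutive first-tier probes
#'   whose four |log2 ratios| all exceed this are positive.
#' @param t_second Threshold applied to every probe tested in the second
#'   (confirmation) screen.
#' @param neighbor_window A confirmation requires a newly selected
#'   second-tier probe within this many probe ranks of the original probe.
#' @return A `screen_thresholds` list.
#' @examples
#' screen_thresholds()
#' @export
screen_thresholds <- function(t_single = 0.8, t_pair = 0.5, t_second = 0.5,
                              neighbor_window = 3L) {
  if (any(c(t_single, t_pair, t_second) <= 0) || neighbor_window < 1) {
    abort("All screening thresholds must be positive.")
  }
  if (t_pair > t_single) {
    abort("`t_pair` must not exceed `t_single`.")
  }
  structure(
    list(t_single = t_single, t_pair = t_pair, t_second = t_second,
         neighbor_window = as.integer(neighbor_window)),
    class = "screen_thresholds"
  )
}

#' @export
print.screen_thresholds <- function(x, ...) {
  cat(sprintf(
    "<screen_thresholds> single > %.2f, adjacent pair > %.2f, second screen > %.2f (neighbor window %d)\n",
    x$t_single, x$t_pair, x$t_second, x$neighbor_window))
  invisible(x)
}

check_signals <- function(signals, probe_map) {
  needed <- c("probe_id", "log2_a", "log2_b")
  missing_cols <- setdiff(needed, names(signals))
  if (length(missing_cols) > 0) {
    abort(paste0("Signal table lacks column(s): ",
                 paste(missing_cols, collapse = ", "),
                 "; both dye-swap experiments are required."))
  }
  if (anyNA(signals$log2_a) || anyNA(signals$log2_b) ||
      any(!is.finite(signals$log2_a)) || any(!is.finite(signals$log2_b))) {
    abort("Signals must be finite in both dye-swap experiments for every probe.")
  }
  unknown <- setdiff(unique(signals$probe_id), probe_map$probe_id)
  if (length(unknown) > 0) {
    abort(paste0("Signal probe id(s) absent from the probe map: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  invisible(TRUE)
}

#' First-screen probe positivity on the genome-wide tier
#'
#' A probe is positive when both dye-swap |log2 ratios| strictly exceed
#' `t_single`, or when it and an adjacent probe (consecutive on the same
#' chromosome of the supplied map) have all four |log2 ratios| strictly
#' above `t_pair`. Both experiments must agree in sign (after orientation
#' normalisation), and an adjacent pair must share direction: a genuine
#' copy-number change shifts both hybridisations the same way, so
#' discordant-sign probes are rejected as artifacts.
#'
#' @param signals Tibble (`probe_id`, `log2_a`, `log2_b`), optionally with a
#'   `mouse_id` column to screen several mice at once. Both columns must be
#'   in sample-over-reference orientation (see [simulate_signals()]).
#' @param probe_map Probe map covering every signal probe.
#' @param thresholds A [screen_thresholds()].
#' @return Tibble of positive probes: `mouse_id` (if supplied), `probe_id`,
#'   `chrom`, `pos`, `tier`, `direction` (`loss`/`gain`), `rule`
#'   (`single`/`adjacent_pair`; `single` wins when both apply).
#' @examples
#' map <- tibble::tibble(probe_id = c("a", "b"), chrom = "chr1",
#'                       pos = c(1000, 3000), tier = "first")
#' sig <- tibble::tibble(probe_id = c("a", "b"),
#'                       log2_a = c(-0.9, 0), log2_b = c(-0.85, 0))
#' first_screen(sig, map)
#' @export
first_screen <- function(signals, probe_map, thresholds = screen_thresholds()) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  check_signals(signals, probe_map)
  has_mouse <- "mouse_id" %in% names(signals)
  if (!has_mouse) signals <- mutate(signals, mouse_id = "sample")

  scored <- signals %>%
    inner_join(probe_map, by = "probe_id") %>%
    arrange(.data$mouse_id, .data$chrom, .data$pos) %>%
    group_by(.data$mouse_id, .data$chrom) %>%
    mutate(
      consistent = sign(.data$log2_a) == sign(.data$log2_b),
      single = .data$consistent &
        abs(.data$log2_a) > thresholds$t_single &
        abs(.data$log2_b) > thresholds$t_single,
      pair_ok = .data$consistent &
        abs(.data$log2_a) > thresholds$t_pair &
        abs(.data$log2_b) > thresholds$t_pair,
      dir = sign(.data$log2_a),
      pair_with_prev = .data$pair_ok & lag(.data$pair_ok, default = FALSE) &
        .data$dir == lag(.data$dir, default = 0),
      pair_with_next = .data$pair_ok & lead(.data$pair_ok, default = FALSE) &
        .data$dir == lead(.data$dir, default = 0),
      positive = .data$single | .data$pair_with_prev | .data$pair_with_next
    ) %>%
    ungroup() %>%
    filter(.data$positive) %>%
    mutate(
      direction = if_else(.data$dir < 0, "loss", "gain"),
      rule = if_else(.data$single, "single", "adjacent_pair")
    ) %>%
    select(any_of(c("mouse_id", "probe_id", "chrom", "pos", "tier",
                    "direction", "rule")))
  if (!has_mouse) scored$mouse_id <- NULL
  scored
}

#' Select dense confirmation-tier probes around first-screen positives
#'
#' For each positive probe, picks the `k` nearest dense-tier probes on the
#' same chromosome, split as evenly as possible between the two sides
#' (5 + 5 for the default k = 10) and filled from the other side near a
#' chromosome edge. The original probe itself is carried along (rank 0) so
#' the confirmation array re-measures it. A dense probe occupying exactly
#' the original position is not counted among the `k` new neighbours.
#'
#' @param positives First-screen positive probes (needs `probe_id`, `chrom`,
#'   `pos`; a `mouse_id`/`direction` column is carried through).
#' @param dense_map Dense-tier probe map covering the neighbourhoods.
#' @param k Number of newly selected neighbours per positive probe (>= 10
#'   by design; smaller values are refused).
#' @return A second-screen probe map: `origin_probe_id`, `probe_id`,
#'   `chrom`, `pos`, `tier`, `rank` (dense-grid rank distance from the
#'   original probe; 0 for the original itself), plus carried columns.
#' @export
select_second_tier_probes <- function(positives, dense_map, k = 10L) {
  if (k < 10L) abort("At least 10 neighbouring probes are selected per positive (k >= 10).")
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(positives)))
  carry <- intersect(c("mouse_id", "direction"), names(positives))

  dense_map <- dense_map[order(dense_map$chrom, dense_map$pos), ]
  dense_by_chrom <- split(dense_map, dense_map$chrom)

  purrr::map_dfr(seq_len(nrow(positives)), function(i) {
    p <- positives[i, ]
    dm <- dense_by_chrom[[p$chrom]]
    if (is.null(dm)) dm <- dense_map[0, ]
    dm <- dm[dm$pos != p$pos, , drop = FALSE]
    if (nrow(dm) < k) {
      abort(sprintf(
        "Only %d dense probes available on %s; %d are required around probe %s.",
        nrow(dm), p$chrom, k, p$probe_id))
    }
    n_left_avail <- sum(dm$pos < p$pos)
    n_right_avail <- nrow(dm) - n_left_avail
    n_left <- floor(k / 2)
    n_right <- k - n_left
    # one-sided fill near chromosome edges
    if (n_left_avail < n_left) {
      n_right <- n_right + (n_left - n_left_avail)
      n_left <- n_left_avail
    } else if (n_right_avail < n_right) {
      n_left <- n_left + (n_right - n_right_avail)
      n_right <- n_right_avail
    }
    left <- dm[dm$pos < p$pos, ]
    right <- dm[dm$pos > p$pos, ]
    sel <- bind_rows(
      tail(left, n_left) %>% mutate(rank = rev(seq_len(n_left))),
      head(right, n_right) %>% mutate(rank = seq_len(n_right))
    )
    origin <- tibble(probe_id = p$probe_id, chrom = p$chrom, pos = p$pos,
                     tier = "first", rank = 0L)
    out <- bind_rows(origin, sel %>% select("probe_id", "chrom", "pos", "tier", "rank")) %>%
      mutate(origin_probe_id = p$probe_id) %>%
      arrange(.data$pos)
    for (col in carry) out[[col]] <- p[[col]]
    out %>% select(any_of(c("mouse_id", "origin_probe_id", "probe_id", "chrom",
                            "pos", "tier", "rank", "direction")))
  })
}

#' Second-screen confirmation of first-screen positive probes
#'
#' A first-screen positive probe is confirmed when (1) the probe itself
#' again shows both dye-swap |log2 ratios| strictly above `t_second` on the
#' confirmation array, and (2) at least one newly selected neighbouring
#' probe within `neighbor_window` probe ranks does too. Tested probes must
#' match the original direction.
#'
#' @param positives First-screen positives being confirmed (needs
#'   `probe_id`, `direction`; `mouse_id` carried through if present).
#' @param second_signals Dye-swap signals measured on the confirmation
#'   array, covering the selected probes.
#' @param second_map Output of [select_second_tier_probes()].
#' @param thresholds A [screen_thresholds()].
#' @return One row per original positive probe: `origin_probe_id`,
#'   `confirmed`, `n_support`, and a `support` list-column holding every
#'   second-screen probe (any rank, original included) that passed the
#'   `t_second` rule in the original direction -- the input to interval
#'   estimation.
#' @export
second_screen <- function(positives, second_signals, second_map,
                          thresholds = screen_thresholds()) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  stopifnot(all(c("probe_id", "direction") %in% names(positives)))
  has_mouse <- "mouse_id" %in% names(positives) && "mouse_id" %in% names(second_signals)

  join_by <- if (has_mouse) c("mouse_id", "probe_id") else "probe_id"
  map_cols <- intersect(c("mouse_id", "origin_probe_id", "probe_id", "chrom",
                          "pos", "rank", "tier"), names(second_map))
  measured <- second_map %>%
    select(all_of(map_cols)) %>%
    inner_join(second_signals %>%
                 select(any_of(c("mouse_id", "probe_id", "log2_a", "log2_b"))),
               by = join_by)

  purrr::map_dfr(seq_len(nrow(positives)), function(i) {
    p <- positives[i, ]
    rows <- measured[measured$origin_probe_id == p$probe_id, , drop = FALSE]
    if (has_mouse) rows <- rows[rows$mouse_id == p$mouse_id, , drop = FALSE]
    orig <- rows[rows$rank == 0L, , drop = FALSE]
    if (nrow(orig) == 0L) {
      abort(sprintf("Probe %s is missing from the second-screen data.", p$probe_id))
    }
    want_sign <- if (p$direction == "loss") -1 else 1
    passes <- sign(rows$log2_a) == want_sign & sign(rows$log2_b) == want_sign &
      abs(rows$log2_a) > thresholds$t_second &
      abs(rows$log2_b) > thresholds$t_second
    cond1 <- any(passes[rows$rank == 0L])
    cond2 <- any(passes[rows$rank >= 1L & rows$rank <= thresholds$neighbor_window])
    support <- rows[passes, , drop = FALSE] %>%
      select(any_of(c("probe_id", "chrom", "pos", "rank", "tier")))
    out <- tibble(
      origin_probe_id = p$probe_id,
      direction = p$direction,
      confirmed = cond1 && cond2,
      n_support = nrow(support),
      support = list(support)
    )
    if (has_mouse) out <- mutate(out, mouse_id = p$mouse_id, .before = 1)
    out
  })
}
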