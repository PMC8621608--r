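test_that("family analysis removes inherited positives and keeps de novo ones", {
  f1 <- tibble::tibble(probe_id = "p", chrom = "chr1", pos = 5e6,
                       direction = "loss")
  none <- f1[0, ]

  # same-coordinate same-direction parental probe: inherited
  expect_equal(nrow(family_filter(f1, f1, none)), 0)
  # clean parents: retained
  expect_equal(nrow(family_filter(f1, none, none)), 1)
  # direction mismatch in the dam: retained
  dam_gain <- dplyr::mutate(f1, direction = "gain")
  expect_equal(nrow(family_filter(f1, none, dam_gain)), 1)
  # parental probe just inside/outside the window
  near <- dplyr::mutate(f1, pos = pos + 10000)
  far <- dplyr::mutate(f1, pos = pos + 10001)
  expect_equal(nrow(family_filter(f1, near, none)), 0)
  expect_equal(nrow(family_filter(f1, far, none)), 1)
  # absent parental data cannot be treated as a clean screen
  expect_error(family_filter(f1, NULL, none), "parental screening")
})

test_that("family analysis agrees with a literal brute-force check", {
  # oracle: triple loop over the rule as stated
  oracle <- function(f1, parents, window) {
    keep <- logical(nrow(f1))
    for (i in seq_len(nrow(f1))) {
      match_found <- FALSE
      for (j in seq_len(nrow(parents))) {
        if (parents$chrom[j] == f1$chrom[i] &&
            parents$direction[j] == f1$direction[i] &&
            abs(parents$pos[j] - f1$pos[i]) <= window) match_found <- TRUE
      }
      keep[i] <- !match_found
    }
    f1[keep, ]
  }
  set.seed(99)
  for (rep in 1:20) {
    mk <- function(n) tibble::tibble(
      probe_id = sprintf("r%d_%d", rep, seq_len(n)),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos = sample(seq(2000, 20000, 2000), n, replace = TRUE),
      direction = sample(c("loss", "gain"), n, replace = TRUE))
    f1 <- mk(6)
    sire <- mk(3)
    dam <- mk(3)
    got <- family_filter(f1, sire, dam, window = 4000)
    want <- oracle(f1, dplyr::bind_rows(sire, dam), 4000)
    expect_equal(got$probe_id, want$probe_id)
  }
})

test_that("candidates are maximal same-direction runs of consecutive probes", {
  big <- toy_map(600)
  run575 <- big %>%
    dplyr::slice(10:584) %>%
    dplyr::transmute(probe_id, chrom, pos, direction = "loss")
  cand <- call_candidates(run575, big)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_pos_first, 575)
  expect_equal(cand$cnv_type, "L")
  expect_equal(cand$kind, "deletion")

  map <- toy_map(10)
  one <- tibble::tibble(probe_id = "chr1_p05", chrom = "chr1", pos = 10000,
                        direction = "loss")
  c1 <- call_candidates(one, map)
  expect_equal(c1$n_pos_first, 1)
  expect_equal(c1$cnv_type, "S")

  # a flat probe between two runs splits them
  split <- tibble::tibble(
    probe_id = c("chr1_p02", "chr1_p03", "chr1_p05"),
    chrom = "chr1", pos = c(4000, 6000, 10000), direction = "loss")
  expect_equal(nrow(call_candidates(split, map)), 2)

  # direction flips split runs too, and kinds follow direction
  flip <- tibble::tibble(
    probe_id = c("chr1_p02", "chr1_p03"), chrom = "chr1",
    pos = c(4000, 6000), direction = c("loss", "gain"))
  cf <- call_candidates(flip, map)
  expect_equal(nrow(cf), 2)
  expect_setequal(cf$kind, c("deletion", "duplication"))

  # gap tolerance merges across one flat probe when asked
  expect_equal(nrow(call_candidates(split, map, gap_tolerance = 1L)), 1)

  expect_equal(nrow(call_candidates(one[0, ], map)), 0)
})

test_that("type classification is a partition on first-screen support", {
  expect_equal(classify_cnv_type(c(1L, 2L, 575L)), c("S", "L", "L"))
  expect_error(classify_cnv_type(0L))
})

test_that("interval estimation spans the outermost supporting probes", {
  cand <- tibble::tibble(
    mouse_id = "0mGyO7", chrom = "Chr1", kind = "deletion",
    n_pos_first = 1L, cnv_type = "S", first_pos = 7323466, last_pos = 7323466,
    status = "candidate", probe_ids = list("pX"))
  support <- tibble::tibble(
    mouse_id = "0mGyO7", origin_probe_id = "pX",
    pos = c(7323388, 7323466, 7323541))
  est <- estimate_interval(cand, support)
  expect_equal(est$start, 7323388)
  expect_equal(est$end, 7323541)
  expect_equal(est$size, 153)
  expect_equal(est$size, est$end - est$start)

  # a single supporting probe cannot be sized
  lone <- dplyr::mutate(cand, first_pos = 100, last_pos = 100)
  expect_error(estimate_interval(lone, support[0, ]), "cannot be sized")

  # support belonging to other probes or mice is ignored
  foreign <- dplyr::mutate(support, origin_probe_id = "pY")
  expect_error(estimate_interval(cand, foreign), "cannot be sized")
})

test_that("gene overlap counting uses closed intervals with >= 1 bp overlap", {
  calls <- tibble::tibble(mouse_id = "m", chrom = "chr1",
                          start = 1000, end = 2000)
  genes <- tibble::tibble(
    chrom = "chr1",
    start = c(500, 900, 1500, 2000, 2001),
    end = c(800, 1100, 1600, 2400, 2500))
  out <- annotate_genes(calls, genes)
  # overlapping: [900,1100], [1500,1600], [2000,2400]; abutting 2001 excluded
  expect_equal(out$gene_count, 3)

  expect_equal(annotate_genes(calls, genes[0, ])$gene_count, 0)

  # brute-force closed-interval oracle on random cases
  set.seed(17)
  for (rep in 1:10) {
    rc <- tibble::tibble(mouse_id = "m", chrom = "chr1",
                         start = sample(1000, 1), end = 0)
    rc$end <- rc$start + sample(500, 1)
    rg <- tibble::tibble(chrom = "chr1", start = sample(1500, 20, replace = TRUE),
                         end = 0)
    rg$end <- rg$start + sample(300, 20, replace = TRUE)
    want <- sum(rg$start <= rc$end & rg$end >= rc$start)
    expect_equal(annotate_genes(rc, rg)$gene_count, want)
  }
})

test_that("mouse tallies exclude multi-CNV animals and count mice once", {
  mice <- tibble::tibble(
    mouse_id = sprintf("m%02d", 1:18),
    role = "f1",
    sex = rep(c("M", "F"), 9),
    group = rep(c("non_irradiated", "irradiated"), each = 9))
  call_row <- function(id, kind = "deletion", type = "L",
                       status = "confirmed") {
    tibble::tibble(mouse_id = id, kind = kind, cnv_type = type, status = status)
  }
  calls <- dplyr::bind_rows(
    call_row("m01"), call_row("m01", type = "S"),   # both L and S deletions
    call_row("m03", kind = "duplication"),
    call_row("m10"), call_row("m12", type = "S"),
    call_row("m14", status = "rejected"),           # rejected calls never count
    call_row("m05"), call_row("m05"), call_row("m05"), call_row("m05"))

  all_del <- tally_mice(mice, calls, kind = "deletion")
  ctl <- all_del[all_del$group == "non_irradiated", ]
  irr <- all_del[all_del$group == "irradiated", ]
  # m05 (4 confirmed calls) is excluded from numerator AND denominator
  expect_equal(ctl$n_with, 1)
  expect_equal(ctl$n_total, 8)
  expect_equal(irr$n_with, 2)
  expect_equal(irr$n_total, 9)

  # the dual-type mouse appears in both the S and the L stratum
  l_del <- tally_mice(mice, calls, kind = "deletion", cnv_type = "L")
  s_del <- tally_mice(mice, calls, kind = "deletion", cnv_type = "S")
  expect_equal(l_del$n_with[l_del$group == "non_irradiated"], 1)
  expect_equal(s_del$n_with[s_del$group == "non_irradiated"], 1)

  # sex strata partition the pooled denominator
  m <- tally_mice(mice, calls, kind = "deletion", sex = "M")
  f <- tally_mice(mice, calls, kind = "deletion", sex = "F")
  expect_equal(m$n_total + f$n_total, all_del$n_total)
  expect_equal(m$n_with + f$n_with, all_del$n_with)

  # callless cohort tallies to (0, n)
  zero <- tally_mice(mice, calls[0, ], kind = "deletion")
  expect_equal(zero$n_with, c(0, 0))

  expect_error(tally_mice(mice, calls, kind = "inversion"), "deletion")
  expect_error(tally_mice(mice, calls, cnv_type = "XL"), "S")
})
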