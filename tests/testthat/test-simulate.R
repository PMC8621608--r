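test_that("probe maps tile each chromosome at the configured spacing", {
  cfg <- tiny_config(n_chromosomes = 1L, chromosome_length = 1e7)
  first <- simulate_probe_map(cfg, "first")
  expect_equal(nrow(first), 5000)
  expect_equal(first$pos[1:3], c(2000, 4000, 6000))
  expect_false(anyDuplicated(first$probe_id) > 0)

  second <- simulate_probe_map(cfg, "second")
  expect_equal(nrow(second), 100000)

  # identical config => identical coordinates
  expect_identical(first, simulate_probe_map(cfg, "first"))

  # restricting the dense tier to regions keeps only covered probes
  reg <- tibble::tibble(chrom = "chr1", start = 5000, end = 6000)
  expect_equal(simulate_probe_map(cfg, "second", regions = reg)$pos,
               seq(5000, 6000, 100))

  expect_error(simulate_probe_map(tiny_config(chromosome_length = 500)),
               "spacing exceeds")
})

test_that("cohort generation is deterministic and respects the rate knobs", {
  cfg <- tiny_config(seed = 42L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$mice, c2$mice)
  expect_identical(c1$cnvs, c2$cnvs)

  # group sizes and trio structure
  f1 <- dplyr::filter(c1$mice, role == "f1")
  expect_equal(sum(f1$group == "non_irradiated"), 4)
  expect_equal(sum(f1$group == "irradiated"), 4)
  roles <- dplyr::count(c1$mice, family, role)
  expect_true(all(roles$n[roles$role %in% c("sire", "dam")] == 1))

  # zero de novo rates leave only founder/inherited CNVs
  c0 <- simulate_cohort(tiny_config(denovo_rate_non_irradiated = 0,
                                    denovo_rate_irradiated = 0))
  expect_false(any(c0$cnvs$origin == "de_novo"))

  expect_error(tiny_config(denovo_rate_irradiated = -1), "non-negative")
  expect_error(tiny_config(second_tier_spacing = 3000), "smaller")
  expect_error(tiny_config(duplication_fraction = 1.5), "0, 1")
})

test_that("de novo incidence matches the configured Poisson rates", {
  cfg <- tiny_config(seed = 7L, n_f1_per_group = c(10000L, 10000L),
                     n_f1_per_family = 10L, inherited_cnv_rate = 0,
                     denovo_rate_non_irradiated = 0.074,
                     denovo_rate_irradiated = 0.23)
  cohort <- simulate_cohort(cfg)
  f1 <- dplyr::filter(cohort$mice, role == "f1")
  counts <- dplyr::count(cohort$cnvs, mouse_id)
  per_mouse <- dplyr::left_join(f1, counts, by = "mouse_id") %>%
    dplyr::mutate(n = dplyr::coalesce(n, 0L))
  for (grp in c("non_irradiated", "irradiated")) {
    rate <- if (grp == "irradiated") 0.23 else 0.074
    x <- per_mouse$n[per_mouse$group == grp]
    se <- sqrt(rate / length(x))
    expect_lt(abs(mean(x) - rate), 3 * se)
  }
})

test_that("zero-noise signals equal the copy-number shift exactly", {
  cfg <- tiny_config(n_chromosomes = 1L, chromosome_length = 1e5, noise_sd = 0)
  map <- simulate_probe_map(cfg, "first")
  mice <- tibble::tibble(mouse_id = c("m_del", "m_dup"))
  cnvs <- tibble::tibble(
    mouse_id = c("m_del", "m_dup"), chrom = "chr1",
    start = c(10100, 50100), end = c(30100, 70100),
    copy_number = c(1L, 3L)
  )
  sig <- simulate_signals(mice, cnvs, map, cfg)
  with_pos <- dplyr::inner_join(sig, map, by = "probe_id")

  del_in <- with_pos$mouse_id == "m_del" & with_pos$pos > 10100 & with_pos$pos < 30100
  expect_true(all(with_pos$log2_a[del_in] == -1))
  expect_true(all(with_pos$log2_b[del_in] == -1))
  dup_in <- with_pos$mouse_id == "m_dup" & with_pos$pos > 50100 & with_pos$pos < 70100
  expect_true(all(with_pos$log2_a[dup_in] == log2(1.5)))
  expect_true(all(with_pos$log2_a[!del_in & !dup_in] == 0))

  # boundary probes exactly on start/end are not inside
  edge <- tibble::tibble(mouse_id = "m_del", chrom = "chr1",
                         start = 2000, end = 4000, copy_number = 1L)
  sig_edge <- simulate_signals(tibble::tibble(mouse_id = "m_del"), edge, map, cfg)
  expect_true(all(sig_edge$log2_a == 0))

  expect_error(
    simulate_signals(mice, dplyr::mutate(cnvs, mouse_id = "ghost"), map, cfg),
    "unknown mouse")
  expect_error(
    simulate_signals(mice, dplyr::mutate(cnvs, end = 1e9), map, cfg),
    "within the genome")
})

test_that("dye-swap orientation flag flips experiment B only", {
  cfg <- tiny_config(n_chromosomes = 1L, chromosome_length = 1e5, noise_sd = 0.2)
  map <- simulate_probe_map(cfg, "first")
  mice <- tibble::tibble(mouse_id = "m1")
  none <- tibble::tibble(mouse_id = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         copy_number = integer())
  norm <- simulate_signals(mice, none, map, cfg, seed = 9L)
  raw <- simulate_signals(mice, none, map, cfg, seed = 9L, raw_orientation = TRUE)
  expect_identical(norm$log2_a, raw$log2_a)
  expect_identical(norm$log2_b, -raw$log2_b)
})

test_that("inherited CNVs trace back to exactly one parent at identical coordinates", {
  cfg <- tiny_config(seed = 11L, n_f1_per_group = c(40L, 40L),
                     inherited_cnv_rate = 1.5)
  cohort <- simulate_cohort(cfg)
  fams <- cohort$mice %>% dplyr::select(mouse_id, family, role)
  inh <- dplyr::filter(cohort$cnvs, origin %in% c("inherited_sire", "inherited_dam"))
  expect_gt(nrow(inh), 0)
  founders <- dplyr::filter(cohort$cnvs, origin == "founder") %>%
    dplyr::inner_join(fams, by = "mouse_id")
  for (i in seq_len(nrow(inh))) {
    kid_family <- fams$family[fams$mouse_id == inh$mouse_id[i]]
    src_role <- if (inh$origin[i] == "inherited_sire") "sire" else "dam"
    hits <- founders$family == kid_family & founders$role == src_role &
      founders$chrom == inh$chrom[i] & founders$start == inh$start[i] &
      founders$end == inh$end[i]
    expect_equal(sum(hits), 1)
  }
})

test_that("lifespans show no strata differences when all hazard ratios are 1", {
  cfg <- tiny_config(seed = 5L, n_f1_per_group = c(1000L, 1000L),
                     n_f1_per_family = 4L, inherited_cnv_rate = 0,
                     denovo_rate_non_irradiated = 0.3,
                     denovo_rate_irradiated = 0.3,
                     hazard_ratios = c(sex = 1, irradiation = 1, cnv = 1))
  cohort <- simulate_cohort(cfg)
  f1 <- dplyr::filter(cohort$mice, role == "f1") %>%
    dplyr::mutate(cnv = mouse_id %in%
                    cohort$cnvs$mouse_id[cohort$cnvs$origin == "de_novo"])
  sd <- survival::survdiff(
    survival::Surv(lifespan_days, rep(1, nrow(f1))) ~ sex + group + cnv,
    data = f1)
  p <- stats::pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("configured hazard ratios shift group lifespans in the expected direction", {
  cfg <- tiny_config(seed = 13L, n_f1_per_group = c(1500L, 1500L),
                     n_f1_per_family = 5L, inherited_cnv_rate = 0,
                     denovo_rate_non_irradiated = 0,
                     denovo_rate_irradiated = 0)
  cohort <- simulate_cohort(cfg)
  f1 <- dplyr::filter(cohort$mice, role == "f1")
  # females carry hazard 1.972 > 1 => shorter lives than males
  expect_lt(mean(f1$lifespan_days[f1$sex == "F"]),
            mean(f1$lifespan_days[f1$sex == "M"]))
  # reference stratum mean near the configured 914 days
  ref <- f1$lifespan_days[f1$sex == "M" & f1$group == "non_irradiated"]
  expect_lt(abs(mean(ref) - 914), 3 * sd(ref) / sqrt(length(ref)))
})
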