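# Shared fixtures: tiny configurations, toy probe maps and hand-built
# signal tables. Everything is generated in code; no stored data.

tiny_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed, n_f1_per_group = c(4L, 4L), n_f1_per_family = 2L,
    n_chromosomes = 2L, chromosome_length = 1e6, noise_sd = 0,
    denovo_rate_non_irradiated = 0.5, denovo_rate_irradiated = 1,
    size_log10_range = c(4, 5), inherited_cnv_rate = 0.5
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

toy_map <- function(n = 10, spacing = 2000, chrom = "chr1", tier = "first",
                    prefix = chrom) {
  tibble::tibble(
    probe_id = sprintf("%s_p%02d", prefix, seq_len(n)),
    chrom = chrom,
    pos = spacing * seq_len(n),
    tier = tier
  )
}

flat_signals <- function(map, mouse_id = NULL) {
  s <- tibble::tibble(probe_id = map$probe_id, log2_a = 0, log2_b = 0)
  if (!is.null(mouse_id)) s <- dplyr::mutate(s, mouse_id = mouse_id)
  s
}

set_probe <- function(signals, probe_id, a, b) {
  i <- signals$probe_id %in% probe_id
  signals$log2_a[i] <- a
  signals$log2_b[i] <- b
  signals
}

# Independent two-sided Fisher oracle: exhaustive hypergeometric
# enumeration over all tables with the observed margins, summing the
# probabilities of tables no more probable than the observed one (with the
# usual 1 + 1e-7 relative guard against floating-point ties).
fisher_enum_p <- function(a, b, c, d, alternative = "two.sided") {
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  x <- max(0, col1 - row2):min(row1, col1)
  probs <- stats::dhyper(x, row1, row2, col1)
  obs <- stats::dhyper(a, row1, row2, col1)
  switch(alternative,
    two.sided = sum(probs[probs <= obs * (1 + 1e-7)]),
    less = sum(probs[x <= a]),
    greater = sum(probs[x >= a])
  )
}
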