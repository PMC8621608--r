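#' Fisher's exact test on a 2x2 mice-with-CNV table
#'
#' Thin, validated wrapper around [stats::fisher.test()]. The two-sided
#' p-value follows the probability-mass summation convention: it is the sum
#' of the hypergeometric probabilities of all tables with the observed
#' margins that are no more probable than the observed one.
#'
#' @param a,b First group: mice with and without qualifying CNV(s).
#' @param c,d Second group: mice with and without qualifying CNV(s).
#' @param alternative Passed to [stats::fisher.test()]; `"less"` tests for a
#'   lower carrier proportion in the first row.
#' @return The p-value (length-1 numeric).
#' @examples
#' fisher_p(11, 145, 29, 113) # ~0.00103
#' @export
fisher_p <- function(a, b, c, d, alternative = "two.sided") {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Contingency counts must be non-negative integers.")
  }
  if (sum(counts) == 0) abort("The contingency table is empty.")
  fisher.test(matrix(counts, nrow = 2, byrow = TRUE),
              alternative = alternative)$p.value
}

#' Carrier proportions and fold change between two tallies
#'
#' Percentages are reported to 1 decimal place; the fold change is the ratio
#' of the *unrounded* proportions, reported to 1 decimal place (so 11/156 vs
#' 29/142 gives 7.1%, 20.4% and fold 2.9).
#'
#' @param n_a,total_a Carrier count and group size of the first group.
#' @param n_b,total_b Carrier count and group size of the second group.
#' @return One-row tibble: `pct_a`, `pct_b`, `fold`.
#' @examples
#' proportion_fold(11, 156, 29, 142)
#' @export
proportion_fold <- function(n_a, total_a, n_b, total_b) {
  if (total_a <= 0 || total_b <= 0) abort("Group sizes must be positive.")
  p_a <- n_a / total_a
  p_b <- n_b / total_b
  if (p_a == 0) abort("The fold change is undefined when the first proportion is zero.")
  tibble(
    pct_a = round(100 * p_a, 1),
    pct_b = round(100 * p_b, 1),
    fold = round(p_b / p_a, 1)
  )
}

#' Contingency comparison of carrier tallies between two groups
#'
#' Combines [fisher_p()] and [proportion_fold()] into the row format of a
#' published mice-with-CNV table.
#'
#' @inheritParams proportion_fold
#' @inheritParams fisher_p
#' @return One-row tibble: counts, percentages, `fold`, `p_value`,
#'   `alternative`.
#' @export
cnv_contingency <- function(n_a, total_a, n_b, total_b,
                            alternative = "two.sided") {
  p <- fisher_p(n_a, total_a - n_a, n_b, total_b - n_b,
                alternative = alternative)
  pf <- if (n_a > 0) proportion_fold(n_a, total_a, n_b, total_b) else
    tibble(pct_a = 0, pct_b = round(100 * n_b / total_b, 1), fold = NA_real_)
  tibble(
    n_a = n_a, total_a = total_a, pct_a = pf$pct_a,
    n_b = n_b, total_b = total_b, pct_b = pf$pct_b,
    fold = pf$fold, p_value = p, alternative = alternative
  )
}

#' Geometric mean and geometric standard deviation
#'
#' For quantities spanning orders of magnitude (CNV sizes range from about
#' 150 bp to 2 Mb) the geometric mean `exp(mean(log x))` is the appropriate
#' location summary; the geometric SD is `exp(sd(log x))` with the n-1
#' denominator, a unitless multiplicative spread.
#'
#' @param sizes Positive numeric vector (bp).
#' @return One-row tibble: `n`, `gm`, `gsd` (`NA` when n < 2).
#' @examples
#' geometric_stats(c(10, 1000)) # gm 100
#' @export
geometric_stats <- function(sizes) {
  if (length(sizes) == 0) abort("At least one size is required.")
  if (any(sizes <= 0)) abort("Sizes must be positive.")
  lg <- log(sizes)
  tibble(
    n = length(sizes),
    gm = exp(mean(lg)),
    gsd = if (length(sizes) >= 2) exp(sd(lg)) else NA_real_
  )
}

#' Compare two size distributions on the log scale
#'
#' The equality of log-variances is checked with an F-test; if it is not
#' rejected at `alpha`, a pooled-variance two-sided t-test on the logs is
#' used, otherwise the unequal-variance (Welch) form, with the choice
#' flagged in the output.
#'
#' @param sizes_a,sizes_b Positive numeric vectors, each of length >= 2.
#' @param alpha Significance level of the variance pre-test.
#' @return One-row tibble: `n_a`, `n_b`, `f_p`, `var_equal`, `t_p`.
#' @export
log_size_test <- function(sizes_a, sizes_b, alpha = 0.05) {
  if (length(sizes_a) < 2 || length(sizes_b) < 2) {
    abort("Each group needs at least two sizes.")
  }
  if (any(c(sizes_a, sizes_b) <= 0)) abort("Sizes must be positive.")
  la <- log(sizes_a)
  lb <- log(sizes_b)
  if (sd(la) == 0 && sd(lb) == 0) {
    abort("Both groups have zero variance on the log scale; the tests are undefined.")
  }
  f_p <- var.test(la, lb)$p.value
  var_equal <- f_p > alpha
  t_p <- t.test(la, lb, var.equal = var_equal)$p.value
  tibble(n_a = length(sizes_a), n_b = length(sizes_b),
         f_p = f_p, var_equal = var_equal, t_p = t_p)
}

grubbs_min_statistic <- function(x) (mean(x) - min(x)) / sd(x)

grubbs_critical <- function(n, alpha = 0.05) {
  # one-sided test of the sample minimum
  t <- qt(alpha / n, df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t ^ 2 / (n - 2 + t ^ 2))
}

#' Exclude very short-lived mice from the lifespan analysis
#'
#' Iterative one-sided Grubbs (maximum studentized deviation) test of the
#' sample minimum at level `alpha`; a mouse is excluded only when it is both
#' rejected by the Grubbs test and lived `cutoff` days or less, so an
#' unusually short-lived but not extreme animal is retained, as is a
#' statistically extreme one above the hard cutoff.
#'
#' @param mice Tibble with `mouse_id` and `lifespan_days` (a bare numeric
#'   vector is also accepted).
#' @param alpha Grubbs significance level per iteration.
#' @param cutoff Hard lifespan cutoff in days.
#' @return Tibble (`mouse_id`, `lifespan_days`, `grubbs_rejected`,
#'   `excluded`); with fewer than 3 mice no test is run and nothing is
#'   excluded.
#' @export
exclude_short_lived <- function(mice, alpha = 0.05, cutoff = 300) {
  if (is.numeric(mice)) {
    mice <- tibble(mouse_id = paste0("mouse_", seq_along(mice)),
                   lifespan_days = mice)
  }
  stopifnot(all(c("mouse_id", "lifespan_days") %in% names(mice)))
  out <- mice %>%
    select("mouse_id", "lifespan_days") %>%
    mutate(grubbs_rejected = FALSE)
  active <- rep(TRUE, nrow(out))
  repeat {
    x <- out$lifespan_days[active]
    if (length(x) < 3 || sd(x) == 0) break
    g <- grubbs_min_statistic(x)
    if (g <= grubbs_critical(length(x), alpha)) break
    drop_idx <- which(active)[which.min(x)]
    out$grubbs_rejected[drop_idx] <- TRUE
    active[drop_idx] <- FALSE
  }
  mutate(out, excluded = .data$grubbs_rejected & .data$lifespan_days <= cutoff)
}

#' Cox proportional-hazards fit of lifespan on sex, irradiation and CNV
#'
#' Maximises the Cox partial likelihood (Efron tie handling by default) for
#' three binary covariates coded with male, non-irradiated, CNV-free as the
#' reference level 0. All animals live out their natural lifespan in the
#' emulated design, so every record defaults to an observed event; an
#' `event` column (0/1) is honoured when present.
#'
#' @param data Tibble with `lifespan_days`, `sex` (`"M"`/`"F"` or 0/1),
#'   `group` (`"non_irradiated"`/`"irradiated"` or 0/1) and `cnv` (logical
#'   or 0/1), optionally `event`.
#' @param ties `"efron"` or `"breslow"`.
#' @return Object of class `cnv_coxfit` wrapping the [survival::coxph()]
#'   fit, with [tidy()] and [glance()] methods.
#' @export
cox_lifespan_fit <- function(data, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("lifespan_days", "sex", "group", "cnv") %in% names(data)))
  if (any(data$lifespan_days <= 0)) abort("Lifespans must be positive.")
  d <- tibble(
    lifespan_days = data$lifespan_days,
    event = if ("event" %in% names(data)) data$event else 1,
    sex = if (is.character(data$sex) || is.factor(data$sex))
      as.integer(as.character(data$sex) == "F") else as.integer(data$sex),
    irradiation = if (is.character(data$group) || is.factor(data$group))
      as.integer(as.character(data$group) == "irradiated") else as.integer(data$group),
    cnv = as.integer(as.logical(data$cnv))
  )
  for (v in c("sex", "irradiation", "cnv")) {
    if (length(unique(d[[v]])) < 2) {
      abort(sprintf("Covariate `%s` is constant across all mice; its hazard ratio is not estimable.", v))
    }
  }
  if (length(unique(d$lifespan_days[d$event == 1])) < 2) {
    abort("At least two distinct event times are required.")
  }
  fit <- survival::coxph(
    survival::Surv(lifespan_days, event) ~ sex + irradiation + cnv,
    data = d, ties = ties
  )
  structure(list(fit = fit, ties = ties, n = nrow(d), n_events = sum(d$event)),
            class = "cnv_coxfit")
}

#' @export
print.cnv_coxfit <- function(x, ...) {
  cat(sprintf("<cnv_coxfit> %d mice, %d events, %s ties\n",
              x$n, x$n_events, x$ties))
  print(tidy(x))
  invisible(x)
}

#' @rdname cox_lifespan_fit
#' @param x A `cnv_coxfit`.
#' @param ... Unused.
#' @export
tidy.cnv_coxfit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    factor = rownames(s),
    log_hr = unname(s[, "coef"]),
    hazard_ratio = unname(s[, "exp(coef)"]),
    std_error = unname(s[, "se(coef)"]),
    z = unname(s[, "z"]),
    p_value = unname(s[, "Pr(>|z|)"])
  )
}

#' @rdname cox_lifespan_fit
#' @export
glance.cnv_coxfit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$n, n_events = x$n_events, ties = x$ties,
    concordance = unname(s$concordance["C"]),
    logLik = unname(x$fit$loglik[2])
  )
}

#' Cohort-level statistics report
#'
#' Runs the full statistics layer over a cohort and its confirmed calls:
#' mice-with-CNV contingency tables (all deletions, Type L and Type S
#' deletions; pooled and per sex), deletion-size geometric statistics with
#' the F/t test on logs, Grubbs/cutoff lifespan exclusions and the Cox
#' proportional-hazards fit.
#'
#' @param mice Cohort mice tibble (`mouse_id`, `role`, `sex`, `group`,
#'   `lifespan_days`).
#' @param calls Call tibble with `mouse_id`, `kind`, `cnv_type`, `size`,
#'   `status`.
#' @param multi_cnv_threshold See [tally_mice()].
#' @param ties Cox tie handling.
#' @return A `cohort_summary` list: `tallies` (tibble of strata x groups
#'   with Fisher p-values), `sizes` (per-group geometric stats),
#'   `size_test`, `exclusions`, `cox` (a `cnv_coxfit`, or `NULL` when a
#'   covariate is constant).
#' @export
cohort_stats <- function(mice, calls, multi_cnv_threshold = 4L,
                         ties = "efron") {
  f1 <- if ("role" %in% names(mice)) filter(mice, .data$role == "f1") else mice
  strata <- tidyr::expand_grid(
    sex = list(NULL, "M", "F"),
    cnv_type = list(NULL, "L", "S")
  )
  tallies <- purrr::map_dfr(seq_len(nrow(strata)), function(i) {
    sx <- strata$sex[[i]]
    tp <- strata$cnv_type[[i]]
    tl <- tally_mice(f1, calls, kind = "deletion", cnv_type = tp, sex = sx,
                     multi_cnv_threshold = multi_cnv_threshold)
    ctl <- tl[tl$group == "non_irradiated", ]
    irr <- tl[tl$group == "irradiated", ]
    if (nrow(ctl) == 0 || nrow(irr) == 0) return(tibble())
    p <- fisher_p(ctl$n_with, ctl$n_total - ctl$n_with,
                  irr$n_with, irr$n_total - irr$n_with)
    tibble(
      sex = if (is.null(sx)) "all" else sx,
      cnv_type = if (is.null(tp)) "all" else tp,
      n_ctl = ctl$n_with, total_ctl = ctl$n_total, pct_ctl = ctl$pct,
      n_irr = irr$n_with, total_irr = irr$n_total, pct_irr = irr$pct,
      fold = if (ctl$n_with > 0)
        proportion_fold(ctl$n_with, ctl$n_total, irr$n_with, irr$n_total)$fold
      else NA_real_,
      p_two_sided = p
    )
  })

  confirmed_del <- filter(calls, .data$status == "confirmed",
                          .data$kind == "deletion")
  grp <- f1 %>% select("mouse_id", "group")
  del_sizes <- confirmed_del %>% inner_join(grp, by = "mouse_id")
  sizes <- if (nrow(del_sizes) == 0) {
    tibble(group = character(), n = integer(), gm = numeric(), gsd = numeric())
  } else {
    del_sizes %>%
      group_by(.data$group) %>%
      summarise(geometric_stats(.data$size), .groups = "drop")
  }
  sa <- del_sizes$size[del_sizes$group == "non_irradiated"]
  sb <- del_sizes$size[del_sizes$group == "irradiated"]
  size_test <- if (length(sa) >= 2 && length(sb) >= 2 &&
                   (sd(log(sa)) > 0 || sd(log(sb)) > 0)) {
    log_size_test(sa, sb)
  } else NULL

  exclusions <- exclude_short_lived(f1)
  kept <- f1 %>%
    semi_join(filter(exclusions, !.data$excluded), by = "mouse_id") %>%
    mutate(cnv = .data$mouse_id %in%
             calls$mouse_id[calls$status == "confirmed"])
  # small or degenerate cohorts can fail to converge; the report then simply
  # omits the survival fit
  cox <- tryCatch(suppressWarnings(cox_lifespan_fit(kept, ties = ties)),
                  error = function(e) NULL)

  structure(
    list(tallies = tallies, sizes = sizes, size_test = size_test,
         exclusions = exclusions, cox = cox),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat("Mice-with-deletion tallies (non-irradiated vs irradiated):\n")
  print(as.data.frame(x$tallies), row.names = FALSE, digits = 3)
  if (!is.null(x$size_test)) {
    cat(sprintf("\nDeletion sizes: F-test p = %.3f, t-test on logs p = %.3f\n",
                x$size_test$f_p, x$size_test$t_p))
  }
  cat(sprintf("\nLifespan exclusions: %d of %d mice\n",
              sum(x$exclusions$excluded), nrow(x$exclusions)))
  if (!is.null(x$cox)) print(x$cox)
  invisible(x)
}
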