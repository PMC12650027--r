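# Paired comparisons of homing performance across experience levels:
# normality-gated paired t / Wilcoxon signed-rank, Holm correction,
# effect sizes.

default_comparisons <- function() {
  list(c(2, 1), c(3, 2), c(4, 3), c(3, 1), c(4, 2), c(4, 1))
}

#' Paired statistics across walk-experience levels
#'
#' For each comparison `(hi, lo)`: a Shapiro-Wilk gate at `alpha` on the
#' paired differences picks a paired t-test (normal) or a Wilcoxon
#' signed-rank test; p-values are Holm-adjusted over the comparison
#' family.  Effect sizes: paired Cohen's `d_z = mean(diff) / sd(diff)`
#' (and classic d from the averaged variances) for t-tests, `r = |Z| /
#' sqrt(n)` for Wilcoxon.
#'
#' @param rates tibble with columns `agent`, `walks` and the rate in
#'   `value`; one row per agent x experience level.
#' @param value name of the rate column.
#' @param comparisons list of `c(hi, lo)` walk pairs (default: the six
#'   pairwise comparisons of walks 1-4).
#' @param alpha normality-gate level.
#' @param d_mode `"dz"` (paired) or `"classic"`; selects which Cohen's d
#'   fills `effect` for t-tests (both are always reported).
#' @return an `lw_stats` object (tibble subclass): `comparison`, `method`,
#'   `statistic`, `p`, `p_holm`, `effect`, `effect_type`, `d_z`,
#'   `d_classic`, `normal_p`, `degenerate`.
#' @export
paired_stats <- function(rates, value = "overall",
                         comparisons = default_comparisons(),
                         alpha = 0.05, d_mode = c("dz", "classic")) {
  d_mode <- match.arg(d_mode)
  if (length(unique(rates$agent)) < 3)
    abort("at least 3 agents are required for paired statistics.")
  wide <- rates |>
    dplyr::select(dplyr::all_of(c("agent", "walks", value))) |>
    tidyr::pivot_wider(names_from = "walks", values_from = dplyr::all_of(value))
  rows <- purrr::map(comparisons, function(cp) {
    hi <- wide[[as.character(cp[1])]]
    lo <- wide[[as.character(cp[2])]]
    diff <- hi - lo
    n <- length(diff)
    degenerate <- sd(diff) == 0
    d_z <- if (degenerate) {
      if (all(diff == 0)) 0 else NA_real_
    } else mean(diff) / sd(diff)
    d_classic <- if (sd(hi) == 0 && sd(lo) == 0) d_z else
      mean(diff) / sqrt((stats::var(hi) + stats::var(lo)) / 2)
    if (degenerate) {
      return(tibble::tibble(
        comparison = sprintf("LW%d vs. LW%d", cp[1], cp[2]),
        method = "degenerate", statistic = NA_real_,
        p = if (all(diff == 0)) 1 else NA_real_,
        effect = d_z, effect_type = "d_z", d_z = d_z, d_classic = d_classic,
        normal_p = NA_real_, degenerate = TRUE, n = n))
    }
    sw <- shapiro.test(diff)
    if (sw$p.value >= alpha) {
      tt <- t.test(hi, lo, paired = TRUE)
      eff <- if (d_mode == "dz") d_z else d_classic
      tibble::tibble(
        comparison = sprintf("LW%d vs. LW%d", cp[1], cp[2]),
        method = "t-test", statistic = unname(tt$statistic),
        p = tt$p.value, effect = eff,
        effect_type = if (d_mode == "dz") "d_z" else "d_classic",
        d_z = d_z, d_classic = d_classic,
        normal_p = sw$p.value, degenerate = FALSE, n = n)
    } else {
      wt <- suppressWarnings(wilcox.test(hi, lo, paired = TRUE))
      z <- abs(qnorm(wt$p.value / 2))
      tibble::tibble(
        comparison = sprintf("LW%d vs. LW%d", cp[1], cp[2]),
        method = "wilcoxon", statistic = unname(wt$statistic),
        p = wt$p.value, effect = z / sqrt(n), effect_type = "r",
        d_z = d_z, d_classic = d_classic,
        normal_p = sw$p.value, degenerate = FALSE, n = n)
    }
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, p_holm = p.adjust(.data$p, method = "holm"),
                       .after = "p")
  class(out) <- c("lw_stats", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a paired-statistics table
#'
#' @param x an `lw_stats` object.
#' @param ... unused.
#' @export
tidy.lw_stats <- function(x, ...) {
  tibble::as_tibble(x)[, c("comparison", "method", "statistic", "p",
                           "p_holm", "effect", "effect_type")]
}

#' One-row summary of a paired-statistics table
#'
#' @param x an `lw_stats` object.
#' @param ... unused.
#' @export
glance.lw_stats <- function(x, ...) {
  tibble::tibble(n_comparisons = nrow(x),
                 n_significant = sum(x$p_holm < 0.05, na.rm = TRUE),
                 max_effect = max(abs(x$effect), na.rm = TRUE),
                 n_agents = x$n[1])
}

#' Glance at a trained cohort
#'
#' @param x an `lw_cohort` object.
#' @param ... unused.
#' @export
glance.lw_cohort <- function(x, ...) {
  m <- walk_metrics(x$trajectories)
  tibble::tibble(n_agents = length(x$series),
                 n_walks = length(unique(m$walk)),
                 mean_area_last = mean(m$area[m$walk == max(m$walk)]),
                 mean_max_dist_last = mean(m$max_dist[m$walk == max(m$walk)]))
}

#' Tidy a cohort into per-walk metrics
#'
#' @param x an `lw_cohort` object.
#' @param ... unused.
#' @export
tidy.lw_cohort <- function(x, ...) walk_metrics(x$trajectories)
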