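# broom-style accessors for the fitted-object classes.

#' Tidy the per-phase statistics of a rhythm fit
#'
#' @param x A [rhythm_test()] result.
#' @param ... Unused.
#' @return One row per candidate phase with its Kendall tau.
#' @export
tidy.rhythm_fit <- function(x, ...) {
  tibble(phase_h = x$phases, tau = as.numeric(x$per_phase_tau))
}

#' One-row summary of a rhythm fit
#'
#' @param x A [rhythm_test()] result.
#' @param ... Unused.
#' @export
glance.rhythm_fit <- function(x, ...) {
  tibble(
    tau = x$tau, phase_h = x$phase_h, amplitude = x$amplitude,
    mesor = x$mesor, period_h = x$period_h, p = x$p,
    n_perm = x$n_perm, null = x$null
  )
}

#' Tidy a profile-divergence test
#'
#' @param x A [profile_divergence_test()] result.
#' @param ... Unused.
#' @return The nested-model comparison as one row per model.
#' @export
tidy.profile_divergence <- function(x, ...) {
  tibble(
    model = c("shared", "separate"),
    rss = c(x$rss_shared, x$rss_separate),
    df = c(x$df_den + x$df_num, x$df_den)
  )
}

#' @rdname tidy.profile_divergence
#' @export
glance.profile_divergence <- function(x, ...) {
  tibble(
    statistic = x$F, p_value = x$p, df_num = x$df_num, df_den = x$df_den,
    rss_shared = x$rss_shared, rss_separate = x$rss_separate, order = x$order
  )
}

#' Tidy a copy-by-condition interaction test
#'
#' @param x An [interaction_test()] result.
#' @param ... Unused.
#' @return `tidy()`: the ANOVA table; `glance()`: a one-row summary.
#' @export
tidy.ohno_interaction <- function(x, ...) {
  x$anova
}

#' @rdname tidy.ohno_interaction
#' @export
glance.ohno_interaction <- function(x, ...) {
  tibble(
    log2fc_gene1 = x$log2fc_gene1, log2fc_gene2 = x$log2fc_gene2,
    interaction_F = x$interaction_F, interaction_p = x$interaction_p,
    divergent = x$divergent, alpha = x$alpha
  )
}

#' One-row summary of a dispersion estimate
#'
#' @param x An [estimate_common_dispersion()] result.
#' @param ... Unused.
#' @export
glance.dispersion_estimate <- function(x, ...) {
  tibble(dispersion = x$dispersion, method = x$method, loglik = x$loglik)
}
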