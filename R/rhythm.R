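#' Cosine reference waveforms as rank templates
#'
#' Builds one 24-h cosine template per candidate peak phase, evaluated at the
#' sample times, and reduces each to ranks. These are the reference waveforms
#' the rhythmicity statistic correlates observed series against; working with
#' ranks makes the screen invariant to any monotone rescaling of expression.
#' The cosine convention is `cos(2*pi*(t - phase)/period)` with `t` in hours,
#' so `phase` is the peak time.
#'
#' @param times Sample times in hours (one entry per observation, replicate
#'   times repeated).
#' @param period_h Period in hours (fixed 24 for a diel/circadian screen).
#' @param phase_step_h Spacing of the candidate phase grid; must divide
#'   `period_h`.
#' @return A `rhythm_templates` object: list with `phases`, `times`,
#'   `values` (phases x observations cosine values) and `ranks`.
#' @examples
#' reference_waveforms(c(0, 6, 12, 18), phase_step_h = 4)$phases
#' @export
reference_waveforms <- function(times, period_h = 24, phase_step_h = 4) {
  if (abs(period_h / phase_step_h - round(period_h / phase_step_h)) > 1e-9) {
    stopf("phase_step_h (%g) must divide the period (%g h)", phase_step_h, period_h)
  }
  phases <- seq(0, period_h - phase_step_h, by = phase_step_h)
  values <- vapply(times, function(t) cos(2 * pi * (t - phases) / period_h),
    numeric(length(phases)))
  # rounding keeps exact cosine ties (e.g. +/- quarter period) tied despite
  # floating-point asymmetry
  values <- round(matrix(values, nrow = length(phases)), 10)
  ranks <- t(apply(values, 1, rank))
  n_distinct <- apply(ranks, 1, function(r) length(unique(r)))
  if (any(n_distinct < 3L)) {
    stopf("degenerate design: a template has fewer than 3 distinct ranks")
  }
  structure(
    list(phases = phases, times = times, values = values, ranks = ranks,
      period_h = period_h),
    class = "rhythm_templates"
  )
}

#' Kendall's rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation between two equal-length vectors,
#' computed by pair counting. Returns `NA` when either vector has zero
#' variance (all pairs tied).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return tau-b in `[-1, 1]`, or `NA`.
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 3L) stopf("need at least 3 observations")
  iu <- upper.tri(matrix(0, n, n))
  sx <- sign(outer(x, x, "-"))[iu]
  sy <- sign(outer(y, y, "-"))[iu]
  n0 <- length(sx)
  nx <- sum(sx == 0)
  ny <- sum(sy == 0)
  den <- sqrt((n0 - nx) * (n0 - ny))
  if (den == 0) {
    return(NA_real_)
  }
  sum(sx * sy) / den
}

# ---- permutation engine -----------------------------------------------------

# Max-over-phases Kendall statistic for a gene matrix, with a permutation
# null. Implemented through sign matrices: the tau-b numerator for a
# (gene, template) combination is the inner product of the gene's pairwise
# sign vector with the template's, so all genes x all permuted templates
# reduce to one matrix product.
#
# Exchangeability unit:
#  - "observations" (default): every observation is exchangeable under the
#    null (independent fish, destructive sampling); permutations are sampled,
#    independently per gene chunk.
#  - "blocks": replicate blocks (all observations sharing a timepoint) are
#    reassigned to timepoints as units; all T! block permutations are
#    enumerated when feasible, enabling null = "exact".
#
# mat: genes x observations; times: hours per observation.
# Returns per-gene: tau (observed max), phase, p.
rhythm_engine <- function(mat, times, period_h = 24, phase_step_h = 4,
                          n_perm = 1000, seed = 1L,
                          null = c("permutation", "exact"),
                          exchange = c("observations", "blocks"),
                          chunk_size = 50L, max_enumerate = 45000) {
  null <- match.arg(null)
  exchange <- match.arg(exchange)
  if (null == "exact" && exchange == "observations") {
    stopf("exact enumeration is only available with exchange = \"blocks\"")
  }
  tmpl <- reference_waveforms(times, period_h, phase_step_h)
  phases <- tmpl$phases
  fcount <- length(phases)
  tp <- sort(unique(times))
  Tn <- length(tp)
  block <- match(times, tp)
  n <- length(times)
  G <- nrow(mat)

  # pairwise index set
  iu <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ii <- iu[, 1]
  jj <- iu[, 2]
  n0 <- length(ii)

  SX <- sign(mat[, ii, drop = FALSE] - mat[, jj, drop = FALSE])
  nx <- rowSums(SX == 0)
  flat <- nx == n0
  sden_x <- sqrt(pmax(n0 - nx, 0))

  # template values: per phase at distinct timepoints, and per observation
  # (rounded as in reference_waveforms so exact cosine ties stay tied)
  V <- round(matrix(
    vapply(tp, function(t) cos(2 * pi * (t - phases) / period_h), numeric(fcount)),
    nrow = fcount
  ), 10)
  TV <- V[, block, drop = FALSE] # fcount x n

  # observed statistic
  SY_obs <- sign(TV[, ii, drop = FALSE] - TV[, jj, drop = FALSE]) # fcount x n0
  ny_obs <- rowSums(SY_obs == 0)
  NUM_obs <- SX %*% t(SY_obs) # G x fcount
  den_obs <- outer(sden_x, sqrt(pmax(n0 - ny_obs, 0)))
  TAU_obs <- NUM_obs / ifelse(den_obs == 0, NA, den_obs)
  phase_idx <- apply(TAU_obs, 1, function(z) if (all(is.na(z))) NA_integer_ else which.max(z))
  s_obs <- suppressWarnings(apply(TAU_obs, 1, max, na.rm = TRUE))
  s_obs[!is.finite(s_obs)] <- NA_real_

  # max over phases for a TAU matrix whose columns are (perm-major, phase-fast)
  max_over_phases <- function(TAU, P) {
    M <- TAU[, seq(1, by = fcount, length.out = P), drop = FALSE]
    if (fcount > 1L) {
      for (f in 2:fcount) {
        Tf <- TAU[, seq(f, by = fcount, length.out = P), drop = FALSE]
        upd <- !is.na(Tf) & (is.na(M) | Tf > M)
        M[upd] <- Tf[upd]
      }
    }
    M
  }
  tau_cols <- function(SXc, U) {
    SY <- sign(U[ii, , drop = FALSE] - U[jj, , drop = FALSE])
    ny <- colSums(SY == 0)
    NUM <- SXc %*% SY
    den <- outer(sqrt(pmax(n0 - rowSums(SXc == 0), 0)), sqrt(pmax(n0 - ny, 0)))
    NUM / ifelse(den == 0, NA, den)
  }

  if (exchange == "observations") {
    # sampled permutations of all observations, fresh per gene chunk
    p <- rep(NA_real_, G)
    chunks <- split(seq_len(G), ceiling(seq_len(G) / chunk_size))
    for (ci in seq_along(chunks)) {
      idx <- chunks[[ci]]
      withr::with_seed(stream_seed(seed, 200L + ci), {
        perms <- matrix(0L, n_perm, n)
        for (r in seq_len(n_perm)) perms[r, ] <- sample.int(n)
      })
      U <- matrix(0, n, n_perm * fcount)
      for (f in seq_len(fcount)) {
        U[, seq(f, by = fcount, length.out = n_perm)] <-
          matrix(TV[f, t(perms)], nrow = n)
      }
      TAU <- tau_cols(SX[idx, , drop = FALSE], U)
      M <- max_over_phases(TAU, n_perm)
      exceed <- M >= (s_obs[idx] - 1e-12)
      p[idx] <- (1 + rowSums(exceed, na.rm = TRUE)) / (n_perm + 1)
    }
  } else {
    n_all <- factorial(Tn)
    enumerate <- n_all <= max_enumerate
    bi <- block[ii]
    bj <- block[jj]
    if (enumerate) {
      perms <- all_permutations(Tn)
    } else {
      withr::with_seed(stream_seed(seed, 97L), {
        perms <- t(replicate(n_perm, sample.int(Tn)))
      })
    }
    P <- nrow(perms)
    U <- matrix(0, Tn, P * fcount)
    for (f in seq_len(fcount)) {
      U[, seq(f, by = fcount, length.out = P)] <- matrix(V[f, t(perms)], nrow = Tn)
    }
    Uo <- U[block, , drop = FALSE]
    TAU <- tau_cols(SX, Uo)
    M <- max_over_phases(TAU, P)
    if (null == "exact" && enumerate) {
      p <- rowMeans(M >= s_obs - 1e-12)
    } else if (enumerate) {
      # sample permutation indices independently per gene
      withr::with_seed(stream_seed(seed, 98L), {
        pick <- matrix(sample.int(P, G * n_perm, replace = TRUE), G, n_perm)
      })
      exceed <- matrix(
        M[cbind(rep(seq_len(G), n_perm), as.vector(pick))] >=
          rep(s_obs - 1e-12, n_perm),
        G, n_perm
      )
      p <- (1 + rowSums(exceed, na.rm = TRUE)) / (n_perm + 1)
    } else {
      p <- (1 + rowSums(M >= s_obs - 1e-12, na.rm = TRUE)) / (n_perm + 1)
    }
  }

  p[flat] <- 1
  s_obs[flat] <- NA_real_
  phase_idx[flat] <- NA_integer_
  list(
    tau = s_obs, phase_h = phases[phase_idx], p = p, flat = flat,
    phases = phases, per_phase_tau = TAU_obs
  )
}

#' Least-squares cosinor fit
#'
#' Fits `y = mesor + amplitude * cos(2*pi*(t - phase)/period)` by ordinary
#' least squares via the linear sin/cos parameterisation; the phase is the
#' continuous peak time `atan2` of the two coefficients. On noise-free
#' cosine data the planted mesor, amplitude and phase are recovered exactly.
#'
#' @param times Hours per observation.
#' @param y Observed values.
#' @param period_h Period in hours.
#' @return List with `mesor`, `amplitude` (>= 0) and `phase_h` in
#'   `[0, period_h)`.
#' @export
cosinor_fit <- function(times, y, period_h = 24) {
  w <- 2 * pi / period_h
  fit <- lm.fit(cbind(1, cos(w * times), sin(w * times)), y)
  b <- unname(fit$coefficients)
  amp <- sqrt(b[2]^2 + b[3]^2)
  phase <- (atan2(b[3], b[2]) / w) %% period_h
  if (phase > period_h - 1e-9) phase <- 0
  list(mesor = b[1], amplitude = amp, phase_h = phase)
}

#' Test one series for 24-h rhythmicity
#'
#' Nonparametric rhythm test: the statistic is the maximum over candidate
#' peak phases of the Kendall tau-b correlation between the observed series
#' and a cosine rank template. The null distribution is that of the same
#' maximum under permutation of timepoint labels (replicate blocks permuted
#' as units), so the phase-grid maximisation is accounted for. Amplitude and
#' mesor come from a least-squares cosinor fit at the selected phase.
#'
#' @param data A data frame with one row per observation.
#' @param time,value Columns (tidy-eval) giving hours and expression.
#' @param window Optional `c(start, end)` hours; observations outside are
#'   dropped (both endpoints kept).
#' @param period_h,phase_step_h Period (h) and phase-grid step.
#' @param null `"permutation"` (sampled, `n_perm` draws) or `"exact"` (all
#'   distinct block permutations; requires `exchange = "blocks"`).
#' @param exchange Exchangeable unit under the null: `"observations"`
#'   (default; independent animals, destructive sampling) or `"blocks"`
#'   (replicate blocks reassigned to timepoints as units, the conservative
#'   variant).
#' @param n_perm Number of permutations (>= 100; sampled p-values are
#'   `(1 + exceed) / (n_perm + 1)`).
#' @param seed Seed for the permutation draws.
#' @return A `rhythm_fit` object; see [glance.rhythm_fit()].
#' @examples
#' d <- data.frame(t = rep(seq(5, 29, 4), each = 3))
#' d$y <- 2 * cos(2 * pi * (d$t - 9) / 24) + rnorm(nrow(d), 0, 0.3)
#' fit <- rhythm_test(d, t, y, n_perm = 200, seed = 1)
#' glance(fit)
#' @export
rhythm_test <- function(data, time, value, window = NULL,
                        period_h = 24, phase_step_h = 4,
                        null = c("permutation", "exact"),
                        exchange = c("observations", "blocks"),
                        n_perm = 1000, seed = 1L) {
  null <- match.arg(null)
  exchange <- match.arg(exchange)
  if (null == "permutation" && n_perm < 100) {
    stopf("n_perm < 100 gives unstable p-values; refusing")
  }
  t_h <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ value }})
  if (!is.null(window)) {
    keep <- t_h >= window[1] & t_h <= window[2]
    t_h <- t_h[keep]
    y <- y[keep]
  }
  if (length(unique(t_h)) < 4L) stopf("need >= 4 distinct timepoints")
  eng <- rhythm_engine(matrix(y, 1), t_h, period_h, phase_step_h,
    n_perm = n_perm, seed = seed, null = null, exchange = exchange)
  cs <- if (is.na(eng$tau[1])) {
    list(mesor = mean(y), amplitude = NA_real_, phase_h = NA_real_)
  } else {
    cosinor_fit(t_h, y, period_h)
  }
  structure(
    list(
      tau = eng$tau[1], phase_h = cs$phase_h, amplitude = cs$amplitude,
      mesor = cs$mesor, p = eng$p[1], period_h = period_h,
      phases = eng$phases, per_phase_tau = drop(eng$per_phase_tau),
      n_perm = n_perm, null = null,
      window = window %||% range(t_h)
    ),
    class = "rhythm_fit"
  )
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat(sprintf(
    "<rhythm_fit> tau=%.3f phase=%sh amplitude=%.3g mesor=%.3g p=%.4g (%s null)\n",
    x$tau, format(x$phase_h), x$amplitude, x$mesor, x$p, x$null
  ))
  invisible(x)
}

#' Screen a bundle for rhythmic genes per tissue and condition
#'
#' Runs the max-over-phases Kendall rhythm test on every gene within each
#' tissue x condition stratum of a circadian-design bundle, on `log2(cpm +
#' 0.5)` after TMM scaling (the statistic itself is rank-based and unaffected
#' by the log). Statistical windows follow the modelled sampling scheme:
#' diel uses ZT5 through the following ZT5, constant conditions CT9-CT29.
#' Benjamini-Hochberg adjustment is applied within each stratum.
#'
#' @param bundle An [expression_bundle()] whose metadata has `tissue`,
#'   `condition` (diel/LL/DD) and numeric `time` columns.
#' @param windows Named list of `c(start, end)` hour windows per condition.
#' @param alpha Significance threshold on the adjusted p-value.
#' @param tmm Apply TMM factors before cpm.
#' @inheritParams rhythm_test
#' @return A `rhythm_screen` tibble: one row per gene x tissue x condition
#'   with `tau`, `period_h`, `phase_h`, `amplitude`, `mesor`, `p`, `adj_p`,
#'   `significant`.
#' @export
screen_rhythms <- function(bundle,
                           windows = list(diel = c(5, 29), LL = c(9, 29), DD = c(9, 29)),
                           alpha = 0.05, period_h = 24, phase_step_h = 4,
                           null = c("permutation", "exact"),
                           exchange = c("observations", "blocks"),
                           n_perm = 1000, seed = 1L, tmm = TRUE) {
  null <- match.arg(null)
  exchange <- match.arg(exchange)
  stopifnot(inherits(bundle, "expr_bundle"))
  nf <- if (tmm) tmm_factors(bundle) else NULL
  expr <- cpm(bundle, norm_factors = nf, log = TRUE)
  meta <- bundle$samples
  strata <- meta |>
    filter(.data$condition %in% names(windows)) |>
    distinct(.data$tissue, .data$condition)

  res <- map_dfr(seq_len(nrow(strata)), function(i) {
    ti <- strata$tissue[i]
    co <- strata$condition[i]
    win <- windows[[co]]
    sel <- meta$tissue == ti & meta$condition == co &
      meta$time >= win[1] & meta$time <= win[2]
    if (sum(sel) == 0L) {
      return(NULL)
    }
    sub <- expr[, sel, drop = FALSE]
    t_h <- meta$time[sel]
    eng <- rhythm_engine(sub, t_h, period_h, phase_step_h,
      n_perm = n_perm, seed = stream_seed(seed, i), null = null,
      exchange = exchange)
    cs <- lapply(seq_len(nrow(sub)), function(g) {
      if (is.na(eng$tau[g])) {
        list(mesor = mean(sub[g, ]), amplitude = NA_real_, phase_h = NA_real_)
      } else {
        cosinor_fit(t_h, sub[g, ], period_h)
      }
    })
    tibble(
      gene = rownames(sub), tissue = ti, condition = co,
      window_start = win[1], window_end = win[2],
      tau = eng$tau, period_h = period_h,
      phase_h = map_dbl(cs, "phase_h"),
      amplitude = map_dbl(cs, "amplitude"),
      mesor = map_dbl(cs, "mesor"),
      p = eng$p
    ) |>
      mutate(adj_p = p.adjust(.data$p, method = "BH"))
  })
  res <- res |> mutate(significant = .data$adj_p < alpha)
  class(res) <- c("rhythm_screen", class(res))
  attr(res, "alpha") <- alpha
  res
}
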