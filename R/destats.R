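#' Estimate a common negative-binomial dispersion
#'
#' Maximum conditional likelihood estimate of a single dispersion shared by
#' all genes. Counts are first equalized to a common effective depth (each
#' sample scaled to the geometric-mean effective library size), then the
#' sum-constrained NB conditional log-likelihood is maximised over a
#' log-scale dispersion grid refined by golden-section search. A dispersion
#' of 0 (the Poisson limit, evaluated through the multinomial conditional
#' likelihood) is permitted and returned when it dominates the grid.
#'
#' @param counts Genes x samples count matrix.
#' @param groups Factor (or vector) of group labels per sample; the
#'   likelihood conditions on each group's gene-wise sum.
#' @param norm_factors Optional per-sample normalization factors.
#' @param lib_sizes Optional per-sample library sizes; defaults to the column
#'   sums.
#' @param phi_range Dispersion search range (log-spaced grid).
#' @param n_grid Grid size.
#' @return A `dispersion_estimate` object with fields `dispersion` and
#'   `method`.
#' @export
estimate_common_dispersion <- function(counts, groups, norm_factors = NULL,
                                       lib_sizes = NULL,
                                       phi_range = c(1e-4, 4), n_grid = 25) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stopf("all-zero count matrix")
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L && table(groups)[1] < 2L) {
    stopf("need >= 2 groups with >= 2 replicates")
  }
  pseudo <- equalize_counts(counts, norm_factors, lib_sizes)
  pseudo <- pseudo[rowSums(pseudo) > 0, , drop = FALSE]

  glev <- levels(groups)
  group_mats <- lapply(glev, function(g) pseudo[, groups == g, drop = FALSE])
  group_mats <- group_mats[vapply(group_mats, ncol, integer(1)) >= 2L]

  # log P(y | sum) for NB with common dispersion: a ratio of beta-binomial
  # style gamma terms; includes the phi-free multinomial constants so the
  # phi -> 0 limit coincides with the Poisson (multinomial) likelihood below.
  cll <- function(log_phi) {
    r <- 1 / exp(log_phi)
    tot <- 0
    for (Y in group_mats) {
      nk <- ncol(Y)
      z <- rowSums(Y)
      tot <- tot + sum(
        rowSums(lgamma(Y + r) - lgamma(Y + 1)) - nk * lgamma(r) +
          lgamma(nk * r) + lgamma(z + 1) - lgamma(z + nk * r)
      )
    }
    tot
  }
  # Poisson limit: conditional on the sum, counts are multinomial(1/nk)
  cll0 <- sum(vapply(group_mats, function(Y) {
    nk <- ncol(Y)
    z <- rowSums(Y)
    sum(lgamma(z + 1) - rowSums(lgamma(Y + 1)) - z * log(nk))
  }, numeric(1)))

  grid <- seq(log(phi_range[1]), log(phi_range[2]), length.out = n_grid)
  vals <- vapply(grid, cll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, n_grid)]
  opt <- optimize(cll, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  phi <- exp(opt$maximum)
  ll <- opt$objective
  if (cll0 >= ll) {
    phi <- 0
    ll <- cll0
  }
  structure(
    list(dispersion = phi, method = "qCML (equalized depth, grid + golden section)",
      loglik = ll),
    class = "dispersion_estimate"
  )
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("<dispersion_estimate> %.4g (%s)\n", x$dispersion, x$method))
  invisible(x)
}

# Scale each sample's counts to the geometric-mean effective library size.
equalize_counts <- function(counts, norm_factors = NULL, lib_sizes = NULL) {
  lib <- lib_sizes %||% colSums(counts)
  if (any(lib == 0)) {
    stopf("zero library size in sample(s): %s",
      paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  nf <- norm_factors %||% rep(1, ncol(counts))
  eff <- lib * nf
  sweep(counts, 2, geo_mean(eff) / eff, "*")
}

#' Exact negative-binomial test for a two-group contrast
#'
#' For each gene, conditions on the total of the depth-equalized counts: the
#' two group sums are NB with sizes proportional to group size, and the
#' two-sided p-value sums the conditional probabilities of all splits at most
#' as likely as the observed one. In the Poisson limit (`dispersion = 0`)
#' this is the exact binomial split test. Fold changes are
#' `log2` ratios of group mean cpm with a +0.5 offset.
#'
#' @param counts Genes x samples count matrix.
#' @param groups Two-level factor; the second level is the numerator of the
#'   fold change (e.g. `factor(..., levels = c("FW", "SW"))` gives SW vs FW).
#' @param dispersion Common NB dispersion (see
#'   [estimate_common_dispersion()]).
#' @param norm_factors Optional per-sample normalization factors.
#' @param lib_sizes Optional per-sample library sizes; defaults to the column
#'   sums (supply explicitly when testing a subset of genes).
#' @return A tibble of class `de_result`: `gene`, `contrast`, `log2fc`, `p`,
#'   `fdr` (BH within the contrast).
#' @export
nb_exact_test <- function(counts, groups, dispersion, norm_factors = NULL,
                          lib_sizes = NULL) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stopf("exact test needs exactly two groups")
  pseudo <- equalize_counts(counts, norm_factors, lib_sizes)
  g2 <- groups == levels(groups)[2]
  n1 <- sum(!g2)
  n2 <- sum(g2)
  z1 <- round(rowSums(pseudo[, !g2, drop = FALSE]))
  z2 <- round(rowSums(pseudo[, g2, drop = FALSE]))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_p(z1[i], z2[i], n1, n2, dispersion)
  }, numeric(1))

  effl <- (lib_sizes %||% colSums(counts)) * (norm_factors %||% rep(1, ncol(counts)))
  cm <- sweep(counts, 2, effl, "/") * 1e6
  m1 <- rowMeans(cm[, !g2, drop = FALSE])
  m2 <- rowMeans(cm[, g2, drop = FALSE])
  contrast <- paste0(levels(groups)[2], "_vs_", levels(groups)[1])
  out <- tibble(
    gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    contrast = contrast,
    log2fc = log2((m2 + 0.5) / (m1 + 0.5)),
    statistic = NA_real_,
    p = p,
    fdr = bh_fdr(p)
  )
  class(out) <- c("de_result", class(out))
  out
}

# Conditional two-sided exact p for one gene.
nb_exact_p <- function(z1, z2, n1, n2, phi) {
  z <- z1 + z2
  if (z == 0) {
    return(1)
  }
  u <- 0:z
  if (phi <= 1e-8) {
    # Poisson limit: conditional on the total, the split is binomial.
    # (Also used for negligible dispersions, where dnbinom's enormous size
    # parameter loses the precision needed to resolve tied outcomes.)
    lp <- dbinom(u, z, n1 / (n1 + n2), log = TRUE)
  } else {
    r <- 1 / phi
    mu <- z / (n1 + n2)
    lp <- dnbinom(u, size = n1 * r, mu = n1 * mu, log = TRUE) +
      dnbinom(z - u, size = n2 * r, mu = n2 * mu, log = TRUE)
  }
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  pobs <- pr[z1 + 1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-10)]))
}

#' ANOVA-like negative-binomial test over a time course
#'
#' Per gene, fits an NB log-linear model with a stage factor against an
#' intercept-only model (both with log effective-library-size offsets and the
#' supplied common dispersion) and reports the likelihood-ratio statistic
#' against a chi-square with `n_stages - 1` degrees of freedom. With
#' `dispersion = 0` the fits are Poisson.
#'
#' @param counts Genes x samples count matrix.
#' @param stages Factor of stage labels (>= 3 levels, >= 2 replicates each).
#' @param dispersion Common NB dispersion.
#' @param norm_factors Optional per-sample normalization factors.
#' @param lib_sizes Optional per-sample library sizes; defaults to the column
#'   sums.
#' @return A `de_result` tibble: `gene`, `contrast`, `statistic` (LR), `df`,
#'   `p`, `fdr`.
#' @export
timecourse_test <- function(counts, stages, dispersion, norm_factors = NULL,
                            lib_sizes = NULL) {
  counts <- as.matrix(counts)
  stages <- as.factor(stages)
  if (nlevels(stages) < 3L) stopf("timecourse test needs >= 3 stages")
  if (any(table(stages) < 2L)) stopf("every stage needs >= 2 replicates")
  lib <- lib_sizes %||% colSums(counts)
  nf <- norm_factors %||% rep(1, ncol(counts))
  off <- log(lib * nf)
  fam <- if (dispersion > 0) {
    MASS::negative.binomial(theta = 1 / dispersion)
  } else {
    poisson()
  }
  X1 <- model.matrix(~stages)
  X0 <- X1[, 1, drop = FALSE]
  ctrl <- glm.control(epsilon = 1e-12, maxit = 200)
  lr <- vapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    if (all(y == 0)) {
      return(0)
    }
    d1 <- suppressWarnings(
      glm.fit(X1, y, family = fam, offset = off, control = ctrl)$deviance
    )
    d0 <- suppressWarnings(
      glm.fit(X0, y, family = fam, offset = off, control = ctrl)$deviance
    )
    max(d0 - d1, 0)
  }, numeric(1))
  df <- nlevels(stages) - 1L
  p <- pchisq(lr, df = df, lower.tail = FALSE)
  stage_lab <- levels(stages)
  out <- tibble(
    gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    contrast = sprintf("timecourse_%s_%s", stage_lab[1], stage_lab[length(stage_lab)]),
    log2fc = NA_real_,
    statistic = lr,
    df = df,
    p = p,
    fdr = bh_fdr(p)
  )
  class(out) <- c("de_result", class(out))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper over
#' [stats::p.adjust()] with `method = "BH"`): monotone in the raw p-values
#' and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
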