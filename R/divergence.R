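#' Expression divergence index
#'
#' `EDI = |log2(expr1 / expr2)|` for the two members of an ohnologue pair in
#' one tissue. When either value is exactly zero, a pseudo-expression offset
#' is added to both members (keeping the index finite and symmetric);
#' otherwise the raw ratio is used.
#'
#' @param expr1,expr2 Non-negative expression values (recycled as usual).
#' @param offset Positive offset engaged only when either value is 0.
#' @return Non-negative EDI values; 0 iff the two inputs are equal.
#' @examples
#' compute_edi(8, 2) # 2
#' compute_edi(2, 8) # 2 (symmetric)
#' @export
compute_edi <- function(expr1, expr2, offset = 0.5) {
  if (any(expr1 < 0) || any(expr2 < 0)) stopf("expression values must be >= 0")
  if (offset <= 0) stopf("offset must be positive")
  engage <- expr1 == 0 | expr2 == 0
  e1 <- expr1 + offset * engage
  e2 <- expr2 + offset * engage
  abs(log2(e1 / e2))
}

#' Per-tissue EDI table for ohnologue pairs
#'
#' Computes one EDI per pair and tissue from mean normalized expression
#' (TMM-scaled cpm averaged over the tissue's samples), plus a per-pair
#' summary (the median EDI across tissues). Pairs with a copy missing from
#' the matrix are flagged and excluded from the summaries.
#'
#' @param pairs An `ohno_pairs` tibble (or any tibble with `gene1`, `gene2`
#'   and optionally `rediploid_class`).
#' @param bundle An [expression_bundle()] with a `tissue` metadata column.
#' @param offset Zero-handling offset for [compute_edi()].
#' @param tmm Apply TMM scaling before cpm.
#' @return A tibble of class `edi_table`: `pair_id`, `gene1`, `gene2`,
#'   `tissue`, `expr1`, `expr2`, `edi`, `rediploid_class`. The per-pair
#'   medians are available through [edi_summary()].
#' @export
edi_table <- function(pairs, bundle, offset = 0.5, tmm = TRUE) {
  stopifnot(inherits(bundle, "expr_bundle"))
  nf <- if (tmm) tmm_factors(bundle) else NULL
  mes <- mesor_table(bundle, by = "tissue", norm_factors = nf)
  pr <- as_tibble(pairs)[, intersect(
    c("gene1", "gene2", "orthogroup_id", "rediploid_class"), names(pairs)
  )]
  if (!"rediploid_class" %in% names(pr)) pr$rediploid_class <- NA_character_
  pr$pair_id <- paste(pr$gene1, pr$gene2, sep = "|")

  present <- rownames(bundle$counts)
  missing <- pr$gene1 %in% present & pr$gene2 %in% present
  flagged <- pr[!missing, ]
  if (nrow(flagged)) {
    warnf("%d pair(s) have a copy missing from the matrix; excluded", nrow(flagged))
  }
  pr <- pr[missing, ]

  out <- pr |>
    left_join(rename(mes, gene1 = "gene", expr1 = "mesor"),
      by = "gene1", relationship = "many-to-many") |>
    left_join(rename(mes, gene2 = "gene", expr2 = "mesor"),
      by = c("gene2", "tissue")) |>
    mutate(edi = compute_edi(.data$expr1, .data$expr2, offset = offset)) |>
    select(dplyr::any_of(c(
      "pair_id", "orthogroup_id", "gene1", "gene2", "tissue",
      "expr1", "expr2", "edi", "rediploid_class"
    )))
  structure(out,
    flagged = flagged,
    class = c("edi_table", class(out))
  )
}

#' @rdname edi_table
#' @param x An `edi_table`.
#' @return `edi_summary()`: one row per pair with `median_edi` (the Fig-style
#'   per-pair summary) and the number of tissues used.
#' @export
edi_summary <- function(x) {
  x |>
    as_tibble() |>
    group_by(across(dplyr::any_of(c("pair_id", "gene1", "gene2", "rediploid_class")))) |>
    summarise(
      median_edi = median(.data$edi),
      n_tissues = dplyr::n(),
      .groups = "drop"
    )
}

#' Nested-polynomial profile divergence test
#'
#' Compares the temporal expression profiles of the two members of a pair by
#' an extra-sum-of-squares F test on sixth-order centred polynomial fits:
#' each series is first normalized to its own mean, then fitted separately
#' (two coefficient sets) and jointly (one shared set);
#' `F = ((RSS_shared - RSS_separate) / (df_shared - df_separate)) /
#' (RSS_separate / df_separate)`.
#'
#' @param data Data frame with one row per observation of either series.
#' @param time,value,series Columns (tidy-eval): numeric time, expression,
#'   and a two-level series identifier (which gene copy).
#' @param order Polynomial order (default 6).
#' @param normalize Divide each series by its own mean first (ratio scale).
#' @return A `profile_divergence` object; `glance()` gives `F`, `p`,
#'   `rss_shared`, `rss_separate`, `df_num`, `df_den`.
#' @export
profile_divergence_test <- function(data, time, value, series, order = 6,
                                    normalize = TRUE) {
  t_h <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ value }})
  id <- as.factor(dplyr::pull(data, {{ series }}))
  if (nlevels(id) != 2L) stopf("profile test needs exactly two series")
  p_coef <- order + 1L
  if (length(unique(t_h)) < p_coef) {
    stopf("rank-deficient design: a %d-order polynomial needs >= %d distinct timepoints",
      order, p_coef)
  }
  if (length(y) <= 2L * p_coef) {
    stopf("need more than %d observations for separate %d-order fits",
      2L * p_coef, order)
  }
  if (normalize) {
    for (l in levels(id)) {
      sel <- id == l
      m <- mean(y[sel])
      if (m == 0) stopf("series '%s' has zero mean; cannot normalize", l)
      y[sel] <- y[sel] / m
    }
  }
  tc <- t_h - mean(t_h)
  sc <- max(abs(tc))
  if (sc == 0) stopf("all observations share one timepoint")
  X <- outer(tc / sc, 0:order, "^")

  rss <- function(Xm, ym) {
    f <- lm.fit(Xm, ym)
    sum(f$residuals^2)
  }
  sel1 <- id == levels(id)[1]
  rss_sep <- rss(X[sel1, , drop = FALSE], y[sel1]) +
    rss(X[!sel1, , drop = FALSE], y[!sel1])
  rss_sh <- rss(X, y)
  df_sep <- length(y) - 2L * p_coef
  df_num <- p_coef
  extra <- max(rss_sh - rss_sep, 0)
  tol <- 1e-10 * (sum(y^2) + 1)
  if (extra <= tol) {
    # numerically identical fits (e.g. the two series are the same data)
    Fstat <- 0
    pval <- 1
  } else if (rss_sep <= tol) {
    Fstat <- Inf
    pval <- 0
  } else {
    Fstat <- (extra / df_num) / (rss_sep / df_sep)
    pval <- pf(Fstat, df_num, df_sep, lower.tail = FALSE)
  }
  structure(
    list(
      F = Fstat, p = pval, rss_shared = rss_sh, rss_separate = rss_sep,
      df_num = df_num, df_den = df_sep, order = order,
      series_levels = levels(id), normalized = normalize
    ),
    class = "profile_divergence"
  )
}

#' @export
print.profile_divergence <- function(x, ...) {
  cat(sprintf(
    "<profile_divergence> F(%d, %d) = %.4g, p = %.4g\n",
    x$df_num, x$df_den, x$F, x$p
  ))
  invisible(x)
}

#' Two-way ANOVA for differential seawater response within a pair
#'
#' Tests whether the two copies of a pair respond differently to the
#' salinity challenge: a gene-copy x condition ANOVA on `log2(cpm + 0.5)`,
#' reporting the interaction term. The pair is flagged divergent when the
#' interaction p-value is below `alpha`.
#'
#' @param counts1,counts2 Count vectors for the two copies over the same
#'   samples.
#' @param condition Two-level factor (e.g. FW/SW), >= 2 replicates per level.
#' @param lib_sizes Per-sample library sizes (total counts of the parent
#'   matrix).
#' @param norm_factors Optional per-sample normalization factors.
#' @param alpha Divergence threshold on the interaction p-value.
#' @return An `ohno_interaction` object: `log2fc_gene1`, `log2fc_gene2`
#'   (second vs first condition level), `interaction_F`, `interaction_p`,
#'   `divergent`, and the full ANOVA table for `tidy()`.
#' @export
interaction_test <- function(counts1, counts2, condition, lib_sizes,
                             norm_factors = NULL, alpha = 0.05) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stopf("condition must have two levels")
  if (any(table(condition) < 2L)) stopf("empty or singleton condition cell")
  nf <- norm_factors %||% rep(1, length(lib_sizes))
  eff <- lib_sizes * nf
  y <- log2(c(counts1, counts2) / rep(eff, 2) * 1e6 + 0.5)
  d <- tibble(
    y = y,
    copy = factor(rep(c("gene1", "gene2"), each = length(counts1))),
    cond = factor(rep(condition, 2), levels = levels(condition))
  )
  fit <- lm(y ~ copy * cond, data = d)
  av <- anova(fit)
  ip <- av["copy:cond", "Pr(>F)"]
  lfc <- d |>
    group_by(.data$copy, .data$cond) |>
    summarise(m = mean(.data$y), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cond", values_from = "m")
  l2 <- lfc[[levels(condition)[2]]] - lfc[[levels(condition)[1]]]
  structure(
    list(
      log2fc_gene1 = l2[lfc$copy == "gene1"],
      log2fc_gene2 = l2[lfc$copy == "gene2"],
      interaction_F = av["copy:cond", "F value"],
      interaction_p = ip,
      divergent = ip < alpha,
      alpha = alpha,
      anova = as_tibble(av, rownames = "term")
    ),
    class = "ohno_interaction"
  )
}

#' @export
print.ohno_interaction <- function(x, ...) {
  cat(sprintf(
    "<ohno_interaction> log2FC %.2f vs %.2f, interaction p = %.4g (%sdivergent at %.2g)\n",
    x$log2fc_gene1, x$log2fc_gene2, x$interaction_p,
    if (x$divergent) "" else "not ", x$alpha
  ))
  invisible(x)
}

#' Cluster developmental expression profiles
#'
#' Hierarchical clustering of standardized per-gene profiles with
#' `1 - Pearson r` distance and average linkage, cut at `k` clusters.
#' Deterministic for a given input: genes are processed in id order and the
#' tree cut follows [stats::cutree()].
#'
#' @param profiles Genes x stages matrix (typically per-stage means of the
#'   significant genes), or a tibble with a `gene` column followed by stage
#'   columns.
#' @param k Number of clusters.
#' @return A tibble of class `profile_clusters` (`gene`, `cluster`);
#'   attributes `centroids` (k x stages matrix of mean standardized
#'   profiles) and `hclust` (the tree). Zero-variance genes are excluded
#'   with a warning.
#' @export
cluster_profiles <- function(profiles, k = 5) {
  if (is.data.frame(profiles)) {
    g <- profiles$gene
    profiles <- as.matrix(profiles[, setdiff(names(profiles), "gene")])
    rownames(profiles) <- g
  }
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  v <- apply(profiles, 1, sd)
  if (any(v == 0)) {
    warnf("excluding %d zero-variance profile(s): %s", sum(v == 0),
      paste(head(rownames(profiles)[v == 0], 5), collapse = ", "))
    profiles <- profiles[v > 0, , drop = FALSE]
  }
  if (nrow(profiles) < k) stopf("fewer profiles (%d) than clusters (%d)", nrow(profiles), k)
  z <- t(scale(t(profiles)))
  d <- as.dist(1 - cor(t(z)))
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, k = k)
  cent <- t(vapply(seq_len(k), function(j) colMeans(z[cl == j, , drop = FALSE]),
    numeric(ncol(z))))
  rownames(cent) <- paste0("cluster", seq_len(k))
  out <- tibble(gene = names(cl), cluster = unname(cl))
  structure(out,
    centroids = cent, hclust = hc, k = k,
    class = c("profile_clusters", class(out))
  )
}

#' Combine all divergence evidence into a per-pair report
#'
#' Joins the upstream tables into one row per ohnologue pair: median EDI,
#' rhythm significance of each copy, profile-divergence and seawater
#' interaction tests (BH-adjusted across pairs), developmental DE
#' significance of each copy and cluster memberships. Each assay context is
#' classified as `none`, `one-copy-regulated` (exactly one copy significant)
#' or `different-dynamics` (both copies significant but with different
#' dynamics: different clusters, divergent profiles, or a significant
#' condition interaction); the overall `mode` is the combination (`both`
#' when different assays show the two kinds).
#'
#' @param pairs An `ohno_pairs` tibble.
#' @param edi Optional [edi_table()] output.
#' @param rhythm Optional [screen_rhythms()] output.
#' @param profile Optional tibble `pair_id`, `F`, `p` from per-pair
#'   [profile_divergence_test()] runs (see [pair_profile_tests()]).
#' @param interaction Optional tibble `pair_id`, `log2fc_gene1`,
#'   `log2fc_gene2`, `interaction_p` (see [pair_interaction_tests()]).
#' @param de_timecourse,de_sw Optional `de_result` tibbles from
#'   [timecourse_test()] / [nb_exact_test()].
#' @param clusters Optional [cluster_profiles()] output.
#' @param thresholds Named list: `fdr_de` (default 0.01), `p_profile`
#'   (0.01), `alpha_interaction` (0.05), `alpha_rhythm` (0.05).
#' @return A `divergence_report` tibble, one row per pair.
#' @export
pair_divergence_report <- function(pairs, edi = NULL, rhythm = NULL,
                                   profile = NULL, interaction = NULL,
                                   de_timecourse = NULL, de_sw = NULL,
                                   clusters = NULL,
                                   thresholds = list()) {
  th <- utils::modifyList(
    list(fdr_de = 0.01, p_profile = 0.01, alpha_interaction = 0.05,
      alpha_rhythm = 0.05),
    thresholds
  )
  rep_tbl <- as_tibble(pairs) |>
    mutate(pair_id = paste(.data$gene1, .data$gene2, sep = "|")) |>
    select(dplyr::any_of(c(
      "pair_id", "orthogroup_id", "gene1", "gene2", "rediploid_class"
    )))

  if (!is.null(edi)) {
    rep_tbl <- left_join(rep_tbl,
      edi_summary(edi)[, c("pair_id", "median_edi")], by = "pair_id")
  }
  if (!is.null(rhythm)) {
    sig <- rhythm |>
      as_tibble() |>
      group_by(gene = .data$gene) |>
      summarise(rhythmic = any(.data$adj_p < th$alpha_rhythm), .groups = "drop")
    rep_tbl <- rep_tbl |>
      left_join(rename(sig, gene1 = "gene", rhythmic_gene1 = "rhythmic"), by = "gene1") |>
      left_join(rename(sig, gene2 = "gene", rhythmic_gene2 = "rhythmic"), by = "gene2")
  }
  if (!is.null(de_timecourse)) {
    rep_tbl <- join_copy_sig(rep_tbl, de_timecourse, "tc_sig", th$fdr_de)
  }
  if (!is.null(de_sw)) {
    rep_tbl <- join_copy_sig(rep_tbl, de_sw, "sw_sig", th$fdr_de)
  }
  if (!is.null(clusters)) {
    cl <- as_tibble(clusters)
    rep_tbl <- rep_tbl |>
      left_join(rename(cl, gene1 = "gene", cluster_gene1 = "cluster"), by = "gene1") |>
      left_join(rename(cl, gene2 = "gene", cluster_gene2 = "cluster"), by = "gene2")
  }
  if (!is.null(profile)) {
    pro <- as_tibble(profile) |>
      group_by(.data$pair_id) |>
      summarise(profile_p = min(.data$p), .groups = "drop") |>
      mutate(profile_fdr = bh_fdr(.data$profile_p))
    rep_tbl <- left_join(rep_tbl, pro, by = "pair_id")
  }
  if (!is.null(interaction)) {
    int <- as_tibble(interaction) |>
      mutate(interaction_fdr = bh_fdr(.data$interaction_p)) |>
      select(dplyr::any_of(c(
        "pair_id", "log2fc_gene1", "log2fc_gene2",
        "interaction_p", "interaction_fdr"
      ))) |>
      mutate(
        interaction_div_05 = .data$interaction_fdr < 0.05,
        interaction_div_01 = .data$interaction_fdr < 0.01
      )
    rep_tbl <- left_join(rep_tbl, int, by = "pair_id")
  }

  col_or <- function(nm, default = NA) {
    if (nm %in% names(rep_tbl)) rep_tbl[[nm]] else rep(default, nrow(rep_tbl))
  }
  smolt_mode <- assay_mode(
    sig1 = col_or("tc_sig_gene1"), sig2 = col_or("tc_sig_gene2"),
    dyn = !is.na(col_or("cluster_gene1")) & !is.na(col_or("cluster_gene2")) &
      col_or("cluster_gene1") != col_or("cluster_gene2")
  )
  sw_mode <- assay_mode(
    sig1 = col_or("sw_sig_gene1"), sig2 = col_or("sw_sig_gene2"),
    dyn = !is.na(col_or("interaction_fdr")) &
      col_or("interaction_fdr") < th$alpha_interaction
  )
  rhythm_mode <- assay_mode(
    sig1 = col_or("rhythmic_gene1"), sig2 = col_or("rhythmic_gene2"),
    dyn = !is.na(col_or("profile_fdr")) & col_or("profile_fdr") < th$p_profile
  )
  modes <- cbind(smolt = smolt_mode, seawater = sw_mode, rhythm = rhythm_mode)
  overall <- apply(modes, 1, function(m) {
    m <- m[!is.na(m)]
    has_one <- any(m == "one-copy-regulated")
    has_dyn <- any(m == "different-dynamics")
    if (has_one && has_dyn) {
      "both"
    } else if (has_one) {
      "one-copy-regulated"
    } else if (has_dyn) {
      "different-dynamics"
    } else {
      "none"
    }
  })
  rep_tbl$mode_smolt <- smolt_mode
  rep_tbl$mode_seawater <- sw_mode
  rep_tbl$mode_rhythm <- rhythm_mode
  rep_tbl$mode <- overall
  class(rep_tbl) <- c("divergence_report", class(rep_tbl))
  attr(rep_tbl, "thresholds") <- th
  rep_tbl
}

join_copy_sig <- function(rep_tbl, de, prefix, fdr_cut) {
  sig <- as_tibble(de) |>
    mutate(sig = .data$fdr < fdr_cut) |>
    select("gene", "sig")
  rep_tbl |>
    left_join(setNames(sig, c("gene1", paste0(prefix, "_gene1"))), by = "gene1") |>
    left_join(setNames(sig, c("gene2", paste0(prefix, "_gene2"))), by = "gene2")
}

# Classify one assay context: NA when no evidence is available.
assay_mode <- function(sig1, sig2, dyn) {
  out <- rep(NA_character_, length(sig1))
  known <- !is.na(sig1) & !is.na(sig2)
  one <- known & (sig1 != sig2)
  both <- known & sig1 & sig2
  none <- known & !sig1 & !sig2
  out[one] <- "one-copy-regulated"
  out[both & dyn] <- "different-dynamics"
  out[both & !dyn] <- "none"
  out[none] <- "none"
  out
}

#' Run the profile-divergence test for every pair of a screen
#'
#' Convenience wrapper applying [profile_divergence_test()] to the two copies
#' of each pair over one tissue/condition stratum of a time-course bundle.
#'
#' @param pairs An `ohno_pairs` tibble.
#' @param bundle A time-course [expression_bundle()] (numeric `time`).
#' @param tissue,condition Stratum to test in.
#' @param window Optional `c(start, end)` hour window.
#' @param order Polynomial order.
#' @param tmm Apply TMM scaling.
#' @return Tibble `pair_id`, `tissue`, `condition`, `F`, `p` (pairs with a
#'   missing copy are skipped).
#' @export
pair_profile_tests <- function(pairs, bundle, tissue, condition,
                               window = NULL, order = 6, tmm = TRUE) {
  stopifnot(inherits(bundle, "expr_bundle"))
  nf <- if (tmm) tmm_factors(bundle) else NULL
  expr <- cpm(bundle, norm_factors = nf)
  meta <- bundle$samples
  sel <- meta$tissue == tissue & meta$condition == condition
  if (!is.null(window)) {
    sel <- sel & meta$time >= window[1] & meta$time <= window[2]
  }
  t_h <- meta$time[sel]
  pr <- as_tibble(pairs)
  map_dfr(seq_len(nrow(pr)), function(i) {
    g1 <- pr$gene1[i]
    g2 <- pr$gene2[i]
    if (!g1 %in% rownames(expr) || !g2 %in% rownames(expr)) {
      return(NULL)
    }
    d <- tibble(
      time = rep(t_h, 2),
      value = c(expr[g1, sel], expr[g2, sel]),
      series = rep(c("gene1", "gene2"), each = sum(sel))
    )
    fit <- profile_divergence_test(d, time, value, series, order = order)
    tibble(
      pair_id = paste(g1, g2, sep = "|"), tissue = tissue,
      condition = condition, F = fit$F, p = fit$p
    )
  })
}

#' Run the seawater interaction test for every pair
#'
#' @param pairs An `ohno_pairs` tibble.
#' @param bundle A two-condition [expression_bundle()] (e.g. FW/SW).
#' @param alpha Interaction significance threshold.
#' @param tmm Apply TMM scaling.
#' @return Tibble `pair_id`, `log2fc_gene1`, `log2fc_gene2`,
#'   `interaction_F`, `interaction_p`, `divergent`.
#' @export
pair_interaction_tests <- function(pairs, bundle, alpha = 0.05, tmm = TRUE) {
  stopifnot(inherits(bundle, "expr_bundle"))
  nf <- if (tmm) tmm_factors(bundle) else rep(1, ncol(bundle$counts))
  lib <- colSums(bundle$counts)
  cond <- factor(bundle$samples$condition)
  pr <- as_tibble(pairs)
  map_dfr(seq_len(nrow(pr)), function(i) {
    g1 <- pr$gene1[i]
    g2 <- pr$gene2[i]
    if (!g1 %in% rownames(bundle$counts) || !g2 %in% rownames(bundle$counts)) {
      return(NULL)
    }
    fit <- interaction_test(bundle$counts[g1, ], bundle$counts[g2, ],
      cond, lib, norm_factors = nf, alpha = alpha)
    tibble(
      pair_id = paste(g1, g2, sep = "|"),
      log2fc_gene1 = fit$log2fc_gene1, log2fc_gene2 = fit$log2fc_gene2,
      interaction_F = fit$interaction_F, interaction_p = fit$interaction_p,
      divergent = fit$divergent
    )
  })
}
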