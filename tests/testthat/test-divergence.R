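test_that("EDI is the absolute log2 ratio with symmetric zero handling", {
  expect_equal(compute_edi(8, 2), 2)
  expect_equal(compute_edi(2, 8), 2)
  expect_equal(compute_edi(7.3, 7.3), 0)
  # offset engages only when a value is 0, keeping the index finite
  expect_equal(compute_edi(0, 0), 0)
  expect_equal(compute_edi(0, 1.5, offset = 0.5), abs(log2(0.5 / 2)))
  expect_error(compute_edi(-1, 2), ">= 0")
  expect_error(compute_edi(1, 2, offset = 0), "positive")
  set.seed(51)
  a <- rexp(200)
  b <- rexp(200)
  expect_equal(compute_edi(a, b), compute_edi(b, a))
  # scale invariance when the offset is disengaged
  expect_equal(compute_edi(3.7 * a, 3.7 * b), compute_edi(a, b))
})

test_that("the EDI table matches a brute-force recomputation from the matrix", {
  fx <- quick_sim(seed = 23, n = 20, design = "atlas", n_background = 50)
  syn <- simulate_synteny(fx$cfg, fx$truth)
  pairs <- suppressWarnings(call_ohnolog_pairs(fx$sim$trees, fx$sim$groups, syn))
  ex <- simulate_expression(fx$cfg, fx$truth)
  edi <- edi_table(pairs, ex$bundle)
  expect_equal(nrow(edi), nrow(pairs) * length(fx$cfg$tissues))
  nf <- tmm_factors(ex$bundle)
  cmx <- cpm(ex$bundle, norm_factors = nf)
  meta <- ex$bundle$samples
  for (i in sample(nrow(edi), 30)) {
    r <- edi[i, ]
    e1 <- mean(cmx[r$gene1, meta$tissue == r$tissue])
    e2 <- mean(cmx[r$gene2, meta$tissue == r$tissue])
    expect_equal(r$edi, abs(log2(e1 / e2)), tolerance = 1e-12)
  }
  # per-pair summary is the median across tissues
  sm <- edi_summary(edi)
  one <- edi[edi$pair_id == sm$pair_id[1], ]
  expect_equal(sm$median_edi[1], median(one$edi))
  # a missing copy flags the pair and drops it
  crippled <- ex$bundle
  crippled$counts <- crippled$counts[
    setdiff(rownames(crippled$counts), pairs$gene1[1]), ]
  expect_warning(edi2 <- edi_table(pairs, crippled), "missing")
  expect_false(pairs$gene1[1] %in% edi2$gene1)
})

test_that("identical pair rows give zero EDI and a planted median is recovered", {
  counts <- rbind(g1 = rep(100L, 11), g2 = rep(100L, 11))
  # edi values 0..10 planted via exact powers of two on gene2
  counts2 <- rbind(ga = 64L * 2L^(0:10), gb = rep(64L, 11))
  m <- rbind(counts, counts2)
  colnames(m) <- paste0("t", 1:11)
  meta <- tibble::tibble(sample = colnames(m), tissue = colnames(m),
    condition = "atlas", time = NA_real_, replicate = 1L)
  b <- expression_bundle(m, meta)
  pairs <- tibble::tibble(gene1 = c("g1", "ga"), gene2 = c("g2", "gb"))
  edi <- edi_table(pairs, b, tmm = FALSE)
  sm <- edi_summary(edi)
  expect_equal(sm$median_edi[sm$gene1 == "g1"], 0)
  expect_equal(sm$median_edi[sm$gene1 == "ga"], 5)
})

test_that("profile divergence equals the nested OLS oracle and is symmetric", {
  set.seed(53)
  t_h <- rep(seq(5, 29, 4), each = 3)
  for (rep in 1:20) {
    y1 <- 2^cos(2 * pi * t_h / 24) * exp(rnorm(21, 0, 0.2))
    y2 <- 2^cos(2 * pi * (t_h - 6) / 24) * exp(rnorm(21, 0, 0.2))
    d <- data.frame(time = rep(t_h, 2), value = c(y1, y2),
      series = rep(c("a", "b"), each = 21))
    fit <- profile_divergence_test(d, time, value, series)
    # independent oracle: nested linear models on the same normalized data
    yn <- c(y1 / mean(y1), y2 / mean(y2))
    tc <- rep(t_h, 2) - mean(rep(t_h, 2))
    X <- outer(tc / max(abs(tc)), 0:6, "^")
    grp <- factor(rep(c("a", "b"), each = 21))
    av <- anova(lm(yn ~ X - 1), lm(yn ~ X:grp - 1))
    expect_equal(fit$F, av$F[2], tolerance = 1e-8)
    expect_equal(fit$p, av[["Pr(>F)"]][2], tolerance = 1e-8)
    expect_lte(fit$rss_separate, fit$rss_shared + 1e-12)
    # relabelling which gene is series 1 changes nothing
    d_swap <- d
    d_swap$series <- rep(c("b", "a"), each = 21)
    fit2 <- profile_divergence_test(d_swap, time, value, series)
    expect_equal(fit2$F, fit$F, tolerance = 1e-10)
  }
})

test_that("identical series give F = 0 and degenerate designs are named", {
  t_h <- rep(seq(5, 29, 4), each = 3)
  y <- 2 + cos(t_h)
  d <- data.frame(time = rep(t_h, 2), value = rep(y, 2),
    series = rep(c("a", "b"), each = 21))
  fit <- profile_divergence_test(d, time, value, series)
  expect_equal(fit$F, 0)
  expect_equal(fit$p, 1)
  short <- data.frame(time = rep(rep(c(1, 2, 3), each = 3), 2),
    value = rnorm(18), series = rep(c("a", "b"), each = 9))
  expect_error(profile_divergence_test(short, time, value, series),
    "distinct timepoints")
})

test_that("profile-divergence type-I error is near nominal on a shared curve", {
  set.seed(55)
  t_h <- rep(seq(5, 29, 4), each = 3)
  curve <- 2^(1.5 * cos(2 * pi * (t_h - 9) / 24))
  hits <- vapply(1:1000, function(i) {
    y1 <- curve * exp(rnorm(21, 0, 0.2))
    y2 <- curve * exp(rnorm(21, 0, 0.2))
    d <- data.frame(time = rep(t_h, 2), value = c(y1, y2),
      series = rep(c("a", "b"), each = 21))
    profile_divergence_test(d, time, value, series)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.005)
  expect_lte(mean(hits), 0.02)
})

test_that("the copy-by-condition interaction matches a general linear model", {
  set.seed(57)
  cond <- factor(rep(c("FW", "SW"), each = 6), levels = c("FW", "SW"))
  lib <- rep(1e6, 12)
  c1 <- rpois(12, 200 * 2^(cond == "SW") * 2)
  c2 <- rpois(12, 150 * rep(1, 12))
  fit <- interaction_test(c1, c2, cond, lib)
  y <- log2(c(c1, c2) / rep(lib, 2) * 1e6 + 0.5)
  d <- data.frame(y = y, copy = rep(c("g1", "g2"), each = 12),
    cond = rep(cond, 2))
  av <- anova(lm(y ~ copy * cond, data = d))
  expect_equal(fit$interaction_F, av["copy:cond", "F value"], tolerance = 1e-10)
  expect_equal(fit$interaction_p, av["copy:cond", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(glance(fit)$interaction_p, fit$interaction_p)
  expect_true(all(c("term", "Pr(>F)") %in% names(tidy(fit))))
  # identical responses: no interaction by construction
  same <- interaction_test(c1, c1, cond, lib)
  expect_gt(same$interaction_p, 0.9)
  expect_error(interaction_test(c1[1:6], c2[1:6], cond[1:6], lib[1:6]),
    "two levels|singleton")
})

test_that("a planted response difference is detected in nearly every run", {
  set.seed(59)
  cond <- factor(rep(c("FW", "SW"), each = 6), levels = c("FW", "SW"))
  lib <- rep(1e6, 12)
  hits <- vapply(1:200, function(i) {
    base1 <- 2^rnorm(1, 7, 0.1)
    # copy 1 responds with 2 log2 units, copy 2 not at all; residual sd 0.25
    y1 <- round(2^(log2(base1) + 2 * (cond == "SW") + rnorm(12, 0, 0.25)))
    y2 <- round(2^(log2(base1) + rnorm(12, 0, 0.25)))
    interaction_test(y1, y2, cond, lib)$interaction_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("profile clustering recovers planted archetypes and its invariances", {
  set.seed(61)
  shapes <- archetype_shapes(6, 5)
  profiles <- shapes[rep(1:5, each = 40), ] +
    matrix(rnorm(200 * 6, 0, 0.2), 200, 6)
  rownames(profiles) <- sprintf("g%03d", 1:200)
  cl <- cluster_profiles(profiles, k = 5)
  ari <- mclust::adjustedRandIndex(cl$cluster, rep(1:5, each = 40))
  expect_gte(ari, 0.9)
  # deterministic re-run
  cl2 <- cluster_profiles(profiles, k = 5)
  expect_identical(cl$cluster, cl2$cluster)
  # affine per-gene rescaling leaves correlation distances unchanged
  rescaled <- profiles * rexp(200) + rnorm(200)
  cl3 <- cluster_profiles(rescaled, k = 5)
  expect_identical(cl$cluster, cl3$cluster)
  # identical profiles always share a cluster
  twin <- rbind(profiles, g999 = profiles["g001", ])
  cl4 <- cluster_profiles(twin, k = 5)
  expect_equal(cl4$cluster[cl4$gene == "g999"], cl4$cluster[cl4$gene == "g001"])
  # perfectly anti-correlated profiles sit at the maximal distance
  anti <- rbind(a = shapes[1, ], b = -shapes[1, ], shapes[2:5, ] +
    matrix(rnorm(24, 0, 0.05), 4, 6))
  z <- t(scale(t(anti)))
  expect_equal(max(1 - cor(t(z))), (1 - cor(z["a", ], z["b", ])), tolerance = 1e-12)
  expect_equal(1 - cor(z["a", ], z["b", ]), 2, tolerance = 1e-12)
  # zero-variance profiles are excluded with a warning
  flat <- rbind(profiles[1:20, ], flatgene = rep(3, 6))
  expect_warning(cl5 <- cluster_profiles(flat, k = 3), "zero-variance")
  expect_false("flatgene" %in% cl5$gene)
})

test_that("divergence modes follow the one-copy / different-dynamics definitions", {
  pairs <- tibble::tibble(
    orthogroup_id = paste0("OG", 1:4),
    gene1 = paste0("a", 1:4), gene2 = paste0("b", 1:4),
    rediploid_class = "late"
  )
  de <- tibble::tibble(
    gene = c(paste0("a", 1:4), paste0("b", 1:4)),
    contrast = "timecourse_T1_T6",
    log2fc = NA_real_, statistic = 1, df = 5L,
    p = 1, fdr = c(0.001, 0.001, 0.001, 0.5, 0.001, 0.001, 0.5, 0.5)
  )
  clusters <- tibble::tibble(
    gene = c("a1", "b1", "a2", "b2", "a3", "b3"),
    cluster = c(1L, 1L, 1L, 2L, 1L, 1L)
  )
  rep_tbl <- pair_divergence_report(pairs, de_timecourse = de, clusters = clusters)
  modes <- setNames(rep_tbl$mode_smolt, rep_tbl$orthogroup_id)
  expect_identical(unname(modes[c("OG1", "OG2", "OG3", "OG4")]),
    c("none", "different-dynamics", "one-copy-regulated", "none"))
  expect_identical(rep_tbl$mode[rep_tbl$orthogroup_id == "OG2"],
    "different-dynamics")
})

test_that("the report recovers exactly the planted divergent pairs", {
  fx <- quick_sim(seed = 7, n = 30, design = "smolt")
  syn <- simulate_synteny(fx$cfg, fx$truth)
  pairs <- suppressWarnings(call_ohnolog_pairs(fx$sim$trees, fx$sim$groups, syn))
  ex_sm <- simulate_expression(fx$cfg, fx$truth)
  truth <- ex_sm$truth
  cfg_sw <- sim_config(seed = 7, n_orthogroups = 30, p_loss_post_wgd = 0.2,
    n_negative_controls = 5, design = "seawater")
  ex_sw <- simulate_expression(cfg_sw, truth)
  truth <- ex_sw$truth

  b <- ex_sm$bundle
  stages <- factor(b$samples$time)
  nf <- tmm_factors(b)
  disp <- estimate_common_dispersion(b$counts, stages, norm_factors = nf)
  de_tc <- timecourse_test(b$counts, stages, disp$dispersion, norm_factors = nf)
  sig <- de_tc$gene[de_tc$fdr < 0.01]
  lcpm <- cpm(b, norm_factors = nf, log = TRUE)[sig, , drop = FALSE]
  prof <- vapply(split(seq_len(ncol(lcpm)), b$samples$time),
    function(ix) rowMeans(lcpm[, ix, drop = FALSE]), numeric(nrow(lcpm)))
  cl <- cluster_profiles(prof, k = 5)

  bw <- ex_sw$bundle
  cond <- factor(bw$samples$condition, levels = c("FW", "SW"))
  nfw <- tmm_factors(bw)
  dsw <- estimate_common_dispersion(bw$counts, cond, norm_factors = nfw)
  de_sw <- nb_exact_test(bw$counts, cond, dsw$dispersion, norm_factors = nfw)
  it <- pair_interaction_tests(pairs, bw)

  rep_tbl <- pair_divergence_report(pairs, de_timecourse = de_tc,
    de_sw = de_sw, clusters = cl, interaction = it)
  planted <- truth$divergent_pairs
  planted$pair_id <- paste(planted$gene1, planted$gene2, sep = "|")
  for (ctx in c("smolt", "seawater")) {
    pl <- planted[planted$context == ctx, ]
    got <- setNames(rep_tbl[[paste0("mode_", ctx)]], rep_tbl$pair_id)
    expect_identical(unname(got[pl$pair_id]), pl$mode)
    others <- setdiff(rep_tbl$pair_id, pl$pair_id)
    expect_true(all(got[others] == "none", na.rm = TRUE))
  }
})
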