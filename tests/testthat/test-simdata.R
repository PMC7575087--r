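test_that("the species partition is validated with the missing group named", {
  expect_error(
    sim_config(species = list(salmonids = c("ssal", "omyk"), outgroups = "drer")),
    "pike"
  )
  expect_error(
    sim_config(species = list(salmonids = "ssal", pike = "eluc", outgroups = "drer")),
    "salmonids"
  )
  expect_error(sim_config(similarity_class_mix = c(early = 0.5, mid = 0.5, late = 0.5)),
    "sum to 1")
  expect_error(sim_config(p_loss_post_wgd = 1.5), "\\[0, 1\\]")
})

test_that("tree simulation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 1, n_orthogroups = 12, n_negative_controls = 3)
  a <- simulate_gene_trees(cfg)
  b <- simulate_gene_trees(cfg)
  expect_identical(
    vapply(a$trees, write_newick, character(1)),
    vapply(b$trees, write_newick, character(1))
  )
  expect_identical(a$truth$true_pairs, b$truth$true_pairs)
  syn_a <- simulate_synteny(cfg, a$truth)
  syn_b <- simulate_synteny(cfg, b$truth)
  expect_identical(syn_a$windows, syn_b$windows)
  cfg_c <- sim_config(seed = 1, n_orthogroups = 12, n_negative_controls = 3,
    design = "seawater")
  ex_a <- simulate_expression(cfg_c, a$truth)
  ex_b <- simulate_expression(cfg_c, b$truth)
  expect_identical(ex_a$bundle$counts, ex_b$bundle$counts)
})

test_that("retention probability controls the pair/singleton split exactly at the ends", {
  all_kept <- simulate_gene_trees(
    sim_config(seed = 2, n_orthogroups = 50, p_loss_post_wgd = 0)
  )
  expect_equal(nrow(all_kept$truth$true_pairs), 50L)
  expect_equal(nrow(all_kept$truth$singletons), 0L)

  all_lost <- simulate_gene_trees(
    sim_config(seed = 2, n_orthogroups = 50, p_loss_post_wgd = 1)
  )
  expect_equal(nrow(all_lost$truth$true_pairs), 0L)
  expect_equal(nrow(all_lost$truth$singletons), 50L)
})

test_that("window similarities fall inside the assigned rediploidization band", {
  fx <- quick_sim(seed = 4, n = 40)
  syn <- simulate_synteny(fx$cfg, fx$truth)
  per_block <- split(syn$windows$pct_identity, syn$windows$block_id)
  cls <- fx$truth$blocks$class[match(names(per_block), fx$truth$blocks$block_id)]
  for (i in seq_along(per_block)) {
    w <- per_block[[i]]
    if (cls[i] == "late") expect_true(all(w > 95))
    if (cls[i] == "mid") expect_true(all(w >= 90 & w <= 95))
    if (cls[i] == "early") expect_true(all(w > 85 & w < 90))
  }
  # every true pair is covered by its block; decoys are covered by none
  for (i in seq_len(nrow(fx$truth$true_pairs))) {
    p <- fx$truth$true_pairs[i, ]
    got <- synteny_supported(
      list(chromosome = p$chr1, start = p$start1, end = p$end1),
      list(chromosome = p$chr2, start = p$start2, end = p$end2), syn
    )
    expect_true(got$supported)
    expect_identical(got$block_id, p$block_id)
  }
  decoys <- fx$truth$singletons[fx$truth$singletons$reason == "neg_synteny_decoy", ]
  for (og in unique(decoys$orthogroup_id)) {
    d <- decoys[decoys$orthogroup_id == og, ]
    got <- synteny_supported(
      list(chromosome = d$chromosome[1], start = d$start[1], end = d$end[1]),
      list(chromosome = d$chromosome[2], start = d$start[2], end = d$end[2]), syn
    )
    expect_false(got$supported)
  }
})

test_that("simulated counts match negative-binomial moments", {
  cfg <- sim_config(seed = 6, n_orthogroups = 10, design = "seawater",
    frac_sw_responsive = 0, n_background = 400, nb_dispersion = 0.1,
    n_replicates = 30)
  sim <- simulate_gene_trees(cfg)
  ex <- simulate_expression(cfg, sim$truth)
  counts <- ex$bundle$counts
  expect_gt(length(counts), 1e4)
  # scale out per-sample depth: var(norm) = mu * mean(c) + phi * mu^2 with
  # c the depth-rescaling factors, so the per-gene moment estimate of phi is
  # (v - m * mean(c)) / m^2
  lib <- colSums(counts)
  cvec <- mean(lib) / lib
  norm <- sweep(counts, 2, cvec, "*")
  m <- rowMeans(norm)
  v <- apply(norm, 1, var)
  keep <- m > 50
  phi_g <- ((v - m * mean(cvec)) / m^2)[keep]
  se_med <- 1.25 * sd(phi_g) / sqrt(length(phi_g))
  expect_gt(length(phi_g), 100)
  expect_lt(abs(median(phi_g) - 0.1), 3 * se_med)
})

test_that("planted phases are exactly recoverable from noise-free means", {
  times <- rep(seq(5, 29, 4), each = 3)
  for (phase in c(0, 3.7, 11, 19.25)) {
    y <- 1.8 * cos(2 * pi * (times - phase) / 24) + 6
    fit <- cosinor_fit(times, y)
    expect_equal(fit$phase_h, phase, tolerance = 1e-9)
    expect_equal(fit$amplitude, 1.8, tolerance = 1e-9)
    expect_equal(fit$mesor, 6, tolerance = 1e-9)
  }
})

test_that("zero amplitude and zero damping give flat expected profiles", {
  cfg <- sim_config(seed = 8, n_orthogroups = 15, design = "circadian",
    frac_rhythmic = 0.5,
    damping_per_tissue = c(OT = 0.8, SV = 0, gill = 0))
  sim <- simulate_gene_trees(cfg)
  ex <- simulate_expression(cfg, sim$truth)
  rhy <- ex$truth$rhythmic_genes
  meta <- ex$bundle$samples
  counts <- ex$bundle$counts
  # gill under constant light: damping 0 means planted rhythms are flat there,
  # so a cosinor fit to the mean profile finds only noise-level amplitude
  sel <- meta$tissue == "gill" & meta$condition == "LL"
  lcpm <- cpm(ex$bundle, log = TRUE)
  amps <- vapply(rhy$gene, function(g) {
    cosinor_fit(meta$time[sel], lcpm[g, sel])$amplitude
  }, numeric(1))
  expect_lt(median(amps), 0.35)
  # same genes keep their full amplitude in diel gill samples
  sel_d <- meta$tissue == "gill" & meta$condition == "diel"
  amps_d <- vapply(rhy$gene, function(g) {
    cosinor_fit(meta$time[sel_d], lcpm[g, sel_d])$amplitude
  }, numeric(1))
  expect_gt(median(amps_d / rhy$amplitude), 0.75)
  # non-rhythmic background genes are flat everywhere
  bg <- grep("^bg", rownames(counts), value = TRUE)[1:50]
  amps_bg <- vapply(bg, function(g) {
    cosinor_fit(meta$time[sel_d], lcpm[g, sel_d])$amplitude
  }, numeric(1))
  expect_lt(median(amps_bg), 0.35)
})

test_that("planted seawater log2 fold changes are recovered on average", {
  cfg <- sim_config(seed = 11, n_orthogroups = 280, p_loss_post_wgd = 0.1,
    design = "seawater", frac_sw_responsive = 1, frac_divergent_pairs = 0,
    n_background = 10000)
  sim <- simulate_gene_trees(cfg)
  ex <- simulate_expression(cfg, sim$truth)
  tr <- ex$truth$sw_responsive
  expect_gt(nrow(tr), 450)
  b <- ex$bundle
  cond <- factor(b$samples$condition, levels = c("FW", "SW"))
  cm <- cpm(b, norm_factors = tmm_factors(b))
  rec <- log2(rowMeans(cm[tr$gene, cond == "SW"]) /
    rowMeans(cm[tr$gene, cond == "FW"]))
  expect_lt(abs(mean(rec) - mean(tr$log2fc)), 0.1)
  expect_lt(
    abs(mean(rec) - cfg$sw_effect_log2fc[["mu"]]),
    0.1 + abs(mean(tr$log2fc) - cfg$sw_effect_log2fc[["mu"]])
  )
})

test_that("every focal expression gene is exactly one of paired or singleton", {
  fx <- quick_sim(seed = 13, n = 25, design = "smolt")
  ex <- simulate_expression(fx$cfg, fx$truth)
  genes <- rownames(ex$bundle$counts)
  focal <- genes[!grepl("^bg", genes)]
  paired <- c(fx$truth$true_pairs$gene1, fx$truth$true_pairs$gene2)
  single <- fx$truth$singletons$gene_id
  expect_length(intersect(paired, single), 0)
  expect_setequal(focal, c(paired, single))
})

test_that("unknown design labels are rejected", {
  expect_error(sim_config(design = "larval"), "arg")
})
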