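#' Developmental archetype curves
#'
#' Fixed profile shapes over developmental stages, scaled to `[-1, 1]`:
#' monotone rise, monotone fall, mid-course peak, mid-course trough, early
#' transient. For `k > 5` (or a stage count other than 6) a cosine-harmonic
#' basis is used instead.
#'
#' @param n_stages Number of stages (default 6, T1-T6).
#' @param k Number of archetypes.
#' @return A `k x n_stages` matrix, rows named `A1..Ak`.
#' @export
archetype_shapes <- function(n_stages = 6L, k = 5L) {
  if (n_stages == 6L && k <= 5L) {
    shapes <- rbind(
      seq(-1, 1, length.out = 6),
      seq(1, -1, length.out = 6),
      c(-1, 0.2, 1, 1, 0.2, -1),
      c(1, -0.2, -1, -1, -0.2, 1),
      c(-0.8, 1, 0.4, -0.2, -0.6, -1)
    )[seq_len(k), , drop = FALSE]
  } else {
    t01 <- seq(0, 1, length.out = n_stages)
    shapes <- t(vapply(seq_len(k), function(j) cos(pi * j * t01), numeric(n_stages)))
  }
  rownames(shapes) <- paste0("A", seq_len(k))
  colnames(shapes) <- paste0("T", seq_len(n_stages))
  shapes
}

#' Simulate an expression experiment with known ground truth
#'
#' Draws negative-binomial counts whose log2 mean is
#' `baseline + cosine term + archetype term + seawater term`, on top of
#' log-uniform library sizes within 2-fold of the configured centre. The
#' design decides which term is active:
#' \describe{
#'   \item{atlas}{per-gene, per-tissue baselines over the tissue panel
#'     (copies of a pair share correlated tissue profiles).}
#'   \item{circadian}{a planted fraction of genes oscillates with
#'     `amplitude * cos(2*pi*(t - phase)/24)`; under constant conditions the
#'     amplitude is multiplied by the tissue's damping factor.}
#'   \item{smolt}{a planted fraction follows an archetype curve over stages
#'     T1-T6; a planted fraction of pairs diverges, either one copy regulated
#'     or the two copies on different archetypes.}
#'   \item{seawater}{a planted gene subset is seawater-induced with log2 fold
#'     changes from the configured distribution; planted divergent pairs have
#'     one copy responsive or both responsive with unequal fold changes.}
#' }
#'
#' @param config A [sim_config()] (its `design` field selects the branch).
#' @param truth The `sim_truth` from [simulate_gene_trees()]; planted effects
#'   are recorded into it.
#' @return A list with `bundle` (an [expression_bundle()]) and `truth` (the
#'   input truth extended with `rhythmic_genes`, `archetype_of_gene`,
#'   `sw_responsive`, `regulated_genes` and `divergent_pairs` as applicable).
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  design <- config$design

  genes <- truth_genes(truth)
  if (nrow(genes) == 0L) stopf("truth contains no focal genes")
  genes$background <- FALSE
  if (config$n_background > 0L) {
    genes <- bind_rows(genes, tibble(
      gene_id = sprintf("bg%04d", seq_len(config$n_background)),
      orthogroup_id = NA_character_, copy = NA_character_,
      pair_of = NA_character_, background = TRUE
    ))
  }
  G <- nrow(genes)

  withr::with_seed(stream_seed(config$seed, 3L), {
    base <- rnorm(G, config$mean_log2_expression[["mu"]],
      config$mean_log2_expression[["sigma"]])
    names(base) <- genes$gene_id
    # copies of a pair share a correlated baseline
    is_b <- genes$copy == "b" & !is.na(genes$pair_of)
    base[is_b] <- base[match(genes$pair_of[is_b], genes$gene_id)] + rnorm(sum(is_b), 0, 0.3)

    out <- switch(design,
      atlas = sim_design_atlas(config, genes, base, truth),
      circadian = sim_design_circadian(config, genes, base, truth),
      smolt = sim_design_smolt(config, genes, base, truth),
      seawater = sim_design_seawater(config, genes, base, truth),
      stopf("unknown design label '%s'", design)
    )
    meta <- out$meta
    log2cpm <- out$log2cpm
    truth <- out$truth

    lib <- exp(runif(nrow(meta), log(config$library_size / 2),
      log(config$library_size * 2)))
    mu <- sweep(2^log2cpm, 2, lib / 1e6, "*")
    phi <- config$nb_dispersion
    counts <- if (phi > 0) {
      matrix(rnbinom(length(mu), size = 1 / phi, mu = mu), nrow(mu), ncol(mu))
    } else {
      matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
    }
    dimnames(counts) <- dimnames(log2cpm)
    list(
      bundle = expression_bundle(counts, meta),
      truth = truth
    )
  })
}

# Focal gene table: id, locus, pair membership (pair_of = partner copy "a").
truth_genes <- function(truth) {
  pairs <- truth$true_pairs
  rows <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    rows[[1]] <- tibble(
      gene_id = pairs$gene1, orthogroup_id = pairs$orthogroup_id,
      copy = "a", pair_of = NA_character_
    )
    rows[[2]] <- tibble(
      gene_id = pairs$gene2, orthogroup_id = pairs$orthogroup_id,
      copy = "b", pair_of = pairs$gene1
    )
  }
  if (!is.null(truth$singletons) && nrow(truth$singletons)) {
    rows[[3]] <- tibble(
      gene_id = truth$singletons$gene_id,
      orthogroup_id = truth$singletons$orthogroup_id,
      copy = NA_character_, pair_of = NA_character_
    )
  }
  bind_rows(rows) |> arrange(.data$gene_id)
}

sim_design_atlas <- function(config, genes, base, truth) {
  tissues <- config$tissues
  meta <- tidyr::expand_grid(tissue = tissues, replicate = seq_len(config$n_replicates)) |>
    mutate(
      condition = "atlas", time = NA_real_,
      sample = sprintf("atlas_%s_r%d", .data$tissue, .data$replicate)
    ) |>
    select("sample", "tissue", "condition", "time", "replicate")
  G <- nrow(genes)
  eff <- matrix(rnorm(G * length(tissues), 0, 1.5), G, length(tissues),
    dimnames = list(genes$gene_id, tissues))
  is_b <- genes$copy == "b" & !is.na(genes$pair_of)
  eff[is_b, ] <- eff[match(genes$pair_of[is_b], genes$gene_id), , drop = FALSE] +
    matrix(rnorm(sum(is_b) * length(tissues), 0, 0.6), sum(is_b), length(tissues))
  log2cpm <- base + eff[, match(meta$tissue, tissues), drop = FALSE]
  colnames(log2cpm) <- meta$sample
  list(meta = meta, log2cpm = log2cpm, truth = truth)
}

sim_design_circadian <- function(config, genes, base, truth) {
  tps <- config$timepoints
  meta <- bind_rows(lapply(names(tps), function(cond) {
    tidyr::expand_grid(
      tissue = config$tissues, time = tps[[cond]],
      replicate = seq_len(config$n_replicates)
    ) |>
      mutate(condition = cond)
  })) |>
    mutate(sample = sprintf(
      "circ_%s_%s_t%02d_r%d", .data$tissue, .data$condition,
      as.integer(.data$time), .data$replicate
    )) |>
    select("sample", "tissue", "condition", "time", "replicate")

  G <- nrow(genes)
  focal <- genes$gene_id[!genes$background]
  n_rhy <- round(config$frac_rhythmic * length(focal))
  rhythmic <- sort(sample(focal, n_rhy))
  amp <- rlnorm(n_rhy, config$amplitude_lognormal[["mu"]],
    config$amplitude_lognormal[["sigma"]])
  phase <- runif(n_rhy, 0, 24)
  rhy <- tibble(gene = rhythmic, amplitude = amp, phase_h = phase)

  damp <- config$damping_per_tissue
  log2cpm <- matrix(rep(base, ncol = nrow(meta)), G, nrow(meta),
    dimnames = list(genes$gene_id, meta$sample))
  for (k in seq_len(n_rhy)) {
    g <- rhy$gene[k]
    d <- ifelse(meta$condition == "diel", 1, damp[meta$tissue])
    log2cpm[g, ] <- log2cpm[g, ] +
      rhy$amplitude[k] * d * cos(2 * pi * (meta$time - rhy$phase_h[k]) / 24)
  }
  truth$rhythmic_genes <- rhy
  truth$damping_per_tissue <- damp
  list(meta = meta, log2cpm = log2cpm, truth = truth)
}

sim_design_smolt <- function(config, genes, base, truth) {
  stages <- config$timepoints %||% paste0("T", 1:6)
  S <- length(stages)
  meta <- tidyr::expand_grid(
    tissue = config$tissues[1], time = stages,
    replicate = seq_len(config$n_replicates)
  ) |>
    mutate(
      condition = "stage",
      sample = sprintf("smolt_%s_r%d", .data$time, .data$replicate)
    ) |>
    select("sample", "tissue", "condition", "time", "replicate")

  shapes <- archetype_shapes(S, config$n_archetypes)
  plan <- plan_regulation(genes, config, context = "smolt")
  arch <- plan$assignment |>
    mutate(archetype = ifelse(is.na(.data$effect_id), NA_integer_, .data$effect_id))

  G <- nrow(genes)
  log2cpm <- matrix(rep(base, ncol = length(stages) * config$n_replicates),
    G, nrow(meta), dimnames = list(genes$gene_id, meta$sample))
  stage_idx <- match(meta$time, stages)
  half <- config$archetype_swing_log2 / 2
  for (i in which(!is.na(arch$archetype))) {
    g <- arch$gene[i]
    log2cpm[g, ] <- log2cpm[g, ] + half * shapes[arch$archetype[i], stage_idx]
  }
  truth$archetype_of_gene <- arch |>
    filter(!is.na(.data$archetype)) |>
    select(gene = "gene", archetype = "archetype")
  truth$regulated_genes <- bind_rows(
    truth$regulated_genes,
    tibble(gene = arch$gene[!is.na(arch$archetype)], context = "smolt")
  )
  truth$divergent_pairs <- bind_rows(truth$divergent_pairs, plan$divergent)
  list(meta = meta, log2cpm = log2cpm, truth = truth)
}

sim_design_seawater <- function(config, genes, base, truth) {
  meta <- tidyr::expand_grid(
    condition = c("FW", "SW"), replicate = seq_len(config$n_replicates)
  ) |>
    mutate(
      tissue = config$tissues[1], time = NA_character_,
      sample = sprintf("sw_%s_r%d", .data$condition, .data$replicate)
    ) |>
    select("sample", "tissue", "condition", "time", "replicate")

  plan <- plan_regulation(genes, config, context = "seawater")
  fc_mu <- config$sw_effect_log2fc[["mu"]]
  fc_sd <- config$sw_effect_log2fc[["sigma"]]
  assignment <- plan$assignment
  # draw fold changes; effect_id 1 = primary induction, 2 = divergent partner
  # (equal magnitude, opposite sign), 3 = partner sharing the same response
  full <- !is.na(assignment$effect_id)
  fc <- rep(NA_real_, nrow(assignment))
  fc[full] <- rnorm(sum(full), fc_mu, fc_sd)
  div <- which(full & assignment$effect_id == 2L)
  fc[div] <- -fc[match(assignment$pair_partner[div], assignment$gene)]
  share <- which(full & assignment$effect_id == 3L)
  fc[share] <- fc[match(assignment$pair_partner[share], assignment$gene)]
  assignment$log2fc <- fc

  G <- nrow(genes)
  log2cpm <- matrix(rep(base, ncol = nrow(meta)), G, nrow(meta),
    dimnames = list(genes$gene_id, meta$sample))
  sw <- meta$condition == "SW"
  for (i in which(!is.na(fc))) {
    log2cpm[assignment$gene[i], sw] <- log2cpm[assignment$gene[i], sw] + fc[i]
  }
  truth$sw_responsive <- assignment |>
    filter(!is.na(.data$log2fc)) |>
    select(gene = "gene", log2fc = "log2fc")
  truth$regulated_genes <- bind_rows(
    truth$regulated_genes,
    tibble(gene = assignment$gene[!is.na(fc)], context = "seawater")
  )
  truth$divergent_pairs <- bind_rows(truth$divergent_pairs, plan$divergent)
  list(meta = meta, log2cpm = log2cpm, truth = truth)
}

# Decide which genes carry a planted effect and which pairs diverge.
# effect_id semantics: 1 = primary effect, 2 = different-dynamics partner
# (distinct archetype / attenuated fold change), 3 = shared-effect partner,
# NA = no planted effect.
plan_regulation <- function(genes, config, context) {
  pairs <- genes |>
    filter(.data$copy == "b", !is.na(.data$pair_of)) |>
    select(gene2 = "gene_id", gene1 = "pair_of", orthogroup_id = "orthogroup_id")
  n_pairs <- nrow(pairs)
  n_div <- round(config$frac_divergent_pairs * n_pairs)
  n_one <- ceiling(n_div / 2)
  n_dyn <- n_div - n_one
  div_idx <- if (n_pairs) sample(seq_len(n_pairs), n_div) else integer(0)
  one_idx <- div_idx[seq_len(n_one)]
  dyn_idx <- setdiff(div_idx, one_idx)
  rest_idx <- setdiff(seq_len(n_pairs), div_idx)
  both_idx <- rest_idx[runif(length(rest_idx)) < frac_effect(config, context)]

  assignment <- tibble(
    gene = genes$gene_id,
    pair_partner = NA_character_,
    effect_id = NA_integer_
  )
  set_eff <- function(assignment, gene, id, partner = NA_character_) {
    i <- match(gene, assignment$gene)
    assignment$effect_id[i] <- id
    assignment$pair_partner[i] <- partner
    assignment
  }
  k <- max(1L, config$n_archetypes)
  for (i in one_idx) {
    assignment <- set_eff(assignment, pairs$gene1[i], 1L)
  }
  for (i in dyn_idx) {
    assignment <- set_eff(assignment, pairs$gene1[i], 1L)
    assignment <- set_eff(assignment, pairs$gene2[i], 2L, pairs$gene1[i])
  }
  for (i in both_idx) {
    assignment <- set_eff(assignment, pairs$gene1[i], 1L)
    assignment <- set_eff(assignment, pairs$gene2[i], 3L, pairs$gene1[i])
  }
  singles <- genes$gene_id[is.na(genes$copy) & !genes$background]
  on <- singles[runif(length(singles)) < frac_effect(config, context)]
  for (g in on) assignment <- set_eff(assignment, g, 1L)

  if (context == "smolt") {
    # map effect ids to archetypes: primary and shared partner share one
    # archetype; different-dynamics partners get a different one
    prim <- sample.int(k, nrow(assignment), replace = TRUE)
    eff <- assignment$effect_id
    arch <- ifelse(is.na(eff), NA_integer_, prim)
    i3 <- which(eff %in% 3L)
    arch[i3] <- arch[match(assignment$pair_partner[i3], assignment$gene)]
    i2 <- which(eff %in% 2L)
    if (length(i2) && k > 1L) {
      p <- arch[match(assignment$pair_partner[i2], assignment$gene)]
      off <- 1L + (prim[i2] %% (k - 1L)) # in 1..k-1, so never the partner's
      arch[i2] <- (p - 1L + off) %% k + 1L
    }
    assignment$effect_id <- arch
  }

  divergent <- tibble(
    orthogroup_id = pairs$orthogroup_id[c(one_idx, dyn_idx)],
    gene1 = pairs$gene1[c(one_idx, dyn_idx)],
    gene2 = pairs$gene2[c(one_idx, dyn_idx)],
    context = context,
    mode = c(
      rep("one-copy-regulated", length(one_idx)),
      rep("different-dynamics", length(dyn_idx))
    )
  )
  list(assignment = assignment, divergent = divergent)
}

frac_effect <- function(config, context) {
  if (context == "smolt") config$frac_regulated else config$frac_sw_responsive
}
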