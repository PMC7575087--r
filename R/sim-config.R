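#' Configuration for the synthetic-study generator
#'
#' Collects every knob of the synthetic data generator: the species partition
#' and orthogroup count for gene-tree simulation, the rediploidization class
#' mix for synteny windows, and the design-specific expression parameters
#' (tissue atlas, diel/circadian time course, smoltification stages T1-T6, or
#' a freshwater/seawater challenge). Defaults emulate the study conditions the
#' designs are modelled on: 4-h circadian sampling with n = 3, six
#' developmental stages with n = 6, FW/SW groups with n = 6, negative-binomial
#' counts around library sizes of one million reads.
#'
#' @param seed Master seed; each artifact (trees, synteny, expression) draws
#'   from its own stream derived from this seed by a fixed offset.
#' @param n_orthogroups Number of orthogroups (gene trees).
#' @param species List with elements `salmonids` (>= 2 species, first or
#'   `focal` is the focal species), `pike` (exactly one id), `outgroups`
#'   (>= 1 id), `focal`.
#' @param p_loss_post_wgd Probability that one Ss4R copy was lost in the focal
#'   species, leaving a singleton.
#' @param similarity_class_mix Named proportions over `early`, `mid`, `late`
#'   rediploidization classes; must sum to 1.
#' @param n_negative_controls Number of extra orthogroups carrying two focal
#'   copies but violating one calling criterion each (intruder species, wrong
#'   sister, mixed sister, no mirrored pair, synteny decoy), cycled in order.
#' @param design One of `"atlas"`, `"circadian"`, `"smolt"`, `"seawater"`.
#' @param tissues Tissue panel; defaults per design (11-tissue atlas; optic
#'   tectum, saccus vasculosus and gill for the circadian design; gill for the
#'   smolt and seawater designs).
#' @param timepoints For `circadian`: named list of hour vectors per condition
#'   (`diel`, `LL`, `DD`); for `smolt`: stage labels. Defaults follow the
#'   modelled designs (diel ZT5-ZT29 at 4 h, LL CT9-CT29, DD CT1-CT29; stages
#'   T1-T6).
#' @param n_replicates Replicates per timepoint/group (default 3 circadian,
#'   6 smolt/seawater, 2 atlas).
#' @param frac_rhythmic Fraction of genes given a planted cosine rhythm
#'   (circadian design).
#' @param amplitude_lognormal `c(mu, sigma)` of the log-normal distribution of
#'   planted cosine amplitudes, in log2-expression units (median 2 by default).
#' @param damping_per_tissue Named multipliers in `[0, 1]` applied to planted
#'   amplitudes under constant (LL/DD) conditions; default keeps rhythms in the
#'   optic tectum only.
#' @param n_archetypes Number of developmental archetype curves (fixed shapes
#'   over stages; default 5).
#' @param frac_regulated Fraction of genes given an archetype effect in the
#'   smolt design.
#' @param archetype_swing_log2 Peak-to-trough swing of archetype effects in
#'   log2 units.
#' @param frac_divergent_pairs Fraction of true pairs planted as divergent in
#'   the smolt/seawater designs (split evenly between "one copy regulated" and
#'   "different dynamics" modes).
#' @param sw_effect_log2fc `c(mu, sigma)` of the normal distribution of
#'   planted seawater-induction log2 fold changes.
#' @param frac_sw_responsive Fraction of genes planted as seawater-responsive.
#' @param nb_dispersion Negative-binomial dispersion of simulated counts
#'   (0 gives Poisson counts).
#' @param mean_log2_expression `c(mu, sigma)` of per-gene baseline log2 cpm.
#' @param n_background Number of unregulated background genes added to every
#'   expression matrix. They emulate the transcriptome context in which
#'   normalization and FDR control operate in a real experiment, where the
#'   focal gene family is a tiny minority; without them, planted induction of
#'   a large fraction of the (small) focal set would bias the scaling
#'   factors. Background genes carry baseline expression only and are named
#'   `bg####`.
#' @param library_size Centre of the per-sample library-size distribution;
#'   sizes are drawn log-uniformly within 2-fold of this value.
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(seed = 1L,
                       n_orthogroups = 50L,
                       species = list(
                         salmonids = c("ssal", "omyk", "salp"),
                         pike = "eluc",
                         outgroups = c("drer", "gacu", "hsap"),
                         focal = "ssal"
                       ),
                       p_loss_post_wgd = 0.2,
                       similarity_class_mix = c(early = 0.25, mid = 0.35, late = 0.40),
                       n_negative_controls = 0L,
                       design = c("atlas", "circadian", "smolt", "seawater"),
                       tissues = NULL,
                       timepoints = NULL,
                       n_replicates = NULL,
                       frac_rhythmic = 0.3,
                       amplitude_lognormal = c(mu = log(2), sigma = 0.25),
                       damping_per_tissue = c(OT = 0.8, SV = 0, gill = 0),
                       n_archetypes = 5L,
                       frac_regulated = 0.4,
                       archetype_swing_log2 = 2,
                       frac_divergent_pairs = 0.3,
                       sw_effect_log2fc = c(mu = 2, sigma = 0.5),
                       frac_sw_responsive = 0.3,
                       nb_dispersion = 0.05,
                       mean_log2_expression = c(mu = 5, sigma = 1.5),
                       n_background = 500L,
                       library_size = 1e6) {
  design <- match.arg(design)
  if (is.null(species$focal)) species$focal <- species$salmonids[1]
  if (length(species$salmonids %||% character(0)) < 2L) {
    stopf("species partition is missing group 'salmonids' (need >= 2 species)")
  }
  if (length(species$pike %||% character(0)) != 1L) {
    stopf("species partition is missing group 'pike' (need exactly 1 species)")
  }
  if (length(species$outgroups %||% character(0)) < 1L) {
    stopf("species partition is missing group 'outgroups' (need >= 1 species)")
  }
  check_prob <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0 | x > 1)) stopf("%s must lie in [0, 1]", nm)
  }
  check_prob(p_loss_post_wgd, "p_loss_post_wgd")
  check_prob(frac_rhythmic, "frac_rhythmic")
  check_prob(frac_regulated, "frac_regulated")
  check_prob(frac_divergent_pairs, "frac_divergent_pairs")
  check_prob(frac_sw_responsive, "frac_sw_responsive")
  check_prob(damping_per_tissue, "damping_per_tissue")
  if (abs(sum(similarity_class_mix) - 1) > 1e-8) {
    stopf("similarity_class_mix must sum to 1")
  }
  if (!all(c("early", "mid", "late") %in% names(similarity_class_mix))) {
    stopf("similarity_class_mix needs proportions named early, mid, late")
  }

  if (is.null(tissues)) {
    tissues <- switch(design,
      atlas = c(
        "brain", "gill", "liver", "gut", "heart", "muscle",
        "kidney", "spleen", "skin", "eye", "ovary"
      ),
      circadian = c("OT", "SV", "gill"),
      smolt = "gill",
      seawater = "gill"
    )
  }
  if (is.null(n_replicates)) {
    n_replicates <- switch(design, atlas = 2L, circadian = 3L, smolt = 6L, seawater = 6L)
  }
  if (n_replicates < 1L) stopf("n_replicates must be >= 1")
  if (is.null(timepoints)) {
    timepoints <- switch(design,
      circadian = list(
        diel = seq(5, 29, by = 4),
        LL = seq(9, 29, by = 4),
        DD = seq(1, 29, by = 4)
      ),
      smolt = paste0("T", 1:6),
      NULL
    )
  }
  if (design == "circadian") {
    miss <- setdiff(names(damping_per_tissue), tissues)
    if (length(setdiff(tissues, names(damping_per_tissue)))) {
      stopf("damping_per_tissue must name every circadian tissue")
    }
  }

  structure(
    list(
      seed = as.integer(seed), n_orthogroups = as.integer(n_orthogroups),
      species = species, p_loss_post_wgd = p_loss_post_wgd,
      similarity_class_mix = similarity_class_mix,
      n_negative_controls = as.integer(n_negative_controls),
      design = design, tissues = tissues, timepoints = timepoints,
      n_replicates = as.integer(n_replicates),
      frac_rhythmic = frac_rhythmic,
      amplitude_lognormal = amplitude_lognormal,
      damping_per_tissue = damping_per_tissue,
      n_archetypes = as.integer(n_archetypes),
      frac_regulated = frac_regulated,
      archetype_swing_log2 = archetype_swing_log2,
      frac_divergent_pairs = frac_divergent_pairs,
      sw_effect_log2fc = sw_effect_log2fc,
      frac_sw_responsive = frac_sw_responsive,
      nb_dispersion = nb_dispersion,
      mean_log2_expression = mean_log2_expression,
      n_background = as.integer(n_background),
      library_size = library_size
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> design=%s seed=%d orthogroups=%d (+%d negative controls) p_loss=%.2f\n",
    x$design, x$seed, x$n_orthogroups, x$n_negative_controls, x$p_loss_post_wgd
  ))
  invisible(x)
}
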