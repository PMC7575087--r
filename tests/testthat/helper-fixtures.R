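# Shared fixture builders; everything is generated in code at test time.

# A minimal taxon partition matching the generator's default species.
default_groups <- function() {
  taxon_groups(
    salmonids = c("ssal", "omyk", "salp"),
    pike = "eluc",
    outgroups = c("drer", "gacu", "hsap"),
    focal = "ssal"
  )
}

# A tiny hand-laid synteny map: one block pair with two 1-Mbp windows.
toy_synteny <- function(pct = c(96, 97)) {
  synteny_map(
    blocks = tibble::tibble(
      block_id = "b1", chrA = "ssa01", startA = 1L, endA = 2000000L,
      chrB = "ssa02", startB = 1L, endB = 2000000L
    ),
    windows = tibble::tibble(
      block_id = "b1", window_index = 1:2, pct_identity = pct
    )
  )
}

# Simulated study bundle shared by several test files.
quick_sim <- function(seed = 7, n = 30, design = "smolt", ...) {
  cfg <- sim_config(
    seed = seed, n_orthogroups = n, p_loss_post_wgd = 0.2,
    n_negative_controls = 5, design = design, ...
  )
  sim <- simulate_gene_trees(cfg)
  list(cfg = cfg, sim = sim, truth = sim$truth)
}

pair_key <- function(d) paste(d$gene1, d$gene2)

# Wrap a bare ape phylogeny (labels already in gene|species|chr:start-end
# form) as a gene_tree without a newick round trip.
as_gene_tree <- function(phy, og = "OGX") {
  structure(
    list(
      phylo = phy,
      leaves = ohnodiverge:::parse_leaf_labels(phy$tip.label),
      orthogroup_id = og
    ),
    class = "gene_tree"
  )
}

# TRUE per row when gene1's locus canonically precedes gene2's.
locus_before_vec <- function(p) {
  mapply(
    ohnodiverge:::locus_before,
    p$chr1, p$start1, p$chr2, p$start2
  )
}

# Pair table stripped of companion attributes, for whole-table comparisons.
strip_pairs <- function(p) {
  out <- as.data.frame(p)
  attr(out, "singletons") <- NULL
  attr(out, "ambiguous") <- NULL
  out
}
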