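groups <- default_groups()

make_tree <- function(newick, og = "OGX") parse_newick(newick, orthogroup_id = og)

# node index of the smallest clade containing a set of tip labels
mrca_node <- function(gt, labels) {
  ape::getMRCA(gt$phylo, match(labels, gt$phylo$tip.label))
}

test_that("salmonid-only monophyly follows the leaf species sets", {
  gt <- make_tree(
    "(((a|ssal|1:1-2,b|omyk|1:1-2),c|eluc|1:1-2),d|drer|1:1-2);"
  )
  salm <- mrca_node(gt, c("a|ssal|1:1-2", "b|omyk|1:1-2"))
  expect_true(is_salmonid_only_clade(gt, salm, groups))
  with_pike <- mrca_node(gt, c("a|ssal|1:1-2", "c|eluc|1:1-2"))
  expect_false(is_salmonid_only_clade(gt, with_pike, groups))

  intro <- make_tree(
    "(((a|ssal|1:1-2,z|drer|1:1-2),c|eluc|1:1-2),d|drer|2:1-2);"
  )
  bad <- mrca_node(intro, c("a|ssal|1:1-2", "z|drer|1:1-2"))
  expect_false(is_salmonid_only_clade(intro, bad, groups))
})

test_that("monophyly verdicts match an independent clade enumeration on random trees", {
  set.seed(101)
  for (rep in 1:100) {
    phy <- ape::rtree(12)
    sp <- sample(c("ssal", "omyk", "salp", "eluc", "drer", "hsap"), 12, TRUE)
    phy$tip.label <- sprintf("g%02d|%s|1:%d-%d", 1:12, sp, 1:12, 13:24)
    gt <- as_gene_tree(phy)
    parts <- ape::prop.part(gt$phylo)
    internal <- sort(unique(gt$phylo$edge[, 1]))
    for (k in seq_along(internal)) {
      tips <- parts[[k]] # prop.part lists clades in node order from the root
      oracle <- all(gt$leaves$species[
        match(gt$phylo$tip.label[tips], gt$leaves$label)
      ] %in% groups$salmonids)
      expect_identical(
        is_salmonid_only_clade(gt, internal[k], groups), oracle
      )
    }
  }
})

test_that("pike sister criterion distinguishes exact, mixed and absent sisters", {
  gt <- make_tree(
    "(((a|ssal|1:1-2,b|omyk|1:1-2),c|eluc|1:1-2),d|drer|1:1-2);"
  )
  salm <- mrca_node(gt, c("a|ssal|1:1-2", "b|omyk|1:1-2"))
  expect_true(sister_is_pike(gt, salm, groups))

  mixed <- make_tree(
    "(((a|ssal|1:1-2,b|omyk|1:1-2),(c|eluc|1:1-2,z|drer|1:1-2)),d|drer|2:1-2);"
  )
  salm_m <- mrca_node(mixed, c("a|ssal|1:1-2", "b|omyk|1:1-2"))
  expect_false(sister_is_pike(mixed, salm_m, groups))
  expect_true(sister_is_pike(mixed, salm_m, groups, mode = "contains"))

  wrong <- make_tree(
    "(((a|ssal|1:1-2,b|omyk|1:1-2),z|gacu|1:1-2),c|eluc|1:1-2);"
  )
  salm_w <- mrca_node(wrong, c("a|ssal|1:1-2", "b|omyk|1:1-2"))
  expect_false(sister_is_pike(wrong, salm_w, groups))

  root <- length(gt$phylo$tip.label) + 1L
  expect_error(sister_is_pike(gt, root, groups), "no sister")
})

test_that("conservation in another salmonid requires a mirrored pair by default", {
  mirrored <- make_tree(paste0(
    "((((a|ssal|1:1-2,t1|omyk|1:1-2),(b|ssal|2:1-2,t2|omyk|2:1-2)),",
    "p|eluc|1:1-2),o|drer|1:1-2);"
  ))
  clade <- mrca_node(mirrored, c("a|ssal|1:1-2", "b|ssal|2:1-2"))
  expect_true(conserved_in_other_salmonid(mirrored, clade, groups))

  focal_only <- make_tree(
    "(((a|ssal|1:1-2,b|ssal|2:1-2),p|eluc|1:1-2),o|drer|1:1-2);"
  )
  clade2 <- mrca_node(focal_only, c("a|ssal|1:1-2", "b|ssal|2:1-2"))
  expect_false(conserved_in_other_salmonid(focal_only, clade2, groups))

  one_trout <- make_tree(paste0(
    "((((a|ssal|1:1-2,t1|omyk|1:1-2),b|ssal|2:1-2),",
    "p|eluc|1:1-2),o|drer|1:1-2);"
  ))
  clade3 <- mrca_node(one_trout, c("a|ssal|1:1-2", "b|ssal|2:1-2"))
  expect_false(conserved_in_other_salmonid(one_trout, clade3, groups))

  two_same_side <- make_tree(paste0(
    "(((((a|ssal|1:1-2,t1|omyk|1:1-2),t2|omyk|2:1-2),b|ssal|2:1-2),",
    "p|eluc|1:1-2),o|drer|1:1-2);"
  ))
  clade4 <- mrca_node(two_same_side, c("a|ssal|1:1-2", "b|ssal|2:1-2"))
  expect_false(conserved_in_other_salmonid(two_same_side, clade4, groups))
  expect_true(conserved_in_other_salmonid(two_same_side, clade4, groups,
    mode = "any2"))
})

test_that("synteny support agrees with a brute-force scan over blocks", {
  set.seed(7)
  blocks <- tibble::tibble(
    block_id = sprintf("b%02d", 1:50),
    chrA = sprintf("ssa%02d", sample(1:20, 50, TRUE)),
    startA = sample(1:100, 50) * 100000L,
    chrB = sprintf("ssa%02d", 20L + sample(1:20, 50, TRUE)),
    startB = sample(1:100, 50) * 100000L
  )
  blocks$endA <- blocks$startA + 999999L
  blocks$endB <- blocks$startB + 999999L
  map <- synteny_map(blocks, tibble::tibble(
    block_id = blocks$block_id, window_index = 1L, pct_identity = 90
  ))
  for (rep in 1:200) {
    l1 <- list(chromosome = sprintf("ssa%02d", sample(1:40, 1)),
      start = sample(1:11000000, 1))
    l1$end <- l1$start + 1999L
    l2 <- list(chromosome = sprintf("ssa%02d", sample(1:40, 1)),
      start = sample(1:11000000, 1))
    l2$end <- l2$start + 1999L
    got <- synteny_supported(l1, l2, map)
    # independent linear scan
    hit <- NA_character_
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      inA <- function(l) l$chromosome == b$chrA && l$start >= b$startA && l$end <= b$endA
      inB <- function(l) l$chromosome == b$chrB && l$start >= b$startB && l$end <= b$endB
      if ((inA(l1) && inB(l2)) || (inA(l2) && inB(l1))) {
        hit <- b$block_id
        break
      }
    }
    expect_identical(got$supported, !is.na(hit))
    if (!is.na(hit)) expect_identical(got$block_id, hit)
  }
})

test_that("rediploidization classification uses the published identity bands", {
  expect_identical(classify_rediploidization(96), "late")
  expect_identical(classify_rediploidization(92), "mid")
  expect_identical(classify_rediploidization(87), "early")
  # mid closed on both ends
  expect_identical(classify_rediploidization(95), "mid")
  expect_identical(classify_rediploidization(90), "mid")
  expect_identical(classify_rediploidization(numeric(0)), "unknown")
  # configurable boundaries
  expect_identical(classify_rediploidization(92, boundaries = c(93, 97)), "early")
})

test_that("caller returns exactly the planted pairs and canonical records", {
  fx <- quick_sim(seed = 3, n = 40)
  syn <- simulate_synteny(fx$cfg, fx$truth)
  pairs <- suppressWarnings(call_ohnolog_pairs(fx$sim$trees, fx$sim$groups, syn))
  expect_setequal(pair_key(pairs), pair_key(fx$truth$true_pairs))
  # canonical ordering: gene1 locus sorts before gene2
  expect_true(all(locus_before_vec(pairs)))
  # deterministic output order
  expect_identical(pairs$orthogroup_id, sort(pairs$orthogroup_id))
  # classes recovered from the planted window bands
  truth_class <- fx$truth$true_pairs$class[
    match(pairs$orthogroup_id, fx$truth$true_pairs$orthogroup_id)
  ]
  expect_identical(pairs$rediploid_class, truth_class)
  # singletons account for every unpaired focal gene
  expect_setequal(
    ohno_singletons(pairs)$gene_id,
    fx$truth$singletons$gene_id
  )
})

test_that("every planted criterion violation is rejected for the recorded reason", {
  fx <- quick_sim(seed = 5, n = 20)
  syn <- simulate_synteny(fx$cfg, fx$truth)
  pairs <- suppressWarnings(call_ohnolog_pairs(fx$sim$trees, fx$sim$groups, syn))
  neg <- fx$truth$negative_pairs
  expect_gt(nrow(neg), 0)
  expect_length(intersect(pair_key(pairs), pair_key(neg)), 0)
  # the synteny decoy is specifically rejected for lack of a covering block
  sing <- ohno_singletons(pairs)
  decoys <- fx$truth$singletons$gene_id[
    fx$truth$singletons$reason == "neg_synteny_decoy"
  ]
  expect_true(all(
    sing$reason[sing$gene_id %in% decoys] == "no_synteny_support"
  ))
})

test_that("relaxed sister and conservation modes admit the matching negatives", {
  fx <- quick_sim(seed = 5, n = 20)
  syn <- simulate_synteny(fx$cfg, fx$truth)
  strict <- suppressWarnings(call_ohnolog_pairs(fx$sim$trees, fx$sim$groups, syn))
  relaxed <- suppressWarnings(call_ohnolog_pairs(fx$sim$trees, fx$sim$groups, syn,
    sister_mode = "contains", conservation_mode = "any2"))
  neg <- fx$truth$negative_pairs
  admitted <- intersect(pair_key(relaxed), pair_key(neg))
  admissible <- pair_key(neg[neg$type %in% c("neg_mixed_sister", "neg_no_mirror"), ])
  expect_setequal(admitted, admissible)
  expect_true(all(pair_key(strict) %in% pair_key(relaxed)))
})

test_that("caller is invariant to clade rotation and skips focal-free trees", {
  fx <- quick_sim(seed = 9, n = 15)
  syn <- simulate_synteny(fx$cfg, fx$truth)
  before <- suppressWarnings(call_ohnolog_pairs(fx$sim$trees, fx$sim$groups, syn))
  rotated <- lapply(fx$sim$trees, function(gt) {
    gt$phylo <- ape::rotateConstr(gt$phylo, rev(sort(gt$phylo$tip.label)))
    gt
  })
  after <- suppressWarnings(call_ohnolog_pairs(rotated, fx$sim$groups, syn))
  expect_identical(strip_pairs(before), strip_pairs(after))

  no_focal <- parse_newick("((a|omyk|1:1-2,b|salp|1:1-2),c|eluc|1:1-2);",
    orthogroup_id = "OGNF")
  expect_warning(
    out <- call_ohnolog_pairs(c(fx$sim$trees, list(OGNF = no_focal)),
      fx$sim$groups, syn),
    "no focal-species leaves"
  )
  expect_identical(nrow(out), nrow(before))
})

test_that("unrooted trees are rejected rather than auto-rooted", {
  gt <- parse_newick(
    "(a|ssal|1:1-2,b|ssal|2:1-2,p|eluc|1:1-2,o|drer|1:1-2);",
    orthogroup_id = "OGU"
  )
  expect_false(ape::is.rooted(gt$phylo))
  expect_error(
    call_ohnolog_pairs(list(gt), groups, toy_synteny()),
    "unrooted"
  )
})
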