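#' Define the taxon groups used by the ohnologue caller
#'
#' @param salmonids Character vector of salmonid species ids.
#' @param pike Single species id for the Northern pike lineage (the sister
#'   lineage that diverged just before the Ss4R duplication).
#' @param outgroups Character vector of non-salmonid, non-pike species ids.
#' @param focal Focal salmonid species (Atlantic salmon); must be one of
#'   `salmonids`.
#' @return A `taxon_groups` object.
#' @export
taxon_groups <- function(salmonids, pike, outgroups, focal = salmonids[1]) {
  if (length(pike) != 1L) stopf("species partition needs exactly one pike lineage")
  if (length(salmonids) < 2L) stopf("species partition needs >= 2 salmonids")
  if (length(outgroups) < 1L) stopf("species partition needs >= 1 outgroup")
  all_sp <- c(salmonids, pike, outgroups)
  if (anyDuplicated(all_sp)) {
    stopf("taxon groups must be disjoint; duplicated: %s",
      paste(unique(all_sp[duplicated(all_sp)]), collapse = ", "))
  }
  if (!focal %in% salmonids) stopf("focal species '%s' is not a salmonid", focal)
  structure(
    list(salmonids = salmonids, pike = pike, outgroups = outgroups, focal = focal),
    class = "taxon_groups"
  )
}

#' Read / write a species-group table
#'
#' The table has columns `species`, `group` (one of `salmonid`, `pike`,
#' `outgroup`) and `focal` (logical, TRUE for exactly one salmonid).
#'
#' @param path TSV path.
#' @return `read_species_groups()` returns a `taxon_groups` object;
#'   `write_species_groups()` invisibly returns `path`.
#' @export
read_species_groups <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("species", "group", "focal")
  if (!all(need %in% names(tab))) {
    stopf("species-group table must have columns %s", paste(need, collapse = ", "))
  }
  taxon_groups(
    salmonids = tab$species[tab$group == "salmonid"],
    pike = tab$species[tab$group == "pike"],
    outgroups = tab$species[tab$group == "outgroup"],
    focal = tab$species[tab$group == "salmonid" & tab$focal][1]
  )
}

#' @rdname read_species_groups
#' @param groups A `taxon_groups` object.
#' @export
write_species_groups <- function(groups, path) {
  tab <- tibble(
    species = c(groups$salmonids, groups$pike, groups$outgroups),
    group = c(
      rep("salmonid", length(groups$salmonids)), "pike",
      rep("outgroup", length(groups$outgroups))
    ),
    focal = c(groups$salmonids == groups$focal, FALSE,
      rep(FALSE, length(groups$outgroups)))
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

# ---- topology helpers ------------------------------------------------------

# Indices of the tip descendants of `node` (tips are their own descendants).
tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) {
    return(node)
  }
  tips <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- phy$edge[phy$edge[, 1] == cur, 2]
    tips <- c(tips, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(tips)
}

tree_root <- function(phy) {
  length(phy$tip.label) + 1L
}

node_parent <- function(phy, node) {
  hit <- phy$edge[phy$edge[, 2] == node, 1]
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

node_children <- function(phy, node) {
  phy$edge[phy$edge[, 1] == node, 2]
}

leaf_species <- function(tree, tips) {
  tree$leaves$species[match(tree$phylo$tip.label[tips], tree$leaves$label)]
}

# ---- the three tree-topology criteria --------------------------------------

#' Criterion (i): is the clade under a node salmonid-only?
#'
#' TRUE iff every leaf under `node` belongs to a salmonid species. This is the
#' first requirement for a clade to contain an Ss4R duplicate pair.
#'
#' @param tree A `gene_tree`.
#' @param node Node index (tip or internal, in \pkg{ape} numbering).
#' @param groups A `taxon_groups` object.
#' @return Logical scalar.
#' @export
is_salmonid_only_clade <- function(tree, node, groups) {
  sp <- leaf_species(tree, tips_under(tree$phylo, node))
  all(sp %in% groups$salmonids)
}

#' Criterion (ii): is the sister clade Northern pike?
#'
#' In `"exact"` mode the sister subtree's species set must equal `{pike}`;
#' in `"contains"` mode it suffices that pike is present in the sister.
#'
#' @inheritParams is_salmonid_only_clade
#' @param mode `"exact"` (default, strict reading) or `"contains"`.
#' @return Logical scalar; passing the root is an error (no sister defined).
#' @export
sister_is_pike <- function(tree, node, groups, mode = c("exact", "contains")) {
  mode <- match.arg(mode)
  phy <- tree$phylo
  if (node == tree_root(phy)) stopf("root has no sister clade")
  parent <- node_parent(phy, node)
  sibs <- setdiff(node_children(phy, parent), node)
  sib_tips <- unlist(lapply(sibs, tips_under, phy = phy))
  sp <- unique(leaf_species(tree, sib_tips))
  if (mode == "exact") identical(sort(sp), sort(groups$pike)) else groups$pike %in% sp
}

#' Criterion (iii): is the duplicate pair conserved in another salmonid?
#'
#' For a salmonid-only clade whose two children are the candidate duplicate
#' sub-clades, checks that at least one non-focal salmonid species retains the
#' duplication. In `"mirrored"` mode (default) the species must contribute a
#' leaf to each of the two sub-clades; in `"any2"` mode two leaves anywhere in
#' the clade suffice.
#'
#' @inheritParams is_salmonid_only_clade
#' @param node The clade node whose two children are the duplicate sub-clades.
#' @param mode `"mirrored"` (default) or `"any2"`.
#' @return Logical scalar.
#' @export
conserved_in_other_salmonid <- function(tree, node, groups,
                                        mode = c("mirrored", "any2")) {
  mode <- match.arg(mode)
  phy <- tree$phylo
  kids <- node_children(phy, node)
  others <- setdiff(groups$salmonids, groups$focal)
  if (mode == "any2") {
    sp <- leaf_species(tree, tips_under(phy, node))
    return(any(vapply(others, function(s) sum(sp == s) >= 2L, logical(1))))
  }
  if (length(kids) < 2L) {
    return(FALSE)
  }
  sp_by_kid <- lapply(kids, function(k) unique(leaf_species(tree, tips_under(phy, k))))
  any(vapply(others, function(s) {
    sum(vapply(sp_by_kid, function(x) s %in% x, logical(1))) >= 2L
  }, logical(1)))
}

# ---- synteny ----------------------------------------------------------------

#' Build a synteny map from block and window tables
#'
#' @param blocks Tibble with columns `block_id`, `chrA`, `startA`, `endA`,
#'   `chrB`, `startB`, `endB` (1-based inclusive coordinates).
#' @param windows Tibble with columns `block_id`, `window_index`,
#'   `pct_identity` (ordered 1-Mbp windows along the block).
#' @return A `synteny_map` object.
#' @export
synteny_map <- function(blocks, windows) {
  blocks <- as_tibble(blocks)
  windows <- as_tibble(windows)
  stopifnot(
    all(c("block_id", "chrA", "startA", "endA", "chrB", "startB", "endB") %in%
      names(blocks)),
    all(c("block_id", "window_index", "pct_identity") %in% names(windows))
  )
  if (any(blocks$startA > blocks$endA) || any(blocks$startB > blocks$endB)) {
    stopf("malformed block intervals (start > end)")
  }
  if (any(windows$pct_identity < 0 | windows$pct_identity > 100)) {
    stopf("pct_identity must lie in [0, 100]")
  }
  structure(list(blocks = blocks, windows = windows), class = "synteny_map")
}

#' Is a gene pair supported by an Ss4R collinear block?
#'
#' TRUE iff one gene lies inside a block's A interval and the other inside the
#' same block's B interval (either orientation). A gene "lies inside" an
#' interval when its own interval is contained in it (1-based inclusive).
#'
#' @param locus1,locus2 Lists (or one-row data frames) with `chromosome`,
#'   `start`, `end`.
#' @param map A `synteny_map`.
#' @return A list with `supported` (logical) and `block_id` (character or NA).
#' @export
synteny_supported <- function(locus1, locus2, map) {
  b <- map$blocks
  inA1 <- locus_in(locus1, b$chrA, b$startA, b$endA)
  inB1 <- locus_in(locus1, b$chrB, b$startB, b$endB)
  inA2 <- locus_in(locus2, b$chrA, b$startA, b$endA)
  inB2 <- locus_in(locus2, b$chrB, b$startB, b$endB)
  hit <- (inA1 & inB2) | (inB1 & inA2)
  if (any(hit)) {
    list(supported = TRUE, block_id = b$block_id[which(hit)[1]])
  } else {
    list(supported = FALSE, block_id = NA_character_)
  }
}

locus_in <- function(locus, chr, start, end) {
  locus$chromosome == chr & locus$start >= start & locus$end <= end
}

# ---- rediploidization classification ---------------------------------------

#' Classify rediploidization timing from windowed sequence similarity
#'
#' Residual sequence similarity between duplicated blocks reflects how early
#' recombination between the duplicated regions was blocked: late-rediploidized
#' regions still exceed 95% identity, early ones sit near 87%.
#'
#' @param pct_identity Numeric vector of window percent identities for the
#'   pair's supporting block.
#' @param boundaries Two class boundaries `c(early_mid, mid_late)`; the mid
#'   class is closed on both ends (`boundaries[1] <= m <= boundaries[2]`).
#' @return `"late"`, `"mid"`, `"early"`, or `"unknown"` when no windows are
#'   available.
#' @examples
#' classify_rediploidization(c(96, 97))  # "late"
#' classify_rediploidization(92)         # "mid"
#' classify_rediploidization(87)         # "early"
#' @export
classify_rediploidization <- function(pct_identity, boundaries = c(90, 95)) {
  pct_identity <- pct_identity[!is.na(pct_identity)]
  if (length(pct_identity) == 0L) {
    return("unknown")
  }
  m <- mean(pct_identity)
  if (m > boundaries[2]) {
    "late"
  } else if (m >= boundaries[1]) {
    "mid"
  } else {
    "early"
  }
}

# ---- the caller -------------------------------------------------------------

#' Call Ss4R ohnologue pairs from gene trees and synteny
#'
#' Applies the four-part definition of an Ss4R ohnologue pair to every gene
#' tree: (i) the two focal-species genes sit in a monophyletic clade containing
#' only salmonid genes, (ii) that clade's sister is Northern pike, (iii) the
#' duplication is conserved in at least one other salmonid, and finally the two
#' genes must fall in the two intervals of one Ss4R collinear block. Each
#' called pair is annotated with its block, the block's mean windowed percent
#' identity, and the rediploidization class.
#'
#' Focal genes that end up in no pair are reported as singletons (with the
#' reason they failed); salmonid clades carrying more than two focal genes are
#' reported as ambiguous rather than resolved by guessing.
#'
#' @param trees A list of `gene_tree` objects.
#' @param groups A `taxon_groups` object.
#' @param map A `synteny_map`.
#' @param sister_mode Passed to [sister_is_pike()].
#' @param conservation_mode Passed to [conserved_in_other_salmonid()].
#' @param boundaries Passed to [classify_rediploidization()].
#' @return A tibble of class `ohno_pairs`, one row per called pair, ordered by
#'   orthogroup then canonical gene1 locus, with columns `orthogroup_id`,
#'   `gene1`, `gene2`, `chr1`, `start1`, `chr2`, `start2`, `block_id`,
#'   `mean_pct_identity`, `rediploid_class`. Attributes `singletons` and
#'   `ambiguous` carry the companion tables (see [ohno_singletons()]).
#' @export
call_ohnolog_pairs <- function(trees, groups, map,
                               sister_mode = c("exact", "contains"),
                               conservation_mode = c("mirrored", "any2"),
                               boundaries = c(90, 95)) {
  sister_mode <- match.arg(sister_mode)
  conservation_mode <- match.arg(conservation_mode)
  stopifnot(inherits(groups, "taxon_groups"), inherits(map, "synteny_map"))

  pairs <- list()
  singles <- list()
  ambig <- list()

  for (tree in trees) {
    og <- tree$orthogroup_id %||% NA_character_
    if (!ape::is.rooted(tree$phylo)) {
      stopf("tree %s is unrooted; ohnologue calling requires explicit rooting", og)
    }
    focal_leaves <- tree$leaves[tree$leaves$species == groups$focal, ]
    if (nrow(focal_leaves) == 0L) {
      warnf("tree %s has no focal-species leaves; skipped", og)
      next
    }
    res <- call_pairs_one_tree(tree, groups, map, sister_mode,
      conservation_mode, boundaries)
    pairs[[length(pairs) + 1L]] <- res$pairs
    ambig[[length(ambig) + 1L]] <- res$ambiguous
    paired_genes <- if (nrow(res$pairs)) c(res$pairs$gene1, res$pairs$gene2) else character(0)
    amb_genes <- if (nrow(res$ambiguous)) res$ambiguous$gene_id else character(0)
    left <- focal_leaves[!focal_leaves$gene_id %in% c(paired_genes, amb_genes), ]
    if (nrow(left)) {
      singles[[length(singles) + 1L]] <- tibble(
        orthogroup_id = og,
        gene_id = left$gene_id,
        chromosome = left$chromosome,
        start = left$start,
        reason = res$reason
      )
    }
  }

  out <- bind_rows(pairs)
  if (nrow(out)) {
    out <- out[order(out$orthogroup_id, chr_rank(out$chr1), out$chr1, out$start1), ]
  }
  structure(
    as_tibble(out),
    singletons = bind_rows(singles),
    ambiguous = bind_rows(ambig),
    class = c("ohno_pairs", class(as_tibble(out)))
  )
}

# One tree: locate candidate salmonid-only clades with pike sister and apply
# the remaining criteria. Returns pairs, ambiguous genes and a failure reason.
call_pairs_one_tree <- function(tree, groups, map, sister_mode,
                                conservation_mode, boundaries) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  root <- tree_root(phy)
  internal <- setdiff(unique(phy$edge[, 1]), integer(0))

  empty_pairs <- tibble(
    orthogroup_id = character(0), gene1 = character(0), gene2 = character(0),
    chr1 = character(0), start1 = integer(0), chr2 = character(0),
    start2 = integer(0), block_id = character(0),
    mean_pct_identity = numeric(0), rediploid_class = character(0)
  )
  empty_amb <- tibble(orthogroup_id = character(0), gene_id = character(0))

  # candidate clades: salmonid-only, not the root, pike sister
  cand <- internal[vapply(internal, function(u) {
    u != root &&
      is_salmonid_only_clade(tree, u, groups) &&
      sister_is_pike(tree, u, groups, mode = sister_mode)
  }, logical(1))]
  # keep maximal candidates only (not nested inside another candidate)
  if (length(cand) > 1L) {
    tipsets <- lapply(cand, tips_under, phy = phy)
    keep <- vapply(seq_along(cand), function(i) {
      !any(vapply(seq_along(cand), function(j) {
        i != j && all(tipsets[[i]] %in% tipsets[[j]])
      }, logical(1)))
    }, logical(1))
    cand <- cand[keep]
  }

  reason <- if (length(cand) == 0L) "no_salmonid_clade_with_pike_sister" else "unpaired"
  pairs <- empty_pairs
  amb <- empty_amb

  for (u in cand) {
    tips <- tips_under(phy, u)
    sp <- leaf_species(tree, tips)
    focal_tips <- tips[sp == groups$focal]
    if (length(focal_tips) < 2L) {
      reason <- "single_focal_copy"
      next
    }
    if (length(focal_tips) > 2L) {
      lv <- tree$leaves[match(phy$tip.label[focal_tips], tree$leaves$label), ]
      amb <- bind_rows(amb, tibble(
        orthogroup_id = tree$orthogroup_id %||% NA_character_,
        gene_id = lv$gene_id
      ))
      next
    }
    kids <- node_children(phy, u)
    kid_tips <- lapply(kids, tips_under, phy = phy)
    split_ok <- length(kids) == 2L &&
      all(vapply(kid_tips, function(x) sum(x %in% focal_tips) == 1L, logical(1)))
    if (!split_ok) {
      reason <- "focal_copies_not_in_separate_subclades"
      next
    }
    if (!conserved_in_other_salmonid(tree, u, groups, mode = conservation_mode)) {
      reason <- "not_conserved_in_other_salmonid"
      next
    }
    lv <- tree$leaves[match(phy$tip.label[focal_tips], tree$leaves$label), ]
    syn <- synteny_supported(
      list(chromosome = lv$chromosome[1], start = lv$start[1], end = lv$end[1]),
      list(chromosome = lv$chromosome[2], start = lv$start[2], end = lv$end[2]),
      map
    )
    if (!syn$supported) {
      reason <- "no_synteny_support"
      next
    }
    # canonical ordering: numeric-aware chromosome, then start
    first_first <- locus_before(lv$chromosome[1], lv$start[1],
      lv$chromosome[2], lv$start[2])
    i1 <- if (first_first) 1L else 2L
    i2 <- 3L - i1
    wins <- map$windows$pct_identity[map$windows$block_id == syn$block_id]
    pairs <- bind_rows(pairs, tibble(
      orthogroup_id = tree$orthogroup_id %||% NA_character_,
      gene1 = lv$gene_id[i1], gene2 = lv$gene_id[i2],
      chr1 = lv$chromosome[i1], start1 = lv$start[i1],
      chr2 = lv$chromosome[i2], start2 = lv$start[i2],
      block_id = syn$block_id,
      mean_pct_identity = mean(wins),
      rediploid_class = classify_rediploidization(wins, boundaries)
    ))
  }
  list(pairs = pairs, ambiguous = amb, reason = reason)
}

#' Companion tables of an ohnologue-pair call
#'
#' @param pairs An `ohno_pairs` tibble from [call_ohnolog_pairs()].
#' @return `ohno_singletons()`: focal genes assigned to no pair, with the
#'   criterion they failed; `ohno_ambiguous()`: focal genes in clades with more
#'   than two focal copies (tandem duplicates inside the Ss4R clade), reported
#'   rather than resolved.
#' @export
ohno_singletons <- function(pairs) attr(pairs, "singletons")

#' @rdname ohno_singletons
#' @export
ohno_ambiguous <- function(pairs) attr(pairs, "ambiguous")
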