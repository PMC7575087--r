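#' Simulate gene trees with a salmonid-specific duplication node
#'
#' Generates one rooted gene tree per orthogroup. With probability
#' `1 - p_loss_post_wgd` the focal salmon retains both Ss4R copies: the two
#' copies sit in two sub-clades of a salmonid-only clade, mirrored in at least
#' one other salmonid, with Northern pike as the sister lineage and outgroups
#' outside. Otherwise one copy was lost: the tree carries a single focal gene
#' and is additionally labelled with a (randomly chosen) criterion its
#' topology violates (`loss_clean`, `criterion_i` intruder, `criterion_ii`
#' wrong sister). `n_negative_controls` extra orthogroups carry two focal
#' copies but violate exactly one calling criterion each, cycling through
#' intruder, wrong sister, mixed sister, unmirrored duplication, and synteny
#' decoy; these exercise the caller's precision.
#'
#' Focal genes are laid out on duplicated chromosome pairs in 1-Mbp slots so
#' that [simulate_synteny()] can emit covering collinear blocks; decoy genes
#' are placed on an unduplicated chromosome.
#'
#' @param config A [sim_config()].
#' @return A list with `trees` (named list of `gene_tree`), `truth` (a
#'   `sim_truth` list recording true pairs, singletons, per-criterion negative
#'   cases and the block layout) and `groups` (the `taxon_groups`).
#' @export
simulate_gene_trees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$species
  groups <- taxon_groups(sp$salmonids, sp$pike, sp$outgroups, sp$focal)
  n <- config$n_orthogroups
  n_neg <- config$n_negative_controls
  n_tot <- n + n_neg

  withr::with_seed(stream_seed(config$seed, 1L), {
    classes <- sample(c("early", "mid", "late"), n_tot,
      replace = TRUE, prob = config$similarity_class_mix[c("early", "mid", "late")])
    lost <- runif(n) < config$p_loss_post_wgd
    loss_type <- sample(c("loss_clean", "criterion_i", "criterion_ii"),
      n, replace = TRUE)
    neg_cycle <- c("neg_intruder", "neg_wrong_sister", "neg_mixed_sister",
      "neg_no_mirror", "neg_synteny_decoy")
    types <- c(
      ifelse(lost, loss_type, "pair"),
      if (n_neg > 0L) neg_cycle[(seq_len(n_neg) - 1L) %% length(neg_cycle) + 1L]
    )

    layout <- block_layout(n_tot, classes)

    trees <- vector("list", n_tot)
    pair_rows <- list()
    single_rows <- list()
    neg_rows <- list()
    og_rows <- list()
    for (i in seq_len(n_tot)) {
      og <- sprintf("OG%04d", i)
      built <- build_orthogroup_tree(og, types[i], layout[i, ], groups)
      trees[[i]] <- parse_newick(built$newick, orthogroup_id = og)
      og_rows[[i]] <- tibble(
        orthogroup_id = og, type = types[i],
        class = classes[i], block_id = layout$block_id[i]
      )
      if (!is.null(built$pair)) {
        pair_rows[[length(pair_rows) + 1L]] <-
          bind_cols(built$pair, tibble(class = classes[i]))
      }
      if (!is.null(built$singletons)) {
        single_rows[[length(single_rows) + 1L]] <- built$singletons
      }
      if (!is.null(built$negative)) {
        neg_rows[[length(neg_rows) + 1L]] <- built$negative
      }
    }
    names(trees) <- sprintf("OG%04d", seq_len(n_tot))

    truth <- structure(
      list(
        orthogroups = bind_rows(og_rows),
        true_pairs = bind_rows(pair_rows),
        singletons = bind_rows(single_rows),
        negative_pairs = bind_rows(neg_rows),
        blocks = attr(layout, "blocks"),
        groups = groups
      ),
      class = "sim_truth"
    )
    list(trees = trees, truth = truth, groups = groups)
  })
}

# Assign each orthogroup a 1-Mbp slot in a duplicated-block pair; blocks hold
# up to 5 orthogroups of a single rediploidization class. Chromosomes come in
# duplicated pairs (ssa<2b-1>, ssa<2b>).
block_layout <- function(n_tot, classes, per_block = 5L, gene_len = 2000L) {
  ord <- order(factor(classes, levels = c("early", "mid", "late")), seq_len(n_tot))
  slot <- integer(n_tot)
  block <- integer(n_tot)
  b <- 0L
  for (cl in c("early", "mid", "late")) {
    idx <- ord[classes[ord] == cl]
    if (!length(idx)) next
    for (k in seq_along(idx)) {
      if ((k - 1L) %% per_block == 0L) b <- b + 1L
      block[idx[k]] <- b
      slot[idx[k]] <- (k - 1L) %% per_block + 1L
    }
  }
  startA <- (slot - 1L) * 1000000L + 500001L
  out <- tibble(
    block_id = sprintf("b%02d", block),
    chrA = sprintf("ssa%02d", 2L * block - 1L),
    chrB = sprintf("ssa%02d", 2L * block),
    startA = startA, endA = startA + gene_len - 1L,
    startB = startA, endB = startA + gene_len - 1L
  )
  blocks <- out |>
    mutate(class = classes, block_num = block) |>
    group_by(.data$block_id, .data$chrA, .data$chrB) |>
    summarise(
      class = .data$class[1],
      n_slots = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      startA = 1L, endA = pmax(.data$n_slots, 1L) * 1000000L,
      startB = 1L, endB = .data$endA
    )
  attr(out, "blocks") <- blocks
  out
}

# Build one orthogroup's newick string plus its truth records.
build_orthogroup_tree <- function(og, type, slot, groups) {
  foc <- groups$focal
  other <- setdiff(groups$salmonids, foc)
  mirror_sp <- other[1]
  extra_sp <- if (length(other) > 1L) other[2] else NULL
  pike <- groups$pike
  outs <- groups$outgroups

  bl <- function() sprintf("%.4f", runif(1, 0.05, 0.3))
  leaf <- function(sp, copy, chr = "un", start = 1000L, end = 3000L) {
    sprintf("%s_%s_%s|%s|%s:%d-%d", og, sp, copy, sp, chr, start, end)
  }
  tip <- function(lab) sprintf("%s:%s", lab, bl())
  cl <- function(...) sprintf("(%s):%s", paste(..., sep = ","), bl())

  two_copy <- type %in% c("pair", "neg_intruder", "neg_wrong_sister",
    "neg_mixed_sister", "neg_no_mirror", "neg_synteny_decoy")

  decoy <- identical(type, "neg_synteny_decoy")
  focA <- leaf(foc, "a", slot$chrA, slot$startA, slot$endA)
  focB_chr <- if (decoy) "ssaU1" else slot$chrB
  focB <- leaf(foc, "b", focB_chr, slot$startB, slot$endB)

  # duplicate sub-clades; the mirroring salmonid appears in both
  sub_a <- cl(tip(focA), tip(leaf(mirror_sp, "a")))
  sub_b <- cl(tip(focB), tip(leaf(mirror_sp, "b")))
  if (!is.null(extra_sp) && runif(1) < 0.5) {
    sub_a <- cl(sub_a, tip(leaf(extra_sp, "a")))
  }

  out_tail <- function(core) {
    # ladder of outgroups; root children are (ladder, last outgroup)
    for (o in outs[-length(outs)]) core <- cl(core, tip(leaf(o, "x")))
    sprintf("(%s,%s);", core, tip(leaf(outs[length(outs)], "x")))
  }

  salm <- cl(sub_a, sub_b)
  newick <- switch(type,
    pair = ,
    neg_synteny_decoy = out_tail(cl(salm, tip(leaf(pike, "p")))),
    neg_intruder = {
      sub_a2 <- cl(cl(tip(focA), tip(leaf(outs[1], "i"))), tip(leaf(mirror_sp, "a")))
      out_tail(cl(cl(sub_a2, sub_b), tip(leaf(pike, "p"))))
    },
    neg_wrong_sister = {
      core <- cl(cl(salm, tip(leaf(outs[2] %||% outs[1], "s"))), tip(leaf(pike, "p")))
      sprintf("(%s,%s);", core, tip(leaf(outs[length(outs)], "x")))
    },
    neg_mixed_sister = {
      mixed <- cl(tip(leaf(pike, "p")), tip(leaf(outs[1], "m")))
      out_tail(cl(salm, mixed))
    },
    neg_no_mirror = {
      sub_a3 <- cl(cl(tip(focA), tip(leaf(mirror_sp, "a1"))), tip(leaf(mirror_sp, "a2")))
      out_tail(cl(cl(sub_a3, tip(focB)), tip(leaf(pike, "p"))))
    },
    loss_clean = out_tail(cl(cl(tip(focA), tip(leaf(mirror_sp, "a"))),
      tip(leaf(pike, "p")))),
    criterion_i = {
      salm1 <- cl(cl(tip(focA), tip(leaf(outs[1], "i"))), tip(leaf(mirror_sp, "a")))
      out_tail(cl(salm1, tip(leaf(pike, "p"))))
    },
    criterion_ii = {
      salm1 <- cl(tip(focA), tip(leaf(mirror_sp, "a")))
      core <- cl(cl(salm1, tip(leaf(outs[2] %||% outs[1], "s"))), tip(leaf(pike, "p")))
      sprintf("(%s,%s);", core, tip(leaf(outs[length(outs)], "x")))
    },
    stopf("unknown orthogroup type '%s'", type)
  )

  gene_a <- sprintf("%s_%s_a", og, foc)
  gene_b <- sprintf("%s_%s_b", og, foc)
  pair <- NULL
  singles <- NULL
  negative <- NULL
  if (identical(type, "pair")) {
    pair <- tibble(
      orthogroup_id = og,
      gene1 = gene_a, gene2 = gene_b,
      chr1 = slot$chrA, start1 = slot$startA, end1 = slot$endA,
      chr2 = slot$chrB, start2 = slot$startB, end2 = slot$endB,
      block_id = slot$block_id
    )
  } else if (two_copy) {
    negative <- tibble(orthogroup_id = og, gene1 = gene_a, gene2 = gene_b, type = type)
    singles <- tibble(
      orthogroup_id = og,
      gene_id = c(gene_a, gene_b),
      chromosome = c(slot$chrA, focB_chr),
      start = c(slot$startA, slot$startB),
      end = c(slot$endA, slot$endB),
      reason = type
    )
  } else {
    singles <- tibble(
      orthogroup_id = og, gene_id = gene_a,
      chromosome = slot$chrA, start = slot$startA, end = slot$endA,
      reason = type
    )
  }
  list(newick = newick, pair = pair, singletons = singles, negative = negative)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d orthogroups: %d true pairs, %d singleton genes, %d negative cases\n",
    nrow(x$orthogroups), nrow(x$true_pairs), nrow(x$singletons),
    nrow(x$negative_pairs)
  ))
  invisible(x)
}
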