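#' Parse a gene tree from a newick string
#'
#' Reads one rooted gene tree whose leaf labels carry the gene identity and
#' genomic locus under the scheme `gene|species|chr:start-end`
#' (e.g. `"clock1a|ssal|ssa01:500001-502000"`). The topology is read with
#' \pkg{ape}; leaf labels are decomposed into a locus table used by the
#' ohnologue caller.
#'
#' @param text A newick string (single tree, terminated by `;`).
#' @param orthogroup_id Optional orthogroup identifier attached to the tree.
#' @param leaf_label_scheme Currently only `"gene|species|chr:start-end"`.
#' @return A `gene_tree` object: a list with elements `phylo` (an
#'   [ape::read.tree()] phylogeny), `leaves` (a tibble with columns `label`,
#'   `gene_id`, `species`, `chromosome`, `start`, `end`) and `orthogroup_id`.
#' @examples
#' gt <- parse_newick("((a|ssal|1:10-20,b|ssal|11:10-20),c|eluc|2:5-9);")
#' gt$leaves
#' @export
parse_newick <- function(text, orthogroup_id = NA_character_,
                         leaf_label_scheme = "gene|species|chr:start-end") {
  if (!identical(leaf_label_scheme, "gene|species|chr:start-end")) {
    stopf("unsupported leaf label scheme: %s", leaf_label_scheme)
  }
  check_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = protect_label_colons(text)),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(phy)) stopf("malformed newick string")
  phy$tip.label <- gsub("@", ":", phy$tip.label, fixed = TRUE)
  leaves <- parse_leaf_labels(phy$tip.label)
  if (anyDuplicated(leaves$gene_id)) {
    stopf("duplicated gene ids within tree: %s",
      paste(unique(leaves$gene_id[duplicated(leaves$gene_id)]), collapse = ", "))
  }
  structure(
    list(phylo = phy, leaves = leaves, orthogroup_id = orthogroup_id),
    class = "gene_tree"
  )
}

# The locus colon inside leaf labels (gene|species|chr:start-end) collides
# with the newick branch-length separator; swap it for '@' around the
# low-level parser/writer. The pattern only matches a colon that follows a
# '|' segment and precedes a start-end coordinate pair, which a branch
# length never does.
protect_label_colons <- function(text) {
  gsub("\\|([^,():;|]+):([0-9]+)-([0-9]+)", "|\\1@\\2-\\3", text)
}

# Cheap structural pre-check so malformed input fails with a position.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stopf("unbalanced parenthesis at position %d", i)
    }
  }
  if (depth != 0L) {
    stopf("unbalanced parenthesis at position %d (%d unclosed)",
      nchar(text), depth)
  }
  if (!grepl(";\\s*$", text)) stopf("newick string must end with ';'")
  invisible(TRUE)
}

parse_leaf_labels <- function(labels) {
  pat <- "^([^|]+)\\|([^|]+)\\|([^:|]+):([0-9]+)-([0-9]+)$"
  ok <- grepl(pat, labels)
  if (any(!ok)) {
    stopf("leaf label '%s' does not match scheme gene|species|chr:start-end",
      labels[which(!ok)[1]])
  }
  tibble(
    label = labels,
    gene_id = sub(pat, "\\1", labels),
    species = sub(pat, "\\2", labels),
    chromosome = sub(pat, "\\3", labels),
    start = as.integer(sub(pat, "\\4", labels)),
    end = as.integer(sub(pat, "\\5", labels))
  )
}

#' Write a gene tree back to a newick string
#'
#' @param tree A `gene_tree` object.
#' @return A newick string; `parse_newick(write_newick(x))` preserves the
#'   topology and leaf labels of `x`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "gene_tree"))
  phy <- tree$phylo
  phy$tip.label <- gsub(":", "@", phy$tip.label, fixed = TRUE)
  gsub("@", ":", ape::write.tree(phy), fixed = TRUE)
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf(
    "<gene_tree> %s: %d leaves, %d species\n",
    x$orthogroup_id %||% "(unnamed)",
    nrow(x$leaves), length(unique(x$leaves$species))
  ))
  invisible(x)
}

#' Read a directory of newick gene trees
#'
#' One tree per `*.nwk` file; the file stem is used as the orthogroup id.
#'
#' @param dir Directory containing `*.nwk` files.
#' @return A named list of `gene_tree` objects, sorted by orthogroup id.
#' @export
read_gene_trees <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.nwk$", full.names = TRUE))
  if (length(files) == 0L) stopf("no .nwk files found under %s", dir)
  trees <- lapply(files, function(f) {
    parse_newick(readLines(f, warn = FALSE)[1],
      orthogroup_id = sub("\\.nwk$", "", basename(f)))
  })
  names(trees) <- vapply(trees, function(t) t$orthogroup_id, character(1))
  trees
}

#' Write gene trees as one newick file per orthogroup
#'
#' @param trees A list of `gene_tree` objects.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_gene_trees <- function(trees, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(trees, function(t) {
    path <- file.path(dir, paste0(t$orthogroup_id, ".nwk"))
    writeLines(write_newick(t), path)
    path
  }, character(1))
  invisible(paths)
}
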