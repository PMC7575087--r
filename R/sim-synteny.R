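#' Simulate Ss4R collinear blocks with windowed sequence similarity
#'
#' Emits the duplicated-block table implied by the gene-tree layout plus
#' 1-Mbp window percent identities drawn inside each block's assigned
#' rediploidization band: late `(95.5, 99)` so all windows exceed 95%, mid
#' `(90.2, 94.8)`, early `(85.5, 89)` centred near 87%. Every true pair lies
#' inside its block's two intervals; synteny-decoy genes sit on an
#' unduplicated chromosome covered by no block.
#'
#' @param config A [sim_config()].
#' @param truth The `sim_truth` from [simulate_gene_trees()].
#' @return A `synteny_map` (see [synteny_map()]); the window table has one row
#'   per 1-Mbp window.
#' @export
simulate_synteny <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  blocks <- truth$blocks
  withr::with_seed(stream_seed(config$seed, 2L), {
    windows <- map_dfr(seq_len(nrow(blocks)), function(i) {
      nw <- as.integer(blocks$endA[i] / 1e6)
      band <- switch(blocks$class[i],
        late = c(95.5, 99),
        mid = c(90.2, 94.8),
        early = c(85.5, 89)
      )
      tibble(
        block_id = blocks$block_id[i],
        window_index = seq_len(nw),
        pct_identity = round(runif(nw, band[1], band[2]), 3)
      )
    })
    synteny_map(
      blocks = blocks[, c("block_id", "chrA", "startA", "endA",
        "chrB", "startB", "endB")],
      windows = windows
    )
  })
}

#' Read / write synteny block and window tables
#'
#' @param blocks_path,windows_path TSV paths for the block table
#'   (`block_id, chrA, startA, endA, chrB, startB, endB`) and window table
#'   (`block_id, window_index, pct_identity`).
#' @return `read_synteny()` returns a `synteny_map`.
#' @export
read_synteny <- function(blocks_path, windows_path) {
  synteny_map(
    readr::read_tsv(blocks_path, show_col_types = FALSE, comment = "#"),
    readr::read_tsv(windows_path, show_col_types = FALSE, comment = "#")
  )
}

#' @rdname read_synteny
#' @param map A `synteny_map`.
#' @export
write_synteny <- function(map, blocks_path, windows_path) {
  readr::write_tsv(map$blocks, blocks_path)
  readr::write_tsv(map$windows, windows_path)
  invisible(c(blocks_path, windows_path))
}
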