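#' Worked-example contingency tables
#'
#' Small tables used throughout the documentation and tests:
#'
#' * `three_items` — 130 respondents on three binary items `a`, `b`, `c`;
#'   frequencies `(20, 15, 10, 15, 0, 15, 25, 30)` over patterns
#'   `000 .. 111` (the pattern `100` is unobserved).
#' * `two_cell` — an extreme 3-item table with only two observed patterns,
#'   `n_100 = n_110 = 65` (`N = 130`); triggers the second-order estimation
#'   problem under MEL.
#' * `single_cell_2x2` — a 2x2 table with a single observation in cell `01`;
#'   triggers the first-order (empty-set) problem for a margin-shift model.
#' * `diagonal_2x2` — 2x2 table `n = (1, 0, 0, 1)`; first-order problem
#'   absent, second-order present for the margin-shift model.
#' * `perfect_guttman` — two items, `n = (30, 0, 30, 30)`; the empty
#'   Guttman-error cell forces the sample `H` coefficients to 1 and makes
#'   any smaller `H` benchmark infeasible under MEL.
#'
#' @return named list of [sparse_table()] objects.
#' @export
example_tables <- function() {
  b3 <- rep(2L, 3)
  list(
    three_items = sparse_table(
      index_to_pattern(c(0, 1, 2, 3, 5, 6, 7), b3),
      counts = c(20, 15, 10, 15, 15, 25, 30), cats = b3),
    two_cell = sparse_table(
      index_to_pattern(c(4, 6), b3), counts = c(65, 65), cats = b3),
    single_cell_2x2 = sparse_table(
      matrix(c(0L, 1L), 1, 2), counts = 1, cats = c(2L, 2L)),
    diagonal_2x2 = sparse_table(
      rbind(c(0L, 0L), c(1L, 1L)), counts = c(1, 1), cats = c(2L, 2L)),
    perfect_guttman = sparse_table(
      rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L)), counts = c(30, 30, 30),
      cats = c(2L, 2L)))
}

#' Write the example tables as frequency-table fixtures
#'
#' Emits each table of [example_tables()] as a `pattern`/`count` TSV plus a
#' JSON manifest describing the catalog.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_example_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- example_tables()
  manifest <- lapply(names(tabs), function(nm) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    write_freq_table(tabs[[nm]], f)
    list(name = nm, file = basename(f), J = tabs[[nm]]$J,
         N = tabs[[nm]]$N, support_cells = nrow(tabs[[nm]]$patterns))
  })
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}
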