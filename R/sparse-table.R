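#' Lexicographic cell index of response patterns
#'
#' Converts response patterns of `J` categorical variables (scores `0 ..
#' cats[j] - 1`) to their 0-based rank in the lexicographic vectorization of
#' the contingency table, with the *last* variable's score varying fastest.
#' For three binary variables the table vector is therefore ordered
#' `000, 001, 010, 011, 100, 101, 110, 111`.
#'
#' @param patterns integer vector (one pattern) or matrix (one pattern per
#'   row) of scores.
#' @param cats integer vector of per-variable category counts `c_j`; variable
#'   `j` takes scores in `0 .. cats[j] - 1`.  A scalar is recycled to `J`
#'   variables where `J` is taken from `patterns`.
#' @return numeric vector of 0-based cell indices.  Indices are returned as
#'   doubles because the full table length `prod(cats)` easily exceeds
#'   `.Machine$integer.max`; they are exact as long as `prod(cats) < 2^53`.
#' @seealso [index_to_pattern()] for the inverse.
#' @examples
#' pattern_index(c(0, 1, 1), c(2, 2, 2))  # 3
#' pattern_index(rbind(c(0, 0, 0), c(1, 1, 0)), 2)
#' @export
pattern_index <- function(patterns, cats) {
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1L)
  J <- ncol(patterns)
  cats <- check_cats(cats, J)
  check_patterns(patterns, cats)
  ## place value of variable j is prod(cats[(j+1):J])
  place <- rev(cumprod(rev(c(cats[-1L], 1))))
  as.numeric(patterns %*% place)
}

#' Response pattern of a lexicographic cell index
#'
#' Inverse of [pattern_index()]: recovers the score pattern whose rank in the
#' last-variable-fastest lexicographic order is `index` (0-based).
#'
#' @param index numeric vector of 0-based cell indices.
#' @param cats integer vector of per-variable category counts.
#' @return integer matrix with one pattern per row.
#' @export
index_to_pattern <- function(index, cats) {
  cats <- as.integer(cats)
  J <- length(cats)
  if (any(index < 0) || any(index >= prod(cats)))
    stop("cell index out of range for the given category counts", call. = FALSE)
  out <- matrix(0L, length(index), J)
  rem <- as.numeric(index)
  for (j in J:1) {
    out[, j] <- as.integer(rem %% cats[j])
    rem <- (rem - out[, j]) / cats[j]
  }
  out
}

check_cats <- function(cats, J) {
  cats <- as.integer(cats)
  if (length(cats) == 1L) cats <- rep(cats, J)
  if (length(cats) != J || any(cats < 2L))
    stop("`cats` must give a category count >= 2 for each of the ", J,
         " variables", call. = FALSE)
  cats
}

check_patterns <- function(patterns, cats) {
  for (j in seq_along(cats)) {
    pj <- patterns[, j]
    if (any(pj != floor(pj)) || any(pj < 0L) || any(pj >= cats[j]))
      stop("score out of range for variable ", j,
           " (scores must be integers in 0..", cats[j] - 1L, ")",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Sparse contingency table
#'
#' Stores a `J`-variate contingency table as its *support*: the list of
#' response patterns with positive observed count, plus (optionally) cells
#' that were added with count zero by support augmentation.  The full table
#' of `prod(cats)` cells is never materialized, so tables on, say, 40 binary
#' items (`2^40` cells) are representable as long as the number of distinct
#' observed patterns is modest.
#'
#' Support cells are kept in ascending lexicographic index order (last
#' variable fastest), so weight vectors aligned with a table's support are
#' reproducible.
#'
#' @param x either an integer matrix of raw response patterns (one respondent
#'   per row, merged by summing duplicate rows), or a matrix of *distinct*
#'   patterns combined with `counts`.
#' @param counts optional nonnegative integer vector of per-pattern counts;
#'   if omitted every row of `x` counts as one respondent.  Zero counts are
#'   only allowed for cells flagged in `augmented`.
#' @param cats per-variable category counts; defaults to `max(score) + 1`
#'   per variable (at least 2).
#' @param augmented optional logical vector marking cells included with zero
#'   observed count (support augmentation).
#' @return an object of class `sparse_table` with components `J`, `cats`,
#'   `patterns` (support matrix, one cell per row), `counts`, `N`,
#'   `augmented` and `index` (lexicographic cell indices).
#' @examples
#' ## Respondent rows: three binary items
#' x <- rbind(c(0, 1, 1), c(0, 1, 1), c(1, 1, 0))
#' sparse_table(x)
#'
#' ## Pattern + count form
#' sparse_table(rbind(c(0, 0), c(1, 1)), counts = c(3, 2))
#' @export
sparse_table <- function(x, counts = NULL, cats = NULL, augmented = NULL) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty table: no response patterns given", call. = FALSE)
  storage.mode(x) <- "integer"
  J <- ncol(x)
  if (is.null(cats)) cats <- pmax(apply(x, 2L, max) + 1L, 2L)
  cats <- check_cats(cats, J)
  check_patterns(x, cats)

  if (is.null(counts)) {
    counts <- rep(1, nrow(x))
    if (is.null(augmented)) augmented <- rep(FALSE, nrow(x))
  } else {
    counts <- as.numeric(counts)
    if (length(counts) != nrow(x))
      stop("`counts` must have one entry per pattern row", call. = FALSE)
    if (any(counts < 0) || any(counts != floor(counts)))
      stop("counts must be nonnegative integers", call. = FALSE)
    if (is.null(augmented)) augmented <- counts == 0
  }
  augmented <- as.logical(augmented)

  idx <- pattern_index(x, cats)
  ## merge duplicate patterns
  o <- order(idx)
  idx <- idx[o]; x <- x[o, , drop = FALSE]
  counts <- counts[o]; augmented <- augmented[o]
  grp <- cumsum(!duplicated(idx))
  counts <- as.numeric(tapply(counts, grp, sum))
  augmented <- as.logical(tapply(augmented, grp, all))
  keep <- !duplicated(idx)
  x <- x[keep, , drop = FALSE]
  idx <- idx[keep]

  if (any(counts == 0 & !augmented))
    stop("zero-count cells are only allowed when flagged as augmented",
         call. = FALSE)
  N <- sum(counts)
  if (N <= 0) stop("table has total count zero", call. = FALSE)

  structure(
    list(J = J, cats = cats, patterns = x, counts = counts, N = N,
         augmented = augmented, index = idx),
    class = "sparse_table")
}

#' @export
print.sparse_table <- function(x, max_rows = 20L, ...) {
  cat(sprintf("Sparse %d-way contingency table (%s cells total)\n",
              x$J, format(prod(x$cats), big.mark = ",")))
  cat(sprintf("  N = %g respondents over %d support cells (%d augmented)\n",
              x$N, nrow(x$patterns), sum(x$augmented)))
  df <- as.data.frame(x)
  if (nrow(df) > max_rows) {
    print(utils::head(df, max_rows))
    cat("  ... ", nrow(df) - max_rows, " more cells\n", sep = "")
  } else print(df)
  invisible(x)
}

#' @export
as.data.frame.sparse_table <- function(x, ...) {
  data.frame(pattern = pattern_to_string(x$patterns, x$cats),
             count = x$counts,
             augmented = x$augmented,
             stringsAsFactors = FALSE)
}

#' Pattern string codec
#'
#' Patterns are written as plain digit strings (`"011"`) when every variable
#' has single-digit categories, and comma-separated scores otherwise.
#'
#' @param patterns pattern matrix (one per row).
#' @param cats per-variable category counts.
#' @return character vector of pattern strings.
#' @export
pattern_to_string <- function(patterns, cats) {
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1L)
  if (all(cats <= 10L)) apply(patterns, 1L, paste0, collapse = "")
  else apply(patterns, 1L, paste0, collapse = ",")
}

#' @rdname pattern_to_string
#' @param strings character vector of pattern strings.
#' @param J number of variables (used to validate digit strings).
#' @export
string_to_pattern <- function(strings, J = NULL) {
  parse1 <- function(s) {
    if (grepl(",", s, fixed = TRUE)) as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
    else as.integer(strsplit(s, "", fixed = TRUE)[[1L]])
  }
  out <- lapply(strings, parse1)
  len <- lengths(out)
  if (any(len != len[1L]) || (!is.null(J) && len[1L] != J))
    stop("pattern strings have inconsistent length", call. = FALSE)
  if (any(vapply(out, anyNA, logical(1L))))
    stop("malformed pattern string", call. = FALSE)
  do.call(rbind, out)
}

#' Marginal-cell value over a support
#'
#' Sums a weight vector aligned with a table's support over the cells whose
#' pattern matches a marginal cell, i.e. agrees with `values` on the
#' variables in `variables`.  With the observed counts as weights this is the
#' observed marginal frequency (one entry of A'n); with expected frequencies
#' it is the corresponding model margin.
#'
#' @param x a [sparse_table()].
#' @param variables integer vector of variable indices (1-based, distinct).
#' @param values integer vector of fixed scores for those variables.
#' @param weights optional numeric vector aligned with the support; defaults
#'   to the observed counts.
#' @return a single number.
#' @examples
#' tab <- example_tables()$three_items
#' margin_value(tab, 1, 1)        # m^a_1 = 70
#' margin_value(tab, c(1, 3), c(0, 1))  # m^{ac}_{01} = 30
#' @export
margin_value <- function(x, variables, values, weights = NULL) {
  stopifnot(inherits(x, "sparse_table"))
  if (is.null(weights)) weights <- x$counts
  if (length(weights) != nrow(x$patterns))
    stop("`weights` must align with the support (", nrow(x$patterns),
         " cells)", call. = FALSE)
  variables <- as.integer(variables)
  if (anyDuplicated(variables) || any(variables < 1L) || any(variables > x$J))
    stop("marginal-cell variable index out of range", call. = FALSE)
  sel <- margin_mask(x$patterns, variables, values)
  sum(weights[sel])
}

## logical mask of support cells contributing to a marginal cell
margin_mask <- function(patterns, variables, values) {
  sel <- rep(TRUE, nrow(patterns))
  for (k in seq_along(variables))
    sel <- sel & (patterns[, variables[k]] == values[k])
  sel
}

#' Dense table vector
#'
#' Expands a sparse table to the full vector of `prod(cats)` cell counts in
#' lexicographic order.  Refuses to materialize tables above `cap` cells,
#' since only ML estimation ever needs the dense representation.
#'
#' @param x a [sparse_table()].
#' @param cap maximum permitted number of cells (default `1e7`).
#' @return numeric vector of length `prod(x$cats)`.
#' @export
as_dense <- function(x, cap = 1e7) {
  stopifnot(inherits(x, "sparse_table"))
  L <- prod(x$cats)
  if (L > cap)
    stop("refusing to materialize a table with ", format(L, big.mark = ","),
         " cells (cap = ", format(cap, big.mark = ","),
         "); use MEL or MAEL estimation instead", call. = FALSE)
  n <- numeric(L)
  n[x$index + 1] <- x$counts
  n
}

## all-cells sparse_table for ML estimation (guarded by cap)
full_support_table <- function(x, cap = 1e7) {
  L <- prod(x$cats)
  if (L > cap)
    stop("ML estimation needs the full ", format(L, big.mark = ","),
         "-cell table, above the materialization cap (",
         format(cap, big.mark = ","), "); use MEL or MAEL", call. = FALSE)
  pat <- index_to_pattern(seq_len(L) - 1, x$cats)
  cnt <- numeric(L)
  cnt[x$index + 1] <- x$counts
  sparse_table(pat, counts = cnt, cats = x$cats, augmented = cnt == 0)
}

#' Read and write frequency-table files
#'
#' The frequency-table format is a two-column TSV with header `pattern`,
#' `count`; patterns use the codec of [pattern_to_string()].  Observation
#' files are CSVs with one row per respondent, one integer column per item
#' and a header row of item names.
#'
#' @param file path to the file.
#' @param cats optional per-variable category counts (defaults to scores seen
#'   in the file).
#' @return a [sparse_table()].
#' @export
read_freq_table <- function(file, cats = NULL) {
  df <- tryCatch(
    utils::read.delim(file, colClasses = c("character", "numeric")),
    error = function(e) stop("cannot parse frequency table '", file, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("empty frequency table: ", file, call. = FALSE)
  if (!all(c("pattern", "count") %in% names(df)))
    stop("frequency table must have columns 'pattern' and 'count' (",
         file, ")", call. = FALSE)
  pat <- tryCatch(string_to_pattern(df$pattern),
                  error = function(e) stop("malformed pattern in '", file,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  sparse_table(pat, counts = df$count, cats = cats)
}

#' @rdname read_freq_table
#' @param x a [sparse_table()] to write.
#' @export
write_freq_table <- function(x, file) {
  stopifnot(inherits(x, "sparse_table"))
  df <- data.frame(pattern = pattern_to_string(x$patterns, x$cats),
                   count = x$counts)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname read_freq_table
#' @export
read_responses <- function(file, cats = NULL) {
  df <- tryCatch(utils::read.csv(file),
                 error = function(e) stop("cannot parse observation file '",
                                          file, "': ", conditionMessage(e),
                                          call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("empty observation file: ", file, call. = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || any(is.na(m)))
    stop("observation file must be all-integer item scores: ", file,
         call. = FALSE)
  sparse_table(m, cats = cats)
}
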