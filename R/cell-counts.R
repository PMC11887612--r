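#' Eight-cell outcome count table
#'
#' Constructs the fundamental data object of the model: for one binary
#' outcome, the count of cases \code{r} and births \code{n} in each of the
#' eight cells defined by race (\code{x}: 1 = non-Black, 2 = Black),
#' prepartum BMI class (\code{m1}: 1 = optimal, 2 = non-optimal) and adjusted
#' GWG class (\code{m2}: 1 = optimal, 2 = non-optimal).
#'
#' @param x,m1,m2 integer vectors of cell indices, each element in \{1, 2\}.
#' @param r case counts, one per cell, with \code{0 <= r <= n}.
#' @param n birth counts, one per cell.
#' @param outcome single character label for the outcome.
#' @return A data frame of class \code{"cell_counts"} with exactly eight rows
#'   (one per cell, zero-filled for combinations not supplied) and columns
#'   \code{x}, \code{m1}, \code{m2}, \code{r}, \code{n}. The outcome label is
#'   stored in attribute \code{"outcome"}.
#' @examples
#' cc <- cell_counts(x = c(1, 2), m1 = c(1, 1), m2 = c(1, 1),
#'                   r = c(10, 30), n = c(1000, 1000), outcome = "cesarean")
#' cc
#' @export
cell_counts <- function(x, m1, m2, r, n, outcome = "outcome") {
  len <- length(x)
  if (!all(lengths(list(m1, m2, r, n)) == len))
    stop("x, m1, m2, r, n must have equal length")
  if (!all(x %in% 1:2 & m1 %in% 1:2 & m2 %in% 1:2))
    stop("cell indices x, m1, m2 must all be 1 or 2")
  if (anyNA(r) || anyNA(n) || any(r < 0) || any(n < 0) || any(r > n))
    stop("case counts must satisfy 0 <= r <= n in every cell")
  full <- expand.grid(m2 = 1:2, m1 = 1:2, x = 1:2)[, c("x", "m1", "m2")]
  key_in <- paste(x, m1, m2)
  if (anyDuplicated(key_in))
    stop("duplicate cells supplied: ", paste(unique(key_in[duplicated(key_in)]), collapse = "; "))
  idx <- match(paste(full$x, full$m1, full$m2), key_in)
  full$r <- ifelse(is.na(idx), 0, r[idx])
  full$n <- ifelse(is.na(idx), 0, n[idx])
  rownames(full) <- NULL
  structure(full, outcome = as.character(outcome)[1L],
            class = c("cell_counts", "data.frame"))
}

#' @export
print.cell_counts <- function(x, ...) {
  cat("Cell counts for outcome:", attr(x, "outcome"), "\n")
  cat(sprintf("  total births %s, total cases %s\n",
              format(sum(x$n), big.mark = ","), format(sum(x$r), big.mark = ",")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# Row lookup helper: counts for one cell.
cell_row <- function(cells, x, m1, m2) {
  cells[cells$x == x & cells$m1 == m1 & cells$m2 == m2, , drop = FALSE]
}

#' Read cell-count tables from CSV
#'
#' Reads a pre-aggregated count table with columns \code{outcome}, \code{x},
#' \code{m1}, \code{m2}, \code{r}, \code{n}, bypassing the record-level stage.
#'
#' @param path path to a CSV file.
#' @return A named list of \code{\link{cell_counts}} objects, one per outcome.
#' @export
read_cell_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("outcome", "x", "m1", "m2", "r", "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cell-count file is missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$outcome), function(d)
    cell_counts(d$x, d$m1, d$m2, d$r, d$n, outcome = d$outcome[1L]))
  out[unique(df$outcome)]
}

#' Write cell-count tables to CSV
#'
#' @param cells a \code{cell_counts} object or list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cell_counts <- function(cells, path) {
  if (inherits(cells, "cell_counts")) cells <- list(cells)
  df <- do.call(rbind, lapply(cells, function(cc)
    cbind(outcome = attr(cc, "outcome"), as.data.frame(cc))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Joint mediator prevalence table
#'
#' The percent probability of each of the four (BMI class, GWG class)
#' combinations, by race. Either computed from an aggregated
#' \code{\link{cell_counts}} table or constructed directly from percentages.
#'
#' @param x a \code{cell_counts} object, or a numeric matrix/vector of
#'   percentages: 2 races (rows, non-Black then Black) by 4 mediator cells
#'   (columns, in order (m1, m2) = (1,1), (2,1), (1,2), (2,2)).
#' @param ... passed to methods.
#' @return A 2 x 4 matrix of class \code{"prevalence_table"}; each row sums
#'   to 100.
#' @details When constructed from percentages, each row is rescaled to sum
#'   exactly to 100 so that published, rounded columns (which can sum to
#'   99.9 or 100.1) remain usable; rescaling beyond 0.5% is an error.
#' @export
prevalence_table <- function(x, ...) UseMethod("prevalence_table")

#' @rdname prevalence_table
#' @export
prevalence_table.cell_counts <- function(x, ...) {
  n_race <- tapply(x$n, x$x, sum)
  if (any(n_race == 0)) stop("race with zero births: cannot form prevalence table")
  pct <- matrix(0, 2, 4)
  ord <- cell_order()
  for (i in 1:2) for (j in 1:4) {
    nij <- cell_row(x, i, ord$m1[j], ord$m2[j])$n
    pct[i, j] <- 100 * nij / n_race[[as.character(i)]]
  }
  new_prevalence_table(pct)
}

#' @rdname prevalence_table
#' @export
prevalence_table.default <- function(x, ...) {
  pct <- matrix(as.numeric(x), nrow = 2, byrow = FALSE)
  if (!identical(dim(pct), c(2L, 4L)))
    stop("expected 2 x 4 matrix of percentages (races by mediator cells)")
  rs <- rowSums(pct)
  if (any(abs(rs - 100) > 0.5))
    stop("each race's four percentages must sum to 100 (got ",
         paste(format(rs), collapse = ", "), ")")
  new_prevalence_table(100 * pct / rs)
}

# canonical cell ordering for the four mediator combinations
cell_order <- function() list(m1 = c(1L, 2L, 1L, 2L), m2 = c(1L, 1L, 2L, 2L))

new_prevalence_table <- function(pct) {
  stopifnot(all(abs(rowSums(pct) - 100) < 1e-9 * 100))
  dimnames(pct) <- list(race = c("non_black", "black"),
                        cell = c("opt_opt", "nonopt_opt", "opt_nonopt", "nonopt_nonopt"))
  structure(pct, class = "prevalence_table")
}

#' @export
print.prevalence_table <- function(x, digits = 1, ...) {
  cat("Joint prevalence of mediator combinations (% within race)\n")
  lab <- c("BMI optimal,     GWG optimal    ",
           "BMI non-optimal, GWG optimal    ",
           "BMI optimal,     GWG non-optimal",
           "BMI non-optimal, GWG non-optimal")
  for (j in 1:4)
    cat(sprintf("  %s  non-Black %5.*f   Black %5.*f\n",
                lab[j], digits, x[1, j], digits, x[2, j]))
  invisible(x)
}

# prevalence fractions (summing to 1) for one race, in cell_order()
prevalence_fractions <- function(prev, race) as.numeric(prev[race, ]) / 100

#' Reference joint mediator prevalence, US singleton births 2016-2021
#'
#' The joint distribution of optimal/non-optimal prepartum BMI and 40-week
#' adjusted GWG among non-Black and Black mothers, as estimated from national
#' vital-statistics natality records of singleton births (17.7 million
#' records after missingness deletions). Black mothers are more likely to
#' have both mediators non-optimal (51.3% vs 41.7%) and less likely to have
#' both optimal (9.7% vs 15.1%).
#'
#' @return A \code{\link{prevalence_table}}.
#' @export
reference_prevalence <- function() {
  prevalence_table(matrix(c(15.1, 14.0, 29.2, 41.7,
                            9.7, 14.7, 24.2, 51.3), nrow = 2, byrow = TRUE))
}

#' Write a prevalence table as TSV
#'
#' @param prev a \code{prevalence_table}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_prevalence_tsv <- function(prev, path) {
  ord <- cell_order()
  df <- data.frame(m1 = ord$m1, m2 = ord$m2,
                   non_black = as.numeric(prev[1, ]),
                   black = as.numeric(prev[2, ]))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
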