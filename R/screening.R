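#' Pearson correlation matrix with exact two-tailed p-values
#'
#' Pairwise Pearson R over complete rows, with p-values from the exact
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom (two-tailed). Zero-variance variables are excluded with a
#' warning.
#'
#' @param table complete monitoring table (no missing values in the chosen
#'   variables; at least 3 rows).
#' @param variables character vector of columns to correlate.
#' @return A `correlation_matrix`: list with `r`, `p` (matrices), `n`,
#'   `variables`.
#' @export
pearson_matrix <- function(table, variables) {
  stopifnot(all(variables %in% names(table)))
  x <- as.matrix(table[, variables, drop = FALSE])
  if (anyNA(x)) stop("table has missing values; resolve censoring first")
  if (nrow(x) < 3) stop("need at least 3 complete rows")
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    warning("excluding zero-variance variable(s): ",
            paste(variables[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
    variables <- variables[v > 0]
  }
  n <- nrow(x)
  r <- cor(x)
  p <- r_to_p(r, n)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, variables = variables),
            class = "correlation_matrix")
}

r_to_p <- function(r, n) {
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Read a square labelled correlation matrix from CSV
#'
#' Reconstructs a `correlation_matrix` object from a printed correlation
#' table (square CSV, first column = variable names); p-values are derived
#' from the stated sample size via the exact t transform.
#'
#' @param path CSV file.
#' @param n sample size behind the printed correlations.
#' @return A `correlation_matrix`.
#' @export
read_correlation_csv <- function(path, n) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vars <- d[[1]]
  r <- as.matrix(d[, -1, drop = FALSE])
  rownames(r) <- vars
  r[upper.tri(r)] <- t(r)[upper.tri(r)]  # accept lower-triangle input
  stopifnot(identical(colnames(r), vars), max(abs(r - t(r))) < 1e-12,
            all(abs(diag(r) - 1) < 1e-12))
  p <- r_to_p(r, n)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, variables = vars),
            class = "correlation_matrix")
}

#' The campaign's printed predictor correlation matrix
#'
#' The 15-variable Pearson matrix published for the 396-sample campaign,
#' shipped as a plain-text fixture; p-values derived from n = 396.
#'
#' @return A `correlation_matrix`.
#' @export
taihu_correlations <- function() {
  read_correlation_csv(
    system.file("extdata", "pearson_taihu.csv", package = "lakexergy",
                mustWork = TRUE), n = 396)
}

#' Strongly correlated predictor pairs
#'
#' All unordered pairs with `|R| > threshold` (absolute value: strongly
#' negative pairs count) and `p < alpha`, sorted by `|R|` descending.
#'
#' @param cm a `correlation_matrix`.
#' @param threshold absolute correlation cutoff (strict; default 0.7).
#' @param alpha significance cutoff (default 0.05).
#' @return data.frame `var1`, `var2`, `r`, `p`.
#' @export
strong_pairs <- function(cm, threshold = 0.7, alpha = 0.05) {
  stopifnot(inherits(cm, "correlation_matrix"))
  idx <- which(upper.tri(cm$r) & abs(cm$r) > threshold & cm$p < alpha,
               arr.ind = TRUE)
  out <- data.frame(var1 = cm$variables[idx[, 1]],
                    var2 = cm$variables[idx[, 2]],
                    r = cm$r[idx], p = cm$p[idx],
                    stringsAsFactors = FALSE)
  out[order(-abs(out$r), out$var1, out$var2), , drop = FALSE]
}

#' Default predictor retention preference
#'
#' Ordered most-preferred-first. Dissolved nutrient fractions are preferred
#' over totals and water temperature over dissolved oxygen, reproducing the
#' published 11-predictor set; chlorophyll-a is excluded from candidates
#' because it enters the indicator calculation itself.
#'
#' @return character vector.
#' @export
taihu_retain_policy <- function() {
  c("NH4_N", "NO3_N", "PO4_P", "WTEMP", "TSS", "PH", "WIND", "SOLR",
    "WD", "SDD", "PREC", "NOISE", "TN", "TP", "DTP", "DO")
}

#' Filter collinear predictors by ordered preference
#'
#' Walks candidates in preference order, keeping a variable only if it is
#' not strongly paired with an already-kept variable. A variable removed
#' once stays removed, so in a chain A~B, B~C with preference A > B > C the
#' result is {A, C}. Every member of a strong pair must appear in the
#' preference list.
#'
#' @param cm a `correlation_matrix`.
#' @param retain_policy ordered character vector, most preferred first.
#' @param threshold,alpha passed to [strong_pairs()].
#' @return Character vector of retained predictors, in preference order
#'   followed by any unlisted (unpaired) variables in matrix order.
#' @export
select_predictors <- function(cm, retain_policy = taihu_retain_policy(),
                              threshold = 0.7, alpha = 0.05) {
  pairs <- strong_pairs(cm, threshold, alpha)
  paired_vars <- unique(c(pairs$var1, pairs$var2))
  uncovered <- setdiff(paired_vars, retain_policy)
  if (length(uncovered))
    stop("retain policy does not cover strongly paired variable(s): ",
         paste(uncovered, collapse = ", "))
  ordered <- c(intersect(retain_policy, cm$variables),
               setdiff(cm$variables, retain_policy))
  kept <- character()
  for (v in ordered) {
    mates <- c(pairs$var2[pairs$var1 == v], pairs$var1[pairs$var2 == v])
    if (!any(mates %in% kept)) kept <- c(kept, v)
  }
  kept
}

#' Write a correlation matrix as a labelled square CSV
#'
#' @param cm a `correlation_matrix`.
#' @param path output file.
#' @export
write_correlation_csv <- function(cm, path) {
  d <- data.frame(variable = cm$variables, cm$r, check.names = FALSE)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
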