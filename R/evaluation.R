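#' Model adequacy statistics with pass/fail judgment
#'
#' Computes the four watershed-modelling adequacy statistics and judges the
#' prediction against the conventional gate:
#' \itemize{
#'   \item `NSE = 1 - sum((O - P)^2) / sum((O - mean(O))^2)` (1 perfect, 0
#'     no better than the observation mean); pass if `NSE > 0.5`.
#'   \item `RSR = RMSE / sd(O)` computed on the same sums, so the identity
#'     `NSE = 1 - RSR^2` holds exactly; pass if `RSR <= 0.7` (boundary
#'     inclusive).
#'   \item `PBIAS = 100 * sum(O - P) / sum(O)` (negative values indicate
#'     overprediction); pass if `-25 <= PBIAS <= 25`.
#'   \item `R^2`: squared Pearson correlation of O and P (reported, not
#'     gated).
#' }
#'
#' @param observed,predicted numeric vectors of equal length (>= 2);
#'   `observed` must have nonzero variance, and nonzero sum for PBIAS.
#' @param nse_min,rsr_max,pbias_max configurable gate thresholds.
#' @return An `adequacy_report`: list with `r_squared`, `nse`, `rsr`,
#'   `pbias`, `pass` (named logical), `pass_all`, `n`.
#' @export
adequacy <- function(observed, predicted, nse_min = 0.5, rsr_max = 0.7,
                     pbias_max = 25) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 2) stop("need at least 2 observations")
  if (anyNA(observed) || anyNA(predicted)) stop("missing values not allowed")
  ss_obs <- sum((observed - mean(observed))^2)
  if (ss_obs == 0) stop("NSE/RSR undefined: observed values have zero variance")
  if (sum(observed) == 0) stop("PBIAS undefined: observed values sum to zero")
  ss_err <- sum((observed - predicted)^2)
  nse <- 1 - ss_err / ss_obs
  rsr <- sqrt(ss_err) / sqrt(ss_obs)
  pbias <- 100 * sum(observed - predicted) / sum(observed)
  r2 <- if (var(predicted) == 0) 0 else cor(observed, predicted)^2
  pass <- c(nse = nse > nse_min, rsr = rsr <= rsr_max,
            pbias = abs(pbias) <= pbias_max)
  structure(list(r_squared = r2, nse = nse, rsr = rsr, pbias = pbias,
                 pass = pass, pass_all = all(pass), n = length(observed),
                 thresholds = list(nse_min = nse_min, rsr_max = rsr_max,
                                   pbias_max = pbias_max)),
            class = "adequacy_report")
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat(sprintf(
    "Model adequacy (n = %d)\n  R2    = %.3f\n  NSE   = %.3f (> %.2f: %s)\n  RSR   = %.3f (<= %.2f: %s)\n  PBIAS = %.1f%% (|.| <= %.0f: %s)\n  overall: %s\n",
    x$n, x$r_squared, x$nse, x$thresholds$nse_min,
    ifelse(x$pass["nse"], "pass", "FAIL"),
    x$rsr, x$thresholds$rsr_max, ifelse(x$pass["rsr"], "pass", "FAIL"),
    x$pbias, x$thresholds$pbias_max,
    ifelse(x$pass["pbias"], "pass", "FAIL"),
    ifelse(x$pass_all, "agreeable", "not agreeable")))
  invisible(x)
}

#' Write an adequacy report as JSON
#'
#' @param report an `adequacy_report`.
#' @param path output file.
#' @export
write_adequacy_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
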