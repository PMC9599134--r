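## Passive decay estimation --------------------------------------------------
##
## During the feedback-free decay phase the adaptation state relaxes
## geometrically; the cycle series is modelled as x(m) = x0 * a^(m - m0)
## with a the per-cycle decay rate. Individual series are too noisy for a
## stable exponential fit, so the rate is estimated on the group-averaged
## series, with a participant-level bootstrap for the confidence interval.

## Profiled nonlinear least squares: for fixed a the optimal x0 is linear,
## x0*(a) = sum(x * a^k) / sum(a^(2k)), so the fit reduces to a 1-D search.
decay_sse <- function(a, x, k) {
  g <- a^k
  x0 <- sum(x * g) / sum(g * g)
  list(sse = sum((x - x0 * g)^2), x0 = x0)
}

#' Fit an exponential decay to a cycle series
#'
#' Nonlinear least squares of `x(m) = x0 * a^(m - m0)` on a (typically
#' group-averaged) corrected cycle series, with `a` constrained to
#' (0, 1.2] and `x0` free. `x0` is profiled out analytically, leaving a 1-D
#' minimization over `a` (coarse grid then local refinement), which is
#' deterministic and has no convergence failures on non-degenerate input.
#'
#' @param x Numeric decay series (corrected angular deviation per cycle,
#'   degrees); NAs are dropped.
#' @param cycles Cycle indices for `x` (default `seq_along(x)`).
#' @param a_max Upper bound of the decay-rate search (default 1.2).
#' @return A list with `a_hat`, `x0_hat`, `sse`, `degenerate` (TRUE when the
#'   series is indistinguishable from zero and `a` is unidentifiable).
#' @examples
#' fit_decay(10 * 0.95^(0:39))  # recovers a = 0.95, x0 = 10
#' @export
fit_decay <- function(x, cycles = seq_along(x), a_max = 1.2) {
  keep <- is.finite(x)
  x <- x[keep]
  k <- cycles[keep] - min(cycles[keep])
  if (length(x) < 5) stop("decay fit needs at least 5 cycles")
  if (max(abs(x)) < 1e-8) {
    return(list(a_hat = NA_real_, x0_hat = 0, sse = 0, degenerate = TRUE))
  }
  grid <- seq(0.05, a_max, by = 0.025)
  sse_grid <- vapply(grid, function(a) decay_sse(a, x, k)$sse, numeric(1))
  i <- which.min(sse_grid)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(a) decay_sse(a, x, k)$sse, c(lo, hi), tol = 1e-10)
  fit <- decay_sse(opt$minimum, x, k)
  list(a_hat = opt$minimum, x0_hat = fit$x0, sse = fit$sse, degenerate = FALSE)
}

#' Bootstrap the group decay rate
#'
#' Resamples participants with replacement `n_boot` times (default 1000);
#' each resample's series are averaged across participants and fit with
#' [fit_decay()]. The confidence interval is the empirical percentile
#' interval of the resampled rates.
#'
#' @param mat Participants-by-cycles matrix of corrected decay series
#'   (see [decay_matrix()]).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return An object of class `decay_fit`: list with `a_hat`, `x0_hat`
#'   (point fit on the full group mean), `bootstrap_a`, `ci` (percentile
#'   bounds), `n_boot`, `level`, `seed`, `n_participants`.
#' @export
bootstrap_decay <- function(mat, n_boot = 1000, seed = 1L, level = 0.95) {
  if (!is.matrix(mat) || nrow(mat) < 2) {
    stop("`mat` must be a participants x cycles matrix with >= 2 rows")
  }
  point <- fit_decay(colMeans(mat, na.rm = TRUE))
  set.seed(as.integer(seed))
  boots <- rep(NA_real_, n_boot)
  fails <- 0L
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(mat), nrow(mat), replace = TRUE)
    fit <- tryCatch(fit_decay(colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)),
                    error = function(e) NULL)
    if (is.null(fit) || isTRUE(fit$degenerate)) fails <- fails + 1L
    else boots[b] <- fit$a_hat
  }
  if (fails > 0.05 * n_boot) {
    stop("bootstrap failed on ", fails, " of ", n_boot, " resamples")
  }
  alpha <- (1 - level) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(list(a_hat = point$a_hat, x0_hat = point$x0_hat,
                 degenerate = point$degenerate, bootstrap_a = boots,
                 ci = ci, n_boot = n_boot, level = level,
                 seed = as.integer(seed), n_participants = nrow(mat)),
            class = "decay_fit")
}

#' Format a decay-rate confidence interval
#'
#' Renders the interval in the conventional "(0.958, 0.971)" style.
#'
#' @param fit A `decay_fit` object.
#' @param digits Decimal places (default 3).
#' @return Character scalar.
#' @export
format_ci <- function(fit, digits = 3) {
  sprintf("(%.*f, %.*f)", digits, fit$ci[1], digits, fit$ci[2])
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Decay rate a = %.4f (x0 = %.2f deg), %d%% CI %s, %d bootstrap resamples of %d participants\n",
              x$a_hat, x$x0_hat, round(100 * x$level), format_ci(x),
              x$n_boot, x$n_participants))
  invisible(x)
}
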