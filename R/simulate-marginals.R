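#' Fit a boundary-inflated beta marginal to a printed median and IQR
#'
#' Per-site methylation summaries often sit on the boundary (medians of
#' exactly 0% or 100%), which no continuous beta can reproduce; the
#' generator therefore uses a three-part marginal on `[0, 100]`: point
#' masses `p0` at 0 and `p100` at 100 plus a location-scale beta body,
#' `lo + (hi - lo) * Beta(a, b)` rescaled to percent, on a sub-interval of
#' (0, 100). Fitting is by quantile matching: the minimum boundary mass
#' implied by the quantile ranks is allocated first (a median of 100 forces
#' `p100 >= 0.5`, a quartile on the boundary forces mass `>= 0.25`, with a
#' small buffer so the boundary quantile is attained robustly), then the
#' body's four parameters are optimised so the interior quantile targets
#' are met; the location-scale freedom lets skewed triplets (e.g.
#' `50 [40; 55]`) be matched that a two-parameter beta cannot reach.
#'
#' @param median,q1,q3 Target percent quantiles, `0 <= q1 <= median <= q3
#'   <= 100`.
#' @param boundary_buffer Extra mass above the geometric minimum allocated
#'   to a boundary atom (default 0.05).
#' @return A `site_dist` object: list with `p0`, `p100`, `a`, `b`, the
#'   `target` quantiles and the `achieved` quantiles of the fit.
#' @examples
#' fit_bounded_distribution(50, 40, 55)
#' fit_bounded_distribution(100, 87, 100)$p100  # >= 0.5
#' @export
fit_bounded_distribution <- function(median, q1, q3, boundary_buffer = 0.05) {
  if (is.na(median) || is.na(q1) || is.na(q3) ||
      !(0 <= q1 && q1 <= median && median <= q3 && q3 <= 100)) {
    abort(paste0("infeasible quantile ordering: q1=", q1, " median=", median,
                 " q3=", q3))
  }
  p0_min <- if (median <= 0) 0.5 else if (q1 <= 0) 0.25 else 0
  p100_min <- if (median >= 100) 0.5 else if (q3 >= 100) 0.25 else 0
  p0 <- if (p0_min > 0) min(p0_min + boundary_buffer, 0.9) else 0
  p100 <- if (p100_min > 0) min(p100_min + boundary_buffer, 0.9) else 0
  if (p0 + p100 >= 1) {  # degenerate two-sided case: rescale
    s <- 0.95 / (p0 + p100)
    p0 <- p0 * s
    p100 <- p100 * s
  }
  targets <- c(q1 = q1, median = median, q3 = q3)
  u <- c(0.25, 0.5, 0.75)
  interior <- targets > 0 & targets < 100
  body_mass <- 1 - p0 - p100
  lo <- 0
  hi <- 1
  if (!any(interior)) {
    # fully degenerate summary (e.g. constant 0); thin body hugging the mass
    a <- if (p0 >= p100) 1 else 50
    b <- if (p0 >= p100) 50 else 1
  } else {
    u_body <- (u[interior] - p0) / body_mass
    t_body <- targets[interior] / 100
    start <- c(log(moment_start(t_body)), -6, -6)
    obj <- function(par) {
      a <- exp(par[1])
      b <- exp(par[2])
      lo <- 0.5 * stats::plogis(par[3])
      hi <- 1 - 0.5 * stats::plogis(par[4])
      qs <- lo + (hi - lo) * qbeta(u_body, a, b)
      sum((qs - t_body)^2) +
        1e-6 * ((par[1] - log(2))^2 + (par[2] - log(2))^2) +
        1e-7 * ((par[3] + 6)^2 + (par[4] + 6)^2)
    }
    fit <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    a <- exp(fit$par[1])
    b <- exp(fit$par[2])
    lo <- 0.5 * stats::plogis(fit$par[3])
    hi <- 1 - 0.5 * stats::plogis(fit$par[4])
  }
  dist <- structure(
    list(p0 = p0, p100 = p100, a = a, b = b, lo = lo, hi = hi,
         target = targets, achieved = NULL),
    class = "site_dist"
  )
  dist$achieved <- qsitedist(u, dist)
  names(dist$achieved) <- names(targets)
  dist
}

moment_start <- function(t_body) {
  m <- mean(t_body)
  m <- min(max(m, 0.02), 0.98)
  k <- 8
  c(max(m * k, 0.05), max((1 - m) * k, 0.05))
}

#' Quantile function of a boundary-inflated beta marginal
#'
#' @param u Probabilities in `[0, 1]`.
#' @param dist A `site_dist` from [fit_bounded_distribution()].
#' @return Percent values in `[0, 100]`.
#' @export
qsitedist <- function(u, dist) {
  body_mass <- 1 - dist$p0 - dist$p100
  out <- numeric(length(u))
  lo <- u <= dist$p0
  hi <- u > 1 - dist$p100
  mid <- !lo & !hi
  out[lo] <- 0
  out[hi] <- 100
  if (any(mid)) {
    lo <- dist$lo %||% 0
    hi <- dist$hi %||% 1
    out[mid] <- 100 *
      (lo + (hi - lo) * qbeta((u[mid] - dist$p0) / body_mass, dist$a, dist$b))
  }
  out
}

#' Draw from a boundary-inflated beta marginal
#'
#' @param n Number of draws.
#' @param dist A `site_dist`.
#' @return Percent values.
#' @export
rsitedist <- function(n, dist) qsitedist(runif(n), dist)

#' @export
print.site_dist <- function(x, ...) {
  cat(sprintf(
    "<site_dist> p0=%.3f p100=%.3f beta(%.2f, %.2f) | target %s [%s; %s] -> achieved %.1f [%.1f; %.1f]\n",
    x$p0, x$p100, x$a, x$b,
    x$target[["median"]], x$target[["q1"]], x$target[["q3"]],
    x$achieved[["median"]], x$achieved[["q1"]], x$achieved[["q3"]]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.site_dist <- function(x, ...) {
  tibble(
    parameter = c("p0", "p100", "a", "b"),
    value = c(x$p0, x$p100, x$a, x$b)
  )
}

#' @exportS3Method generics::glance
glance.site_dist <- function(x, ...) {
  tibble(
    target_median = x$target[["median"]], target_q1 = x$target[["q1"]],
    target_q3 = x$target[["q3"]],
    achieved_median = x$achieved[["median"]], achieved_q1 = x$achieved[["q1"]],
    achieved_q3 = x$achieved[["q3"]],
    max_abs_error = max(abs(x$achieved - x$target))
  )
}

#' Spearman-to-Pearson copula calibration
#'
#' For a Gaussian copula with latent Pearson correlation `rho_p`, the
#' population Spearman correlation of the (continuous) margins is
#' `(6 / pi) * asin(rho_p / 2)`. Inverting gives the latent correlation to
#' use for a target rank correlation: `rho_p = 2 * sin(pi * rho_s / 6)`.
#'
#' @param rho_s Target Spearman correlation(s), `|rho_s| <= 1`.
#' @return Latent Pearson correlation(s).
#' @examples
#' spearman_to_pearson(0.5)  # 0.5176381
#' @export
spearman_to_pearson <- function(rho_s) {
  stopifnot(all(abs(rho_s) <= 1))
  2 * sin(pi * rho_s / 6)
}
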