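#' Pooled breakpoint proportions of a class pair
#'
#' The pooled cumulative origination proportions
#' (nA * C_A + nB * C_B) / (nA + nB) at each taxon breakpoint, dropping
#' breakpoints where the pooled value is 0 or 1 (the centered difference
#' there is degenerate: zero asymptotic variance under the null). The last
#' breakpoint is always dropped since both curves end at 1.
#'
#' @param dist_a,dist_b Single-class `age_distribution` tibbles on the same
#'   timeline, or lists with elements `n` and `cum`.
#' @return List with `p` (pooled proportions, strictly inside (0, 1)) and
#'   `kept` (the retained taxon indices).
#' @export
pooled_probs <- function(dist_a, dist_b) {
  a <- as_curve(dist_a); b <- as_curve(dist_b)
  if (length(a$cum) != length(b$cum)) {
    abort("curves live on different numbers of taxa.")
  }
  p <- (a$n * a$cum + b$n * b$cum) / (a$n + b$n)
  kept <- which(p > 0 & p < 1)
  if (!length(kept)) {
    abort("degenerate pair: no breakpoint with pooled proportion in (0, 1).")
  }
  list(p = p[kept], kept = kept, n_a = a$n, n_b = b$n)
}

curve_label <- function(x, fallback) {
  if (is.data.frame(x)) x$class[1]
  else if (is.list(x) && !is.null(x$class)) x$class
  else fallback
}

as_curve <- function(x) {
  if (is.data.frame(x)) {
    list(n = x$n[1], cum = one_class_cum(x))
  } else {
    stopifnot(is.list(x), !is.null(x$n), !is.null(x$cum))
    list(n = x$n, cum = x$cum)
  }
}

#' Brownian-bridge covariance at pooled breakpoints
#'
#' The centered difference of two empirical CDFs converges weakly to a
#' Brownian bridge; its covariance at breakpoint proportions p_i <= p_j is
#' p_i (1 - p_j). This matrix calibrates the simultaneous band.
#'
#' @param p Numeric vector, strictly increasing, inside (0, 1).
#' @return Symmetric positive-semidefinite covariance matrix.
#' @export
bridge_covariance <- function(p) {
  if (any(p <= 0 | p >= 1)) abort("pooled proportions must lie strictly in (0, 1).")
  if (is.unsorted(p, strictly = FALSE)) abort("pooled proportions must be nondecreasing.")
  outer(p, p, function(x, y) pmin(x, y) * (1 - pmax(x, y)))
}

# Monte-Carlo sample of max_i |Z_i| / sqrt(Sigma_ii), Z ~ N(0, Sigma).
# Drawn in blocks to bound memory at large n_mc.
max_modulus_sample <- function(sigma, n_mc, seed, block = 200000L) {
  k <- nrow(sigma)
  d <- sqrt(diag(sigma))
  if (any(d <= 0)) abort("covariance has a zero-variance coordinate.")
  corr <- sigma / tcrossprod(d)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("covariance matrix is not positive semidefinite.")
  # PSD square root via eigen (chol can fail on the exactly singular edge)
  es <- eigen(corr, symmetric = TRUE)
  rt <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  withr::with_seed(seed, {
    out <- numeric(n_mc)
    done <- 0L
    while (done < n_mc) {
      m <- min(block, n_mc - done)
      z <- matrix(rnorm(m * k), m, k) %*% rt
      mx <- abs(z[, 1])
      if (k > 1) for (j in 2:k) mx <- pmax(mx, abs(z[, j]))
      out[(done + 1):(done + m)] <- mx
      done <- done + m
    }
    out
  })
}

#' Monte-Carlo maximum-modulus critical value
#'
#' The (1 - alpha) quantile of max_i |Z_i| / sqrt(Sigma_ii) over `n_mc`
#' draws of Z ~ N(0, Sigma): the simultaneous critical value of the
#' covariance-adjusted joint confidence band. With a single breakpoint it
#' reduces to the two-sided standard normal quantile (1.96 at alpha 0.05).
#'
#' @param sigma Covariance matrix (see [bridge_covariance()]).
#' @param alpha Simultaneous error level in (0, 1).
#' @param n_mc Monte-Carlo replications (default 1e6).
#' @param seed Integer seed; the draw is reproducible.
#' @return The critical value `c_alpha`.
#' @export
max_modulus_quantile <- function(sigma, alpha = 0.05, n_mc = 1e6, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_mc >= 1e3)
  mx <- max_modulus_sample(as.matrix(sigma), n_mc, seed)
  unname(quantile(mx, probs = 1 - alpha, type = 7))
}

#' Simultaneous confidence band for the difference of two curves
#'
#' At each retained breakpoint s the band is
#' D_s +/- c_alpha * se_s with D_s = C_A(s) - C_B(s),
#' se_s = sqrt(p_s (1 - p_s) (1/nA + 1/nB)) from the pooled proportion
#' p_s, and c_alpha the Monte-Carlo maximum-modulus quantile of the
#' Brownian-bridge correlation — so all breakpoints are covered
#' simultaneously at level 1 - alpha.
#'
#' @inheritParams pooled_probs
#' @inheritParams max_modulus_quantile
#' @param method `"max_modulus"` (Monte-Carlo calibration, default) or
#'   `"scheffe"` (chi-square based `c_alpha = sqrt(qchisq(1 - alpha, k))`,
#'   a conservative closed-form alternative for sensitivity analysis).
#' @return A tibble with one row per retained breakpoint: `taxon_index`,
#'   `D`, `se`, `band_low`, `band_high`; attributes `c_alpha`, `alpha`,
#'   `seed`.
#' @export
joint_band <- function(dist_a, dist_b, alpha = 0.05, n_mc = 1e6, seed = 1L,
                       method = c("max_modulus", "scheffe")) {
  method <- match.arg(method)
  fit <- band_fit(dist_a, dist_b, alpha, n_mc, seed, method)
  fit$band
}

# Shared machinery of joint_band and stochastic_order_test: one MC sample
# serves both the critical value and the max-modulus p-value.
band_fit <- function(dist_a, dist_b, alpha, n_mc, seed, method = "max_modulus") {
  a <- as_curve(dist_a); b <- as_curve(dist_b)
  pp <- pooled_probs(a, b)
  sigma <- bridge_covariance(pp$p)
  d_all <- a$cum - b$cum
  D <- d_all[pp$kept]
  se <- sqrt(pp$p * (1 - pp$p) * (1 / a$n + 1 / b$n))
  t_stat <- max(abs(D) / se)
  if (method == "scheffe") {
    c_alpha <- sqrt(qchisq(1 - alpha, df = length(pp$p)))
    p_two <- stats::pchisq(t_stat^2, df = length(pp$p), lower.tail = FALSE)
  } else {
    mx <- max_modulus_sample(sigma, n_mc, seed)
    c_alpha <- unname(quantile(mx, probs = 1 - alpha, type = 7))
    p_two <- mean(mx >= t_stat)
  }
  band <- tibble::tibble(
    taxon_index = pp$kept, D = D, se = se,
    band_low = D - c_alpha * se, band_high = D + c_alpha * se
  )
  attr(band, "c_alpha") <- c_alpha
  attr(band, "alpha") <- alpha
  attr(band, "seed") <- seed
  list(band = band, t_stat = t_stat, p_two = p_two, c_alpha = c_alpha,
       n_a = a$n, n_b = b$n)
}

#' Test whether one gene class is stochastically younger than another
#'
#' A class is stochastically younger when its age CDF dominates the
#' other's everywhere — equivalently, when its cumulative origination
#' curve lies everywhere at or below the other's. The test statistic is
#' the maximum standardized curve difference
#' T = max_s |D_s| / se_s; its null distribution is the maximum modulus of
#' the correlated Gaussian vector with the Brownian-bridge covariance of
#' the pooled curve, evaluated by Monte Carlo. The verdict reads the signs
#' of the breakpoints whose simultaneous band excludes zero:
#' all negative (A's curve lower) gives `A_younger`, all positive
#' `B_younger`, both signs `crossing`, none `no_difference`.
#'
#' @inheritParams joint_band
#' @param labels Length-2 character vector naming the two classes (taken
#'   from the distributions when available).
#' @return A `stoch_order_test` object; see [tidy()] for the per-breakpoint
#'   band and [glance()] for the one-row summary.
#' @export
stochastic_order_test <- function(dist_a, dist_b, alpha = 0.05, n_mc = 1e6,
                                  seed = 1L,
                                  method = c("max_modulus", "scheffe"),
                                  labels = NULL) {
  method <- match.arg(method)
  if (is.null(labels)) {
    labels <- c(curve_label(dist_a, "A"), curve_label(dist_b, "B"))
  }
  fit <- band_fit(dist_a, dist_b, alpha, n_mc, seed, method)
  band <- fit$band
  sig <- band$band_low > 0 | band$band_high < 0
  verdict <- if (!any(sig)) {
    "no_difference"
  } else {
    neg <- any(sig & band$D < 0)
    pos <- any(sig & band$D > 0)
    if (neg && pos) "crossing" else if (neg) "A_younger" else "B_younger"
  }
  structure(
    list(pair = labels, band = band, t_stat = fit$t_stat,
         p_two_sided = fit$p_two, c_alpha = fit$c_alpha, alpha = alpha,
         n_mc = n_mc, seed = seed, method = method,
         n_a = fit$n_a, n_b = fit$n_b, verdict = verdict),
    class = "stoch_order_test"
  )
}

#' @export
print.stoch_order_test <- function(x, ...) {
  cat(sprintf("Stochastic order test: %s (n=%d) vs %s (n=%d)\n",
              x$pair[1], x$n_a, x$pair[2], x$n_b))
  cat(sprintf("  T = %.4f, c_%.3g = %.4f, two-sided p = %.4g\n",
              x$t_stat, x$alpha, x$c_alpha, x$p_two_sided))
  cat(sprintf("  verdict: %s (%d breakpoints, method %s, seed %d)\n",
              x$verdict, nrow(x$band), x$method, x$seed))
  invisible(x)
}

#' @rdname stochastic_order_test
#' @param x A `stoch_order_test`.
#' @param ... Unused.
#' @export
tidy.stoch_order_test <- function(x, ...) {
  dplyr::mutate(x$band,
                class_a = x$pair[1], class_b = x$pair[2],
                excludes_zero = .data$band_low > 0 | .data$band_high < 0,
                .before = 1)
}

#' @rdname stochastic_order_test
#' @export
glance.stoch_order_test <- function(x, ...) {
  tibble::tibble(
    class_a = x$pair[1], class_b = x$pair[2], n_a = x$n_a, n_b = x$n_b,
    statistic = x$t_stat, p_two_sided = x$p_two_sided, c_alpha = x$c_alpha,
    alpha = x$alpha, n_mc = x$n_mc, seed = x$seed, method = x$method,
    verdict = x$verdict
  )
}
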