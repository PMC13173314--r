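# One-dimensional Gaussian mixture by EM with deterministic quantile
# initialization; returns the maximized log-likelihood and parameters.
fit_gmm1d <- function(x, k, max_iter = 200, tol = 1e-8) {
  n <- length(x)
  if (k == 1L) {
    mu <- mean(x)
    sd1 <- stats::sd(x) * sqrt((n - 1) / n)
    ll <- sum(stats::dnorm(x, mu, sd1, log = TRUE))
    return(list(k = 1L, weight = 1, mean = mu, sd = sd1, loglik = ll))
  }
  qs <- stats::quantile(x, probs = seq(0.5 / k, 1 - 0.5 / k, length.out = k),
                        names = FALSE)
  mu <- qs
  sdv <- rep(stats::sd(x) / k, k)
  sdv[sdv <= 0] <- 1e-6
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sdv[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sdv <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    sdv <- pmax(sdv, 1e-4 * stats::sd(x))
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(k = k, weight = w, mean = mu, sd = sdv, loglik = ll)
}

gmm_bic <- function(fit, n) {
  p <- if (fit$k == 1L) 2 else 3 * fit$k - 1
  -2 * fit$loglik + p * log(n)
}

#' Classify an area distribution as unimodal or bimodal
#'
#' Fits one- and two-component Gaussian mixtures to log-transformed
#' normalized areas and reports `"bimodal"` when the two-component model is
#' decisively better (`delta_BIC = BIC_1 - BIC_2 > threshold`, default 10)
#' AND the fitted component means are separated by more than the pooled
#' fitted standard deviation. Fewer than `min_n` observations yields
#' `"insufficient-n"` with no classification.
#'
#' @param areas Positive numeric vector (normalized cell areas).
#' @param min_n Minimum sample size for a classification (default 30).
#' @param bic_threshold Required BIC improvement (default 10).
#' @return List with `classification` (`"unimodal"`, `"bimodal"` or
#'   `"insufficient-n"`), `score` (delta BIC), `separation` (mean distance
#'   in pooled-sd units), and the two fits.
#' @export
classify_modality <- function(areas, min_n = 30L, bic_threshold = 10) {
  areas <- areas[is.finite(areas)]
  if (any(areas <= 0)) stop_invalid("areas must be positive")
  if (length(areas) < min_n) {
    return(list(classification = "insufficient-n", score = NA_real_,
                separation = NA_real_, n = length(areas)))
  }
  x <- log(areas)
  f1 <- fit_gmm1d(x, 1L)
  f2 <- fit_gmm1d(x, 2L)
  dbic <- gmm_bic(f1, length(x)) - gmm_bic(f2, length(x))
  pooled_sd <- sqrt(sum(f2$weight * f2$sd^2))
  sep <- abs(diff(f2$mean)) / pooled_sd
  bimodal <- dbic > bic_threshold && sep > 1
  list(classification = if (bimodal) "bimodal" else "unimodal",
       score = dbic, separation = sep, n = length(x),
       fit1 = f1, fit2 = f2)
}
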