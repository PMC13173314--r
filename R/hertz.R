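#' Generate a Hertz force-indentation curve
#'
#' Forward model of spherical-tip indentation:
#' `F = (4/3) E_eff sqrt(R) delta^(3/2)` for depths past the contact point,
#' zero before. Depths are sampled on a uniform grid to `depth_max`, with an
#' optional pre-contact baseline segment and additive force noise.
#'
#' @param E_eff Effective Young's modulus, Pa (`E / (1 - nu^2)` lumped into
#'   one parameter).
#' @param R_tip Tip radius, um (a 20 um spherical tip has R_tip = 10).
#' @param depth_max Maximum indentation depth, um (default 3.5).
#' @param n Number of post-contact samples (default 100).
#' @param contact_offset Pre-contact travel included before the contact
#'   point, um (sampled at the same spacing, zero force).
#' @param noise_sd Force noise sd as a fraction of the maximum force.
#' @param noise_type `"additive"` or `"multiplicative"`.
#' @param seed Integer seed.
#' @return An `indentation_curve` data frame with `depth_um` and `force_nN`,
#'   with `tip_radius_um` as an attribute.
#' @export
generate_indentation_curve <- function(E_eff, R_tip = 10, depth_max = 3.5,
                                       n = 100, contact_offset = 0,
                                       noise_sd = 0,
                                       noise_type = c("additive",
                                                      "multiplicative"),
                                       seed = 1L) {
  noise_type <- match.arg(noise_type)
  check_positive(E_eff, "E_eff")
  check_positive(R_tip, "R_tip")
  check_positive(depth_max, "depth_max")
  dstep <- depth_max / (n - 1)
  pre <- if (contact_offset > 0) -rev(seq(dstep, contact_offset, by = dstep)) else numeric()
  depth <- c(pre, seq(0, depth_max, length.out = n))
  f_N <- hertz_force(depth, E_eff, R_tip, 0)
  f_nN <- f_N * 1e9
  f_nN <- with_seed(seed, {
    if (noise_sd > 0) {
      if (noise_type == "additive") {
        f_nN + stats::rnorm(length(f_nN), sd = noise_sd * max(f_nN))
      } else {
        f_nN * (1 + stats::rnorm(length(f_nN), sd = noise_sd))
      }
    } else f_nN
  })
  out <- data.frame(depth_um = depth + contact_offset, force_nN = f_nN)
  attr(out, "tip_radius_um") <- R_tip
  class(out) <- c("indentation_curve", class(out))
  out
}

# Hertz force in N for depth in um past contact point delta0 (um),
# E in Pa, R in um.
hertz_force <- function(depth_um, E_eff, R_um, delta0_um) {
  d <- pmax(depth_um - delta0_um, 0) * 1e-6
  (4 / 3) * E_eff * sqrt(R_um * 1e-6) * d^1.5
}

#' Fit the Hertz contact model to a force-indentation curve
#'
#' Jointly fits the effective Young's modulus and the contact point by least
#' squares over the window up to 100% of the force maximum: for a candidate
#' contact point the modulus has a closed-form least-squares solution, and
#' the contact point is found by 1D minimization (initialized near the
#' depth where force reaches 5% of its maximum). R^2 is computed on the
#' force residuals over the fitted window; fits with `R^2 > 0.95` are
#' flagged accepted.
#'
#' @param curve An `indentation_curve` data frame (`depth_um`, `force_nN`),
#'   or any data frame with those columns.
#' @param tip_radius_um Tip radius, um; defaults to the curve's attribute.
#' @param pmax_fraction Upper end of the fit window as a fraction of the
#'   force maximum (default 1 = 100% of Pmax).
#' @return A `hertz_fit` list: `E_eff_Pa`, `E_eff_kPa`, `contact_point_um`,
#'   `r_squared`, `accepted`, `n_fit`.
#' @export
fit_hertz <- function(curve, tip_radius_um = attr(curve, "tip_radius_um"),
                      pmax_fraction = 1) {
  if (is.null(tip_radius_um)) stop_invalid("tip radius required")
  check_positive(tip_radius_um, "tip_radius_um")
  depth <- curve$depth_um
  force <- curve$force_nN * 1e-9
  if (length(depth) < 10L) stop_invalid("need >= 10 samples to fit")
  if (all(force == 0)) stop_invalid("all-zero force curve")
  fmax <- max(force)
  win <- force <= pmax_fraction * fmax + 1e-300
  d <- depth[win]; f <- force[win]
  if (sum(f > 0.05 * fmax) < 10L) {
    stop_invalid("need >= 10 post-contact samples to fit")
  }
  # non-monotonicity beyond noise -> warn
  dec <- diff(f[f > 0.2 * fmax])
  if (length(dec) && min(dec) < -0.1 * fmax) {
    warning("force decreases substantially within the fit window")
  }
  sse <- function(delta0) {
    g <- hertz_force(d, 1, tip_radius_um, delta0)
    if (all(g == 0)) return(sum(f^2))
    e_hat <- sum(f * g) / sum(g * g)
    sum((f - e_hat * g)^2)
  }
  i5 <- which(f >= 0.05 * fmax)[1]
  init <- d[max(i5, 1L)]
  span <- diff(range(d))
  lo <- min(d) - 0.05 * span
  hi <- min(init + 0.45 * span, max(d) - 0.3 * span)
  if (hi <= lo) hi <- lo + 0.1 * span
  opt <- stats::optimize(sse, interval = c(lo, hi), tol = 1e-10)
  delta0 <- opt$minimum
  g <- hertz_force(d, 1, tip_radius_um, delta0)
  E <- sum(f * g) / sum(g * g)
  resid <- f - E * g
  r2 <- 1 - sum(resid^2) / sum((f - mean(f))^2)
  if (!is.finite(E) || E <= 0) {
    stop(errorCondition(
      paste0("Hertz fit failed: E = ", format(E), ", residual SS = ",
             format(sum(resid^2))),
      class = c("drusenmorph_fit_error", "error")))
  }
  structure(list(E_eff_Pa = E, E_eff_kPa = E / 1000,
                 contact_point_um = delta0, r_squared = r2,
                 accepted = r2 > 0.95, n_fit = length(d)),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E_eff = %.3f kPa, contact point = %.3f um, R2 = %.4f (%s)\n",
              x$E_eff_kPa, x$contact_point_um, x$r_squared,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}
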