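#' Bending stiffness of a cylindrical cantilever post
#'
#' Tip stiffness of a cylindrical Euler-Bernoulli cantilever under a point
#' load at the free end: \eqn{k = 3 E I / L^3} with second moment
#' \eqn{I = \pi d^4 / 64}. This is the calibration constant that turns a
#' measured post deflection into a force.
#'
#' @param geometry a [PostGeometry-class].
#' @return stiffness in N/m.
#' @examples
#' postBendingStiffness(PostGeometry())  # ~10.91 N/m
#' @export
postBendingStiffness <- function(geometry) {
  stopIfNot(is(geometry, "PostGeometry"), "geometry must be a PostGeometry",
            "invalidGeometryError")
  validObject(geometry)
  I <- pi * geometry@diameter^4 / 64
  3 * geometry@elasticModulus * I / geometry@length^3
}

#' Force from post deflection
#'
#' Linear-elastic force readout \eqn{F = k v} of the cantilever transducer.
#'
#' @param deflection post tip deflection v in m (may be a vector).
#' @param stiffness post bending stiffness k in N/m, > 0.
#' @return force in N, same sign as the deflection.
#' @export
forceFromDeflection <- function(deflection, stiffness) {
  stopIfNot(is.numeric(stiffness) && length(stiffness) == 1 && stiffness > 0,
            "stiffness must be a scalar > 0", "invalidGeometryError")
  stiffness * deflection
}

#' Stretch ratio from post separation
#'
#' Global tissue stretch \eqn{\lambda = s / s_0} from the current and rest
#' tip-to-tip post separations. Separations below the rest separation are
#' returned with a `compression` attribute flagging them as outside the
#' tensile analysis range.
#'
#' @param separation current tip-to-tip separation s in m (vectorized).
#' @param restSeparation rest separation s0 in m, > 0.
#' @return stretch ratio(s), with attribute `compression` (logical vector)
#'   TRUE where s < s0.
#' @export
stretchFromSeparation <- function(separation, restSeparation) {
  stopIfNot(is.numeric(restSeparation) && restSeparation > 0,
            "restSeparation must be > 0", "invalidGeometryError")
  stopIfNot(all(separation >= 0), "separation must be >= 0",
            "invalidGeometryError")
  lam <- separation / restSeparation
  attr(lam, "compression") <- separation < restSeparation
  lam
}

#' Nominal (first Piola) stress from force
#'
#' \eqn{\sigma = F / (w t)}, force referred to the undeformed rectangular
#' cross-section.
#'
#' @param force force in N (vectorized).
#' @param width undeformed specimen width in m, > 0.
#' @param thickness undeformed specimen thickness in m, > 0.
#' @return stress in Pa.
#' @export
nominalStress <- function(force, width, thickness) {
  stopIfNot(is.numeric(width) && width > 0 && is.numeric(thickness) &&
              thickness > 0,
            "width and thickness must be > 0", "invalidSpecimenError")
  force / (width * thickness)
}

# sigma(eps) under the exponential law.
fungStress <- function(alpha, beta, eps) alpha * (exp(beta * eps) - 1)

#' Fit the exponential constitutive law to a stress-stretch record
#'
#' Nonlinear least squares of \eqn{\sigma = \alpha(e^{\beta\epsilon} - 1)}
#' with engineering strain \eqn{\epsilon = \lambda - 1}. Starting values come
#' from the log-slope of the upper third of the curve
#' (\eqn{\beta_0}), with \eqn{\alpha_0} set so the peak stress is matched;
#' bounded Levenberg-Marquardt restarts from perturbed starts are attempted
#' before failing.
#'
#' @param curve a [StressStrainCurve-class].
#' @param epsRef reference strain at which the effective tangent modulus is
#'   evaluated (default 0.3, the midpoint of a lambda <= 1.6 protocol).
#' @param maxRestarts bounded number of perturbed restarts on
#'   non-convergence.
#' @return a [FungFit-class] carrying (alpha, beta), the tangent modulus at
#'   `epsRef`, the residual norm and r-squared.
#' @examples
#' lam <- seq(1, 1.6, length.out = 20)
#' curve <- StressStrainCurve(lam, 0.02e6 * (exp(8 * (lam - 1)) - 1))
#' coef(fitFung(curve))
#' @export
fitFung <- function(curve, epsRef = 0.3, maxRestarts = 8L) {
  stopIfNot(is(curve, "StressStrainCurve"),
            "curve must be a StressStrainCurve", "dataQualityError")
  validObject(curve)
  eps <- curve@stretch - 1
  sig <- curve@stress
  stopIfNot(diff(range(sig)) > 0, "stresses are all equal",
            "dataQualityError")
  n3 <- max(3L, ceiling(length(sig) / 3))
  idx <- order(eps)[(length(eps) - n3 + 1):length(eps)]
  # data-quality guard: a tensile record must stiffen overall
  if (stats::coef(stats::lm(sig ~ eps))[2] <= 0)
    stopIfNot(FALSE, "stress decreases with strain; not a tensile record",
              "dataQualityError")
  pos <- sig > 0 & eps > 0
  beta0 <- if (sum(pos & seq_along(sig) %in% idx) >= 2) {
    b <- stats::coef(stats::lm(log(sig[idx][sig[idx] > 0]) ~
                                 eps[idx][sig[idx] > 0]))[2]
    if (is.finite(b) && b > 0) b else 5
  } else 5
  alpha0 <- max(sig) / max(expm1(beta0 * max(eps)), 1e-8)
  dat <- data.frame(eps = eps, sig = sig)
  fit <- NULL
  # deterministic perturbation grid keeps restarts reproducible
  mults <- c(1, 0.5, 2, 0.25, 4, 0.1, 10, 0.05, 20)[seq_len(maxRestarts + 1)]
  starts <- lapply(mults, function(m) c(alpha0 / m, max(0.2, beta0 * m)))
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(sig ~ a * (exp(b * eps) - 1), data = dat,
                        start = list(a = st[1], b = st[2]),
                        lower = c(1e-12, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  stopIfNot(!is.null(fit), "Fung fit failed to converge after restarts",
            "fitFailureError")
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  ss_tot <- sum((sig - mean(sig))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  new("FungFit", alpha = unname(cf["a"]), beta = unname(cf["b"]),
      effModulus = unname(cf["a"] * cf["b"] * exp(cf["b"] * epsRef)),
      epsRef = epsRef, residualNorm = sqrt(sum(res^2)),
      rSquared = min(1, r2))
}

#' Effective (tangent) modulus of a fitted exponential law
#'
#' Tangent stiffness \eqn{d\sigma/d\epsilon = \alpha \beta
#' e^{\beta \epsilon_{ref}}} of the fitted law at a reference strain. With
#' `epsRef = 0` this is the toe-region modulus \eqn{\alpha\beta}.
#'
#' @param fit a [FungFit-class].
#' @param epsRef reference engineering strain, >= 0.
#' @return modulus in Pa.
#' @export
effectiveModulus <- function(fit, epsRef = 0.3) {
  stopIfNot(is(fit, "FungFit"), "fit must be a FungFit",
            "invalidArgumentError")
  stopIfNot(is.numeric(epsRef) && all(epsRef >= 0), "epsRef must be >= 0",
            "invalidArgumentError")
  fit@alpha * fit@beta * exp(fit@beta * epsRef)
}

#' Stress-stretch curve from a two-post force record
#'
#' Converts a simulated or measured two-post record (deflection, separation,
#' force per step) into a [StressStrainCurve-class] via the cantilever force
#' readout and the nominal stress definition. Steps at compression
#' (s < s0) or duplicate stretch are dropped; a rest-state (lambda = 1,
#' sigma = 0) anchor is prepended when absent.
#'
#' @param record data.frame with columns `separation_m` and either `force_N`
#'   or `deflection_m` (the latter converted using `stiffness`).
#' @param geometry the [PostGeometry-class] of the posts.
#' @param width,thickness undeformed specimen cross-section, m.
#' @param stiffness post stiffness; defaults to
#'   `postBendingStiffness(geometry)`.
#' @return a [StressStrainCurve-class].
#' @export
curveFromRecord <- function(record, geometry, width = 1e-3,
                            thickness = 40e-6,
                            stiffness = postBendingStiffness(geometry)) {
  stopIfNot(is.data.frame(record) && "separation_m" %in% names(record),
            "record must contain separation_m", "dataQualityError")
  F <- if ("force_N" %in% names(record)) record$force_N
       else forceFromDeflection(record$deflection_m, stiffness)
  lam <- as.numeric(stretchFromSeparation(record$separation_m,
                                          geometry@baseSeparation))
  sig <- nominalStress(F, width, thickness)
  keep <- lam >= 1
  lam <- lam[keep]; sig <- sig[keep]
  o <- order(lam)
  lam <- lam[o]; sig <- sig[o]
  dup <- c(FALSE, diff(lam) <= 1e-12)
  lam <- lam[!dup]; sig <- sig[!dup]
  if (lam[1] > 1 + 1e-12) {
    lam <- c(1, lam); sig <- c(0, sig)
  }
  StressStrainCurve(lam, sig, specimenWidth = width,
                    specimenThickness = thickness)
}

#' Write per-specimen constitutive fit results to CSV
#'
#' Writes the standard fit table with header
#' `specimen_id,alpha_Pa,beta,eff_modulus_Pa,r2,eps_ref`.
#'
#' @param fits named list of [FungFit-class] objects (names = specimen ids).
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
writeFitTable <- function(fits, path) {
  tab <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(specimen_id = id, alpha_Pa = f@alpha, beta = f@beta,
               eff_modulus_Pa = f@effModulus, r2 = f@rSquared,
               eps_ref = f@epsRef)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
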