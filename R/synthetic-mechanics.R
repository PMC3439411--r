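#' Generate a noisy stress-stretch record from an exponential tissue law
#'
#' Samples stretch ratios uniformly on \[1, `lambdaMax`\], evaluates
#' \eqn{\sigma = \alpha(e^{\beta(\lambda - 1)} - 1)} and adds i.i.d. Gaussian
#' noise. Deterministic per seed.
#'
#' @param model a [TissueModel-class].
#' @param nPoints number of points, >= 3.
#' @param noiseSD additive stress noise sd in Pa, >= 0.
#' @param seed RNG seed.
#' @param lambdaMax protocol maximum stretch (default 1.6).
#' @return a [StressStrainCurve-class].
#' @examples
#' gen <- genStressStrain(TissueModel(0.02e6, 8), nPoints = 20,
#'                        noiseSD = 0, seed = 1)
#' @export
genStressStrain <- function(model, nPoints, noiseSD = 0, seed = 1L,
                            lambdaMax = 1.6) {
  stopIfNot(is(model, "TissueModel"), "model must be a TissueModel",
            "invalidSpecError")
  validObject(model)
  stopIfNot(nPoints >= 3, "nPoints must be >= 3", "invalidSpecError")
  stopIfNot(noiseSD >= 0, "noiseSD must be >= 0", "invalidSpecError")
  withSeed(seed, {
    lam <- sort(c(1, stats::runif(nPoints - 1L, 1, lambdaMax)))
    # break exact ties (probability ~0, but cheap) without moving lambda = 1
    lam <- lam + cumsum(c(0, ifelse(diff(lam) <= 0, 1e-9, 0)))
    sig <- fungStress(model@alpha, model@beta, lam - 1)
    if (noiseSD > 0) sig <- sig + stats::rnorm(length(sig), 0, noiseSD)
    StressStrainCurve(lam, sig, specimenWidth = model@width,
                      specimenThickness = model@thickness)
  })
}

# Tissue tension (N) at stretch lambda for a TissueModel.
tissueForce <- function(model, lambda) {
  fungStress(model@alpha, model@beta, lambda - 1) * model@width *
    model@thickness
}

#' Simulate a two-post uniaxial stretch experiment
#'
#' A specimen of rest length s0 spans two elastomeric cantilever posts.
#' Each post base is displaced outward by d; tissue tension deflects each
#' tip back inward by v, so the current tissue length is
#' \eqn{s = s_0 + 2d - 2v} and the global stretch \eqn{\lambda = s/s_0}.
#' At every step the scalar force balance
#' \deqn{F_{tissue}(\lambda) = k v}
#' is solved for v by bracketed root-finding on \eqn{v \in [0, d]}
#' (tolerance 1e-12 m; the residual is strictly monotone in v so the root is
#' unique).
#'
#' @param geometry a [PostGeometry-class]; its `baseSeparation` is the rest
#'   tissue length s0.
#' @param model a [TissueModel-class].
#' @param gripDisplacements per-post base displacements d in m, nonnegative
#'   and nondecreasing.
#' @return data.frame with columns `step`, `displacement_m`, `deflection_m`,
#'   `separation_m`, `stretch`, `force_N`; stretch is nondecreasing across
#'   steps.
#' @examples
#' rec <- simulateTwoPostTest(PostGeometry(), TissueModel(0.02e6, 8),
#'                            seq(0, 150e-6, by = 25e-6))
#' @export
simulateTwoPostTest <- function(geometry, model, gripDisplacements) {
  stopIfNot(is(geometry, "PostGeometry") && is(model, "TissueModel"),
            "need a PostGeometry and a TissueModel", "invalidSpecError")
  validObject(geometry); validObject(model)
  d <- as.numeric(gripDisplacements)
  stopIfNot(all(d >= 0), "grip displacements must be nonnegative",
            "invalidProtocolError")
  stopIfNot(all(diff(d) >= 0), "grip displacements must be nondecreasing",
            "invalidProtocolError")
  k <- postBendingStiffness(geometry)
  s0 <- geometry@baseSeparation
  solveStep <- function(di) {
    if (di == 0) return(0)
    resid <- function(v)
      tissueForce(model, (s0 + 2 * di - 2 * v) / s0) - k * v
    # resid(0) >= 0, resid(d) < 0 (tissue slack but post loaded)
    if (resid(0) <= 0) return(0)
    stopIfNot(resid(di) < 0, "no equilibrium root in physical bracket",
              "equilibriumFailureError")
    stats::uniroot(resid, c(0, di), tol = 1e-12)$root
  }
  v <- vapply(d, solveStep, numeric(1))
  s <- s0 + 2 * d - 2 * v
  data.frame(step = seq_along(d), displacement_m = d, deflection_m = v,
             separation_m = s, stretch = s / s0, force_N = k * v)
}

#' Write / read a mechanical record CSV
#'
#' The on-disk schema is
#' `step,displacement_m,deflection_m,separation_m,stretch,force_N`.
#'
#' @param record a record data.frame as returned by
#'   [simulateTwoPostTest()].
#' @param path CSV path.
#' @return `writeMechRecord` returns the path invisibly; `readMechRecord`
#'   returns the record data.frame.
#' @export
writeMechRecord <- function(record, path) {
  cols <- c("step", "displacement_m", "deflection_m", "separation_m",
            "stretch", "force_N")
  stopIfNot(all(cols %in% names(record)), "record lacks schema columns",
            "dataQualityError")
  utils::write.csv(record[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMechRecord
#' @export
readMechRecord <- function(path) {
  rec <- utils::read.csv(path)
  cols <- c("step", "displacement_m", "deflection_m", "separation_m",
            "stretch", "force_N")
  stopIfNot(all(cols %in% names(rec)), "file lacks mechanical record schema",
            "dataQualityError")
  rec[cols]
}
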