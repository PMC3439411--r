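#' @import methods
NULL

# Evaluate expr under a fixed RNG state, restoring the caller's stream after.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-call child seed from a base seed and small integers, < 2^31.
childSeed <- function(seed, ...) {
  parts <- c(as.integer(seed), as.integer(c(...)))
  h <- 0
  for (p in parts) h <- (h * 7919 + (p %% 104729) + 104729) %% 2147483629L
  as.integer(h)
}

stopIfNot <- function(cond, msg, class) {
  if (!isTRUE(cond))
    stop(structure(class = c(class, "valvemechError", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  invisible(TRUE)
}

# Sample from the von Mises distribution (Best & Fisher rejection sampler).
# kappa = 0 falls back to the uniform circular law.
rVonMises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return((runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
  }
  out
}

# Axial (period-pi) orientation sample about 0 with concentration kappa.
rAxialOrientation <- function(n, kappa) {
  (rVonMises(n, 0, kappa) / 2) %% pi
}

# Smallest axial angular distance (degrees, period 180).
axialDistance <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

clamp <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

asImage <- function(x) EBImage::Image(x)
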