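# Shared in-code fixtures; everything is generated at test time.

# Regular n-gon outline of given radius.
regularPolygon <- function(n, r = 1, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Axis-aligned rectangle outline with prescribed circularity
# (CI = pi * r / (1 + r)^2 for aspect r solves to a closed form).
rectangleForCI <- function(ci, scale = 10) {
  stopifnot(ci > 0, ci <= pi / 4)
  disc <- (pi - 2 * ci)^2 - 4 * ci^2
  r <- ((pi - 2 * ci) - sqrt(disc)) / (2 * ci)
  rbind(c(0, 0), c(scale, 0), c(scale, scale * r), c(0, scale * r))
}

# Sinusoidal grating whose stripes run at `angleDeg` from the x axis.
gratingImage <- function(angleDeg, size = 128, period = 8) {
  a <- angleDeg * pi / 180
  outer(seq_len(size), seq_len(size), function(x, y)
    sin(2 * pi * (-x * sin(a) + y * cos(a)) / period))
}

# Multi-component test pattern sampled on (optionally rotated) coordinates;
# rotating the sampling grid is an exact, border-free image rotation.
patternImage <- function(size = 192, rotateDeg = 0) {
  a <- rotateDeg * pi / 180
  cen <- (size + 1) / 2
  outer(seq_len(size), seq_len(size), function(x, y) {
    u <- cos(a) * (x - cen) + sin(a) * (y - cen)
    v <- -sin(a) * (x - cen) + cos(a) * (y - cen)
    sin(2 * pi * v / 7) + 0.6 * sin(2 * pi * (0.45 * u + 0.9 * v) / 11)
  })
}

# Brute-force lattice search for the exponential-law least squares.
gridSearchFung <- function(eps, sig, alphaRange, betaRange, n = 61) {
  alphas <- exp(seq(log(alphaRange[1]), log(alphaRange[2]),
                    length.out = n))
  betas <- seq(betaRange[1], betaRange[2], length.out = n)
  best <- c(NA, NA, Inf)
  for (a in alphas) for (b in betas) {
    sse <- sum((sig - a * (exp(b * eps) - 1))^2)
    if (sse < best[3]) best <- c(a, b, sse)
  }
  list(alpha = best[1], beta = best[2],
       dAlpha = diff(log(alphaRange)) / (n - 1),
       dBeta = diff(betaRange) / (n - 1))
}

# Independent bisection solve of the two-post equilibrium in v.
bisectTwoPost <- function(k, model, s0, d, tol = 1e-12) {
  f <- function(v) {
    lam <- (s0 + 2 * d - 2 * v) / s0
    model@alpha * (exp(model@beta * (lam - 1)) - 1) * model@width *
      model@thickness - k * v
  }
  lo <- 0; hi <- d
  if (f(lo) <= 0) return(0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
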