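#' Ordinary least-squares linear trend
#'
#' The shared trend fit used for circularity and alignment trajectories:
#' slope, intercept and r-squared of y regressed on x. Exact on affine data.
#'
#' @param x,y numeric vectors of equal length, >= 2 distinct x values.
#' @return list with `slope`, `intercept`, `rSquared`.
#' @examples
#' linearTrend(1:5, 3 - 0.3 * (1:5))$slope
#' @export
linearTrend <- function(x, y) {
  stopIfNot(length(x) == length(y) && length(x) >= 2,
            "x and y must have equal length >= 2", "insufficientDataError")
  stopIfNot(length(unique(x)) >= 2, "all x values are equal",
            "degenerateDesignError")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::resid(fit)^2) / ssTot else 1
  list(slope = unname(cf[2]), intercept = unname(cf[1]), rSquared = r2)
}

# Insert-and-absorb compact letter display. sigPairs: 2-column matrix of
# group indices that differ significantly. Groups are processed in the
# given order (descending mean, ties by label).
compactLetters <- function(nGroups, sigPairs) {
  sets <- list(seq_len(nGroups))
  if (nrow(sigPairs)) {
    for (k in seq_len(nrow(sigPairs))) {
      i <- sigPairs[k, 1]; j <- sigPairs[k, 2]
      for (s in seq_along(sets)) {
        if (all(c(i, j) %in% sets[[s]])) {
          a <- setdiff(sets[[s]], i)
          b <- setdiff(sets[[s]], j)
          sets[[s]] <- a
          sets[[length(sets) + 1]] <- b
        }
      }
      # absorb sets contained in another
      drop <- rep(FALSE, length(sets))
      for (s in seq_along(sets)) {
        for (t in seq_along(sets)) {
          if (s != t && !drop[t] && all(sets[[s]] %in% sets[[t]]) &&
              (length(sets[[s]]) < length(sets[[t]]) || s > t))
            drop[s] <- TRUE
        }
      }
      sets <- sets[!drop]
    }
  }
  # deterministic letter order: sets sorted by their smallest member
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letters_out <- rep("", nGroups)
  for (s in seq_along(sets)) {
    ch <- letters[(s - 1) %% 26 + 1]
    if (s > 26) ch <- paste0(ch, (s - 1) %/% 26)
    for (g in sets[[s]]) letters_out[g] <- paste0(letters_out[g], ch)
  }
  letters_out
}

#' One-way ANOVA with Tukey HSD post hoc and compact letter display
#'
#' Omnibus one-way ANOVA followed by all-pairs Tukey HSD (Tukey-Kramer for
#' unequal group sizes), with each group assigned compact letters: groups
#' sharing no letter differ at level `alpha`. Letters are deterministic:
#' groups are ordered by descending mean (ties by label order) before the
#' insert-and-absorb assignment.
#'
#' @param values numeric response values.
#' @param groups group labels, same length as `values`; >= 2 groups with
#'   >= 2 values each.
#' @param alpha significance level (default 0.05).
#' @param logTransform optionally log-transform the response first (a
#'   variance-stabilizing option; default FALSE).
#' @return a [ComparisonResult-class] with the F statistic, omnibus p,
#'   the Tukey pair table and per-group letters.
#' @examples
#' v <- c(1, 1.2, 0.9, 5, 5.3, 4.8, 1.1, 0.8, 1.3)
#' g <- rep(c("a", "b", "c"), each = 3)
#' oneWayAnovaTukey(v, g)
#' @export
oneWayAnovaTukey <- function(values, groups, alpha = 0.05,
                             logTransform = FALSE) {
  stopIfNot(length(values) == length(groups),
            "values and groups must have equal length",
            "insufficientDataError")
  g <- factor(groups)
  stopIfNot(nlevels(g) >= 2, "need at least 2 groups",
            "insufficientDataError")
  stopIfNot(all(table(g) >= 2), "every group needs at least 2 values",
            "insufficientDataError")
  y <- if (logTransform) log(values) else values
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  Fstat <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairNames <- rownames(tuk)
  pr <- do.call(rbind, strsplit(pairNames, "-", fixed = TRUE))
  pairs <- data.frame(group1 = pr[, 1], group2 = pr[, 2],
                      diff = tuk[, "diff"], lwr = tuk[, "lwr"],
                      upr = tuk[, "upr"], pAdj = tuk[, "p adj"],
                      row.names = NULL)
  means <- tapply(y, g, mean)
  ord <- order(-means, levels(g))
  lev <- levels(g)[ord]
  sig <- pairs[pairs$pAdj < alpha, , drop = FALSE]
  sigIdx <- cbind(match(sig$group1, lev), match(sig$group2, lev))
  if (nrow(sigIdx)) {
    sigIdx <- t(apply(sigIdx, 1, sort))
    sigIdx <- sigIdx[order(sigIdx[, 1], sigIdx[, 2]), , drop = FALSE]
  }
  let <- compactLetters(nlevels(g), sigIdx)
  back <- match(levels(g), lev)
  new("ComparisonResult", test = "one-way ANOVA + Tukey HSD",
      statistic = Fstat, pValue = p, df = c(an[["Df"]][1], an[["Df"]][2]),
      alpha = alpha, groups = levels(g), letters = let[back], pairs = pairs)
}

#' Two-sample Student's t-test
#'
#' Classic pooled-variance two-sided Student's t-test (Welch's correction
#' available by flag). Identical samples give t = 0, p = 1; zero pooled
#' variance with unequal means is flagged as degenerate.
#'
#' @param a,b numeric samples, each with >= 2 values.
#' @param alpha significance level (default 0.05).
#' @param welch use the Welch unequal-variance form (default FALSE).
#' @return a [ComparisonResult-class]; `pairs` holds one row with the mean
#'   difference and a `significant` flag at `alpha`.
#' @examples
#' twoSampleT(c(1, 2, 3), c(2, 3, 4))
#' @export
twoSampleT <- function(a, b, alpha = 0.05, welch = FALSE) {
  stopIfNot(length(a) >= 2 && length(b) >= 2,
            "each sample needs at least 2 values", "insufficientDataError")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(statistic = 0, p.value = 1,
                  parameter = length(a) + length(b) - 2)
    } else {
      stopIfNot(FALSE,
                "zero pooled variance with unequal means",
                "degenerateVarianceError")
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
    res <- list(statistic = unname(tt$statistic), p.value = tt$p.value,
                parameter = unname(tt$parameter))
  }
  pairs <- data.frame(group1 = "a", group2 = "b",
                      diff = mean(a) - mean(b),
                      pAdj = res$p.value,
                      significant = res$p.value < alpha)
  new("ComparisonResult",
      test = if (welch) "Welch two-sample t" else "Student's two-sample t",
      statistic = res$statistic, pValue = res$p.value, df = res$parameter,
      alpha = alpha, groups = c("a", "b"), letters = character(0),
      pairs = pairs)
}
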