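#' Built-in stain color-classification profiles
#'
#' Returns the editable default [StainProfile-class] for a supported
#' stain. The rules encode how each constituent is isolated before
#' thresholding:
#' \describe{
#'   \item{movat}{collagen via the CMYK yellow channel; GAGs via the
#'     blue-minus-red RGB difference.}
#'   \item{trichrome}{connective tissue via the blue-minus-red RGB
#'     difference (all blue-stained pixels; whether nuclei should be
#'     excluded is an assumption, adjustable through the rule).}
#'   \item{vvg}{elastin via inverted luminance (stain darkness).}
#' }
#' Each rule's `threshold` is `"otsu"` by default and may be overridden
#' with a fixed value in \[0,1\].
#'
#' @param stain one of `"movat"`, `"trichrome"`, `"vvg"`.
#' @return a [StainProfile-class].
#' @examples
#' stainProfile("movat")
#' @export
stainProfile <- function(stain = c("movat", "trichrome", "vvg")) {
  stain <- match.arg(stain)
  rules <- switch(stain,
    movat = list(
      collagen = list(space = "cmyk", channel = "y", threshold = "otsu"),
      gag = list(space = "rgb_diff", channels = c("b", "r"),
                 threshold = "otsu")),
    trichrome = list(
      connective_tissue = list(space = "rgb_diff", channels = c("b", "r"),
                               threshold = "otsu")),
    vvg = list(
      elastin = list(space = "inv_luminance", threshold = "otsu")))
  new("StainProfile", stainName = stain, rules = rules)
}

#' Read / write a stain profile as YAML
#'
#' @param path YAML path.
#' @param profile a [StainProfile-class].
#' @return `readStainProfile` returns a [StainProfile-class];
#'   `writeStainProfile` returns the path invisibly.
#' @export
readStainProfile <- function(path) {
  y <- yaml::read_yaml(path)
  stopIfNot(!is.null(y$stain) && !is.null(y$rules),
            "profile YAML needs 'stain' and 'rules'", "configError")
  rules <- lapply(y$rules, function(r) {
    if (!is.null(r$channels)) r$channels <- as.character(r$channels)
    r
  })
  new("StainProfile", stainName = y$stain, rules = rules)
}

#' @rdname readStainProfile
#' @export
writeStainProfile <- function(profile, path) {
  yaml::write_yaml(list(stain = profile@stainName, rules = profile@rules),
                   path)
  invisible(path)
}

# Scalar channel image per rule, in [0,1]-ish range suitable for Otsu.
ruleChannel <- function(rgb, rule) {
  R <- rgb[, , 1]; G <- rgb[, , 2]; B <- rgb[, , 3]
  switch(rule$space,
    cmyk = {
      K <- 1 - pmax(R, pmax(G, B))
      chan <- match(tolower(rule$channel), c("c", "m", "y", "k"))
      stopIfNot(!is.na(chan), "unknown CMYK channel", "configError")
      if (chan == 4) K else {
        prim <- list(R, G, B)[[chan]]
        out <- (1 - prim - K) / (1 - K + 1e-9)
        out[K > 1 - 1e-6] <- 0
        clamp(out, 0, 1)
      }
    },
    rgb_diff = {
      pick <- function(ch) switch(tolower(ch), r = R, g = G, b = B,
                                  stopIfNot(FALSE, "unknown RGB channel",
                                            "configError"))
      clamp(pick(rule$channels[1]) - pick(rule$channels[2]), 0, 1)
    },
    inv_luminance = clamp(1 - (0.299 * R + 0.587 * G + 0.114 * B), 0, 1))
}

#' Split a stained RGB image into per-constituent masks
#'
#' For every constituent in the profile the image is reduced to the rule's
#' grayscale channel (CMYK channel, RGB channel difference, or inverted
#' luminance) and thresholded (Otsu by default, fixed-value override via
#' the rule) into a binary mask.
#'
#' @param image RGB array `[x, y, 3]` in \[0,1\], or a
#'   [HistologySlide-class].
#' @param profile a [StainProfile-class].
#' @return named list of logical masks, one per constituent.
#' @export
splitConstituents <- function(image, profile) {
  if (is(image, "HistologySlide")) image <- image@rgb
  stopIfNot(is.array(image) && length(dim(image)) == 3 &&
              dim(image)[3] == 3,
            "image must be an RGB array [x, y, 3]", "configError")
  stopIfNot(is(profile, "StainProfile"), "profile must be a StainProfile",
            "configError")
  validObject(profile)
  out <- list()
  for (nm in names(profile@rules)) {
    rule <- profile@rules[[nm]]
    chan <- ruleChannel(image, rule)
    th <- if (identical(rule$threshold, "otsu")) {
      # signal floor: stain colors are saturated in their rule channel, so
      # a channel whose bright tail stays below 0.25 holds no constituent
      # and Otsu would only split background noise
      if (stats::quantile(chan, 0.99) < 0.25) Inf
      else EBImage::otsu(asImage(chan), range = c(0, 1))
    } else as.numeric(rule$threshold)
    out[[nm]] <- chan > th
  }
  out
}

#' Leaflet-normalized constituent area fractions
#'
#' Computes per-constituent fractions \eqn{|mask \cap leaflet| /
#' |leaflet|} and attaches the collagen/GAG fractional ratio when both
#' constituents are present (flagged undefined, with an NA ratio, when the
#' GAG fraction is zero).
#'
#' @param masks named list of logical constituent masks.
#' @param leafletMask logical leaflet mask of the same shape, nonempty.
#' @return a [CompositionFractions-class].
#' @export
areaFractions <- function(masks, leafletMask) {
  stopIfNot(is.matrix(leafletMask) && any(leafletMask),
            "leaflet mask is empty", "invalidMaskError")
  stopIfNot(length(masks) >= 1 && !is.null(names(masks)),
            "masks must be a named list", "invalidMaskError")
  A <- sum(leafletMask)
  fr <- vapply(masks, function(m) {
    stopIfNot(identical(dim(m), dim(leafletMask)),
              "mask and leaflet shapes differ", "invalidMaskError")
    sum(m & leafletMask) / A
  }, numeric(1))
  ratio <- NA_real_
  defined <- FALSE
  if (all(c("collagen", "gag") %in% names(fr))) {
    if (fr[["gag"]] > 0) {
      ratio <- fr[["collagen"]] / fr[["gag"]]
      defined <- TRUE
    }
  }
  new("CompositionFractions", fractions = fr, leafletArea = A,
      collagenGagRatio = ratio, ratioDefined = defined)
}

#' Normalize specimen fractions to a reference group
#'
#' Divides every specimen's value by the reference-group mean, so the
#' reference group has relative mean exactly 1 (the wild-type-scaled
#' convention for reporting relative matrix fractions).
#'
#' @param values numeric per-specimen fractions.
#' @param groups group label per specimen.
#' @param reference the reference group label.
#' @return numeric vector of relative values, same order as `values`.
#' @examples
#' normalizeToReference(c(0.3, 0.32, 0.15, 0.14),
#'                      c("wt", "wt", "mut", "mut"), "wt")
#' @export
normalizeToReference <- function(values, groups, reference) {
  stopIfNot(length(values) == length(groups),
            "values and groups must have equal length", "normalizationError")
  ref <- values[groups == reference]
  stopIfNot(length(ref) > 0, "reference group is empty",
            "normalizationError")
  m <- mean(ref)
  stopIfNot(is.finite(m) && m != 0, "reference group mean is zero",
            "normalizationError")
  values / m
}

#' Write a composition table to CSV
#'
#' Writes the standard schema
#' `specimen_id,stain,constituent,fraction,ratio_collagen_gag` (the ratio
#' column is repeated on each constituent row of a specimen, NA when
#' undefined).
#'
#' @param compositions named list of [CompositionFractions-class]
#'   (names = specimen ids).
#' @param stain stain name recorded in the table.
#' @param path CSV path.
#' @return the table, invisibly.
#' @export
writeCompositionTable <- function(compositions, stain, path) {
  tab <- do.call(rbind, lapply(names(compositions), function(id) {
    cf <- compositions[[id]]
    data.frame(specimen_id = id, stain = stain,
               constituent = names(cf@fractions),
               fraction = unname(cf@fractions),
               ratio_collagen_gag = if (cf@ratioDefined)
                 cf@collagenGagRatio else NA_real_)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
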