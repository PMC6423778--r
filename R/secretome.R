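#' Spot densitometry on a membrane image
#'
#' For every spot in the layout: integrated intensity over the spot disc
#' minus `disc area x local background`, where the local background is the
#' median intensity in an annulus of inner radius r and outer radius 2r
#' around the spot center. When the annulus would overlap another spot's
#' disc, that spot falls back to the global image median with a warning.
#' Negative densities are clipped to 0.
#'
#' @param img intensity matrix (rows = y, cols = x).
#' @param layout a [membrane_layout()] within image bounds.
#' @return data.frame: `analyte`, `is_reference`, `raw_density` per spot.
#' @export
quantify_spots <- function(img, layout) {
  h <- nrow(img); w <- ncol(img)
  if (any(layout$x - layout$radius < 1) || any(layout$y - layout$radius < 1) ||
      any(layout$x + layout$radius > w) || any(layout$y + layout$radius > h))
    stop("layout outside image bounds")
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  global_med <- stats::median(img)
  ctr <- as.matrix(layout[, c("x", "y")])
  dens <- numeric(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    r <- layout$radius[i]
    d2 <- (xs - layout$x[i])^2 + (ys - layout$y[i])^2
    disc <- d2 <= r^2
    # annulus is unusable if any other spot disc comes within 2r of center
    others <- sqrt((ctr[, 1] - layout$x[i])^2 + (ctr[, 2] - layout$y[i])^2)
    others[i] <- Inf
    clash <- any(others < 2 * r + layout$radius)
    if (clash) {
      warning("annulus of spot ", layout$analyte[i],
              " overlaps a neighbouring disc; using global median background")
      bg <- global_med
    } else {
      ann <- d2 > r^2 & d2 <= (2 * r)^2
      bg <- stats::median(img[ann])
    }
    dens[i] <- max(sum(img[disc]) - sum(disc) * bg, 0)
  }
  data.frame(analyte = layout$analyte, is_reference = layout$is_reference,
             raw_density = dens, stringsAsFactors = FALSE)
}

#' Express raw spot densities as percent of the reference-spot intensity
#'
#' Duplicate spots of the same analyte are averaged at the raw-density
#' stage; the three reference spots are averaged into the 100% level, and
#' every analyte is reported as `100 x density / reference mean`.
#'
#' @param raw data.frame from [quantify_spots()].
#' @return named numeric vector analyte -> percent (references excluded).
#' @export
percent_of_reference <- function(raw) {
  refs <- raw$raw_density[raw$is_reference]
  if (length(refs) == 0) stop("no reference spots in layout")
  ref_mean <- mean(refs)
  if (ref_mean <= 0) stop("all reference densities <= 0: failed membrane")
  an <- raw[!raw$is_reference, , drop = FALSE]
  dens <- tapply(an$raw_density, an$analyte, mean)
  out <- 100 * as.numeric(dens) / ref_mean
  names(out) <- names(dens)
  out[unique(an$analyte)]
}

#' Secretion class from a percent-of-reference value
#'
#' Strictly above 20% of reference is `abundant`, strictly above 5% is
#' `secreted`, otherwise `not_secreted` (5 and 20 themselves fall in the
#' lower class).
#'
#' @param percent nonnegative percent-of-reference value(s).
#' @return character vector of classes (vectorized).
#' @export
classify_secretion <- function(percent) {
  if (any(percent < 0)) stop("percent must be nonnegative")
  ifelse(percent > 20, "abundant",
         ifelse(percent > 5, "secreted", "not_secreted"))
}

#' Full per-membrane cytokine profile
#'
#' Convenience composition of [quantify_spots()], [percent_of_reference()]
#' and [classify_secretion()].
#'
#' @param img intensity matrix.
#' @param layout a [membrane_layout()].
#' @return data.frame of class `cytokine_profile`: `analyte`,
#'   `raw_density`, `percent`, `class`, plus attribute `reference_percents`
#'   (each reference spot as percent of the reference mean).
#' @export
cytokine_profile <- function(img, layout) {
  raw <- quantify_spots(img, layout)
  pct <- percent_of_reference(raw)
  an <- raw[!raw$is_reference, , drop = FALSE]
  dens <- tapply(an$raw_density, an$analyte, mean)[names(pct)]
  out <- data.frame(analyte = names(pct), raw_density = as.numeric(dens),
                    percent = unname(pct),
                    class = classify_secretion(unname(pct)),
                    stringsAsFactors = FALSE)
  attr(out, "reference_percents") <-
    100 * raw$raw_density[raw$is_reference] /
    mean(raw$raw_density[raw$is_reference])
  class(out) <- c("cytokine_profile", "data.frame")
  out
}

#' Shared and exclusive analytes across cytokine profiles
#'
#' An analyte is shared when its class reaches `class_floor` in every
#' preparation, and exclusive to a preparation when it reaches the floor
#' there and nowhere else. Profiles must share one analyte panel.
#'
#' @param profiles named list of `cytokine_profile` objects.
#' @param class_floor `"secreted"` or `"abundant"`.
#' @return list with `shared` (character vector) and `exclusive`
#'   (named list preparation -> character vector).
#' @export
compare_profiles <- function(profiles, class_floor = c("abundant", "secreted")) {
  class_floor <- match.arg(class_floor)
  if (length(profiles) < 2) stop("need >= 2 profiles to compare")
  panels <- lapply(profiles, function(p) sort(p$analyte))
  if (!all(vapply(panels[-1], identical, logical(1), panels[[1]])))
    stop("profiles do not share one analyte panel (mismatched layouts?)")
  rank <- c(not_secreted = 0, secreted = 1, abundant = 2)
  floor_rank <- rank[[class_floor]]
  above <- vapply(profiles, function(p) {
    rank[p$class[match(panels[[1]], p$analyte)]] >= floor_rank
  }, logical(length(panels[[1]])))
  if (length(panels[[1]]) == 1L) above <- matrix(above, nrow = 1)
  rownames(above) <- panels[[1]]
  shared <- panels[[1]][rowSums(above) == length(profiles)]
  exclusive <- lapply(seq_along(profiles), function(j)
    panels[[1]][above[, j] & rowSums(above[, -j, drop = FALSE]) == 0])
  names(exclusive) <- names(profiles)
  list(shared = shared, exclusive = exclusive)
}
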