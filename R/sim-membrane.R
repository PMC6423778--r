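#' Grid layout of a cytokine-array membrane
#'
#' Builds a rectangular spot grid with exactly three reference spots in the
#' upper-left, lower-left and lower-right grid corners (the convention of
#' membrane cytokine arrays, where reference spots define the 100% intensity
#' scale) and one spot per analyte in the remaining cells, row-major.
#'
#' @param analytes character vector of analyte names; must fit into
#'   `n_rows * n_cols - 3` cells.
#' @param n_rows,n_cols grid dimensions.
#' @param pitch center-to-center spot spacing in pixels.
#' @param margin distance from image border to the first spot center.
#' @param radius spot radius in pixels; discs must be pairwise disjoint,
#'   so `2 * radius < pitch` is required.
#' @return a data.frame of class `membrane_layout` with columns `analyte`,
#'   `row`, `col`, `x`, `y`, `radius`, `is_reference`.
#' @export
membrane_layout <- function(analytes, n_rows = 4, n_cols = 6,
                            pitch = 40, margin = 30, radius = 8) {
  if (2 * radius >= pitch) stop("spot discs overlap: need 2 * radius < pitch")
  n_cells <- n_rows * n_cols
  if (length(analytes) > n_cells - 3)
    stop("too many analytes for the grid (3 cells are reference spots)")
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))[, 2:1]
  ref_cells <- c(which(grid$row == 1 & grid$col == 1),
                 which(grid$row == n_rows & grid$col == 1),
                 which(grid$row == n_rows & grid$col == n_cols))
  nm <- rep(NA_character_, n_cells)
  nm[ref_cells] <- "REFERENCE"
  nm[setdiff(seq_len(n_cells), ref_cells)[seq_along(analytes)]] <- analytes
  keep <- !is.na(nm)
  out <- data.frame(analyte = nm[keep],
                    row = grid$row[keep], col = grid$col[keep],
                    x = margin + (grid$col[keep] - 1) * pitch,
                    y = margin + (grid$row[keep] - 1) * pitch,
                    radius = radius,
                    is_reference = nm[keep] == "REFERENCE",
                    stringsAsFactors = FALSE)
  class(out) <- c("membrane_layout", "data.frame")
  out
}

#' Read / write a membrane layout as CSV
#' @param layout a `membrane_layout`.
#' @param path CSV file path.
#' @export
write_membrane_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_membrane_layout
#' @export
read_membrane_layout <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("membrane_layout", "data.frame")
  out
}

#' Render a synthetic cytokine-array membrane image
#'
#' Each spot is a radially symmetric Gaussian blob (sd = radius / 3.5, so
#' over 99% of the blob's mass lies inside the spot disc) whose integrated
#' intensity is `abundance * gain`, on a constant background plus optional
#' Gaussian pixel noise. Reference spots are rendered at the fixed abundance
#' `ref_abundance`, which therefore defines the 100% scale of
#' [percent_of_reference()].
#'
#' @param profile named numeric vector analyte -> abundance (on the scale
#'   where `ref_abundance` is the reference level); analytes missing from
#'   the profile are rendered at abundance 0.
#' @param layout a [membrane_layout()]; spot discs must lie inside the image.
#' @param seed integer seed for the pixel noise.
#' @param width,height image size in pixels; default fits the layout.
#' @param background constant background level, intensity units.
#' @param noise_sd per-pixel Gaussian noise sd (0 = noise-free render).
#' @param gain integrated intensity of a spot at abundance 1.
#' @param ref_abundance abundance at which reference spots are rendered.
#' @return numeric matrix (rows = y, cols = x) of nonnegative intensities.
#' @export
generate_membrane <- function(profile, layout, seed = 1L,
                              width = NULL, height = NULL,
                              background = 1000, noise_sd = 2,
                              gain = 2e4, ref_abundance = 1) {
  stopifnot(inherits(layout, "membrane_layout") || is.data.frame(layout))
  if (is.null(width)) width <- max(layout$x + layout$radius) + 20
  if (is.null(height)) height <- max(layout$y + layout$radius) + 20
  if (any(layout$x - layout$radius < 1) || any(layout$y - layout$radius < 1) ||
      any(layout$x + layout$radius > width) ||
      any(layout$y + layout$radius > height))
    stop("layout positions outside image bounds")
  dmat <- as.matrix(stats::dist(layout[, c("x", "y")]))
  diag(dmat) <- Inf
  if (any(dmat < outer(layout$radius, layout$radius, "+")))
    stop("overlapping spot discs in layout")
  set.seed(seed)
  img <- matrix(background, nrow = height, ncol = width)
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  for (i in seq_len(nrow(layout))) {
    ab <- if (layout$is_reference[i]) ref_abundance
          else if (layout$analyte[i] %in% names(profile))
            profile[[layout$analyte[i]]] else 0
    if (ab == 0) next
    s <- layout$radius[i] / 3.5
    blob <- ab * gain / (2 * pi * s^2) *
      exp(-((xs - layout$x[i])^2 + (ys - layout$y[i])^2) / (2 * s^2))
    img <- img + blob
  }
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow = height)
  pmax(img, 0)
}

#' Write / read a membrane image as 16-bit grayscale TIFF
#'
#' Intensities are scaled by `max_intensity` into [0, 1] and stored at 16
#' bits per sample, so one grey level corresponds to one intensity unit at
#' the default scale (8-bit storage would quantize faint spots away).
#'
#' @param img nonnegative intensity matrix.
#' @param path TIFF path.
#' @param max_intensity full-scale value mapped to 65535.
#' @export
write_membrane_image <- function(img, path, max_intensity = 65535) {
  # quantize by rounding; the TIFF writer itself truncates, which would
  # bias every pixel down by half a grey level
  q <- round(pmin(img / max_intensity, 1) * 65535) / 65535
  tiff::writeTIFF(q, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_membrane_image
#' @export
read_membrane_image <- function(path, max_intensity = 65535) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * max_intensity
}
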