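#' @useDynLib osteopose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a validated bone cross-section object
#'
#' A `section_image` bundles a binary raster mask of a mid-diaphyseal bone
#' cross-section (1 = mineralised bone pixel, 0 = background, medulla or
#' vascular space) with its pixel resolution and specimen metadata. All
#' compactness and geometry measurements operate on this object.
#'
#' @param mask integer or logical matrix containing only 0/1 (or FALSE/TRUE).
#' @param resolution pixel size in micrometres per pixel; must be positive.
#' @param side `"left"` or `"right"` femur. Left sections should be passed
#'   through [mirror_section()] before measurement so the sample is
#'   consistently right-sided.
#' @param taxon optional taxon label.
#' @param bone_length optional bone length in millimetres (needed for the
#'   slenderness ratio).
#' @return an object of class `section_image`.
#' @seealso [load_section()], [mirror_section()], [medullary_centre()]
#' @export
section_image <- function(mask, resolution, side = c("right", "left"),
                          taxon = NA_character_, bone_length = NA_real_) {
  side <- match.arg(side)
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  storage.mode(mask) <- "integer"
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0L, 1L))) {
    stop("mask contains values other than 0/1; threshold the image first")
  }
  if (!any(mask == 1L)) stop("empty mask: no bone pixels")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    stop("`resolution` must be a single positive number (um/px)")
  }
  structure(
    list(mask = mask, resolution = resolution, side = side,
         taxon = taxon, bone_length = bone_length),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat("<section_image> ", dim(x$mask)[1], "x", dim(x$mask)[2],
      " px, ", x$resolution, " um/px, side=", x$side,
      if (!is.na(x$taxon)) paste0(", taxon=", x$taxon), "\n", sep = "")
  cat("  bone pixels: ", sum(x$mask), " (",
      round(100 * mean(x$mask), 1), "% of frame)\n", sep = "")
  invisible(x)
}

#' Load a thresholded cross-section raster
#'
#' Reads a single-channel PNG or TIFF mask. Values must be binarisable:
#' either already 0/1, or 0/255-style two-level images. Grey-level images
#' are rejected unless an explicit `threshold` is supplied, in which case
#' pixels with intensity strictly above the threshold (on the 0-1 scale
#' used by the readers) become bone.
#'
#' @param path file path to a `.png`, `.tif` or `.tiff` image.
#' @param resolution micrometres per pixel.
#' @param side `"left"` or `"right"`.
#' @param threshold optional threshold in \[0, 1) for non-binary input.
#' @param taxon,bone_length metadata passed to [section_image()].
#' @return a `section_image`.
#' @export
load_section <- function(path, resolution, side = c("right", "left"),
                         threshold = NULL, taxon = NA_character_,
                         bone_length = NA_real_) {
  side <- match.arg(side)
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel
  vals <- sort(unique(as.vector(img)))
  if (is.null(threshold)) {
    if (length(vals) > 2L) {
      stop("non-binary input in ", path,
           ": supply an explicit `threshold`")
    }
    mask <- (img == max(vals)) * 1L
    if (length(vals) == 1L && vals[1] == 0) {
      stop("empty mask (no bone pixels) in ", path)
    }
  } else {
    mask <- (img > threshold) * 1L
  }
  if (!any(mask == 1L)) stop("empty mask (no bone pixels) in ", path)
  section_image(mask, resolution, side, taxon = taxon,
                bone_length = bone_length)
}

#' Write a section mask to disk
#'
#' Writes the 0/1 mask as an 8-bit single-channel PNG (0/255), the exact
#' inverse of [load_section()]: a write-then-read round trip reproduces the
#' mask bit for bit.
#'
#' @param s a `section_image`.
#' @param path output path ending in `.png`.
#' @export
write_section <- function(s, path) {
  stopifnot(inherits(s, "section_image"))
  png::writePNG(matrix(as.numeric(s$mask), nrow(s$mask)), path)
  invisible(path)
}

#' Mirror a left section into right-side convention
#'
#' Left femora are mirrored across the vertical axis and relabelled right so
#' that the whole sample is consistently sided; right sections pass through
#' unchanged. All section parameters are reflection-invariant, so mirroring
#' only matters for consistency of orientation-bearing outputs.
#'
#' @param s a `section_image`.
#' @return a `section_image` with `side == "right"`.
#' @export
mirror_section <- function(s) {
  stopifnot(inherits(s, "section_image"))
  if (s$side == "right") return(s)
  s$mask <- s$mask[, rev(seq_len(ncol(s$mask))), drop = FALSE]
  s$side <- "right"
  s
}

# Interior decomposition shared by the compactness and geometry modules.
# Non-bone connected components (4-connectivity) that do not touch the frame
# border are enclosed by the outer boundary: the largest is the medulla,
# smaller ones are vascular canals. Returns the filled section mask
# (bone + all enclosed space) and the enclosed-component labels.
section_interior <- function(s) {
  m <- s$mask == 1L
  lab <- cc_label(!m)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0L]
  enclosed <- lab
  enclosed[enclosed %in% border] <- 0L
  filled <- m | enclosed > 0L
  list(filled = filled, enclosed = enclosed)
}

#' Locate the medullary centre of a cross-section
#'
#' The medulla is taken to be the largest connected component (4-connectivity)
#' of non-bone pixels enclosed by the outer boundary of the section; its pixel
#' centroid anchors the radial compactness analysis. Solid sections without
#' any enclosed cavity fall back to the centroid of the bone pixels, flagged
#' as degenerate.
#'
#' @param s a `section_image`.
#' @return list with `centre` (length-2 numeric, row/col pixel-centre
#'   coordinates, 1-based), `degenerate` flag, and `medulla_px`, the pixel
#'   count of the medullary component (0 when degenerate).
#' @export
medullary_centre <- function(s) {
  stopifnot(inherits(s, "section_image"))
  interior <- section_interior(s)
  enc <- interior$enclosed
  if (any(enc > 0L)) {
    sizes <- tabulate(enc[enc > 0L])
    med <- which.max(sizes)
    idx <- which(enc == med, arr.ind = TRUE)
    list(centre = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
         degenerate = FALSE, medulla_px = nrow(idx))
  } else {
    idx <- which(s$mask == 1L, arr.ind = TRUE)
    list(centre = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
         degenerate = TRUE, medulla_px = 0L)
  }
}
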