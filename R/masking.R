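#' Downscale a section image to a working width
#'
#' H&E rasters are reduced to a fixed working width (default 400 px) with
#' retained aspect ratio before masking and registration; this keeps memory
#' use small without hurting tissue/background separation. An image already
#' at or below the target width is returned unchanged. The image scale is
#' updated so that full-resolution spot coordinates keep mapping correctly
#' into the downscaled raster.
#'
#' @param img a [section_image()].
#' @param target_width working width in pixels (default 400).
#' @return A [section_image()] of width `target_width` (or the input).
#' @export
downscale_image <- function(img, target_width = 400) {
  stopifnot(inherits(img, "section_image"))
  if (!is.numeric(target_width) || length(target_width) != 1 ||
      target_width < 16) {
    stop("target_width must be a single integer >= 16")
  }
  d <- dim(img$pixels)
  H <- d[1]; W <- d[2]
  if (W <= target_width) return(img)
  factor <- target_width / W
  new_h <- max(1L, as.integer(round(H * factor)))
  ebi <- EBImage::Image(aperm(img$pixels, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(ebi, w = target_width, h = new_h, filter = "bilinear",
                         antialias = TRUE)
  px <- aperm(EBImage::imageData(out), c(2, 1, 3))
  px[px < 0] <- 0
  px[px > 1] <- 1
  section_image(img$section_id, px, scale = img$scale * factor)
}

#' Otsu threshold of a grayscale raster
#'
#' Returns the gray level maximizing the between-class variance of the
#' 256-bin histogram — the classic bimodal-histogram threshold used to
#' separate stained tissue from the bright array background.
#'
#' @param gray numeric matrix with values in `[0, 1]`.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold, a scalar strictly inside the observed value range.
#' @export
otsu_threshold <- function(gray, n_bins = 256) {
  v <- as.numeric(gray)
  stopifnot(all(is.finite(v)))
  if (length(unique(v)) < 2) {
    stop("degenerate image: constant gray level, no threshold exists")
  }
  breaks <- seq(0, 1, length.out = n_bins + 1)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  omega <- cumsum(p)                  # class-0 mass at threshold after bin t
  mu <- cumsum(p * mids)
  mu_total <- mu[n_bins]
  # between-class variance for a cut after each bin
  denom <- omega * (1 - omega)
  sigma_b <- (mu_total * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  # for well-separated modes the maximum is flat across the empty gap;
  # take the middle of the maximal plateau, as canonical implementations do
  peak <- which(abs(sigma_b - max(sigma_b, na.rm = TRUE)) < 1e-15)
  t_idx <- round(mean(peak))
  breaks[t_idx + 1]
}

#' SLIC superpixel segmentation
#'
#' Simple Linear Iterative Clustering: a local k-means over combined color
#' and position, yielding compact, color-homogeneous segments. The distance
#' is `dc^2 + (ds/S)^2 * compactness^2` where `S` is the expected segment
#' spacing; small disconnected fragments are merged into an adjacent segment
#' so every segment is spatially connected.
#'
#' @param img a [section_image()] or an H x W (x C) numeric array.
#' @param n_segments requested number of segments (the result has at most
#'   this many non-empty, connected segments).
#' @param compactness weight of spatial vs color distance; higher gives more
#'   regular, squarer segments (default 10, with channel values in `[0,1]`
#'   scaled to a 0-100 range internally so the default behaves like the
#'   usual Lab-space setting).
#' @param max_iter number of assignment/update sweeps (default 10).
#' @return A list with `pixels` (H x W integer matrix of segment ids,
#'   `1..n_segments`) and `n_segments` (the realized count), class
#'   `superpixel_labels`.
#' @export
slic_superpixels <- function(img, n_segments, compactness = 10,
                             max_iter = 10) {
  px <- if (inherits(img, "section_image")) img$pixels else img
  if (length(dim(px)) == 2) px <- array(px, dim = c(dim(px), 1))
  d <- dim(px)
  n_pix <- d[1] * d[2]
  if (!is.numeric(n_segments) || n_segments < 2 || n_segments > n_pix) {
    stop("n_segments must be between 2 and the pixel count (", n_pix, ")")
  }
  # scale [0,1] channels to a Lab-like 0-100 range so compactness=10
  # behaves like the conventional setting
  labels <- slic_cpp(as.numeric(px) * 100, d[1], d[2], d[3],
                     as.integer(n_segments), compactness,
                     as.integer(max_iter))
  structure(list(pixels = labels, n_segments = max(labels)),
            class = "superpixel_labels")
}

#' Segment tissue from array background
#'
#' The masking pipeline: downscale to the working width, convert to
#' luminance, normalize contrast around the Otsu threshold, blur
#' isotropically, partition into SLIC superpixels, then k-means (k = 2) on
#' per-superpixel mean intensity to split superpixels into tissue vs
#' background. The darker cluster that also touches the image border less is
#' taken as tissue. Holes and specks smaller than 1% of the image area are
#' filled/removed as post-processing.
#'
#' @param img a [section_image()] (full resolution or pre-scaled).
#' @param n_segments,compactness SLIC parameters (defaults 1000 and 10).
#' @param blur_sigma Gaussian blur sigma in pixels on the working image
#'   (default 2).
#' @param target_width working width passed to [downscale_image()].
#' @param seed seed for the k-means step (and any other randomness).
#' @return A [tissue_mask()] in the working-image frame; its `source_scale`
#'   relates working pixels to full-resolution coordinates.
#' @export
compute_tissue_mask <- function(img, n_segments = 1000, compactness = 10,
                                blur_sigma = 2, target_width = 400,
                                seed = 1) {
  stopifnot(inherits(img, "section_image"))
  small <- downscale_image(img, target_width)
  gray <- rgb_to_gray(small$pixels)
  thr <- otsu_threshold(gray)  # errors on constant images

  # contrast normalization: map the Otsu threshold to mid-gray so the blur
  # and superpixel stages see a stain-independent intensity scale
  norm <- ifelse(gray <= thr,
                 0.5 * gray / max(thr, 1e-12),
                 0.5 + 0.5 * (gray - thr) / max(1 - thr, 1e-12))

  blurred <- ebi_gblur(norm, blur_sigma)
  n_seg <- min(n_segments, length(gray))
  sp <- slic_superpixels(array(blurred, dim = c(dim(blurred), 1)),
                         n_segments = n_seg, compactness = compactness)
  lab <- sp$pixels
  n_lab <- sp$n_segments

  # cluster on the unblurred normalized intensity (the blur stabilizes
  # superpixel shapes but smears the boundary) and use the per-superpixel
  # median, which ignores partial-volume pixels in boundary-straddling
  # segments
  seg_feat <- as.numeric(tapply(norm, lab, stats::median))
  seg_gray <- as.numeric(tapply(gray, lab, mean))

  set.seed(seed)
  km <- kmeans(cbind(seg_feat), centers = 2, nstart = 5)

  border <- matrix(FALSE, nrow(gray), ncol(gray))
  border[1, ] <- border[nrow(gray), ] <- TRUE
  border[, 1] <- border[, ncol(gray)] <- TRUE
  seg_border <- tapply(border, lab, mean)

  clus_lum <- tapply(seg_gray, km$cluster, mean)
  clus_border <- vapply(1:2, function(k) {
    segs <- which(km$cluster == k)
    sum(seg_border[segs] * tabulate(lab, n_lab)[segs]) /
      sum(tabulate(lab, n_lab)[segs])
  }, numeric(1))
  # stained tissue is darker and interior; when the two cues disagree the
  # luminance cue wins
  darker <- which.min(clus_lum)
  less_border <- which.min(clus_border)
  tissue_cluster <- darker
  if (darker != less_border && diff(range(clus_lum)) < 1e-6) {
    tissue_cluster <- less_border
  }

  mask <- matrix(km$cluster[lab] == tissue_cluster, nrow(lab), ncol(lab))
  mask <- clean_mask(mask, min_frac = 0.01)
  tissue_mask(img$section_id, mask, source_scale = small$scale)
}

# Gaussian blur via EBImage (transposed layout: EBImage stores x,y)
ebi_gblur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  out <- EBImage::gblur(EBImage::Image(t(mat)), sigma = sigma)
  t(EBImage::imageData(out))
}

# remove tissue specks and fill background holes below min_frac of the area
clean_mask <- function(mask, min_frac = 0.01) {
  n_pix <- length(mask)
  min_px <- min_frac * n_pix
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  sizes <- tabulate(EBImage::imageData(lab))
  small_ids <- which(sizes < min_px)
  if (length(small_ids)) {
    drop <- t(EBImage::imageData(lab)) %in% small_ids
    mask[matrix(drop, nrow(mask))] <- FALSE
  }
  inv <- !mask
  lab <- EBImage::bwlabel(EBImage::Image(t(inv)))
  labm <- t(EBImage::imageData(lab))
  sizes <- tabulate(labm[labm > 0])
  touches <- unique(c(labm[1, ], labm[nrow(labm), ], labm[, 1],
                      labm[, ncol(labm)]))
  hole_ids <- setdiff(which(sizes < min_px), touches)
  if (length(hole_ids)) mask[labm %in% hole_ids] <- TRUE
  mask
}
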