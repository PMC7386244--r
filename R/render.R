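#' HSV multi-feature spot colors
#'
#' Encodes several non-negative features (e.g. NMF factor activities) into
#' one color per spot: each feature gets a unique hue by splitting the hue
#' circle into even breaks (`hue_i = (i - 1) / k`), each feature is min-max
#' rescaled to `[0, 1]` across all spots, and each spot takes the hue of its
#' highest-valued feature with the rescaled value in the V channel
#' (saturation 1). A spot where every rescaled value is zero is black, so
#' non-overlapping features show as distinct colors fading to black where
#' absent. Constant (zero-range) features rescale to all zeros.
#'
#' @param F k features x n spots matrix of non-negative finite values;
#'   rownames are feature names, colnames spot identifiers (both optional).
#' @param rescale `"joint"` (default; min-max across all spots, keeping
#'   colors comparable between sections) or `"none"` if `F` is already in
#'   `[0, 1]`.
#' @return A tibble with one row per spot: `spot`, `feature` (winning
#'   feature or `NA` for black spots), `value` (rescaled winner value),
#'   `r`, `g`, `b`.
#' @export
hsv_multifeature <- function(F, rescale = c("joint", "none")) {
  rescale <- match.arg(rescale)
  F <- as.matrix(F)
  stopifnot(nrow(F) >= 1, all(is.finite(F)))
  k <- nrow(F)
  feats <- rownames(F) %||% paste0("feature_", seq_len(k))
  spots <- colnames(F) %||% as.character(seq_len(ncol(F)))
  if (rescale == "joint") {
    lo <- apply(F, 1, min)
    hi <- apply(F, 1, max)
    rng <- hi - lo
    Fs <- (F - lo) / ifelse(rng > 0, rng, 1)
    Fs[rng == 0, ] <- 0
  } else {
    Fs <- F
  }
  winner <- apply(Fs, 2, which.max)        # ties -> lowest index
  value <- Fs[cbind(winner, seq_len(ncol(Fs)))]
  hue <- (winner - 1) / k
  rgb <- hsv_to_rgb(hue, 1, value)
  tibble::tibble(
    spot = spots,
    feature = ifelse(value > 0, feats[winner], NA_character_),
    value = value,
    r = rgb[, 1], g = rgb[, 2], b = rgb[, 3]
  )
}

# exact HSV -> RGB in double precision (S = 1 everywhere in this package,
# but the general formula is kept)
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h6))
  idx <- i %% 6
  sel <- function(k) idx == k
  r[sel(0)] <- v[sel(0)]; g[sel(0)] <- t[sel(0)]; b[sel(0)] <- p[sel(0)]
  r[sel(1)] <- q[sel(1)]; g[sel(1)] <- v[sel(1)]; b[sel(1)] <- p[sel(1)]
  r[sel(2)] <- p[sel(2)]; g[sel(2)] <- v[sel(2)]; b[sel(2)] <- t[sel(2)]
  r[sel(3)] <- p[sel(3)]; g[sel(3)] <- q[sel(3)]; b[sel(3)] <- v[sel(3)]
  r[sel(4)] <- t[sel(4)]; g[sel(4)] <- p[sel(4)]; b[sel(4)] <- v[sel(4)]
  r[sel(5)] <- v[sel(5)]; g[sel(5)] <- p[sel(5)]; b[sel(5)] <- q[sel(5)]
  cbind(r = r, g = g, b = b)
}

#' Segment nuclei centroids from a stained section
#'
#' A deliberately simple intensity-based segmentation: within the tissue
#' mask, pixels darker than the in-mask Otsu threshold are taken as nuclear,
#' labeled into connected components, and components of at least
#' `min_area_px` pixels are reported by centroid. Touching nuclei are not
#' declumped — the goal is capturing overall tissue morphology for the 3D
#' stack, not precise cell segmentation.
#'
#' @param img a [section_image()] in the same frame as `mask`.
#' @param mask a [tissue_mask()]; an empty mask yields an empty point set.
#' @param min_area_px minimum component area in pixels (default 2).
#' @return A tibble `(x, y)` of 0-based centroid coordinates
#'   (x = column, y = row).
#' @export
segment_nuclei <- function(img, mask, min_area_px = 2) {
  stopifnot(inherits(img, "section_image"), inherits(mask, "tissue_mask"))
  if (!identical(dim(img$pixels)[1:2], dim(mask$pixels))) {
    stop("image and mask shapes differ")
  }
  if (!any(mask$pixels)) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  gray <- rgb_to_gray(img$pixels)
  inside <- gray[mask$pixels]
  if (length(unique(inside)) < 2) {
    return(tibble::tibble(x = numeric(0), y = numeric(0)))
  }
  thr <- otsu_threshold(matrix(inside, ncol = 1))
  dark <- gray < thr & mask$pixels
  if (!any(dark)) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(dark)))))
  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[idx]
  size <- tabulate(ids)
  cx <- tapply(idx[, 2] - 1, ids, mean)
  cy <- tapply(idx[, 1] - 1, ids, mean)
  keep <- size[as.integer(names(cx))] >= min_area_px
  tibble::tibble(x = as.numeric(cx[keep]), y = as.numeric(cy[keep]))
}

#' Assemble aligned nuclei point patterns into a 3D stack
#'
#' Section `i` (1-based) gets `z = (i - 1) * z_spacing`, so the stack can be
#' contracted toward true physical section spacing or expanded for easier
#' visual separation of sections. Point count is conserved.
#'
#' @param point_sets list of `(x, y)` tibbles/matrices, one per section,
#'   already in the aligned frame.
#' @param z_spacing positive z distance between consecutive sections.
#' @return A tibble `(x, y, z, section_index)`, sections in input order.
#' @export
stack_sections <- function(point_sets, z_spacing) {
  stopifnot(z_spacing > 0)
  purrr::imap_dfr(point_sets, function(p, i) {
    i <- if (is.character(i)) match(i, names(point_sets)) else i
    P <- as_point_matrix(p)
    tibble::tibble(x = P[, 1], y = P[, 2],
                   z = (i - 1) * z_spacing, section_index = as.integer(i))
  })
}

#' Interpolate a per-spot feature onto a fine pixel grid
#'
#' Linear (barycentric) interpolation between spot centers, an extension
#' for rendering smooth feature surfaces between lattice spots: each grid
#' node inside the triangle of its three nearest spots — on a hexagonal
#' lattice, exactly the local Delaunay triangle — gets the barycentric
#' blend of their values; nodes outside every such triangle (beyond the
#' lattice hull) are `NA`. Exact for features linear in position.
#'
#' @param spots spot tibble with `px_x`, `px_y`.
#' @param values numeric vector, one value per spot.
#' @param grid_step grid spacing in pixels (default 2).
#' @return A tibble `(x, y, value)` covering the spot bounding box.
#' @export
feature_surface <- function(spots, values, grid_step = 2) {
  stopifnot(nrow(spots) == length(values), nrow(spots) >= 3)
  P <- cbind(spots$px_x, spots$px_y)
  gx <- seq(min(P[, 1]), max(P[, 1]), by = grid_step)
  gy <- seq(min(P[, 2]), max(P[, 2]), by = grid_step)
  G <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  # three nearest spots per grid node
  d2 <- outer(rowSums(G^2), rowSums(P^2), "+") - 2 * tcrossprod(G, P)
  idx <- t(apply(d2, 1, function(d) order(d)[1:3]))
  a <- P[idx[, 1], , drop = FALSE]
  b <- P[idx[, 2], , drop = FALSE]
  c_ <- P[idx[, 3], , drop = FALSE]
  det_t <- (b[, 2] - c_[, 2]) * (a[, 1] - c_[, 1]) +
    (c_[, 1] - b[, 1]) * (a[, 2] - c_[, 2])
  w1 <- ((b[, 2] - c_[, 2]) * (G[, 1] - c_[, 1]) +
           (c_[, 1] - b[, 1]) * (G[, 2] - c_[, 2])) / det_t
  w2 <- ((c_[, 2] - a[, 2]) * (G[, 1] - c_[, 1]) +
           (a[, 1] - c_[, 1]) * (G[, 2] - c_[, 2])) / det_t
  w3 <- 1 - w1 - w2
  eps <- 1e-9
  inside <- is.finite(w1) & w1 >= -eps & w2 >= -eps & w3 >= -eps
  val <- w1 * values[idx[, 1]] + w2 * values[idx[, 2]] +
    w3 * values[idx[, 3]]
  val[!inside] <- NA_real_
  tibble::tibble(x = G[, 1], y = G[, 2], value = val)
}

#' Write a point cloud as ASCII PLY
#'
#' @param cloud tibble with `x`, `y`, `z` (e.g. from [stack_sections()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  n <- nrow(cloud)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    "end_header"
  ), con)
  writeLines(sprintf("%g %g %g", cloud$x, cloud$y, cloud$z), con)
  invisible(path)
}

#' Plot spots colored by the HSV multi-feature encoding
#'
#' @param spots spot tibble with `px_x`, `px_y` in the same order as the
#'   columns passed to [hsv_multifeature()].
#' @param colors the [hsv_multifeature()] result.
#' @param point_size plotted spot size.
#' @return A ggplot object (y axis flipped to match raster orientation).
#' @export
plot_spot_colors <- function(spots, colors, point_size = 2) {
  stopifnot(nrow(spots) == nrow(colors))
  df <- dplyr::bind_cols(spots[, c("px_x", "px_y")], colors)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px_x, y = .data$px_y)) +
    ggplot2::geom_point(color = grDevices::rgb(df$r, df$g, df$b),
                        size = point_size) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a factor's spatial activity map
#'
#' @param spots spot tibble aligned with the model's `H` columns.
#' @param model a [fit_nmf()] result.
#' @param factor_index which factor to plot.
#' @return A ggplot object.
#' @export
plot_factor_map <- function(spots, model, factor_index = 1) {
  stopifnot(inherits(model, "factor_model"),
            nrow(spots) == ncol(model$H))
  df <- dplyr::mutate(spots, activity = model$H[factor_index, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px_x, y = .data$px_y,
                                   color = .data$activity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_color_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(color = rownames(model$H)[factor_index]) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Box plot of per-spot factor activities
#' @param object a [fit_nmf()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.factor_model <- function(object, ...) {
  df <- tidy.factor_model(object, matrix = "H")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$activity)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = "factor activity per spot") +
    ggplot2::theme_minimal()
}
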