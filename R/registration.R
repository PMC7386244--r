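#' Extract tissue-edge points from a mask
#'
#' The edge is the mask minus its morphological erosion — exactly the pixels
#' where the binary mask changes value within the 8-neighborhood, i.e. the
#' nonzero-gradient pixels of the binary raster. When more than `max_points`
#' edge pixels exist, a seeded uniform subsample is returned.
#'
#' @param mask a [tissue_mask()].
#' @param max_points cap on the number of returned points (default 2000).
#' @param seed seed for the subsample.
#' @return A tibble with columns `x`, `y` (0-based working-image pixel
#'   coordinates, `x` = column, `y` = row) and attribute `section_id`.
#' @export
extract_edge_points <- function(mask, max_points = 2000, seed = 1) {
  stopifnot(inherits(mask, "tissue_mask"))
  m <- mask$pixels
  if (!any(m) || all(m)) {
    stop("degenerate mask for section '", mask$section_id,
         "': must contain both tissue and background")
  }
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  interior <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    interior <- interior & pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  edge <- which(m & !interior, arr.ind = TRUE)
  if (nrow(edge) < 3) {
    stop("degenerate mask for section '", mask$section_id,
         "': fewer than 3 edge pixels")
  }
  if (nrow(edge) > max_points) {
    set.seed(seed)
    edge <- edge[sort(sample.int(nrow(edge), max_points)), , drop = FALSE]
  }
  out <- tibble::tibble(x = edge[, 2] - 1, y = edge[, 1] - 1)
  attr(out, "section_id") <- mask$section_id
  out
}

# least-squares rigid fit Q ~ R P + t with det(R) constrained to det_sign
fit_rigid <- function(P, Q, det_sign = 1) {
  pc <- colMeans(P); qc <- colMeans(Q)
  Cov <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  sv <- svd(Cov)
  d <- sign(det(sv$u) * det(sv$v))
  e <- if (det_sign > 0) d else -d
  R <- sv$v %*% diag(c(1, e)) %*% t(sv$u)
  t_vec <- qc - as.numeric(R %*% pc)
  M <- diag(3)
  M[1:2, 1:2] <- R
  M[1:2, 3] <- t_vec
  M
}

as_point_matrix <- function(p) {
  if (is.data.frame(p)) as.matrix(p[, c("x", "y")]) else as.matrix(p)
}

#' Apply a rigid transform to 2D points
#'
#' @param points N x 2 matrix or a tibble with columns `x`, `y`.
#' @param transform a [rigid_transform()].
#' @return Points in the same container type as the input.
#' @export
apply_rigid <- function(points, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  P <- as_point_matrix(points)
  out <- cbind(P, 1) %*% t(transform$matrix)
  if (is.data.frame(points)) {
    points$x <- out[, 1]; points$y <- out[, 2]
    points
  } else {
    out[, 1:2, drop = FALSE]
  }
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(transform) {
  rigid_transform(solve(transform$matrix),
                  converged = transform$converged, rmsd = transform$rmsd)
}

#' Register one edge point set onto another by ICP
#'
#' Iterative closest point: alternate nearest-neighbor correspondence (from
#' the transformed source into the target) with a least-squares rigid fit
#' (Kabsch/SVD with determinant constraint). Reflections are handled by an
#' explicit two-branch search — the rotation-only (`det = +1`) and
#' reflection (`det = -1`) branches are optimized separately and the lower
#' final RMSD wins. Each branch is restarted from a small set of coarse
#' initial rotations about the source centroid to escape local minima.
#'
#' @param source,target edge point sets ([extract_edge_points()] tibbles or
#'   N x 2 matrices), at least 3 points each.
#' @param allow_reflection search the `det = -1` branch too (default TRUE).
#' @param max_iter maximum ICP iterations per start (default 100).
#' @param tol relative RMSD change below which iteration stops.
#' @param trim_fraction fraction of the worst correspondences dropped from
#'   each rigid fit (default 0, i.e. no trimming); use ~0.1-0.3 when the
#'   point sets only partially overlap (e.g. a clipped section).
#' @param init_rotations_deg coarse initial rotations tried per branch.
#' @param seed reserved for seeded variants; the algorithm is deterministic.
#' @return A [rigid_transform()] mapping source coordinates into the target
#'   frame, with fields `rmsd`, `converged` and attribute `trace` (the
#'   per-iteration RMSD of the winning start, non-increasing).
#' @export
icp_register <- function(source, target, allow_reflection = TRUE,
                         max_iter = 100, tol = 1e-6, trim_fraction = 0,
                         init_rotations_deg = seq(-40, 40, by = 20),
                         seed = 1) {
  stopifnot(trim_fraction >= 0, trim_fraction < 1)
  P <- as_point_matrix(source)
  Q <- as_point_matrix(target)
  if (nrow(P) < 3 || nrow(Q) < 3) stop("ICP needs at least 3 points per set")

  nn_match <- function(Pt) nn2d_cpp(Pt, Q)
  pc <- colMeans(P); qc <- colMeans(Q)

  run_branch <- function(det_sign, theta0) {
    # start: rotate about the source centroid by theta0, then align centroids
    R0 <- matrix(c(cos(theta0), sin(theta0), -sin(theta0), cos(theta0)), 2)
    if (det_sign < 0) R0 <- R0 %*% diag(c(-1, 1))
    M <- diag(3)
    M[1:2, 1:2] <- R0
    M[1:2, 3] <- qc - as.numeric(R0 %*% pc)
    trace <- numeric(0)
    prev <- Inf
    converged <- FALSE
    n_keep <- max(3, ceiling((1 - trim_fraction) * nrow(P)))
    for (it in seq_len(max_iter)) {
      Pt <- cbind(P, 1) %*% t(M)
      j <- nn_match(Pt[, 1:2, drop = FALSE])
      keep <- seq_len(nrow(P))
      if (n_keep < nrow(P)) {
        d2 <- rowSums((Pt[, 1:2, drop = FALSE] - Q[j, , drop = FALSE])^2)
        keep <- order(d2)[seq_len(n_keep)]
      }
      M <- fit_rigid(P[keep, , drop = FALSE],
                     Q[j[keep], , drop = FALSE], det_sign)
      Pt <- cbind(P, 1) %*% t(M)
      rmsd <- sqrt(mean(rowSums((Pt[keep, 1:2, drop = FALSE] -
                                   Q[j[keep], , drop = FALSE])^2)))
      trace <- c(trace, rmsd)
      if (is.finite(prev) && abs(prev - rmsd) < tol * max(prev, 1e-12)) {
        converged <- TRUE
        break
      }
      prev <- rmsd
    }
    list(M = M, rmsd = rmsd, trace = trace, converged = converged)
  }

  branches <- if (allow_reflection) c(1, -1) else 1
  best <- NULL
  for (s in branches) {
    for (th in init_rotations_deg * pi / 180) {
      res <- run_branch(s, th)
      if (is.null(best) || res$rmsd < best$rmsd) best <- res
    }
  }
  out <- rigid_transform(best$M, converged = best$converged, rmsd = best$rmsd)
  attr(out, "trace") <- best$trace
  out
}

#' Warp an image into a target frame by backward mapping
#'
#' Every output pixel samples the input image at the inverse-transformed
#' location with bicubic (Catmull-Rom) interpolation, which gives a smooth
#' result and is exact for integer translations. Samples falling outside the
#' input raster take the fill color (white by default, matching the H&E
#' background).
#'
#' @param img a [section_image()] in the source frame.
#' @param transform a [rigid_transform()] mapping source to target frame.
#' @param out_shape output `(H, W)`; defaults to the input shape.
#' @param fill background RGB fill, length 3 in `[0,1]`.
#' @return A [section_image()] in the target frame.
#' @export
warp_image_backward <- function(img, transform, out_shape = NULL,
                                fill = c(1, 1, 1)) {
  stopifnot(inherits(img, "section_image"))
  px <- img$pixels
  d <- dim(px)
  if (is.null(out_shape)) out_shape <- d[1:2]
  H <- out_shape[1]; W <- out_shape[2]
  inv <- solve(transform$matrix)

  # output pixel centers, 0-based (x = col, y = row)
  gx <- rep(0:(W - 1), each = H)
  gy <- rep(0:(H - 1), times = W)
  sx <- inv[1, 1] * gx + inv[1, 2] * gy + inv[1, 3]
  sy <- inv[2, 1] * gx + inv[2, 2] * gy + inv[2, 3]

  out <- array(0, dim = c(H, W, 3))
  oob <- sx < 0 | sx > d[2] - 1 | sy < 0 | sy > d[1] - 1
  for (ch in 1:3) {
    v <- bicubic_sample(px[, , ch], sx, sy)
    v[oob] <- fill[ch]
    out[, , ch] <- matrix(v, H, W)
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  section_image(img$section_id, out, scale = img$scale)
}

# Catmull-Rom (Keys a = -0.5) separable bicubic sampling; coordinates 0-based
bicubic_sample <- function(mat, sx, sy) {
  H <- nrow(mat); W <- ncol(mat)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  wk <- function(f, off) {
    t <- abs(f - off)
    a <- -0.5
    ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
           ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
  }
  acc <- numeric(length(sx))
  for (dy in -1:2) {
    wy <- wk(fy, dy)
    ry <- pmin(pmax(y0 + dy, 0), H - 1)
    for (dx in -1:2) {
      wx <- wk(fx, dx)
      rx <- pmin(pmax(x0 + dx, 0), W - 1)
      acc <- acc + wy * wx * mat[1 + ry + H * rx]
    }
  }
  acc
}

#' Align a stack of masked sections to a reference
#'
#' Extracts edge points from every mask and registers each non-reference
#' section onto the reference by [icp_register()]. The reference entry is
#' the identity transform.
#'
#' @param masks list of [tissue_mask()] objects.
#' @param reference_index 1-based index of the reference section (default 1,
#'   i.e. the first image).
#' @param max_points,allow_reflection,seed passed through to edge extraction
#'   and ICP.
#' @return A list of [rigid_transform()]s, one per mask, in input order.
#' @export
align_stack <- function(masks, reference_index = 1, max_points = 2000,
                        allow_reflection = TRUE, seed = 1) {
  stopifnot(length(masks) >= 1,
            reference_index >= 1, reference_index <= length(masks))
  edges <- lapply(masks, function(m) {
    tryCatch(extract_edge_points(m, max_points = max_points, seed = seed),
             error = function(e) {
               stop("section '", m$section_id, "': ", conditionMessage(e))
             })
  })
  ref <- edges[[reference_index]]
  lapply(seq_along(masks), function(i) {
    if (i == reference_index) {
      rigid_transform(diag(3), converged = TRUE, rmsd = 0)
    } else {
      icp_register(edges[[i]], ref, allow_reflection = allow_reflection,
                   seed = seed)
    }
  })
}

#' Map spot coordinates through a working-frame transform
#'
#' Registration runs in the downscaled working frame; this lifts the
#' resulting transform to full-resolution spot coordinates: scale down,
#' transform, scale back. Array coordinates are untouched.
#'
#' @param spots spot tibble (as in [st_dataset()]).
#' @param transform a [rigid_transform()] in the working frame.
#' @param scale working pixels per full-resolution pixel (the mask's
#'   `source_scale`).
#' @return The spot tibble with transformed `px_x`, `px_y`.
#' @export
map_spot_coordinates <- function(spots, transform, scale) {
  stopifnot(scale > 0)
  P <- cbind(spots$px_x * scale, spots$px_y * scale)
  out <- apply_rigid(P, transform) / scale
  spots$px_x <- out[, 1]
  spots$px_y <- out[, 2]
  spots
}

#' Write transforms as JSON
#'
#' @param transforms named list of [rigid_transform()]s (names = section ids).
#' @param path output JSON path.
#' @param scale working-frame scale(s) the transforms were computed at.
#' @return `path`, invisibly.
#' @export
write_transforms <- function(transforms, path, scale = 1) {
  scale <- rep_len(scale, length(transforms))
  recs <- lapply(seq_along(transforms), function(i) {
    tr <- transforms[[i]]
    list(section_id = names(transforms)[i] %||% as.character(i),
         matrix = as.numeric(t(tr$matrix)),
         scale = scale[i],
         is_reflection = tr$is_reflection,
         converged = tr$converged,
         rmsd = tr$rmsd)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read transforms written by [write_transforms()]
#' @param path JSON path.
#' @return Named list of [rigid_transform()]s with attribute `scale`.
#' @export
read_transforms <- function(path) {
  recs <- jsonlite::read_json(path)
  out <- lapply(recs, function(r) {
    rigid_transform(matrix(as.numeric(unlist(r$matrix)), 3, 3, byrow = TRUE),
                    converged = r$converged %||% NA,
                    rmsd = r$rmsd %||% NA_real_)
  })
  names(out) <- vapply(recs, function(r) r$section_id, character(1))
  attr(out, "scale") <- vapply(recs, function(r) as.numeric(r$scale %||% 1),
                               numeric(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
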