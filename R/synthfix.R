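#' Hexagonal Visium-style spot lattice
#'
#' A `rows x cols` hexagonal lattice with the given center-to-center
#' spacing: odd rows are offset by half the spacing in x and the row pitch
#' is `spacing * sqrt(3) / 2`, so the nearest-neighbor distance equals
#' `spacing_um` exactly and every interior spot has six neighbors within
#' 1.5 spacings. Pixel coordinates equal the physical positions (1 px per
#' um at scale 1) unless an affine placement is supplied via `px_origin`
#' and `px_per_um`.
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @param spacing_um center-to-center distance (default 100).
#' @param section_id section id for the generated spots.
#' @param px_origin length-2 `(x, y)` pixel offset of the lattice origin.
#' @param px_per_um pixels per micrometre for the synthesized coordinates.
#' @return A spot tibble as in [st_dataset()].
#' @export
make_hex_grid <- function(rows, cols, spacing_um = 100, section_id = "S1",
                          px_origin = c(0, 0), px_per_um = 1) {
  stopifnot(rows >= 1, cols >= 1)
  g <- expand.grid(array_col = 0:(cols - 1), array_row = 0:(rows - 1))
  odd <- g$array_row %% 2 == 1
  x_um <- (g$array_col + 0.5 * odd) * spacing_um
  y_um <- g$array_row * spacing_um * sqrt(3) / 2
  tibble::tibble(
    barcode = sprintf("spot-%05d", seq_len(nrow(g))),
    section_id = section_id,
    array_row = g$array_row,
    array_col = g$array_col,
    px_x = px_origin[1] + x_um * px_per_um,
    px_y = px_origin[2] + y_um * px_per_um,
    in_tissue = TRUE
  )
}

#' Simulate an H&E-like section image with known ground truth
#'
#' Emulates the appearance the masking pipeline needs: a smooth random
#' tissue blob (thresholded low-frequency noise) rendered in H&E pink over
#' a near-white speckled background, with nuclei as small dark disks at
#' uniform positions inside the blob. The generator is bitwise-reproducible
#' from `(parameters, seed)` and returns the exact ground-truth mask and
#' nuclei centers. It makes no attempt at realistic H&E color statistics
#' beyond what tissue/background segmentation requires.
#'
#' @param width,height image size in pixels (>= 64).
#' @param n_nuclei number of nuclei disks.
#' @param blob_fraction target tissue area fraction (default 0.35).
#' @param nucleus_radius_px nuclei disk radius (default 2).
#' @param seed RNG seed.
#' @param section_id section id.
#' @return A list with `image` ([section_image()]) and `truth` (list with
#'   `mask` ([tissue_mask()]), `nuclei_centers` tibble `(x, y)`, `seed`).
#' @export
simulate_section_image <- function(width, height, n_nuclei = 50,
                                   blob_fraction = 0.35,
                                   nucleus_radius_px = 2, seed = 1,
                                   section_id = "S1") {
  stopifnot(width >= 64, height >= 64, blob_fraction > 0, blob_fraction < 1)
  set.seed(seed)
  # low-frequency noise: coarse Gaussian grid upsampled bilinearly
  coarse <- matrix(rnorm(8 * 8), 8, 8)
  field <- t(EBImage::imageData(EBImage::resize(
    EBImage::Image(t(coarse)), w = width, h = height, filter = "bilinear")))
  thr <- quantile(field, 1 - blob_fraction)
  mask <- field >= thr
  mask <- clean_mask(mask, min_frac = 0.01)

  px <- array(0, dim = c(height, width, 3))
  tissue_rgb <- c(0.91, 0.62, 0.73)
  bg_rgb <- c(0.97, 0.96, 0.97)
  for (ch in 1:3) {
    layer <- matrix(bg_rgb[ch], height, width) +
      matrix(rnorm(height * width, 0, 0.008), height, width)
    layer[mask] <- tissue_rgb[ch] + rnorm(sum(mask), 0, 0.03)
    px[, , ch] <- layer
  }

  centers <- tibble::tibble(x = numeric(0), y = numeric(0))
  if (n_nuclei > 0 && any(mask)) {
    # keep nuclei strictly inside the blob
    inner <- EBImage::erode(EBImage::Image(t(mask)),
                            EBImage::makeBrush(2 * nucleus_radius_px + 3,
                                               "disc"))
    inner <- t(EBImage::imageData(inner)) > 0
    cand <- which(inner, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      # dart-throwing with a minimum center separation so disks stay
      # disjoint and each nucleus has a well-defined centroid
      min_sep <- 2 * nucleus_radius_px + 2
      ord <- sample.int(nrow(cand))
      pick <- matrix(NA_real_, 0, 2)
      for (ci in ord) {
        p <- cand[ci, ]
        if (nrow(pick) == 0 ||
            min((pick[, 1] - p[1])^2 + (pick[, 2] - p[2])^2) >= min_sep^2) {
          pick <- rbind(pick, p)
          if (nrow(pick) >= n_nuclei) break
        }
      }
      centers <- tibble::tibble(x = pick[, 2] - 1, y = pick[, 1] - 1)
      nuc_rgb <- c(0.25, 0.12, 0.35)
      r <- nucleus_radius_px
      for (i in seq_len(nrow(pick))) {
        rr <- max(1, pick[i, 1] - r):min(height, pick[i, 1] + r)
        cc <- max(1, pick[i, 2] - r):min(width, pick[i, 2] + r)
        d2 <- outer((rr - pick[i, 1])^2, (cc - pick[i, 2])^2, "+")
        hit <- d2 <= r^2
        for (ch in 1:3) {
          block <- px[rr, cc, ch]
          block[hit] <- nuc_rgb[ch]
          px[rr, cc, ch] <- block
        }
      }
    }
  }
  px[px < 0] <- 0
  px[px > 1] <- 1
  list(
    image = section_image(section_id, px, scale = 1),
    truth = list(mask = tissue_mask(section_id, mask, source_scale = 1),
                 nuclei_centers = centers, seed = seed)
  )
}

#' Simulate spatially patterned negative-binomial counts
#'
#' Plants `k` smooth Gaussian-bump spatial patterns over the spot positions.
#' Each factor owns a disjoint gene set whose expected expression is
#' `baseline * (1 + effect * pattern)`; all remaining genes are pattern-free
#' at `baseline`. Counts are drawn NB with mean mu and dispersion theta
#' (variance `mu + mu^2 / theta`), matching the Pearson-residual model in
#' [pearson_residuals()].
#'
#' @param spots spot tibble (e.g. [make_hex_grid()]).
#' @param n_genes total genes (must be at least `10 * k`).
#' @param k number of planted spatial factors.
#' @param effect multiplicative effect size at the bump peak (default 5).
#' @param theta NB dispersion (default 10).
#' @param baseline baseline mean count per gene and spot (default 5).
#' @param genes_per_factor genes owned by each factor (default 10).
#' @param bump_sigma_um bump width; default one quarter of the lattice
#'   extent.
#' @param spacing_um lattice spacing for position geometry.
#' @param seed RNG seed.
#' @return A list with `counts` (genes x spots sparse matrix, genes named
#'   `gene_0001...`) and `truth` (list with `factor_patterns` (k x spots,
#'   peak-normalized), `factor_gene_sets` (list of gene-id vectors),
#'   `seed`).
#' @export
simulate_counts <- function(spots, n_genes, k, effect = 5, theta = 10,
                            baseline = 5, genes_per_factor = 10,
                            bump_sigma_um = NULL, spacing_um = 100,
                            seed = 1) {
  stopifnot(n_genes >= k * 10, k >= 1)
  set.seed(seed)
  spots <- spot_positions_um(spots, spacing_um)
  P <- cbind(spots$pos_x_um, spots$pos_y_um)
  n <- nrow(P)
  extent <- max(apply(P, 2, function(v) diff(range(v))), spacing_um)
  if (is.null(bump_sigma_um)) bump_sigma_um <- extent / 4

  # spread bump centers: greedy farthest-point among spots, random start
  centers <- matrix(NA_real_, k, 2)
  centers[1, ] <- P[sample.int(n, 1), ]
  if (k > 1) {
    for (j in 2:k) {
      d2min <- rep(Inf, n)
      for (jj in 1:(j - 1)) {
        d2 <- (P[, 1] - centers[jj, 1])^2 + (P[, 2] - centers[jj, 2])^2
        d2min <- pmin(d2min, d2)
      }
      centers[j, ] <- P[which.max(d2min), ]
    }
  }
  patterns <- t(vapply(seq_len(k), function(j) {
    d2 <- (P[, 1] - centers[j, 1])^2 + (P[, 2] - centers[j, 2])^2
    p <- exp(-d2 / (2 * bump_sigma_um^2))
    p / max(p)
  }, numeric(n)))

  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  owned <- split(gene_ids[seq_len(k * genes_per_factor)],
                 rep(seq_len(k), each = genes_per_factor))
  mu <- matrix(baseline, n_genes, n, dimnames = list(gene_ids, NULL))
  for (j in seq_len(k)) {
    rows <- match(owned[[j]], gene_ids)
    mu[rows, ] <- baseline * (1 + effect *
                                matrix(patterns[j, ], length(rows), n,
                                       byrow = TRUE))
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = theta),
                   n_genes, n, dimnames = list(gene_ids, spots$barcode))
  list(
    counts = Matrix::Matrix(counts, sparse = TRUE),
    truth = list(factor_patterns = patterns,
                 factor_gene_sets = owned, seed = seed)
  )
}

#' Perturb a mask by a known rigid transform
#'
#' Warps a binary mask by the stated rotation (about the image center),
#' optional reflection (x-axis flip before rotation) and translation, using
#' nearest-neighbor backward sampling, and returns the exact transform used
#' — ground truth for registration-recovery tests.
#'
#' @param mask a [tissue_mask()].
#' @param angle_deg rotation in degrees (counter-clockwise in the x-right,
#'   y-down raster frame).
#' @param shift_px length-2 `(dx, dy)` translation in pixels.
#' @param reflect apply an x-flip before rotating.
#' @return A list with `mask` (warped [tissue_mask()]) and `transform` (the
#'   [rigid_transform()] mapping original to perturbed coordinates).
#' @export
perturb_section <- function(mask, angle_deg = 0, shift_px = c(0, 0),
                            reflect = FALSE) {
  stopifnot(inherits(mask, "tissue_mask"))
  m <- mask$pixels
  if (!any(m)) stop("degenerate mask: no tissue")
  H <- nrow(m); W <- ncol(m)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  if (reflect) R <- R %*% diag(c(-1, 1))
  M <- diag(3)
  M[1:2, 1:2] <- R
  M[1:2, 3] <- c(cx + shift_px[1], cy + shift_px[2]) - R %*% c(cx, cy)
  tr <- rigid_transform(M)

  inv <- solve(M)
  gx <- rep(0:(W - 1), each = H)
  gy <- rep(0:(H - 1), times = W)
  sx <- round(inv[1, 1] * gx + inv[1, 2] * gy + inv[1, 3])
  sy <- round(inv[2, 1] * gx + inv[2, 2] * gy + inv[2, 3])
  ok <- sx >= 0 & sx <= W - 1 & sy >= 0 & sy <= H - 1
  vals <- logical(H * W)
  vals[ok] <- m[cbind(sy[ok] + 1, sx[ok] + 1)]
  warped <- matrix(vals, H, W)
  if (!any(warped)) {
    stop("transform pushed the tissue entirely out of frame")
  }
  list(mask = tissue_mask(mask$section_id, warped, mask$source_scale),
       transform = tr)
}

#' Simulate a complete multi-section Visium-style dataset
#'
#' The one-call study generator: for each section, an H&E-like image with
#' ground-truth mask and nuclei, a hexagonal spot lattice placed inside the
#' image frame, and spatially patterned NB counts sharing the same planted
#' factors across sections. Sections beyond the first are recorded together
#' with rigid perturbations of the reference mask for alignment tests.
#'
#' @param preset `"small"` (2 sections, 10x10 spots, 120 genes, 160x200 px)
#'   or `"medium"` (3 sections, 14x14 spots, 200 genes, 240x320 px).
#' @param seed RNG seed; all per-section seeds derive from it.
#' @param n_sections,rows,cols,n_genes,k,width,height optional overrides of
#'   the preset.
#' @return A list with `dataset` ([st_dataset()]) and `truth` (per-section
#'   masks, nuclei, perturbation transforms, factor patterns and gene sets).
#' @export
simulate_visium_dataset <- function(preset = c("small", "medium"), seed = 1,
                                    n_sections = NULL, rows = NULL,
                                    cols = NULL, n_genes = NULL, k = NULL,
                                    width = NULL, height = NULL) {
  preset <- match.arg(preset)
  p <- switch(preset,
    small = list(n_sections = 2, rows = 10, cols = 10, n_genes = 120, k = 3,
                 width = 200, height = 160),
    medium = list(n_sections = 3, rows = 14, cols = 14, n_genes = 200, k = 4,
                  width = 320, height = 240))
  p$n_sections <- n_sections %||% p$n_sections
  p$rows <- rows %||% p$rows
  p$cols <- cols %||% p$cols
  p$n_genes <- n_genes %||% p$n_genes
  p$k <- k %||% p$k
  p$width <- width %||% p$width
  p$height <- height %||% p$height

  sections <- sprintf("S%d", seq_len(p$n_sections))
  ds_list <- list()
  truth <- list(sections = list(), factor_gene_sets = NULL,
                factor_patterns = list(), seed = seed)
  # serial sections share one tissue blob; each section beyond the first is
  # a rigidly perturbed copy of the reference, as on a real slide stack
  base <- simulate_section_image(p$width, p$height, n_nuclei = 60,
                                 seed = seed, section_id = sections[1])
  for (si in seq_len(p$n_sections)) {
    sec <- sections[si]
    img <- base$image
    tr <- rigid_transform(diag(3))
    msk <- base$truth$mask
    nuc <- base$truth$nuclei_centers
    if (si > 1) {
      set.seed(seed + 77 * si)
      pert <- perturb_section(base$truth$mask,
                              angle_deg = runif(1, -20, 20),
                              shift_px = round(runif(2, -15, 15)))
      msk <- pert$mask
      tr <- pert$transform
      img <- warp_image_backward(img, tr)
      nuc <- apply_rigid(nuc, tr)
    }
    img$section_id <- sec
    msk$section_id <- sec
    # lattice inside the central part of the frame
    spacing_px <- min(p$width, p$height) * 0.7 /
      max(p$cols, p$rows * sqrt(3) / 2)
    spots <- make_hex_grid(p$rows, p$cols, spacing_um = 100,
                           section_id = sec,
                           px_origin = c(p$width * 0.12, p$height * 0.12),
                           px_per_um = spacing_px / 100)
    # as on the platform, the in-tissue flag records whether the spot
    # center lies under the (possibly perturbed) tissue blob
    rr <- pmin(pmax(round(spots$px_y) + 1, 1), p$height)
    cc <- pmin(pmax(round(spots$px_x) + 1, 1), p$width)
    spots$in_tissue <- msk$pixels[cbind(rr, cc)]
    cnt <- simulate_counts(spots, p$n_genes, p$k, seed = seed + 13 * si)
    ds_list[[sec]] <- st_dataset(cnt$counts, spots,
                                 images = setNames(list(img), sec),
                                 spacing_um = 100)
    truth$sections[[sec]] <- list(mask = msk, image = img,
                                  nuclei_centers = nuc,
                                  transform = tr)
    truth$factor_gene_sets <- cnt$truth$factor_gene_sets
    truth$factor_patterns[[sec]] <- cnt$truth$factor_patterns
  }
  list(dataset = concat_datasets(ds_list), truth = truth)
}
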