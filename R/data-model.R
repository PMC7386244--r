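#' Spatial transcriptomics dataset
#'
#' Bundles a gene x spot count matrix, a spot table, per-section H&E images
#' and the array center-to-center spacing into one object. Spot order in
#' `spots` matches the column order of `counts`. Visium arrays place spots on
#' a hexagonal lattice with 100 um center-to-center spacing; legacy ST arrays
#' use a square lattice (set `spacing_um` accordingly).
#'
#' @param counts genes x spots matrix of non-negative integer counts
#'   (base matrix or [Matrix::Matrix]); rownames are gene identifiers.
#' @param spots tibble with one row per matrix column, columns `barcode`,
#'   `section_id`, `array_row`, `array_col`, `px_x`, `px_y`, `in_tissue`.
#'   Pixel coordinates are full-resolution, 0-based, origin top-left:
#'   `px_x` is the pixel column, `px_y` the pixel row.
#' @param images named list of [section_image()] objects keyed by section id.
#'   May be empty for expression-only use.
#' @param spacing_um center-to-center spot distance in micrometres.
#'
#' @return An object of class `st_dataset`.
#' @export
st_dataset <- function(counts, spots, images = list(), spacing_um = 100) {
  spots <- tibble::as_tibble(spots)
  req <- c("barcode", "section_id", "array_row", "array_col",
           "px_x", "px_y", "in_tissue")
  missing_cols <- setdiff(req, names(spots))
  if (length(missing_cols) > 0) {
    stop("spot table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (ncol(counts) != nrow(spots)) {
    stop("counts has ", ncol(counts), " columns but spot table has ",
         nrow(spots), " rows")
  }
  if (anyDuplicated(paste(spots$barcode, spots$section_id, sep = "\r"))) {
    stop("duplicated (barcode, section_id) pairs in spot table")
  }
  if (!all(is.finite(spots$px_x)) || !all(is.finite(spots$px_y))) {
    stop("non-finite spot pixel coordinates")
  }
  if (!is.numeric(spacing_um) || length(spacing_um) != 1 || spacing_um <= 0) {
    stop("spacing_um must be a single positive number")
  }
  m <- min(counts)
  if (is.na(m) || m < 0) stop("counts must be non-negative")
  for (id in names(images)) {
    if (!inherits(images[[id]], "section_image")) {
      stop("images[['", id, "']] is not a section_image")
    }
  }
  extra <- setdiff(names(images), unique(spots$section_id))
  if (length(extra) > 0) {
    stop("images present for unknown section(s): ", paste(extra, collapse = ", "))
  }
  structure(
    list(counts = counts, spots = spots, images = images,
         spacing_um = spacing_um),
    class = "st_dataset"
  )
}

#' @exportS3Method base::print
print.st_dataset <- function(x, ...) {
  cat("st_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "spots\n")
  sec <- unique(x$spots$section_id)
  cat("  sections:", paste(sec, collapse = ", "), "\n")
  cat("  images:", length(x$images), " | spacing:", x$spacing_um, "um\n")
  cat("  in tissue:", sum(x$spots$in_tissue), "/", nrow(x$spots), "spots\n")
  invisible(x)
}

#' @export
dim.st_dataset <- function(x) dim(x$counts)

#' Restrict a dataset to spots under the tissue
#'
#' Spots flagged `in_tissue = FALSE` by the platform are loaded but excluded
#' from analysis by default; this drops them (both spot rows and count
#' columns).
#'
#' @param ds an [st_dataset()].
#' @param include_all keep all spots (no-op) when `TRUE`.
#' @return An `st_dataset` containing only in-tissue spots.
#' @export
filter_tissue <- function(ds, include_all = FALSE) {
  stopifnot(inherits(ds, "st_dataset"))
  if (include_all) return(ds)
  keep <- which(ds$spots$in_tissue)
  st_dataset(ds$counts[, keep, drop = FALSE], ds$spots[keep, , drop = FALSE],
             ds$images, ds$spacing_um)
}

#' Section image raster
#'
#' An H x W x 3 numeric array with channel values in `[0, 1]`, plus the scale
#' linking raster pixels to full-resolution pixel coordinates
#' (`raster_px = full_res_px * scale`).
#'
#' @param section_id section identifier.
#' @param pixels H x W x 3 array, values in `[0, 1]`.
#' @param scale raster pixels per full-resolution pixel; `1` when the raster
#'   is itself the full-resolution frame.
#' @return An object of class `section_image`.
#' @export
section_image <- function(section_id, pixels, scale = 1) {
  if (length(dim(pixels)) == 2) {
    pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  }
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            is.numeric(scale), length(scale) == 1, scale > 0)
  rng <- range(pixels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("image channel values must lie in [0, 1]")
  }
  structure(list(section_id = section_id, pixels = pixels, scale = scale),
            class = "section_image")
}

#' @exportS3Method base::print
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("section_image '", x$section_id, "': ", d[1], " x ", d[2],
      " px, scale ", signif(x$scale, 4), "\n", sep = "")
  invisible(x)
}

#' Binary tissue mask
#'
#' @param section_id section identifier.
#' @param pixels H x W logical matrix, `TRUE` = tissue.
#' @param source_scale raster pixels per full-resolution pixel (same
#'   convention as [section_image()]).
#' @return An object of class `tissue_mask`.
#' @export
tissue_mask <- function(section_id, pixels, source_scale = 1) {
  stopifnot(is.matrix(pixels))
  mode(pixels) <- "logical"
  structure(list(section_id = section_id, pixels = pixels,
                 source_scale = source_scale),
            class = "tissue_mask")
}

#' @exportS3Method base::print
print.tissue_mask <- function(x, ...) {
  cat("tissue_mask '", x$section_id, "': ", nrow(x$pixels), " x ",
      ncol(x$pixels), " px, ",
      round(100 * mean(x$pixels), 1), "% tissue\n", sep = "")
  invisible(x)
}

#' Rigid transform in homogeneous coordinates
#'
#' A 3 x 3 homogeneous matrix whose upper-left 2 x 2 block is orthonormal
#' (rotation, optionally composed with a reflection) and whose last row is
#' `(0, 0, 1)`. Applied to row vectors `(x, y, 1)` on the right of `t(matrix)`,
#' see [apply_rigid()].
#'
#' @param matrix 3 x 3 homogeneous transform matrix.
#' @param converged logical, set by [icp_register()].
#' @param rmsd final correspondence RMSD, set by [icp_register()].
#' @return An object of class `rigid_transform` with an `is_reflection` field
#'   derived from the determinant of the linear part.
#' @export
rigid_transform <- function(matrix = diag(3), converged = NA, rmsd = NA_real_) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3, 3)))
  R <- matrix[1:2, 1:2]
  if (max(abs(crossprod(R) - diag(2))) > 1e-8) {
    stop("linear part is not orthonormal")
  }
  if (max(abs(matrix[3, ] - c(0, 0, 1))) > 1e-12) {
    stop("bottom row must be (0, 0, 1)")
  }
  structure(
    list(matrix = matrix, is_reflection = det(R) < 0,
         converged = converged, rmsd = rmsd),
    class = "rigid_transform"
  )
}

#' @exportS3Method base::print
print.rigid_transform <- function(x, ...) {
  ang <- atan2(x$matrix[2, 1], x$matrix[1, 1]) * 180 / pi
  cat("rigid_transform: rotation ", round(ang, 2), " deg",
      if (x$is_reflection) " (with reflection)", ", translation (",
      round(x$matrix[1, 3], 2), ", ", round(x$matrix[2, 3], 2), ")",
      if (!is.na(x$rmsd)) paste0(", rmsd ", signif(x$rmsd, 4)), "\n", sep = "")
  invisible(x)
}

#' Concatenate datasets across sections
#'
#' Takes the union of gene universes (zero-filling genes absent from a
#' section), concatenates spot tables in input order and merges image maps.
#' All inputs must share `spacing_um`; a section id occurring in more than
#' one input is an error.
#'
#' @param ds_list list of [st_dataset()] objects.
#' @return A single `st_dataset` spanning all sections.
#' @export
concat_datasets <- function(ds_list) {
  stopifnot(length(ds_list) >= 1)
  for (ds in ds_list) stopifnot(inherits(ds, "st_dataset"))
  if (length(ds_list) == 1) return(ds_list[[1]])
  spacing <- unique(vapply(ds_list, function(d) d$spacing_um, numeric(1)))
  if (length(spacing) != 1) {
    stop("datasets disagree on spacing_um: ", paste(spacing, collapse = ", "))
  }
  all_sections <- unlist(lapply(ds_list, function(d) unique(d$spots$section_id)))
  if (anyDuplicated(all_sections)) {
    stop("duplicate section_id across datasets: ",
         paste(unique(all_sections[duplicated(all_sections)]), collapse = ", "))
  }
  genes <- unique(unlist(lapply(ds_list, function(d) rownames(d$counts))))
  mats <- lapply(ds_list, function(d) {
    m <- Matrix::Matrix(d$counts, sparse = TRUE)
    out <- Matrix::Matrix(0, length(genes), ncol(m), sparse = TRUE,
                          dimnames = list(genes, colnames(m)))
    out[rownames(m), ] <- m
    out
  })
  counts <- do.call(cbind, mats)
  spots <- dplyr::bind_rows(lapply(ds_list, function(d) d$spots))
  images <- do.call(c, unname(lapply(ds_list, function(d) d$images)))
  st_dataset(counts, spots, images, spacing)
}

# luminance grayscale (Rec.601 weights)
rgb_to_gray <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}
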