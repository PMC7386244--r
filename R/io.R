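#' Read Space Ranger-style Visium output for one section
#'
#' Expects the standard layout: a MatrixMarket count matrix with `features.tsv`
#' and `barcodes.tsv` (optionally gzipped, either at `dir` or under
#' `dir/filtered_feature_bc_matrix/`), and a `spatial/` subdirectory with a
#' tissue positions CSV (v1 headerless `tissue_positions_list.csv` or v2
#' headered `tissue_positions.csv`), `scalefactors_json.json` and at least one
#' tissue image. The low-resolution image and its matching scale factor are
#' loaded by default.
#'
#' Spot pixel coordinates are returned in full-resolution units, 0-based,
#' `px_x` = pixel column and `px_y` = pixel row (the positions file's
#' `pxl_row_in_fullres` maps to `px_y`).
#'
#' @param dir path to the section's Space Ranger output directory.
#' @param section_id identifier to assign to this section.
#' @param image which tissue image to load: `"lowres"` (default) or `"hires"`.
#' @param filter_to_matrix when `TRUE` (default), positions-file rows without
#'   a matrix barcode are dropped; when `FALSE` a barcode mismatch is an error.
#' @return An [st_dataset()] with one section.
#' @export
read_spaceranger <- function(dir, section_id,
                             image = c("lowres", "hires"),
                             filter_to_matrix = TRUE) {
  image <- match.arg(image)
  mat_dir <- dir
  if (!length(find_input(mat_dir, "matrix.mtx", required = FALSE))) {
    sub <- file.path(dir, "filtered_feature_bc_matrix")
    if (dir.exists(sub)) mat_dir <- sub
  }
  mtx_path <- find_input(mat_dir, "matrix.mtx")
  bc_path <- find_input(mat_dir, "barcodes.tsv")
  ft_path <- find_input(mat_dir, c("features.tsv", "genes.tsv"))

  counts <- tryCatch(read_mm(mtx_path), error = function(e) {
    stop("missing input or unreadable matrix: ", mtx_path, " (",
         conditionMessage(e), ")")
  })
  barcodes <- readLines(maybe_gz(bc_path))
  features <- read.delim(maybe_gz(ft_path), header = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(features) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop("matrix dimensions (", nrow(counts), " x ", ncol(counts),
         ") do not match features (", nrow(features), ") / barcodes (",
         length(barcodes), ")")
  }
  gene_ids <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  gene_ids <- make.unique(as.character(gene_ids))
  dimnames(counts) <- list(gene_ids, barcodes)

  spatial <- file.path(dir, "spatial")
  pos_path <- find_input(spatial, c("tissue_positions_list.csv",
                                    "tissue_positions.csv"))
  pos <- read_positions(pos_path)

  sf_path <- find_input(spatial, "scalefactors_json.json")
  sf <- jsonlite::read_json(sf_path)

  img_file <- switch(image,
    lowres = c("tissue_lowres_image.png", "tissue_lowres_image.tiff"),
    hires  = c("tissue_hires_image.png", "tissue_hires_image.tiff"))
  img_path <- find_input(spatial, img_file, required = FALSE)
  images <- list()
  if (length(img_path)) {
    scale <- switch(image,
      lowres = sf$tissue_lowres_scalef,
      hires  = sf$tissue_hires_scalef)
    if (is.null(scale)) scale <- 1
    images[[section_id]] <- section_image(section_id, read_raster(img_path),
                                          as.numeric(scale))
  }

  common <- intersect(barcodes, pos$barcode)
  if (!filter_to_matrix && (length(common) != length(barcodes) ||
                            length(common) != nrow(pos))) {
    stop("barcode mismatch: matrix has ", length(barcodes),
         ", positions file has ", nrow(pos), ", intersection ", length(common))
  }
  if (length(common) == 0) {
    stop("barcode mismatch: no barcode shared between matrix (",
         length(barcodes), ") and positions file (", nrow(pos), ")")
  }
  keep <- barcodes[barcodes %in% common]
  pos <- pos[match(keep, pos$barcode), , drop = FALSE]
  counts <- counts[, keep, drop = FALSE]

  spots <- tibble::tibble(
    barcode = keep,
    section_id = section_id,
    array_row = as.numeric(pos$array_row),
    array_col = as.numeric(pos$array_col),
    px_x = as.numeric(pos$pxl_col_in_fullres),
    px_y = as.numeric(pos$pxl_row_in_fullres),
    in_tissue = as.logical(pos$in_tissue == 1)
  )
  st_dataset(counts, spots, images, spacing_um = 100)
}

POSITION_COLS <- c("barcode", "in_tissue", "array_row", "array_col",
                   "pxl_row_in_fullres", "pxl_col_in_fullres")

read_positions <- function(path) {
  first <- readLines(maybe_gz(path), n = 1)
  has_header <- grepl("barcode", first, fixed = TRUE)
  pos <- read.delim(maybe_gz(path), sep = ",", header = has_header,
                    stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(pos) != 6) {
      stop("headerless positions file must have 6 columns, found ", ncol(pos))
    }
    names(pos) <- POSITION_COLS
  }
  missing_cols <- setdiff(POSITION_COLS, names(pos))
  if (length(missing_cols)) {
    stop("positions file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pos
}

find_input <- function(dir, names, required = TRUE) {
  for (nm in names) {
    for (cand in file.path(dir, c(nm, paste0(nm, ".gz")))) {
      if (file.exists(cand)) return(cand)
    }
  }
  if (required) {
    stop("missing input: ", file.path(dir, names[1]), "[.gz]")
  }
  character(0)
}

maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

read_mm <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("missing input: ", path)
  }
  m <- Matrix::readMM(maybe_gz(path))
  methods::as(m, "CsparseMatrix")
}

read_raster <- function(path) {
  px <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF images requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(px)) == 2) {
    px <- array(rep(px, 3), dim = c(dim(px), 3))
  } else if (dim(px)[3] > 3) {
    px <- px[, , 1:3, drop = FALSE]
  }
  px
}

#' Read a legacy ST count table
#'
#' Legacy Spatial Transcriptomics arrays ship as a plain table with genes on
#' one axis and spot headers encoding array coordinates as `"x_y"` (for
#' example `"12_5"`; adjusted coordinates may be fractional, e.g. `"10_3.5"`).
#' No image accompanies the table; full-resolution pixel coordinates are
#' synthesized as array coordinate times `spacing_um` so that downstream
#' geometry works in a consistent frame.
#'
#' @param counts_path path to a tab- or comma-separated table with gene rows
#'   and `"x_y"` spot columns.
#' @param section_id identifier to assign to this section.
#' @param spacing_um center-to-center spot distance (legacy ST arrays use a
#'   square 200 um lattice; default 100 matches the rest of the package).
#' @return An [st_dataset()] without images.
#' @export
read_legacy_st <- function(counts_path, section_id, spacing_um = 100) {
  if (!file.exists(counts_path)) stop("missing input: ", counts_path)
  tab <- read.delim(maybe_gz(counts_path), header = TRUE, row.names = 1,
                    check.names = FALSE,
                    sep = if (grepl("\\.csv(\\.gz)?$", counts_path)) "," else "\t")
  headers <- colnames(tab)
  parts <- strsplit(headers, "_", fixed = TRUE)
  coords <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    v <- suppressWarnings(as.numeric(p))
    if (length(p) != 2 || anyNA(v)) {
      stop("cannot parse spot header '", headers[i],
           "' as two numbers separated by '_'")
    }
    v
  })
  x <- vapply(coords, `[`, numeric(1), 1)
  y <- vapply(coords, `[`, numeric(1), 2)
  counts <- Matrix::Matrix(as.matrix(tab), sparse = TRUE)
  colnames(counts) <- headers
  spots <- tibble::tibble(
    barcode = headers, section_id = section_id,
    array_row = y, array_col = x,
    px_x = x * spacing_um, px_y = y * spacing_um,
    in_tissue = TRUE
  )
  st_dataset(counts, spots, images = list(), spacing_um = spacing_um)
}

#' Write a dataset as a directory bundle
#'
#' Serializes each section in Space Ranger layout (MatrixMarket matrix,
#' features/barcodes TSV, v1 positions CSV, scale-factors JSON, PNG image)
#' under `dir/<section_id>/`, so a bundle is also a valid Space Ranger
#' fixture and round-trips through [read_spaceranger()] / [read_bundle()].
#'
#' @param ds an [st_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(ds, dir) {
  stopifnot(inherits(ds, "st_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sec in unique(ds$spots$section_id)) {
    sdir <- file.path(dir, sec)
    spdir <- file.path(sdir, "spatial")
    dir.create(spdir, showWarnings = FALSE, recursive = TRUE)
    idx <- which(ds$spots$section_id == sec)
    m <- Matrix::Matrix(ds$counts[, idx, drop = FALSE], sparse = TRUE)
    Matrix::writeMM(m, file.path(sdir, "matrix.mtx"))
    writeLines(ds$spots$barcode[idx], file.path(sdir, "barcodes.tsv"))
    write.table(data.frame(id = rownames(ds$counts),
                           name = rownames(ds$counts),
                           type = "Gene Expression"),
                file.path(sdir, "features.tsv"),
                sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    sp <- ds$spots[idx, ]
    write.table(
      data.frame(sp$barcode, as.integer(sp$in_tissue), sp$array_row,
                 sp$array_col, sp$px_y, sp$px_x),
      file.path(spdir, "tissue_positions_list.csv"),
      sep = ",", quote = FALSE, row.names = FALSE, col.names = FALSE)
    img <- ds$images[[sec]]
    scale <- if (is.null(img)) 1 else img$scale
    jsonlite::write_json(
      list(tissue_lowres_scalef = scale,
           tissue_hires_scalef = scale,
           spot_diameter_fullres = ds$spacing_um * 0.55),
      file.path(spdir, "scalefactors_json.json"), auto_unbox = TRUE)
    if (!is.null(img)) {
      png::writePNG(img$pixels,
                    file.path(spdir, "tissue_lowres_image.png"))
    }
    jsonlite::write_json(list(spacing_um = ds$spacing_um),
                         file.path(sdir, "meta.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a directory bundle written by [write_bundle()]
#'
#' @param dir bundle directory; every subdirectory is read as one section.
#' @return An [st_dataset()] spanning all sections, concatenated in sorted
#'   section-id order.
#' @export
read_bundle <- function(dir) {
  secs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(secs) == 0) stop("missing input: no section directories in ", dir)
  parts <- lapply(secs, function(s) {
    ds <- read_spaceranger(s, basename(s))
    meta <- file.path(s, "meta.json")
    if (file.exists(meta)) {
      sp <- jsonlite::read_json(meta)$spacing_um
      if (!is.null(sp)) ds$spacing_um <- as.numeric(sp)
    }
    ds
  })
  concat_datasets(parts)
}
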