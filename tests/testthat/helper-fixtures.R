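# shared fixture builders and independent brute-force oracles

# minimal Space Ranger-layout fixture on disk; returns its directory
make_spaceranger_fixture <- function(n_genes = 5, n_barcodes = 4,
                                     extra_positions = 0, with_image = TRUE,
                                     dir = tempfile("sr_")) {
  spdir <- file.path(dir, "spatial")
  dir.create(spdir, recursive = TRUE)
  barcodes <- sprintf("BC%02d-1", seq_len(n_barcodes + extra_positions))
  genes <- sprintf("Gene%d", seq_len(n_genes))
  set.seed(99)
  m <- Matrix::Matrix(
    matrix(rpois(n_genes * n_barcodes, 3), n_genes, n_barcodes),
    sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(barcodes[seq_len(n_barcodes)], file.path(dir, "barcodes.tsv"))
  write.table(data.frame(genes, genes, "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n_pos <- n_barcodes + extra_positions
  write.table(
    data.frame(barcodes, 1L, seq_len(n_pos) - 1, 0L,
               100 * seq_len(n_pos), 50 * seq_len(n_pos)),
    file.path(spdir, "tissue_positions_list.csv"),
    sep = ",", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(tissue_lowres_scalef = 0.1,
                            tissue_hires_scalef = 0.5,
                            spot_diameter_fullres = 55),
                       file.path(spdir, "scalefactors_json.json"),
                       auto_unbox = TRUE)
  if (with_image) {
    png::writePNG(array(runif(20 * 30 * 3), c(20, 30, 3)),
                  file.path(spdir, "tissue_lowres_image.png"))
  }
  dir
}

# random spot scatter + neighbor graph (not necessarily a lattice)
random_graph_fixture <- function(n_spots, seed, threshold_um = 150) {
  set.seed(seed)
  spots <- tibble::tibble(
    barcode = sprintf("b%03d", seq_len(n_spots)),
    section_id = "S1",
    array_row = runif(n_spots, 0, 8),
    array_col = runif(n_spots, 0, 8),
    px_x = 0, px_y = 0, in_tissue = TRUE
  )
  build_neighbor_graph(spots, spacing_um = 100, threshold_um = threshold_um)
}

# brute-force spatial lag: explicit double loop over the edge list
oracle_spatial_lag <- function(graph, expr) {
  n <- nrow(graph$nodes)
  adj <- matrix(0, n, n)
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[e]; j <- graph$edges$j[e]
    adj[i, j] <- adj[j, i] <- 1
  }
  lag <- matrix(0, nrow(expr), n)
  for (g in seq_len(nrow(expr))) {
    for (s in seq_len(n)) {
      lag[g, s] <- sum(expr[g, adj[, s] == 1])
    }
  }
  lag
}

# textbook Pearson correlation between expression and assembled lag vectors
oracle_autocorrelation <- function(graph, expr) {
  lag <- oracle_spatial_lag(graph, expr)
  sapply(seq_len(nrow(expr)), function(g) {
    x <- expr[g, ]; l <- lag[g, ]
    if (stats::sd(x) == 0 || stats::sd(l) == 0) NA_real_ else cor(x, l)
  })
}

# brute-force region neighbors: double loop over all node pairs
oracle_region_neighbors <- function(graph, is_target) {
  n <- nrow(graph$nodes)
  adj <- matrix(FALSE, n, n)
  for (e in seq_len(nrow(graph$edges))) {
    adj[graph$edges$i[e], graph$edges$j[e]] <- TRUE
    adj[graph$edges$j[e], graph$edges$i[e]] <- TRUE
  }
  outer_nb <- sort(which(sapply(seq_len(n), function(s) {
    !is_target[s] && any(adj[s, ] & is_target)
  })))
  inner_b <- sort(which(sapply(seq_len(n), function(s) {
    is_target[s] && any(adj[s, ] & !is_target)
  })))
  list(inner = inner_b, outer = outer_nb)
}

as_matrix_xy <- function(p) as.matrix(p[, c("x", "y")])

# rigid transform rotating (and optionally reflecting) about a fixed center
random_rigid_about <- function(center, angle_deg, shift, reflect = FALSE) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  if (reflect) R <- R %*% diag(c(-1, 1))
  M <- diag(3)
  M[1:2, 1:2] <- R
  M[1:2, 3] <- center + shift - as.numeric(R %*% center)
  rigid_transform(M)
}

# analytic asymmetric blob mask for registration tests: a star-like polar
# shape with no rotational or mirror symmetry, centered so that the stated
# perturbations never clip it against the frame
blob_mask_fixture <- function(width = 320, height = 256, seed = 1) {
  set.seed(seed)
  phase <- runif(3, 0, 2 * pi)
  R <- 0.2 * min(width, height)
  cx <- (width - 1) / 2
  cy <- (height - 1) / 2
  cc <- matrix(rep(0:(width - 1), each = height), height)
  rr <- matrix(rep(0:(height - 1), times = width), height)
  theta <- atan2(rr - cy, cc - cx)
  rad <- sqrt((cc - cx)^2 + (rr - cy)^2)
  # mixed harmonics with random phases: no mirror axis, identifiable angle
  r_theta <- R * (1 + 0.18 * sin(2 * theta + phase[1]) +
                    0.14 * cos(3 * theta + phase[2]) +
                    0.1 * sin(5 * theta + phase[3]))
  tissue_mask(paste0("blob", seed), rad <= r_theta)
}
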