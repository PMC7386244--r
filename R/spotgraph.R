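#' Physical spot positions in micrometres
#'
#' Converts array coordinates to physical positions using hexagonal lattice
#' geometry: odd rows are offset by half the spacing in x and the row pitch
#' is `spacing * sqrt(3) / 2`, so that on a Visium-style lattice the nearest
#' center-to-center distance equals `spacing_um` exactly. A `"square"` layout
#' (legacy ST arrays) multiplies both axes by the spacing directly.
#'
#' @param spots spot tibble (as in [st_dataset()]).
#' @param spacing_um center-to-center distance in micrometres.
#' @param layout `"hex"` (Visium, default) or `"square"` (legacy ST).
#' @return The tibble with added columns `pos_x_um`, `pos_y_um`.
#' @export
spot_positions_um <- function(spots, spacing_um = 100,
                              layout = c("hex", "square")) {
  layout <- match.arg(layout)
  if (layout == "hex") {
    odd <- round(spots$array_row) %% 2 == 1
    spots$pos_x_um <- (spots$array_col + 0.5 * odd) * spacing_um
    spots$pos_y_um <- spots$array_row * spacing_um * sqrt(3) / 2
  } else {
    spots$pos_x_um <- spots$array_col * spacing_um
    spots$pos_y_um <- spots$array_row * spacing_um
  }
  spots
}

#' Build the spot neighbor graph
#'
#' Connects spots of the same section whose physical center distance is at
#' most `threshold_um`. With the Visium defaults (100 um spacing, 150 um
#' threshold) each interior lattice spot is connected to exactly its six
#' hexagonal neighbors; spots of different sections are never joined, so
#' multi-section graphs are section-block-diagonal.
#'
#' @param spots spot tibble (as in [st_dataset()]) or an [st_dataset()]
#'   (in-tissue spots are used).
#' @param spacing_um center-to-center distance (default 100).
#' @param threshold_um neighbor distance threshold (default 150).
#' @param layout lattice layout, see [spot_positions_um()].
#' @return An object of class `neighbor_graph`: `nodes` (tibble with
#'   `barcode`, `section_id`, `pos_x_um`, `pos_y_um`), `edges` (tibble with
#'   0-free 1-based node indices `i < j` and `distance_um`), `threshold_um`.
#' @export
build_neighbor_graph <- function(spots, spacing_um = 100, threshold_um = 150,
                                 layout = c("hex", "square")) {
  layout <- match.arg(layout)
  if (inherits(spots, "st_dataset")) {
    spacing_um <- spots$spacing_um
    spots <- spots$spots
  }
  stopifnot(spacing_um > 0, threshold_um > 0)
  spots <- spot_positions_um(tibble::as_tibble(spots), spacing_um, layout)
  n <- nrow(spots)
  edge_list <- list()
  if (n > 0) {
    for (sec in unique(spots$section_id)) {
      idx <- which(spots$section_id == sec)
      if (length(idx) < 2) next
      P <- cbind(spots$pos_x_um[idx], spots$pos_y_um[idx])
      d2 <- outer(rowSums(P^2), rowSums(P^2), "+") - 2 * tcrossprod(P)
      d2[d2 < 0] <- 0
      hit <- which(upper.tri(d2) & d2 <= (threshold_um + 1e-9)^2,
                   arr.ind = TRUE)
      if (nrow(hit) > 0) {
        edge_list[[sec]] <- tibble::tibble(
          i = idx[hit[, 1]], j = idx[hit[, 2]],
          distance_um = sqrt(d2[hit])
        )
      }
    }
  }
  edges <- if (length(edge_list)) {
    dplyr::bind_rows(edge_list)
  } else {
    tibble::tibble(i = integer(0), j = integer(0), distance_um = numeric(0))
  }
  structure(
    list(nodes = spots[, c("barcode", "section_id", "pos_x_um", "pos_y_um")],
         edges = edges, threshold_um = threshold_um),
    class = "neighbor_graph"
  )
}

#' @exportS3Method base::print
print.neighbor_graph <- function(x, ...) {
  cat("neighbor_graph:", nrow(x$nodes), "spots,", nrow(x$edges),
      "edges, threshold", x$threshold_um, "um\n")
  invisible(x)
}

#' Sparse symmetric adjacency matrix of a neighbor graph
#' @param graph a [build_neighbor_graph()] result.
#' @return A symmetric sparse 0/1 [Matrix::sparseMatrix()].
#' @export
graph_adjacency <- function(graph) {
  n <- nrow(graph$nodes)
  Matrix::sparseMatrix(
    i = c(graph$edges$i, graph$edges$j),
    j = c(graph$edges$j, graph$edges$i),
    x = 1, dims = c(n, n)
  )
}

#' Write a neighbor graph as an edge-list TSV
#'
#' Columns: `barcode_i`, `barcode_j`, `section`, `distance_um`.
#'
#' @param graph a [build_neighbor_graph()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  df <- data.frame(
    barcode_i = graph$nodes$barcode[graph$edges$i],
    barcode_j = graph$nodes$barcode[graph$edges$j],
    section = graph$nodes$section_id[graph$edges$i],
    distance_um = graph$edges$distance_um
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spatial lag of expression over the neighbor graph
#'
#' For each gene and spot, the summed expression of that gene across the
#' spot's graph neighbors (a sum, not a mean, so edge spots with fewer
#' neighbors get smaller lags). An isolated spot has lag 0 for every gene.
#'
#' @param graph a [build_neighbor_graph()] result.
#' @param expr genes x spots matrix, columns aligned with `graph$nodes`.
#' @return A genes x spots matrix of lag values.
#' @export
spatial_lag <- function(graph, expr) {
  if (ncol(expr) != nrow(graph$nodes)) {
    stop("expression has ", ncol(expr), " columns but graph has ",
         nrow(graph$nodes), " nodes")
  }
  as.matrix(expr %*% graph_adjacency(graph))
}

#' Rank genes by spatial autocorrelation
#'
#' For each gene, the Pearson correlation between its expression vector and
#' its spatial-lag vector across all spots: genes whose expression varies
#' smoothly over the tissue correlate strongly with their neighborhood sums
#' and rank high, while spatially unstructured genes do not. Spots from all
#' sections are pooled into a single correlation by default (the graph never
#' joins sections, so lags stay within-section); `per_section = TRUE`
#' returns one ranking per section instead.
#'
#' @param graph a [build_neighbor_graph()] result (at least 2 spots).
#' @param expr genes x spots matrix of normalized expression (e.g. clipped
#'   Pearson residuals from [pearson_residuals()] or log-normalized counts),
#'   columns aligned with `graph$nodes`.
#' @param per_section compute one ranking per section (default FALSE).
#' @return A tibble `(gene, r)` sorted by `r` descending, ties broken by
#'   gene identifier; genes whose expression or lag vector has zero variance
#'   get a missing `r` and sort last. With `per_section`, an extra `section_id`
#'   column and sorting within section.
#' @export
rank_spatial_autocorrelation <- function(graph, expr, per_section = FALSE) {
  if (nrow(graph$nodes) < 2) stop("need at least 2 spots")
  if (ncol(expr) != nrow(graph$nodes)) {
    stop("expression has ", ncol(expr), " columns but graph has ",
         nrow(graph$nodes), " nodes")
  }
  genes <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  one_block <- function(cols) {
    E <- as.matrix(expr[, cols, drop = FALSE])
    L <- spatial_lag(subgraph(graph, cols), E)
    Ec <- E - rowMeans(E)
    Lc <- L - rowMeans(L)
    se <- sqrt(rowSums(Ec^2))
    sl <- sqrt(rowSums(Lc^2))
    r <- rowSums(Ec * Lc) / (se * sl)
    r[se == 0 | sl == 0] <- NA
    tibble::tibble(gene = genes, r = as.numeric(r)) |>
      dplyr::arrange(dplyr::desc(.data$r), .data$gene)
  }
  if (!per_section) {
    one_block(seq_len(nrow(graph$nodes)))
  } else {
    purrr::map_dfr(unique(graph$nodes$section_id), function(sec) {
      cols <- which(graph$nodes$section_id == sec)
      dplyr::mutate(one_block(cols), section_id = sec, .before = 1)
    })
  }
}

# induced subgraph on a set of node indices (order preserved)
subgraph <- function(graph, cols) {
  if (length(cols) == nrow(graph$nodes) && all(cols == seq_along(cols))) {
    return(graph)
  }
  pos <- match(seq_len(nrow(graph$nodes)), cols)
  keep <- !is.na(pos[graph$edges$i]) & !is.na(pos[graph$edges$j])
  structure(
    list(nodes = graph$nodes[cols, ],
         edges = tibble::tibble(i = pos[graph$edges$i[keep]],
                                j = pos[graph$edges$j[keep]],
                                distance_um = graph$edges$distance_um[keep]),
         threshold_um = graph$threshold_um),
    class = "neighbor_graph"
  )
}

#' Border spots of a labeled region and its outer neighbors
#'
#' Given region labels, finds the spots just outside a target region (spots
#' not labeled `target` that are graph-adjacent to at least one target spot)
#' and the region's own boundary (target spots adjacent to at least one
#' non-target spot). Typical use: extract the leading edge around a tumor
#' region for edge-vs-core differential expression.
#'
#' @param graph a [build_neighbor_graph()] result.
#' @param labels tibble with columns `barcode`, `section_id`, `label`;
#'   unlabeled spots count as non-target.
#' @param target the region label of interest (must occur in `labels`).
#' @return A tibble of spots with columns `barcode`, `section_id`, `role`
#'   (`"inner_border"` or `"outer_neighbor"`); the two roles are disjoint.
#' @export
region_neighbors <- function(graph, labels, target) {
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("barcode", "section_id", "label") %in% names(labels)))
  key <- function(b, s) paste(b, s, sep = "\r")
  node_key <- key(graph$nodes$barcode, graph$nodes$section_id)
  unknown <- setdiff(key(labels$barcode, labels$section_id), node_key)
  if (length(unknown)) {
    stop(length(unknown), " labeled spot(s) absent from the graph")
  }
  if (!target %in% labels$label) {
    stop("unknown label '", target, "'")
  }
  lab <- rep(NA_character_, nrow(graph$nodes))
  lab[match(key(labels$barcode, labels$section_id), node_key)] <- labels$label
  is_target <- !is.na(lab) & lab == target

  A <- graph_adjacency(graph)
  n_target_nb <- as.numeric(A %*% is_target)
  n_other_nb <- as.numeric(A %*% (!is_target))
  outer_idx <- which(!is_target & n_target_nb > 0)
  inner_idx <- which(is_target & n_other_nb > 0)
  dplyr::bind_rows(
    dplyr::mutate(graph$nodes[inner_idx, c("barcode", "section_id")],
                  role = "inner_border"),
    dplyr::mutate(graph$nodes[outer_idx, c("barcode", "section_id")],
                  role = "outer_neighbor")
  )
}

#' Wilcoxon rank-sum differential expression between two spot groups
#'
#' Two-sided rank-sum test per gene, with exact enumeration of the null
#' distribution when both groups have at most 8 spots and a tie-corrected,
#' continuity-corrected normal approximation otherwise. Genes expressed
#' (count > 0) in less than `min_frac` of the spots of both groups are
#' skipped. P values are adjusted by Benjamini-Hochberg (or Bonferroni).
#'
#' @param expr genes x spots matrix.
#' @param group_a,group_b disjoint spot groups, as column indices or column
#'   names of `expr`, each with at least 2 spots.
#' @param min_frac minimum expressed fraction in at least one group.
#' @param p_adjust `"BH"` (default) or `"bonferroni"`.
#' @return A tibble `(gene, p, p_adjusted, log2_fold_change, frac_a,
#'   frac_b)` sorted by `p`; `log2_fold_change` is `log2((mean_a + 1) /
#'   (mean_b + 1))`.
#' @export
wilcoxon_de <- function(expr, group_a, group_b, min_frac = 0.1,
                        p_adjust = c("BH", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  resolve <- function(g) {
    if (is.character(g)) {
      idx <- match(g, colnames(expr))
      if (anyNA(idx)) stop("unknown spot(s): ",
                           paste(g[is.na(idx)], collapse = ", "))
      idx
    } else as.integer(g)
  }
  ia <- resolve(group_a); ib <- resolve(group_b)
  if (length(intersect(ia, ib)) > 0) stop("groups must be disjoint")
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each group needs at least 2 spots (got ", length(ia), " and ",
         length(ib), ")")
  }
  genes <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  A <- as.matrix(expr[, ia, drop = FALSE])
  B <- as.matrix(expr[, ib, drop = FALSE])
  frac_a <- rowMeans(A > 0)
  frac_b <- rowMeans(B > 0)
  keep <- which(frac_a >= min_frac | frac_b >= min_frac)
  p <- vapply(keep, function(g) {
    rank_sum_test(A[g, ], B[g, ])
  }, numeric(1))
  tibble::tibble(
    gene = genes[keep],
    p = p,
    p_adjusted = stats::p.adjust(p, method = p_adjust),
    log2_fold_change = log2((rowMeans(A)[keep] + 1) /
                              (rowMeans(B)[keep] + 1)),
    frac_a = frac_a[keep],
    frac_b = frac_b[keep]
  ) |>
    dplyr::arrange(.data$p, .data$gene)
}

#' Two-sided rank-sum p value
#'
#' Exact by enumeration of all group assignments when both groups have at
#' most `exact_max` values (ties handled through midranks); otherwise the
#' tie-corrected normal approximation with continuity correction. The exact
#' two-sided p value is the null probability of a rank sum at least as far
#' from its expectation as observed.
#'
#' @param a,b numeric value vectors for the two groups.
#' @param exact_max largest per-group size for the exact path (default 8).
#' @param force one of `"auto"`, `"exact"`, `"normal"` to override the path.
#' @return The two-sided p value.
#' @export
rank_sum_test <- function(a, b, exact_max = 8, force = c("auto", "exact",
                                                         "normal")) {
  force <- match.arg(force)
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  use_exact <- switch(force,
    auto = na <= exact_max && nb <= exact_max,
    exact = TRUE,
    normal = FALSE)
  n <- na + nb
  if (use_exact) {
    e_w <- na * (n + 1) / 2
    dev <- abs(w - e_w)
    combs <- combn(n, na)
    sums <- colSums(matrix(r[combs], nrow = na))
    mean(abs(sums - e_w) >= dev - 1e-9)
  } else {
    e_w <- na * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v_w <- na * nb / 12 * ((n + 1) - tie_term)
    if (v_w <= 0) return(1)
    z <- (w - e_w - sign(w - e_w) * 0.5) / sqrt(v_w)
    min(1, 2 * pnorm(-abs(z)))
  }
}
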