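chain_graph <- function(n = 5) {
  # 1D chain: spots in one row, 100 um apart, threshold 150 um
  spots <- tibble::tibble(
    barcode = letters[1:n], section_id = "S1",
    array_row = 0, array_col = 0:(n - 1),
    px_x = 0, px_y = 0, in_tissue = TRUE
  )
  build_neighbor_graph(spots)
}

test_that("hex lattice neighbor graph has degree six in the interior", {
  g <- build_neighbor_graph(make_hex_grid(10, 10))
  deg <- tabulate(c(g$edges$i, g$edges$j), nrow(g$nodes))
  expect_equal(max(deg), 6)
  interior <- with(g$nodes, which(
    rep(TRUE, 100) &
      make_hex_grid(10, 10)$array_row %in% 1:8 &
      make_hex_grid(10, 10)$array_col %in% 1:8))
  expect_true(all(deg[interior] == 6))
  # undirected, loop-free, within-section
  expect_true(all(g$edges$i < g$edges$j))
})

test_that("edges respect the distance threshold exactly", {
  two <- function(d_cols) {
    spots <- tibble::tibble(
      barcode = c("a", "b"), section_id = "S1",
      array_row = 0, array_col = c(0, d_cols),
      px_x = 0, px_y = 0, in_tissue = TRUE)
    nrow(build_neighbor_graph(spots)$edges)
  }
  expect_equal(two(2), 0)     # 200 um apart
  expect_equal(two(1), 1)     # 100 um apart
  single <- build_neighbor_graph(make_hex_grid(1, 1))
  expect_equal(nrow(single$edges), 0)
})

test_that("spots of different sections are never joined", {
  spots <- dplyr::bind_rows(
    make_hex_grid(3, 3, section_id = "A"),
    make_hex_grid(3, 3, section_id = "B"))
  g <- build_neighbor_graph(spots)
  sec <- g$nodes$section_id
  expect_true(all(sec[g$edges$i] == sec[g$edges$j]))
})

test_that("graphs export as edge-list TSV", {
  g <- chain_graph(4)
  f <- tempfile(fileext = ".tsv")
  write_graph_tsv(g, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("barcode_i", "barcode_j", "section", "distance_um"))
  expect_true(all(tab$distance_um == 100))
})

test_that("spatial lag equals the brute-force neighbor sum", {
  g <- chain_graph(5)
  expr <- matrix(c(1, 2, 3, 4, 5), 1)
  lag <- spatial_lag(g, expr)
  expect_equal(as.numeric(lag), c(2, 4, 6, 8, 4))  # interior: sum of 2

  # isolated node
  spots <- tibble::tibble(barcode = c("a", "b"), section_id = "S1",
                          array_row = c(0, 5), array_col = c(0, 5),
                          px_x = 0, px_y = 0, in_tissue = TRUE)
  gi <- build_neighbor_graph(spots)
  expect_equal(as.numeric(spatial_lag(gi, matrix(c(7, 9), 1))), c(0, 0))

  g50 <- random_graph_fixture(50, seed = 21)
  set.seed(22)
  E <- matrix(rnorm(50 * 8), 8)
  expect_lt(max(abs(spatial_lag(g50, E) - oracle_spatial_lag(g50, E))),
            1e-10)

  expect_error(spatial_lag(g50, E[, 1:10]), "columns")
})

test_that("autocorrelation ranking matches the assembled-vector oracle", {
  g <- random_graph_fixture(30, seed = 31)
  set.seed(32)
  E <- matrix(rnorm(30 * 20), 20,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  rk <- rank_spatial_autocorrelation(g, E)
  oracle <- oracle_autocorrelation(g, E)
  expect_lt(max(abs(rk$r[match(rownames(E), rk$gene)] - oracle)), 1e-10)
  expect_false(is.unsorted(rev(rk$r), na.rm = TRUE))
})

test_that("spatial structure outranks its own permutation; constants last", {
  set.seed(41)
  spots <- make_hex_grid(10, 10)
  g <- build_neighbor_graph(spots)
  pos <- spot_positions_um(spots, 100)
  gradient <- pos$pos_x_um + pos$pos_y_um
  E <- rbind(gradient = gradient,
             permuted = sample(gradient),
             constant = rep(3, 100))
  rk <- rank_spatial_autocorrelation(g, E)
  expect_equal(rk$gene[1], "gradient")
  expect_true(is.na(rk$r[rk$gene == "constant"]))
  expect_equal(rk$gene[3], "constant")
  r_by_gene <- setNames(rk$r, rk$gene)
  expect_gt(r_by_gene["gradient"], r_by_gene["permuted"])
})

test_that("region neighbors on a chain and against brute force", {
  g <- chain_graph(5)
  labels <- tibble::tibble(barcode = letters[1:5], section_id = "S1",
                           label = c("bg", "bg", "roi", "bg", "bg"))
  rn <- region_neighbors(g, labels, "roi")
  expect_equal(sort(rn$barcode[rn$role == "outer_neighbor"]), c("b", "d"))
  expect_equal(rn$barcode[rn$role == "inner_border"], "c")

  all_roi <- dplyr::mutate(labels, label = "roi")
  expect_equal(nrow(region_neighbors(g, all_roi, "roi")), 0)

  expect_error(region_neighbors(g, labels, "nope"), "unknown label")

  for (s in 1:20) {
    gr <- random_graph_fixture(25, seed = 100 + s)
    set.seed(200 + s)
    is_t <- runif(25) < 0.3
    if (!any(is_t)) is_t[1] <- TRUE
    lab <- tibble::tibble(barcode = gr$nodes$barcode, section_id = "S1",
                          label = ifelse(is_t, "t", "o"))
    rn <- region_neighbors(gr, lab, "t")
    oracle <- oracle_region_neighbors(gr, is_t)
    expect_equal(sort(match(rn$barcode[rn$role == "inner_border"],
                            gr$nodes$barcode)), oracle$inner)
    expect_equal(sort(match(rn$barcode[rn$role == "outer_neighbor"],
                            gr$nodes$barcode)), oracle$outer)
  }
})

test_that("rank-sum test: exact path on small groups", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(rank_sum_test(c(5, 7, 5, 7), c(7, 5, 5, 7)), 1)
  # agreement with the standard implementation (no ties, exact)
  set.seed(51)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    expect_equal(rank_sum_test(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("rank-sum test: normal path matches the standard implementation", {
  set.seed(52)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(12)
    a[1:3] <- b[1:3]  # force ties
    expect_equal(rank_sum_test(a, b, force = "normal"),
                 stats::wilcox.test(a, b, exact = FALSE,
                                    correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("wilcoxon_de finds a planted shift and validates inputs", {
  set.seed(61)
  n <- 60
  E <- matrix(abs(rnorm(100 * n, 5, 1)), 100, n,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  E[7, 1:30] <- E[7, 1:30] + 3   # 3 SD shift in group A
  de <- wilcoxon_de(E, 1:30, 31:60)
  expect_equal(de$gene[which.min(de$p_adjusted)], "g007")
  expect_true(all(de$p_adjusted >= de$p - 1e-12))
  expect_gt(de$log2_fold_change[de$gene == "g007"], 0)

  expect_error(wilcoxon_de(E, 1:30, 30:60), "disjoint")
  expect_error(wilcoxon_de(E, 1, 2:10), "at least 2")
})

test_that("lowly expressed genes are skipped by the expression filter", {
  E <- rbind(on = c(5, 6, 7, 8, 1, 2, 1, 3),
             off = c(0, 0, 0, 0, 0, 0, 1, 0))
  de <- wilcoxon_de(E, 1:4, 5:8, min_frac = 0.5)
  expect_equal(de$gene, "on")
})
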