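square_mask <- function() {
  m <- matrix(FALSE, 10, 10)
  m[4:7, 4:7] <- TRUE
  tissue_mask("sq", m)
}

test_that("edge extraction returns exactly the boundary pixels", {
  pts <- extract_edge_points(square_mask())
  expect_equal(nrow(pts), 12)  # 4x4 block minus its 2x2 interior
  # all points on the block perimeter
  expect_true(all(pts$x %in% 3:6 & pts$y %in% 3:6))
  expect_false(any(pts$x %in% 4:5 & pts$y %in% 4:5))

  expect_error(extract_edge_points(tissue_mask("f", matrix(TRUE, 5, 5))),
               "degenerate")
  expect_error(extract_edge_points(tissue_mask("e", matrix(FALSE, 5, 5))),
               "degenerate")
})

test_that("edge count of a disk tracks its perimeter", {
  r <- 30
  m <- matrix(FALSE, 80, 80)
  ctr <- 40
  for (i in 1:80) for (j in 1:80) {
    m[i, j] <- (i - ctr)^2 + (j - ctr)^2 <= r^2
  }
  pts <- extract_edge_points(tissue_mask("d", m), max_points = 5000)
  expect_gte(nrow(pts), 2 * pi * r * 0.7)
  expect_lte(nrow(pts), 2 * pi * r * 1.5)
})

test_that("subsampling caps the point count deterministically", {
  mask <- blob_mask_fixture(seed = 2)
  a <- extract_edge_points(mask, max_points = 100, seed = 7)
  b <- extract_edge_points(mask, max_points = 100, seed = 7)
  expect_equal(nrow(a), 100)
  expect_identical(a, b)
})

test_that("apply_rigid matches closed forms and preserves distances", {
  id <- rigid_transform(diag(3))
  P <- matrix(c(0, 0, 1, 0, 2.5, -3), ncol = 2, byrow = TRUE)
  expect_equal(apply_rigid(P, id), P)

  tr <- rigid_transform(matrix(c(1, 0, 5, 0, 1, 7, 0, 0, 1), 3, byrow = TRUE))
  expect_equal(apply_rigid(matrix(c(0, 0), 1), tr), matrix(c(5, 7), 1))

  rot90 <- rigid_transform(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3,
                                  byrow = TRUE))
  expect_equal(apply_rigid(matrix(c(1, 0), 1), rot90), matrix(c(0, 1), 1),
               tolerance = 1e-12)

  # isometry on random point sets
  set.seed(8)
  for (i in 1:5) {
    th <- runif(1, -pi, pi)
    M <- diag(3)
    M[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    M[1:2, 3] <- runif(2, -20, 20)
    tr <- rigid_transform(M)
    X <- matrix(rnorm(40), ncol = 2)
    dx <- dist(X)
    dy <- dist(apply_rigid(X, tr))
    expect_lt(max(abs(dx - dy)), 1e-9)
  }
})

test_that("ICP recovers known rotations, translations and reflections", {
  mask <- blob_mask_fixture(seed = 3)
  target <- extract_edge_points(mask, seed = 1)

  # identity
  tr0 <- icp_register(target, target)
  expect_lt(tr0$rmsd, 1e-9)
  expect_false(tr0$is_reflection)

  # known rotation + shift: perturb the mask, register back
  pert <- perturb_section(mask, angle_deg = 25, shift_px = c(30, -12))
  src <- extract_edge_points(pert$mask, seed = 1)
  tr <- icp_register(src, target)
  ang <- atan2(tr$matrix[2, 1], tr$matrix[1, 1]) * 180 / pi
  expect_equal(ang, -25, tolerance = 1)
  P <- as_matrix_xy(target)
  mapped <- apply_rigid(apply_rigid(P, pert$transform), tr)
  expect_lt(sqrt(mean(rowSums((mapped - P)^2))), 0.5)

  # mirrored source needs the reflection branch
  mir <- perturb_section(mask, angle_deg = 10, shift_px = c(5, 3),
                         reflect = TRUE)
  srcm <- extract_edge_points(mir$mask, seed = 1)
  trm <- icp_register(srcm, target, allow_reflection = TRUE)
  expect_true(trm$is_reflection)
  mappedm <- apply_rigid(apply_rigid(P, mir$transform), trm)
  expect_lt(sqrt(mean(rowSums((mappedm - P)^2))), 0.5)
  trno <- icp_register(srcm, target, allow_reflection = FALSE)
  expect_gt(trno$rmsd, 5 * trm$rmsd)

  expect_error(icp_register(target[1:2, ], target), "3 points")
})

test_that("the ICP objective trace is non-increasing", {
  mask <- blob_mask_fixture(seed = 4)
  target <- extract_edge_points(mask, seed = 1)
  pert <- perturb_section(mask, angle_deg = -35, shift_px = c(-20, 14))
  src <- extract_edge_points(pert$mask, seed = 1)
  tr <- icp_register(src, target)
  trace <- attr(tr, "trace")
  expect_true(all(diff(trace) <= 1e-9))
})

test_that("backward warp is exact for identity and integer shifts", {
  sim <- simulate_section_image(120, 100, n_nuclei = 10, seed = 5)
  img <- sim$image
  id <- rigid_transform(diag(3))
  w <- warp_image_backward(img, id)
  expect_lt(max(abs(w$pixels - img$pixels)), 1e-6)

  sh <- rigid_transform(matrix(c(1, 0, 10, 0, 1, 0, 0, 0, 1), 3,
                               byrow = TRUE))
  ws <- warp_image_backward(img, sh)
  expect_equal(ws$pixels[, 11:100, ], img$pixels[, 1:90, ], tolerance = 1e-9)
  expect_true(all(ws$pixels[, 1:10, ] == 1))  # vacated strip = white fill

  # rotate +90 then -90 about the center: interior round-trip error small
  ctr <- c((100 - 1) / 2, (120 - 1) / 2)
  rot <- function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    M <- diag(3)
    M[1:2, 1:2] <- R
    M[1:2, 3] <- ctr - R %*% ctr
    rigid_transform(M)
  }
  r1 <- warp_image_backward(img, rot(pi / 2))
  r2 <- warp_image_backward(r1, rot(-pi / 2))
  inner_r <- 30:90; inner_c <- 30:70
  expect_lt(mean(abs(r2$pixels[inner_r, inner_c, ] -
                       img$pixels[inner_r, inner_c, ])), 0.02)
})

test_that("align_stack recovers perturbations with identity at reference", {
  mask <- blob_mask_fixture(seed = 6)
  p2 <- perturb_section(mask, angle_deg = 20, shift_px = c(30, 8))
  p3 <- perturb_section(mask, angle_deg = -20, shift_px = c(-25, 15))
  trs <- align_stack(list(mask, p2$mask, p3$mask))
  expect_equal(trs[[1]]$matrix, diag(3))
  P <- as_matrix_xy(extract_edge_points(mask, seed = 1))
  for (i in 2:3) {
    true_tr <- list(p2, p3)[[i - 1]]$transform
    mapped <- apply_rigid(apply_rigid(P, true_tr), trs[[i]])
    expect_lt(sqrt(mean(rowSums((mapped - P)^2))), 0.5)
  }

  trs2 <- align_stack(list(mask, p2$mask, p3$mask), reference_index = 3)
  expect_equal(trs2[[3]]$matrix, diag(3))

  bad <- tissue_mask("empty", matrix(FALSE, 10, 10))
  expect_error(align_stack(list(mask, bad)), "empty")
})

test_that("spot coordinates follow their images through a transform", {
  spots <- make_hex_grid(3, 3)
  id <- rigid_transform(diag(3))
  expect_equal(map_spot_coordinates(spots, id, 0.5), spots)

  sh <- rigid_transform(matrix(c(1, 0, 10, 0, 1, 0, 0, 0, 1), 3,
                               byrow = TRUE))
  out <- map_spot_coordinates(spots, sh, scale = 0.1)
  expect_equal(out$px_x, spots$px_x + 100)
  expect_equal(out$px_y, spots$px_y)
})

test_that("spots transformed with a mask's transform stay under its warp", {
  # the mask warp is nearest-neighbor rasterized, so only spots within
  # ~1 px of the tissue boundary are at risk; a large blob keeps that
  # ring below 1% of the in-tissue spots
  mask <- blob_mask_fixture(800, 640, seed = 11)
  spots <- make_hex_grid(40, 50, spacing_um = 100,
                         px_origin = c(20, 20), px_per_um = 0.15)
  rr <- round(spots$px_y) + 1
  cc <- round(spots$px_x) + 1
  under <- mask$pixels[cbind(rr, cc)]
  expect_gt(sum(under), 100)
  pert <- perturb_section(mask, angle_deg = 15, shift_px = c(8, -6))
  moved <- map_spot_coordinates(spots[under, ], pert$transform, scale = 1)
  rr2 <- pmin(pmax(round(moved$px_y) + 1, 1), 640)
  cc2 <- pmin(pmax(round(moved$px_x) + 1, 1), 800)
  frac_inside <- mean(pert$mask$pixels[cbind(rr2, cc2)])
  expect_gte(frac_inside, 0.99)
})

test_that("transforms survive a JSON round trip", {
  mask <- blob_mask_fixture(seed = 7)
  pert <- perturb_section(mask, 15, c(4, -9), reflect = TRUE)
  path <- tempfile(fileext = ".json")
  write_transforms(list(A = pert$transform), path, scale = 0.4)
  back <- read_transforms(path)
  expect_equal(back$A$matrix, pert$transform$matrix, tolerance = 1e-12)
  expect_true(back$A$is_reflection)
  expect_equal(attr(back, "scale"), 0.4)
})
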