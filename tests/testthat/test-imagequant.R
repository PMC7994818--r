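# Image quantification: projections, segmentation, morphometry,
# intensities, junction areas.

test_that("maximum projections behave on constant and single-voxel stacks", {
  a <- array(3, c(8, 8, 5))
  st <- image_stack(list(dapi = a), 0.1, 0.28)
  expect_true(all(max_project(st, "z", "dapi") == 3))
  b <- array(0, c(8, 8, 5)); b[3, 6, 2] <- 7
  st2 <- image_stack(list(dapi = b), 0.1, 0.28)
  pz <- max_project(st2, "z", "dapi")
  expect_equal(which(pz == 7, arr.ind = TRUE)[1, ], c(row = 3, col = 6))
  py <- max_project(st2, "y", "dapi")
  expect_equal(which(py == 7, arr.ind = TRUE)[1, ], c(row = 3, col = 2))
  expect_equal(attr(py, "pixel_size"), c(0.1, 0.28))
})

test_that("projection Lamin level is a masked mean and is linear in intensity", {
  # synthetic projection: bright disc on dark background
  a <- array(0, c(40, 40, 3))
  xy <- expand.grid(1:40, 1:40)
  disc <- (xy[[1]] - 20)^2 + (xy[[2]] - 20)^2 <= 100
  for (z in 1:3) a[, , z][as.matrix(xy)[disc, ]] <- 10
  st <- image_stack(list(lamin = a), 0.1, 0.28)
  rep1 <- lamin_level_projection(st, "lamin")
  expect_equal(rep1$mean_intensity, 10)
  expect_equal(rep1$n_pixels, sum(disc))
  # homogeneous of degree 1
  st2 <- image_stack(list(lamin = 2 * a), 0.1, 0.28)
  expect_equal(lamin_level_projection(st2)$mean_intensity,
               2 * rep1$mean_intensity)
  # degenerate constant image
  stc <- image_stack(list(lamin = array(5, c(8, 8, 2))), 0.1, 0.28)
  expect_error(lamin_level_projection(stc), "degenerate")
})

test_that("projection Lamin level ranks a 4-fold cohort correctly", {
  im <- fast_imaging()
  levels <- seq(1, 4, length.out = 12)
  meas <- vapply(seq_along(levels), function(i) {
    st <- render_nucleus_stack(2.5, 1.8, levels[i], im, seed = 50 + i)
    lamin_level_projection(st, "lamin")$mean_intensity
  }, numeric(1))
  expect_gt(correlation(meas, levels, "spearman"), 0.95)
})

test_that("3D segmentation recovers volumes and keeps the largest component", {
  im0 <- fast_imaging(psf_sigma = 0, noise = FALSE)
  st <- render_nucleus_stack(3, 3, 2, im0, seed = 1)
  msk <- segment_nucleus_3d(st, "dapi")
  vol <- sum(msk$mask) * im0$voxel_xy^2 * im0$voxel_z
  expect_equal(vol, 4 / 3 * pi * 27, tolerance = 0.05)
  # two components, one 10x larger: only the larger survives
  a <- array(0, c(30, 30, 12))
  a[5:24, 5:24, 3:10] <- 100        # 3200 voxels
  a[27:29, 27:29, 5:6] <- 100       # 18 voxels
  st2 <- image_stack(list(dapi = a), 0.1, 0.28)
  m2 <- segment_nucleus_3d(st2, "dapi", despeckle = FALSE)
  expect_true(all(m2$mask[5:24, 5:24, 3:10]))
  expect_false(any(m2$mask[27:29, 27:29, ]))
  expect_error(segment_nucleus_3d(st2, "dapi", threshold = 1000),
               "no foreground")
})

test_that("morphometry recovers spheres, oblates and survives rotation", {
  im0 <- fast_imaging(psf_sigma = 0, noise = FALSE)
  st <- render_nucleus_stack(3, 3, 2, im0, seed = 1)
  mor <- nucleus_morphometry(segment_nucleus_3d(st, "dapi"))
  expect_equal(mor$cross_section_area, pi * 9, tolerance = 0.03)
  expect_equal(mor$height, 6, tolerance = 0.03)
  expect_equal(mor$d_nuc, 0, tolerance = 0.05)
  # oblate at default noise: within 0.1 of the analytic index
  im <- fast_imaging()
  st2 <- render_nucleus_stack(4, 1.5, 2, im, seed = 2)
  m2 <- segment_nucleus_3d(st2, "dapi")
  mor2 <- nucleus_morphometry(m2)
  expect_equal(mor2$d_nuc, 2 * log(4 / 1.5), tolerance = 0.1)
  # rotating 90 degrees about z leaves the measures unchanged within 2%
  rot <- m2
  rot$mask <- aperm(m2$mask, c(2, 1, 3))[, dim(m2$mask)[1]:1, ]
  mr <- nucleus_morphometry(rot)
  expect_equal(mr$cross_section_area, mor2$cross_section_area,
               tolerance = 0.02)
  expect_equal(mr$height, mor2$height, tolerance = 0.02)
  # degenerate single-plane mask
  one <- m2
  one$mask[, , -10] <- FALSE
  expect_error(nucleus_morphometry(one), "single z plane")
})

test_that("measured height is insensitive to the axial voxel size", {
  for (vz in c(0.28, 0.18)) {
    im <- imaging_params(voxel_xy = 0.12, voxel_z = vz)
    st <- render_nucleus_stack(2, 3, 2, im, seed = 6)
    h <- nucleus_morphometry(segment_nucleus_3d(st, "dapi"))$height
    expect_equal(h, 6, tolerance = 0.28 / 6) # within one coarse voxel
  }
})

test_that("cell height extends the nuclear height to the cell top", {
  im0 <- fast_imaging(psf_sigma = 0, noise = FALSE)
  st <- render_nucleus_stack(2, 2, 2, im0, seed = 1)
  msk <- segment_nucleus_3d(st, "dapi")
  h_nuc <- nucleus_morphometry(msk)$height
  top <- max(which(apply(msk$mask, 3, any))) * msk$voxel_z
  expect_equal(cell_height_from_nucleus(msk, top), h_nuc)
  expect_equal(cell_height_from_nucleus(msk, top + 2), h_nuc + 2)
  expect_error(cell_height_from_nucleus(msk, top - 1), "below")
  # columnar cell: nucleus height + gap recovers the true height
  truth_gap <- 12 - 4 # 4 um nucleus in a 12 um cell
  nuc_top_true <- max(which(apply(msk$mask, 3, any))) * msk$voxel_z
  h_cell <- cell_height_from_nucleus(msk, nuc_top_true + truth_gap)
  expect_equal(h_cell, 12, tolerance = 0.28 / 12)
})

test_that("in-mask 3D intensities are exact on uniform masks and track 2-fold changes", {
  a <- array(0, c(20, 20, 8)); a[5:15, 5:15, 3:6] <- 7
  m <- list(mask = a > 0, voxel_xy = 0.1, voxel_z = 0.28)
  class(m) <- "nuclear_mask"
  st <- image_stack(list(lamin = a), 0.1, 0.28)
  rep1 <- lamin_in_nucleus_3d(st, m, "lamin")
  expect_equal(rep1$mean_intensity, 7)
  expect_equal(rep1$total_intensity, 7 * sum(m$mask))
  # mask disjoint from signal sees background only
  m2 <- m; m2$mask[] <- FALSE; m2$mask[1:2, 1:2, 1] <- TRUE
  expect_equal(lamin_in_nucleus_3d(st, m2)$mean_intensity, 0)
  # rendered two-level comparison: ratio within 10%
  im <- fast_imaging()
  means <- vapply(c(1.5, 3), function(lv) {
    vals <- vapply(1:6, function(i) {
      st <- render_nucleus_stack(2.5, 1.8, lv, im, seed = 70 + i + lv * 10)
      msk <- segment_nucleus_3d(st, "dapi")
      lamin_in_nucleus_3d(st, msk, "lamin")$mean_intensity
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_equal(means[2] / means[1], 2, tolerance = 0.1)
})

test_that("apico-basal profiles detect constructed asymmetry", {
  im0 <- fast_imaging(noise = FALSE)
  st <- render_nucleus_stack(2.5, 2, 2, im0, seed = 1)
  msk <- segment_nucleus_3d(st, "dapi")
  pr <- apicobasal_profile(st, msk, "lamin")
  expect_equal(pr$apical_basal_ratio, 1, tolerance = 0.05)
  expect_equal(nrow(pr$profile), sum(apply(msk$mask, 3, any)))
  # double the apical half of the lamin channel
  st2 <- st
  nz <- dim(st$channels$lamin)[3]
  mid <- ceiling(nz / 2)
  st2$channels$lamin[, , (mid + 1):nz] <-
    2 * st2$channels$lamin[, , (mid + 1):nz]
  pr2 <- apicobasal_profile(st2, msk, "lamin")
  expect_equal(pr2$apical_basal_ratio, 2, tolerance = 0.15)
  thin <- msk
  thin$mask[, , -(mid + (-1:1))] <- FALSE
  expect_error(apicobasal_profile(st, thin), "fewer than 4")
})

test_that("junction-derived areas are accurate and scale with pixel area", {
  s <- 10
  grid <- as.matrix(expand.grid(x = s * (1:5), y = s * (1:5)))
  jn <- render_junction_image(grid, seed = 3)
  areas <- apical_areas_from_junctions(jn$image, jn$pixel_size)
  expect_equal(nrow(areas), 9) # 3 x 3 interior cells
  expect_equal(areas$area_um2, rep(s^2, 9), tolerance = 0.05)
  # doubling the pixel size quadruples the reported areas
  areas2 <- apical_areas_from_junctions(jn$image, 2 * jn$pixel_size)
  expect_equal(areas2$area_um2, 4 * areas$area_um2)
  # random field round-trip: median relative error < 5%
  set.seed(13)
  centers <- matrix(runif(240, 0, 60), ncol = 2)
  jf <- render_junction_image(centers, seed = 13)
  af <- apical_areas_from_junctions(jf$image, jf$pixel_size)
  tr <- jf$truth[!jf$truth$border, ]
  tx <- tr$center_x - (min(centers[, 1]) - 2)
  ty <- tr$center_y - (min(centers[, 2]) - 2)
  idx <- vapply(seq_len(nrow(af)), function(i)
    which.min((tx - af$centroid_x[i])^2 + (ty - af$centroid_y[i])^2),
    integer(1))
  rel <- abs(af$area_um2 - tr$area_um2[idx]) / tr$area_um2[idx]
  expect_lt(median(rel), 0.05)
  expect_error(apical_areas_from_junctions(matrix(100, 20, 20)),
               "enclosed")
})

test_that("normalization to a reference group is exact and scale invariant", {
  v <- c(2, 2, 2, 6)
  g <- c("ref", "ref", "ref", "other")
  expect_equal(normalize_to_reference(v, g, "ref"), c(1, 1, 1, 3))
  expect_equal(normalize_to_reference(10 * v, g, "ref"),
               normalize_to_reference(v, g, "ref"))
  expect_equal(normalize_to_reference(rep(4, 5), rep("a", 5), "a"),
               rep(1, 5))
  expect_error(normalize_to_reference(v, g, "missing"), "reference")
})

test_that("image stacks round-trip through TIFF and sidecar", {
  im <- fast_imaging()
  st <- render_nucleus_stack(2, 1.5, 2, im, seed = 4)
  pre <- file.path(withr::local_tempdir(), "nuc")
  write_image_stack(st, pre)
  st2 <- read_image_stack(pre)
  expect_equal(st2$voxel_xy, st$voxel_xy)
  expect_equal(st2$voxel_z, st$voxel_z)
  # 16-bit quantisation: relative error bounded by the scale / 2^16
  for (ch in names(st$channels))
    expect_lt(max(abs(st2$channels[[ch]] - st$channels[[ch]])),
              max(st$channels[[ch]]) / 65535 + 1e-9)
})
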