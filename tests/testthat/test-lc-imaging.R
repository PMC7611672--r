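test_that("CNR map equals the voxelwise formula (loop oracle)", {
  set.seed(1)
  ph <- make_phantom(seed = 1)
  cnr <- compute_cnr_map(ph$volume, ph$ref)
  m <- mean(ph$volume[ph$ref$mask])
  s <- sd(ph$volume[ph$ref$mask])
  d <- dim(ph$volume)
  # independent elementwise loop over a random subset of voxels
  idx <- cbind(sample(d[1], 200, TRUE), sample(d[2], 200, TRUE),
               sample(d[3], 200, TRUE))
  for (r in seq_len(nrow(idx))) {
    v <- ph$volume[idx[r, 1], idx[r, 2], idx[r, 3]]
    expect_equal(cnr[idx[r, 1], idx[r, 2], idx[r, 3]], (v - m) / s,
                 tolerance = 1e-12)
  }
  # reference region normalises to mean 0, SD 1
  expect_equal(mean(cnr[ph$ref$mask]), 0, tolerance = 1e-12)
  expect_equal(sd(cnr[ph$ref$mask]), 1, tolerance = 1e-12)
})

test_that("CNR is invariant to affine intensity rescaling", {
  ph <- make_phantom(seed = 2)
  cnr1 <- compute_cnr_map(ph$volume, ph$ref)
  cnr2 <- compute_cnr_map(3.7 * ph$volume + 120, ph$ref)
  expect_equal(as.numeric(cnr1), as.numeric(cnr2), tolerance = 1e-9)
})

test_that("zero-variance reference region errors", {
  vol <- array(5, c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  expect_error(compute_cnr_map(vol, reference_region(mask)), "variance")
})

test_that("a voxel at Mean_REF + 5 SD sits exactly at the threshold", {
  d <- c(10, 10, 5)
  vol <- array(1000, d)
  mask <- array(FALSE, d)
  mask[1:5, , ] <- TRUE
  ref <- reference_region(mask, mean = 1000, sd = 50)
  vol[8, 8, 3] <- 1000 + 5 * 50
  vol[8, 2, 3] <- 1000 + 5.01 * 50
  cnr <- compute_cnr_map(vol, ref)
  expect_equal(cnr[8, 8, 3], 5)
  search <- !mask
  seg <- suppressWarnings(segment_lc(cnr, search))
  expect_false(seg[8, 8, 3])   # strict inequality at the boundary
  expect_true(seg[8, 2, 3])
})

test_that("segmentation recovers planted tubes exactly and is monotone in the threshold", {
  ph <- make_phantom(cnr = c(8, 8, 8), noise_sd = 0, noise_sd_nominal = 50,
                     lc_z = 10:13, seed = 3)
  expect_equal(sum(ph$truth), 8)  # two 4-slice tubes
  cnr <- compute_cnr_map(ph$volume, ph$ref)
  seg <- segment_lc(cnr, ph$search_mask)
  expect_identical(which(seg), which(ph$truth))
  # uniform volume below threshold -> empty mask with warning
  quiet <- make_phantom(cnr = c(2, 2, 2), noise_sd = 0,
                        noise_sd_nominal = 50, seed = 4)
  qcnr <- compute_cnr_map(quiet$volume, quiet$ref)
  expect_warning(empty <- segment_lc(qcnr, quiet$search_mask), "empty")
  expect_false(any(empty))
  # monotone: higher threshold is a subset
  noisy <- make_phantom(seed = 5)
  ncnr <- compute_cnr_map(noisy$volume, noisy$ref)
  m4 <- suppressWarnings(segment_lc(ncnr, noisy$search_mask, k_sd = 4))
  m6 <- suppressWarnings(segment_lc(ncnr, noisy$search_mask, k_sd = 6))
  expect_true(all(which(m6) %in% which(m4)))
})

test_that("atlas probabilities live on the k/N lattice and are order-invariant", {
  set.seed(6)
  d <- c(8, 8, 6)
  masks <- lapply(1:29, function(i) array(runif(prod(d)) < 0.1, d))
  atlas <- build_atlas(masks)
  expect_true(all(abs(atlas$prob * 29 - round(atlas$prob * 29)) < 1e-9))
  shuffled <- build_atlas(masks[sample(29)])
  expect_equal(atlas$prob, shuffled$prob)
  # a voxel present in 3 of 29 subjects: in the 5% mask, not the 25% one
  target <- masks
  for (i in 1:29) target[[i]][1, 1, 1] <- i <= 3
  a2 <- build_atlas(target)
  expect_equal(a2$prob[1, 1, 1], 3 / 29)
  expect_true(atlas_mask(a2, 0.05)[1, 1, 1])
  expect_false(atlas_mask(a2, 0.25)[1, 1, 1])
  # identical masks give probabilities exactly 0 or 1; disjoint give 1/N
  same <- build_atlas(masks[c(1, 1, 1)])
  expect_true(all(same$prob %in% c(0, 1)))
})

test_that("extraction averages atlas voxels with correct subdivision ordering", {
  ph <- make_phantom(cnr = c(3, 6, 6), noise_sd = 0, noise_sd_nominal = 50,
                     seed = 7)
  cnr <- compute_cnr_map(ph$volume, ph$ref)
  summ <- extract_lc_cnr(cnr, ph$truth)
  both <- summ[summ$side == "both", ]
  get <- function(sx) both$mean_cnr[both$subdivision == sx]
  expect_equal(get("caudal"), 3)
  expect_lt(get("caudal"), get("middle"))
  expect_equal(get("middle"), 6)
  expect_equal(get("rostral"), 6)
  # whole equals the voxel-count-weighted mean of the subdivisions
  subs <- both[both$subdivision != "whole", ]
  expect_equal(both$mean_cnr[both$subdivision == "whole"],
               sum(subs$mean_cnr * subs$n_voxels) / sum(subs$n_voxels),
               tolerance = 1e-12)
  # constant CNR inside the atlas -> every summary equals it
  flat <- make_phantom(cnr = c(4, 4, 4), noise_sd = 0,
                       noise_sd_nominal = 50, seed = 8)
  fc <- compute_cnr_map(flat$volume, flat$ref)
  fs <- extract_lc_cnr(fc, flat$truth)
  expect_true(all(abs(fs$mean_cnr - 4) < 1e-9))
  # left/right split covers the whole structure
  expect_equal(sum(summ$n_voxels[summ$side != "both" &
                                   summ$subdivision == "whole"]),
               summ$n_voxels[summ$side == "both" &
                               summ$subdivision == "whole"])
})

test_that("a 25% mask extracts over a subset of the 5% voxels", {
  set.seed(9)
  masks <- lapply(1:20, function(i) {
    m <- array(FALSE, c(8, 8, 6))
    m[4:5, 4, 2:5] <- runif(8) < 0.5
    m
  })
  atlas <- build_atlas(masks)
  vol <- array(rnorm(prod(c(8, 8, 6)), 3, 0.5), c(8, 8, 6))
  n05 <- sum(atlas_mask(atlas, 0.05))
  n25 <- sum(atlas_mask(atlas, 0.25))
  expect_lte(n25, n05)
  if (n25 > 0) {
    s25 <- extract_lc_cnr(vol, atlas, 0.25)
    expect_true(all(s25$n_voxels[s25$subdivision == "whole" &
                                   s25$side == "both"] >= 1))
  }
})

test_that("volumes round-trip through NIfTI", {
  ph <- make_phantom(seed = 10)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, path)
  back <- read_volume(path)
  expect_equal(dim(back), dim(ph$volume))
  expect_equal(as.numeric(back), as.numeric(ph$volume), tolerance = 1e-6)
  atlas <- build_atlas(list(ph$truth, ph$truth))
  apath <- tempfile(fileext = ".nii.gz")
  write_atlas(atlas, apath)
  sidecar <- sub("\\.nii\\.gz$", ".json", apath)
  expect_true(file.exists(sidecar))
  meta <- jsonlite::read_json(sidecar)
  expect_equal(meta$n_subjects, 2)
  unlink(c(path, apath, sidecar))
})
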