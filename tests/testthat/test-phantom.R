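test_that("brain background is tissue-flat with a brighter ventricle", {
  sp <- phantom_spec(grid_shape = c(48, 48, 12), n_tubes = 0, n_dots = 0,
                     n_sulci = 0, n_lacunes = 0, noise_sigma = 0, seed = 1)
  bg <- make_brain_background(sp)
  inside <- bg$data > 0
  vent <- bg$data == sp$csf_mean
  tissue <- inside & !vent
  expect_true(all(bg$data[tissue] == sp$tissue_mean))
  expect_true(sum(vent) > 0)
  expect_true(min(bg$data[vent]) > max(bg$data[tissue]))
  expect_true(attr(bg, "ventricle_top_index") < dim(bg$data)[3])
  # deterministic
  expect_identical(bg$data, make_brain_background(sp)$data)
})

test_that("background sizing error names the problem", {
  sp <- tiny_phantom_spec()
  sp$grid_shape <- c(48L, 48L, 2L)
  expect_error(make_brain_background(sp), "grid too small")
})

test_that("structure sampling respects counts, orientation and placement", {
  sp <- tiny_phantom_spec(seed = 3)
  sp$n_tubes <- 0L; sp$n_dots <- 0L
  set.seed(3)
  expect_equal(nrow(sample_pvs_structures(sp)), 0)

  sp$n_dots <- 5L
  set.seed(3)
  tab <- sample_pvs_structures(sp)
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$type == "dot"))
  expect_true(all(tab$dz == 1))

  sp2 <- tiny_phantom_spec(seed = 4)
  set.seed(4)
  tab2 <- sample_pvs_structures(sp2)
  expect_true(all(tab2$type[1:3] == "tube"))
  expect_true(all(abs(tab2$dz[1:3]) < 1e-12))
  # all centres inside the brain ellipsoid
  geom <- perivox:::phantom_geometry(sp2)
  er <- sqrt(((tab2$cx - geom$centre[1]) / geom$semi[1])^2 +
               ((tab2$cy - geom$centre[2]) / geom$semi[2])^2 +
               ((tab2$cz - geom$centre[3]) / geom$semi[3])^2)
  expect_true(all(er < 1))
  # pairwise centre separation
  ctrs <- as.matrix(tab2[, c("cx", "cy", "cz")])
  dmat <- as.matrix(dist(ctrs))
  expect_true(all(dmat[upper.tri(dmat)] >= sp2$min_separation_mm))
})

test_that("impossible placement fails with the achieved count", {
  sp <- tiny_phantom_spec(seed = 9)
  sp$n_dots <- 500L
  sp$min_separation_mm <- 12
  set.seed(9)
  expect_error(sample_pvs_structures(sp), "achieved")
})

test_that("rasterization paints capsules and never drops a structure", {
  sp <- tiny_phantom_spec()
  # a dot thinner than the in-plane voxel still gets its centre voxel
  st <- data.frame(type = "dot", cx = 16, cy = 16, cz = 11,
                   dx = 0, dy = 0, dz = 1, length_mm = 0.5,
                   radius_mm = 0.1, low_signal = FALSE, contrast = 190)
  m <- rasterize_structures(st, sp)
  expect_gte(sum(m), 1)

  # empty table -> zero mask
  empty <- st[0, ]
  expect_equal(sum(rasterize_structures(empty, sp)), 0)

  # well-separated structures give exactly k 3D components (flood oracle)
  st3 <- data.frame(
    type = c("dot", "dot", "tube"),
    cx = c(10, 24, 16), cy = c(16, 16, 26), cz = c(8, 8, 14),
    dx = c(0, 0, 1), dy = c(0, 0, 0), dz = c(1, 1, 0),
    length_mm = c(3, 3, 6), radius_mm = c(0.8, 0.8, 0.8),
    low_signal = FALSE, contrast = 190)
  m3 <- rasterize_structures(st3, sp)
  expect_equal(flood_count_3d(m3), 3)
})

test_that("rendering honours contrast assignments and noise models", {
  sp <- tiny_phantom_spec(seed = 21)
  sp$noise_sigma <- 0
  sub <- phantom_subject(sp)
  pvs_vox <- sub$volume$data[sub$truth$mask == 1]
  expect_true(all(pvs_vox == sp$pvs_mean))

  sp$low_signal_fraction <- 1
  sub2 <- phantom_subject(sp)
  pvs_vox2 <- sub2$volume$data[sub2$truth$mask == 1]
  expect_true(all(pvs_vox2 > sp$tissue_mean & pvs_vox2 < sp$pvs_mean))

  # Rician noise keeps the zero-signal exterior nonnegative
  sp3 <- tiny_phantom_spec(seed = 22)
  sp3$noise_sigma <- 8
  sub3 <- phantom_subject(sp3)
  expect_true(all(sub3$volume$data >= 0))
  outside <- sub3$volume$data[make_brain_background(sp3)$data == 0]
  expect_gt(mean(outside), 0)  # magnitude noise has positive mean

  # contrast ordering without noise
  sp4 <- tiny_phantom_spec(seed = 23)
  sp4$noise_sigma <- 0
  sub4 <- phantom_subject(sp4)
  tissue <- sub4$volume$data == sp4$tissue_mean
  expect_gt(mean(sub4$volume$data[sub4$truth$mask == 1]),
            mean(sub4$volume$data[tissue]))
})

test_that("truth tables are self-consistent and landmarks obey the 1 cm rule", {
  sub <- phantom_subject(tiny_phantom_spec(seed = 31))
  tr <- sub$truth
  nz <- dim(tr$mask)[3]
  recomputed <- vapply(seq_len(nz), function(k) {
    flood_count_2d(tr$mask[, , k], connectivity = 8)
  }, numeric(1))
  expect_equal(tr$per_slice_counts, as.integer(recomputed))
  expect_equal(tr$cso_slice_index,
               tr$ventricle_top_index + ceiling(10 / sub$spec$voxel_size_mm[3]))
})

test_that("phantom generation is deterministic and seed-extensible", {
  sp <- tiny_phantom_spec(seed = 41)
  a <- phantom_subject(sp)
  b <- phantom_subject(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$mask, b$truth$mask)
  expect_identical(a$truth$structure_table, b$truth$structure_table)

  ds <- phantom_dataset(3, sp, seed = 41)
  ds2 <- phantom_dataset(3, sp, seed = 41)
  expect_identical(ds[[2]]$volume$data, ds2[[2]]$volume$data)
  # distinct derived seeds give distinct volumes
  expect_false(identical(ds[[1]]$volume$data, ds[[2]]$volume$data))
  # extending the dataset preserves earlier subjects
  ds5 <- phantom_dataset(4, sp, seed = 41)
  expect_identical(ds5[[3]]$volume$data, ds[[3]]$volume$data)
})

test_that("synthetic ages cover the cohort range", {
  sp <- tiny_phantom_spec(seed = 51)
  sp$n_tubes <- 1L; sp$n_dots <- 1L
  ds <- phantom_dataset(20, sp, seed = 51)
  ages <- vapply(ds, function(s) s$age, numeric(1))
  expect_true(all(ages >= 42 & ages <= 79))
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(phantom_spec(n_tubes = -1), "counts")
  expect_error(phantom_spec(pvs_mean = 90, tissue_mean = 100), "pvs_mean")
  expect_error(phantom_spec(pvs_radius_mm = c(0, 1)), "positive")
})
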