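test_that("pure-compartment pixels carry exactly the table values", {
  sc <- tiny_scene("HGG")
  tab <- concentration_table()
  for (mt in map_types()) {
    m <- synthesize_map(sc$seg, sc$tumor, tab, mt)
    gm_ref <- tab[tab$map_type == mt & tab$compartment == "GM", "estimate"]
    wm_ref <- tab[tab$map_type == mt & tab$compartment == "WM", "estimate"]
    expect_equal(m$values[1, 1], gm_ref)
    expect_equal(m$values[2, 2], wm_ref)
    expect_equal(m$values[3, 3], 0)  # CSF: zero concentration
    expect_equal(m$values[4, 4], tumor_value(tab, mt, "HGG"))
    expect_true(all(m$values >= 0))
    expect_false(m$normalized)
  }
  # spot check for tCho: GM 1.8, WM 1.45, tumor 4.00
  m <- synthesize_map(sc$seg, sc$tumor, tab, "tCho")
  expect_equal(m$values[cbind(1:4, 1:4)], c(1.8, 1.45, 0, 4.00))
})

test_that("tumor grade selects the ratio sub-range in synthesized maps", {
  sc_l <- tiny_scene("LGG")
  tab <- concentration_table()
  m <- synthesize_map(sc_l$seg, sc_l$tumor, tab, "tCho_over_NAA")
  expect_equal(m$values[4, 4], (0.7 + 2.35) / 2)
})

test_that("tumor can be additive instead of overriding", {
  sc <- tiny_scene("HGG")
  tab <- concentration_table()
  gm <- matrix(0, 8, 8); gm[4, 4] <- 1  # tissue under the tumor pixel
  seg <- tissue_segmentation(gm, matrix(0, 8, 8), matrix(0, 8, 8), "t", 1L)
  m_over <- synthesize_map(seg, sc$tumor, tab, "tCho")
  m_add <- synthesize_map(seg, sc$tumor, tab, "tCho", tumor_additive = TRUE)
  expect_equal(m_over$values[4, 4], 4.00)
  expect_equal(m_add$values[4, 4], 1.8 + 4.00)
})

test_that("shape mismatches are rejected", {
  sc <- tiny_scene()
  bad <- tumor_mask(matrix(0, 4, 4), "HGG")
  expect_error(synthesize_map(sc$seg, bad, concentration_table(), "tCho"),
               "shape")
})

test_that("normalization scales to [0,1], keeps zeros, and is idempotent", {
  m <- metabolite_map(matrix(c(0, 2, 4, 0), 2, 2), "tCho")
  n1 <- normalize_map(m)
  expect_equal(sort(unique(as.vector(n1$values))), c(0, 0.5, 1))
  expect_true(n1$normalized)
  expect_identical(normalize_map(n1)$values, n1$values)
  z <- normalize_map(metabolite_map(matrix(0, 2, 2), "NAA"))
  expect_true(all(z$values == 0))
  expect_true(z$normalized)
})

test_that("block-average downsampling matches hand arithmetic and conserves the mean", {
  blk <- rbind(matrix(1, 2, 4), matrix(3, 2, 4))
  m <- metabolite_map(blk, "tCho")
  lr <- downsample_map(m, 4)
  expect_equal(dim(lr$values), c(1, 1))
  expect_equal(lr$values[1, 1], 2.0)
  set.seed(1)
  hr <- metabolite_map(matrix(runif(128^2), 128, 128), "NAA")
  lr2 <- downsample_map(hr, 4)
  expect_equal(mean(lr2$values), mean(hr$values))
  expect_equal(dim(lr2$values), c(32, 32))
  expect_error(downsample_map(metabolite_map(matrix(0, 6, 6), "tCr"), 4),
               "divisible")
})

test_that("the 32x32 grid at 220 mm FOV has 6.875 mm voxels", {
  hr <- metabolite_map(matrix(0.5, 128, 128), "tCho")
  expect_equal(voxel_size_mm(hr), 1.71875)
  expect_equal(voxel_size_mm(downsample_map(hr, 4)), 6.875)
})

test_that("dataset construction yields five examples per selected slice", {
  cohort <- generate_cohort(2, seed = 21, n_slices = 2)
  ds <- build_dataset(cohort, min_k = 1)
  n_slices_sel <- sum(vapply(cohort, function(s) length(select_slices(s, 1)), 0L))
  expect_equal(length(ds), 5 * n_slices_sel)
  expect_equal(length(ds), nrow(ds$manifest))
  ex <- ds$examples[[1]]
  expect_equal(dim(ex$lr), c(32, 32, 2))
  expect_equal(dim(ex$hr), c(128, 128, 1))
  expect_true(all(ex$lr >= 0 & ex$lr <= 1))
  expect_true(all(ex$hr >= 0 & ex$hr <= 1))
  # fixed seed -> identical dataset
  ds2 <- build_dataset(cohort, min_k = 1)
  expect_identical(ds, ds2)
})

test_that("sampled tumor values are consistent within a subject", {
  subj <- generate_subject(31, "HGG", n_slices = 2)
  ds <- build_dataset(list(subj), mode = "sampled", seed = 4, min_k = 1)
  mf <- ds$manifest
  for (mt in map_types()) {
    idx <- which(mf$map_type == mt)
    if (length(idx) < 2) next
    # the same lesion keeps one tumor value across its slices: the HR maps at
    # a common tumor pixel agree up to each map's normalization
    tpix <- which(subj[[1]]$tumor$mask * subj[[2]]$tumor$mask > 0)[1]
    skip_if(is.na(tpix))
    v <- vapply(idx, function(i) ds$examples[[i]]$hr[, , 1][tpix], 0)
    expect_equal(v[1] > 0, v[2] > 0)
  }
})

test_that("an ineligible cohort produces an empty dataset with a warning", {
  f <- matrix(1, 128, 128); m <- matrix(0, 128, 128); m[64, 64] <- 1
  subj <- structure(list(fake_slice(f, m)), class = "phantom_subject",
                    subject_id = "flat", grade = "HGG")
  expect_warning(ds <- build_dataset(list(subj)), "no eligible")
  expect_equal(length(ds), 0)
})
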