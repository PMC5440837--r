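# Synthetic generators: ideal helices, bundles, receptor fixture, planted
# scenes, image and BiFC simulators.

test_that("ideal helix places C-alphas on the stated parametric curve", {
  h <- build_ideal_helix(helix_spec(n_residues = 10), chain = "A", cb_offset = NA)
  expect_equal(coords(h)[, 3], seq(0, 13.5, by = 1.5))
  # residues i and i+18 share an azimuth (18 * 100 = 1800 = 5 * 360)
  h2 <- build_ideal_helix(helix_spec(n_residues = 20), chain = "A", cb_offset = NA)
  X <- coords(h2)
  az <- atan2(X[, 2], X[, 1])
  expect_equal(az[1], az[19], tolerance = 1e-9)
  expect_equal(az[2], az[20], tolerance = 1e-9)
})

test_that("inter-residue distances follow the closed form for every pair", {
  sp <- helix_spec(n_residues = 14)
  h <- build_ideal_helix(sp, chain = "A", cb_offset = NA)
  X <- coords(h)
  for (i in 1:13) for (j in (i + 1):14) {
    k <- j - i
    expected <- sqrt((k * sp$rise)^2 +
                       2 * sp$helix_radius^2 * (1 - cos(k * sp$twist * pi / 180)))
    expect_equal(sqrt(sum((X[i, ] - X[j, ])^2)), expected, tolerance = 1e-9)
  }
  # consecutive distances are constant
  d <- sqrt(rowSums((X[-1, ] - X[-14, ])^2))
  expect_lt(diff(range(d)), 1e-9)
})

test_that("bundle building honours the groove gap and ring geometry", {
  s11 <- build_bundle(bundle_spec(n_positions = 12, groove_gap = 3))
  expect_equal(nrow(attr(s11, "helices")), 11)
  s12 <- build_bundle(bundle_spec(n_positions = 12, groove_gap = NA))
  expect_equal(nrow(attr(s12, "helices")), 12)
  # minimum inter-axis distance equals 2 R sin(pi / n)
  hel <- attr(s12, "helices")
  # mean CA position over 18 residues (5 exact turns) lies on the helix axis
  cents <- t(vapply(hel$chain, function(ch) {
    sub <- select_atoms(s12, ch, helix_segment(ch, 1, 18))
    colMeans(coords(sub)[sub$atoms$name == "CA", ])[1:2]
  }, numeric(2)))
  dd <- as.matrix(dist(cents))
  diag(dd) <- Inf
  expect_equal(min(dd), 2 * 20 * sin(pi / 12), tolerance = 1e-6)
  # overlapping helices are refused
  expect_error(build_bundle(bundle_spec(n_positions = 12, ring_radius = 2)),
               class = "groovedock_generation_error")
})

test_that("long/short pair superposes exactly and differs by three helices", {
  long <- fx_pair$long; short <- fx_pair$short
  key <- function(s) paste(s$atoms$chain, s$atoms$resno, s$atoms$name)
  shared <- match(key(short), key(long))
  expect_false(anyNA(shared))
  expect_equal(max(abs(coords(short) - coords(long)[shared, ])), 0)
  expect_equal(n_atoms(long) - n_atoms(short), 3 * 24 * 2)
  # filler centroid sits in the groove mouth, inside the ring radius
  filler <- select_atoms(long, fx_pair$filler$chain)
  ctr <- attr(short, "bundle")$centre
  expect_lt(sqrt(sum((colMeans(coords(filler)) - ctr)^2)),
            attr(short, "bundle")$spec$ring_radius + 1e-9)
})

test_that("receptor fixture has protruding M4s and exact n-fold symmetry", {
  rec <- fx_rec$receptor
  hel <- attr(rec, "helices")
  axdist <- vapply(seq_len(nrow(hel)), function(k) {
    sub <- rec$atoms[rec$atoms$chain == hel$chain[k] &
                       rec$atoms$resno >= hel$start[k] &
                       rec$atoms$resno <= hel$end[k], ]
    sqrt(sum(colMeans(sub[, c("x", "y")])^2))
  }, 0)
  is_m4 <- grepl("^M4", hel$label)
  expect_true(min(axdist[is_m4]) > max(axdist[!is_m4]))
  is_m2 <- grepl("^M2", hel$label)
  expect_true(max(axdist[is_m2]) < min(axdist[!is_m2]))
  # rotation by 90 degrees maps subunit k onto k+1
  ca <- rec$atoms[rec$atoms$name == "CA", ]
  chains <- sort(unique(ca$chain))
  rot <- apply_transform(axis_rotation(90, c(0, 0, 0), c(0, 0, 1)),
                         as.matrix(ca[ca$chain == chains[1], c("x", "y", "z")]))
  nxt <- as.matrix(ca[ca$chain == chains[2], c("x", "y", "z")])
  expect_lt(sqrt(mean(rowSums((rot - nxt)^2))), 1e-6)
})

test_that("planted scenes are hard-clash-free and carry an exact transform", {
  pl <- plant_complex(fx_pair$short, fx_rec$receptor, fx_rec$m4_segments[[1]],
                      true_angle = 77.7)
  moved <- apply_transform(pl$ground_truth, fx_pair$short)
  expect_equal(max(abs(coords(moved) - coords(pl$scene$bundle))), 0)
  expect_equal(count_clashes(pl$scene$bundle, pl$scene$receptor,
                             clash_params(cutoff = 2.0)), 0)
  # determinism
  pl2 <- plant_complex(fx_pair$short, fx_rec$receptor, fx_rec$m4_segments[[1]],
                       true_angle = 77.7)
  expect_identical(coords(pl$scene$receptor), coords(pl2$scene$receptor))
})

test_that("coloc image simulation is deterministic and respects rho = 1", {
  p <- coloc_sim_params(n_cells = 2, image_shape = c(64, 64), coloc_fraction = 1,
                        noise_model = "gaussian", noise_sd = 0, seed = 4)
  a <- simulate_coloc_images(p)
  b <- simulate_coloc_images(p)
  expect_identical(a, b)
  # noise-free rho = 1: channels are exact affine images of each other
  cell <- a[[1]]
  lm_r <- stats::lm(as.vector(cell$ch2) ~ as.vector(cell$ch1))
  expect_lt(max(abs(stats::residuals(lm_r))), 1e-9)
  # poisson noise changes pixels but stays deterministic under the seed
  pp <- coloc_sim_params(n_cells = 1, image_shape = c(64, 64), seed = 4)
  expect_identical(simulate_coloc_images(pp), simulate_coloc_images(pp))
})

test_that("BiFC simulation reproduces exact folds at zero noise", {
  p <- bifc_sim_params(n_cells = 5, reporter_fold = 5, cy3_fold = 4,
                       noise_cv = 0, seed = 1)
  d <- simulate_bifc(p)
  expect_equal(d$venus, 5 * d$background)
  expect_equal(d$cy3, 4 * d$background)
  # boundary: reporter_fold exactly at the threshold factor is negative
  d35 <- simulate_bifc(bifc_sim_params(n_cells = 5, reporter_fold = 3.5,
                                       noise_cv = 0, seed = 1))
  cls <- bifc_classify(d35)
  expect_false(any(cls$venus_positive))
  d36 <- simulate_bifc(bifc_sim_params(n_cells = 5, reporter_fold = 3.6,
                                       noise_cv = 0, seed = 1))
  expect_true(all(bifc_classify(d36)$venus_positive))
})

test_that("occluded scene surrounds the filler with crowd helices", {
  occ <- make_occluded_scene()
  expect_gt(n_atoms(occ$receptor), n_atoms(fx_pair$long))
  expect_equal(occ$target$chain, fx_pair$filler$chain)
})

test_that("two-channel images round-trip through two-page TIFF files", {
  p <- coloc_sim_params(n_cells = 1, image_shape = c(64, 64), seed = 8)
  cells <- simulate_coloc_images(p)
  dir <- tempfile("tif")
  paths <- write_coloc_tiffs(cells, dir)
  img <- read_coloc_tiff(paths[1])
  expect_equal(dim(img$ch1), c(64, 64))
  expect_equal(img$ch1, cells[[1]]$ch1, tolerance = 1e-4)
  expect_equal(img$ch2, cells[[1]]$ch2, tolerance = 1e-4)
})
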