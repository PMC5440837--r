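# Docking: Kabsch superposition, helix axis fitting, clash counting, the
# rotation scan, and the full template-guided procedure.

test_that("kabsch recovers identity, known transforms, and refuses mirrors", {
  set.seed(1)
  P <- matrix(rnorm(30), ncol = 3)
  id <- kabsch(P, P)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$transform$R, diag(3), tolerance = 1e-10)
  expect_equal(id$transform$t, c(0, 0, 0), tolerance = 1e-10)
  tr <- axis_rotation(40, c(0, 0, 0), c(0, 0, 1))
  Q <- apply_transform(tr, P) + matrix(rep(c(1, 2, 3), each = 10), ncol = 3)
  fit <- kabsch(P, Q)
  expect_lt(fit$rmsd, 1e-8)
  expect_lt(max(abs(apply_transform(fit$transform, P) - Q)), 1e-8)
  # mirror image: returned rotation still proper, rmsd > 0
  Qm <- P; Qm[, 1] <- -Qm[, 1]
  fm <- kabsch(P, Qm)
  expect_equal(det(fm$transform$R), 1, tolerance = 1e-8)
  expect_gt(fm$rmsd, 0)
  expect_error(kabsch(P, Q[1:5, ]), class = "groovedock_value_error")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch(line, line), class = "groovedock_value_error")
})

test_that("kabsch beats random proper rotations (optimality sanity)", {
  set.seed(42)
  for (k in 1:20) {
    P <- matrix(rnorm(24), ncol = 3)
    Q <- matrix(rnorm(24), ncol = 3)
    opt <- kabsch(P, Q)$rmsd
    cp <- colMeans(P); cq <- colMeans(Q)
    P0 <- sweep(P, 2, cp)
    rand_rmsd <- vapply(1:100, function(i) {
      R <- random_transform()$R
      sqrt(mean(rowSums((sweep(P0 %*% t(R), 2, cq, `+`) - Q)^2)))
    }, 0)
    expect_lte(opt, min(rand_rmsd) + 1e-12)
  }
})

test_that("helix axis fitting is accurate, oriented and equivariant", {
  # the principal axis converges on the true axis as the helix grows
  h <- build_ideal_helix(helix_spec(n_residues = 120), cb_offset = NA)
  ax <- fit_helix_axis(coords(h))
  expect_lt(max(abs(ax$direction - c(0, 0, 1))), 1e-3)
  expect_equal(sqrt(sum(ax$direction^2)), 1, tolerance = 1e-12)
  set.seed(2)
  tr <- random_transform()
  h24 <- build_ideal_helix(helix_spec(), cb_offset = NA)
  ax24 <- fit_helix_axis(coords(h24))
  ax2 <- fit_helix_axis(apply_transform(tr, coords(h24)))
  expect_lt(max(abs(ax2$direction - as.numeric(tr$R %*% ax24$direction))), 1e-3)
  expect_error(fit_helix_axis(coords(h)[1:3, ]), class = "groovedock_value_error")
})

test_that("clash counting uses a strict cutoff and is symmetric", {
  a <- mk_struct(0, 0, 0, chain = "A")
  b1 <- mk_struct(2, 0, 0, chain = "B")
  b2 <- mk_struct(2.5, 0, 0, chain = "B")
  expect_equal(count_clashes(a, b1, clash_params(2.5)), 1)
  expect_equal(count_clashes(a, b2, clash_params(2.5)), 0)  # strict '<'
  expect_equal(count_clashes(b1, a, clash_params(2.5)),
               count_clashes(a, b1, clash_params(2.5)))
  # hydrogens are excluded
  hstr <- mk_struct(c(0, 2), 0, 0, chain = "C", element = c("C", "H"),
                    name = c("CA", "H1"))
  expect_equal(count_clashes(hstr, b1, clash_params(2.5)), 1)
})

test_that("clash counts match a brute-force double loop on random scenes", {
  set.seed(7)
  for (k in 1:20) {
    a <- mk_struct(rnorm(30, sd = 4), rnorm(30, sd = 4), rnorm(30, sd = 4), chain = "A")
    b <- mk_struct(rnorm(30, sd = 4), rnorm(30, sd = 4), rnorm(30, sd = 4), chain = "B")
    expect_equal(count_clashes(a, b), brute_clashes(a, b))
  }
})

test_that("rotation scan profile matches per-angle recomputation", {
  set.seed(3)
  mob <- mk_struct(rnorm(40, 8, 3), rnorm(40, 0, 3), rnorm(40, 0, 5), chain = "A")
  rec <- mk_struct(rnorm(60, 8, 4), rnorm(60, 0, 4), rnorm(60, 0, 5), chain = "B")
  ax <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  sc <- rotation_scan(mob, ax, rec, step = 5)
  expect_equal(nrow(sc$scan), 360 / 5)
  direct <- vapply(sc$scan$angle, function(th) {
    count_clashes(apply_transform(axis_rotation(th, ax$point, ax$direction), mob), rec)
  }, 0)
  expect_equal(sc$scan$clashes, as.integer(direct))
  expect_equal(sc$clash_count, min(direct))
  expect_error(rotation_scan(mob, ax, rec, step = 7), class = "groovedock_value_error")
})

test_that("a clash-free construction at angle zero is recovered", {
  mob <- mk_struct(10, 0, c(-2, 0, 2, 4), chain = "A", name = rep("CA", 4),
                   resno = 1:4)
  # receptor blocks every azimuth except a notch at angle 0
  az <- seq(20, 340, by = 10) * pi / 180
  rec <- mk_struct(10 * cos(az), 10 * sin(az), 0, chain = "B",
                   name = paste0("C", seq_along(az)), resno = seq_along(az))
  sc <- rotation_scan(mob, list(point = c(0, 0, 0), direction = c(0, 0, 1)),
                      rec, step = 10, p = clash_params(3))
  expect_equal(sc$best_angle, 0)
  expect_equal(sc$clash_count, 0)
})

test_that("strip_side_chains keeps backbone + CB only", {
  s <- mk_struct(1:6, 0, 0, chain = "A", resno = rep(1, 6),
                 name = c("N", "CA", "C", "O", "CB", "CG"))
  st <- strip_side_chains(s)
  expect_equal(st$atoms$name, c("N", "CA", "C", "O", "CB"))
  ca_only <- build_ideal_helix(helix_spec(n_residues = 6))
  expect_equal(strip_side_chains(ca_only)$atoms, ca_only$atoms)
  expect_lte(n_atoms(strip_side_chains(s)), n_atoms(s))
})

test_that("template-guided docking recovers planted poses to one scan step", {
  set.seed(11)
  errs <- c(); rmsds <- c()
  for (k in 1:6) {
    alpha <- runif(1, 0, 360)
    pl <- plant_complex(fx_pair$short, fx_rec$receptor, fx_rec$m4_segments[[1]],
                        true_angle = alpha)
    dk <- template_guided_dock(fx_pair$long, fx_pair$filler, fx_pair$short,
                               pl$scene$receptor, fx_rec$m4_segments[[1]])
    errs <- c(errs, ang_err(dk$best_angle, alpha))
    rmsds <- c(rmsds, sqrt(mean(rowSums(
      (coords(dk$query_docked) - coords(pl$scene$bundle))^2))))
    expect_true(dk$best_angle %in% dk$scan$angle)
    expect_equal(dk$clash_count, min(dk$scan$clashes))
  }
  expect_lte(median(errs), 1)
  expect_lt(max(rmsds), 1.0)
})

test_that("docking against the filled (long) bundle reports groove occlusion", {
  occ <- make_occluded_scene()
  expect_error(
    template_guided_dock(fx_pair$long, fx_pair$filler, fx_pair$short,
                         occ$receptor, occ$target),
    class = "groovedock_occluded_error")
})

test_that("clash profiles and relative poses are invariant under global rigid motion", {
  pl <- plant_complex(fx_pair$short, fx_rec$receptor, fx_rec$m4_segments[[1]],
                      true_angle = 123.4)
  dk1 <- template_guided_dock(fx_pair$long, fx_pair$filler, fx_pair$short,
                              pl$scene$receptor, fx_rec$m4_segments[[1]])
  set.seed(5)
  g <- random_transform()
  rec_moved <- apply_transform(g, pl$scene$receptor)
  attr(rec_moved, "pore_axis") <- NULL   # not needed by the dock itself
  dk2 <- template_guided_dock(fx_pair$long, fx_pair$filler, fx_pair$short,
                              rec_moved, fx_rec$m4_segments[[1]])
  expect_equal(dk2$scan$clashes, dk1$scan$clashes)
  expect_equal(dk2$best_angle, dk1$best_angle)
  # relative pose: moving dk1's docked query by g reproduces dk2's pose
  moved <- apply_transform(g, dk1$query_docked)
  expect_lt(max(abs(coords(moved) - coords(dk2$query_docked))), 1e-6)
})

test_that("identical inputs give identical dock results", {
  pl <- plant_complex(fx_pair$short, fx_rec$receptor, fx_rec$m4_segments[[1]], 50)
  d1 <- template_guided_dock(fx_pair$long, fx_pair$filler, fx_pair$short,
                             pl$scene$receptor, fx_rec$m4_segments[[1]])
  d2 <- template_guided_dock(fx_pair$long, fx_pair$filler, fx_pair$short,
                             pl$scene$receptor, fx_rec$m4_segments[[1]])
  expect_identical(d1$scan, d2$scan)
  expect_identical(coords(d1$query_docked), coords(d2$query_docked))
})
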