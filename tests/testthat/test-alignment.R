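test_that("inertia axes of axis-aligned shapes are the identity", {
  box <- rasterize(shape_spec("box", list(w = 5, h = 5), length = 30,
                              pitch = 0.5))
  expect_equal(inertia_axes_3d(box)$rotation, diag(3), tolerance = 1e-12)
  cube <- segment_mask(array(1L, c(9, 9, 9)))
  expect_equal(inertia_axes_3d(cube)$rotation, diag(3), tolerance = 1e-12)
})

test_that("inertia axes form a proper rotation for arbitrary masks", {
  set.seed(11)
  for (trial in 1:8) {
    arr <- array(0L, c(12, 12, 12))
    arr[sample(length(arr), 150)] <- 1L
    R <- inertia_axes_3d(segment_mask(arr))$rotation
    expect_equal(R %*% t(R), diag(3), tolerance = 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
})

test_that("oblique cylinder tilt is recovered within 2 degrees", {
  for (tilt in c(10, 20, 30, 45)) {
    m <- rasterize(shape_spec("oblique_cylinder",
                              list(r = 4, tilt_deg = tilt),
                              length = 40, pitch = 1))
    u_true <- c(sin(tilt * pi / 180), 0, cos(tilt * pi / 180))
    u_rec <- inertia_axes_3d(m)$rotation[3, ]
    ang <- acos(min(1, abs(sum(u_true * u_rec)))) * 180 / pi
    expect_lt(ang, 2)
  }
})

test_that("apply_rotation: identity mode, exact 90-degree permutation,
           and volume conservation on an oblique round trip", {
  box <- rasterize(shape_spec("box", list(w = 4, h = 8), length = 20,
                              pitch = 0.5))
  expect_identical(apply_rotation(box, rotation_spec("none")), box)

  r90 <- apply_rotation(box, rotation_spec("euler", c(0, 0, 90)))
  expect_identical(sum(r90$voxels), sum(box$voxels))  # lattice-preserving
  expect_identical(r90$spacing, box$spacing)

  cyl <- rasterize(shape_spec("cylinder", list(r = 5), length = 30,
                              pitch = 0.5))
  ra <- apply_rotation(cyl, rotation_spec("euler", c(0, 30, 0)))
  rb <- apply_rotation(ra, rotation_spec("euler", c(0, -30, 0)))
  expect_lt(abs(sum(rb$voxels) - sum(cyl$voxels)) / sum(cyl$voxels), 0.02)
})

test_that("principal-inertia alignment straightens an oblique cylinder", {
  m <- rasterize(shape_spec("oblique_cylinder", list(r = 4, tilt_deg = 30),
                            length = 40, pitch = 0.4))
  aligned <- apply_rotation(m, rotation_spec("principal_inertia"))
  csa <- vapply(slice_stack(aligned),
                function(s) sum(s$pixels) * prod(s$pixel_spacing), numeric(1))
  mid <- csa[10:(length(csa) - 10)]
  # every interior cross-section is close to the circular closed form
  expect_lt(max(abs(mid / (pi * 16) - 1)), 0.05)
})

test_that("euler mode validates its angles", {
  expect_error(rotation_spec("euler"), "three finite angles")
  expect_error(rotation_spec("euler", c(0, Inf, 0)), "three finite angles")
})

test_that("slice_stack spans the occupied range with percent-length 0-100", {
  arr <- array(0L, c(8, 8, 50))
  arr[2:5, 2:5, 10:29] <- 1L
  m <- segment_mask(arr, spacing = c(1, 1, 0.5))
  ss <- slice_stack(m)
  expect_length(ss, 20)
  expect_equal(ss[[1]]$percent_length, 0)
  expect_equal(ss[[20]]$percent_length, 100)
  expect_equal(ss[[1]]$plane_index, 10L)
  expect_identical(ss[[1]]$pixel_spacing, c(1, 1))

  # slicing along x gives the orthogonal faces
  sx <- slice_stack(m, axis = "x")
  expect_length(sx, 4)
  expect_identical(sx[[1]]$pixel_spacing, c(1, 0.5))

  expect_error(slice_stack(m, axis = "w"), "axis")
})

test_that("empty planes inside the occupied range are kept as empty sections", {
  db <- rasterize(shape_spec("dumbbell", list(w = 4, h = 4, gap_mm = 3),
                             length = 21, pitch = 1))
  ss <- slice_stack(db)
  empties <- vapply(ss, function(s) sum(s$pixels) == 0L, logical(1))
  expect_identical(sum(empties), 3L)
  # gap sits mid-beam
  expect_true(all(which(empties) > 1 & which(empties) < length(ss)))
})

test_that("intensity volumes are sliced on the same grid", {
  sp <- shape_spec("cylinder", list(r = 3), length = 10, pitch = 0.5,
                   intensity_fill = 100)
  rb <- rasterize(sp)
  ss <- slice_stack(rb$mask, intensity = rb$intensity)
  expect_false(is.null(ss[[1]]$intensity))
  expect_equal(mean_brightness(ss[[1]]), 100)
  bad <- voxel_volume(array(0, c(2, 2, 2)))
  expect_error(slice_stack(rb$mask, intensity = bad), "different grids")
})
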