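test_that("single pixel: exact one-rectangle moments and corner Feret", {
  s <- slice_section(matrix(1L, 1, 1), c(1, 1))
  tn <- inertia_tensor(s)
  expect_equal(tn$Ixx, 1 / 12)
  expect_equal(tn$Iyy, 1 / 12)
  expect_equal(tn$Ixy, 0)
  expect_equal(tn$area, 1)
  expect_equal(feret_max(s), sqrt(2))
  # all pixel centres on the axis -> section modulus flagged null
  expect_warning(z <- section_modulus(s, tn, 0), "degenerate")
  expect_true(is.na(z))
})

test_that("rectangle matches closed forms: I, Z, principal axes, Feret, perimeter", {
  s <- rasterize_section(shape_spec("box", list(w = 10, h = 20), pitch = 0.1))
  tn <- inertia_tensor(s)
  expect_lt(rel_err(tn$Ixx, 10 * 20^3 / 12), 0.005)
  expect_lt(rel_err(tn$Iyy, 20 * 10^3 / 12), 0.005)
  expect_lt(abs(tn$Ixy) / tn$Ixx, 1e-12)
  expect_lt(rel_err(tn$area, 200), 1e-9)
  expect_lt(rel_err(section_modulus(s, tn, 0), 10 * 20^2 / 6), 0.01)
  pr <- principal_axes(tn)
  expect_equal(pr$theta_principal, 90)  # min-I axis is vertical
  expect_lt(rel_err(pr$I_about_minor_axis, 6666.667), 0.005)
  expect_lt(rel_err(pr$I_about_major_axis, 1666.667), 0.005)
  expect_lt(rel_err(feret_max(s), sqrt(10^2 + 20^2)), 0.01)
  expect_lt(rel_err(perimeter(s), 60), 0.02)
})

test_that("circle matches closed forms and is isotropic", {
  s <- rasterize_section(shape_spec("cylinder", list(r = 10), pitch = 0.1))
  tn <- inertia_tensor(s)
  I_cf <- pi * 10^4 / 4
  expect_lt(rel_err(tn$Ixx, I_cf), 0.005)
  expect_lt(rel_err(tn$Iyy, I_cf), 0.005)
  expect_lt(abs(tn$Ixy) / I_cf, 1e-9)
  expect_lt(rel_err(polar_moment(tn), pi * 10^4 / 2), 0.005)
  expect_lt(rel_err(section_modulus(s, tn, 17), pi * 10^3 / 4), 0.01)
  expect_lt(rel_err(feret_max(s), 20), 0.01)
  expect_lt(rel_err(perimeter(s), 2 * pi * 10), 0.02)
  expect_equal(principal_axes(tn)$theta_principal, 0)  # isotropy tie-break
})

test_that("tube: vacuity area, compactness, J and both contours", {
  s <- rasterize_section(shape_spec("tube", list(ro = 10, ri = 8),
                                    pitch = 0.04))
  tn <- inertia_tensor(s)
  tcsa <- total_area_with_vacuities(s)
  expect_lt(rel_err(tn$area, pi * (100 - 64)), 0.01)
  expect_lt(rel_err(tcsa, pi * 100), 0.01)
  expect_lt(rel_err(compactness(tn$area, tcsa), 0.36), 0.01)
  expect_lt(rel_err(polar_moment(tn), pi * (10^4 - 8^4) / 2), 0.01)
  expect_lt(rel_err(perimeter(s), 2 * pi * 18), 0.02)

  # a C-shaped open ring has no enclosed vacuity (notch reaches the border)
  m <- s$pixels
  mid <- ceiling(ncol(m) / 2)
  cshape <- m
  cshape[(ceiling(nrow(m) / 2)):nrow(m), (mid - 2):(mid + 2)] <- 0L
  cs <- slice_section(cshape, s$pixel_spacing)
  expect_equal(total_area_with_vacuities(cs),
               sum(cshape) * prod(s$pixel_spacing))

  # solid circle: TCSA equals CSA
  sc <- rasterize_section(shape_spec("cylinder", list(r = 5), pitch = 0.1))
  expect_equal(total_area_with_vacuities(sc),
               sum(sc$pixels) * prod(sc$pixel_spacing))
})

test_that("axis identities: theta 0 and 90 return Ixx and Iyy exactly", {
  set.seed(3)
  s <- random_section(25, spacing = c(0.7, 1.3))
  tn <- inertia_tensor(s)
  expect_equal(second_moment_about_axis(tn, 0), tn$Ixx)
  expect_equal(second_moment_about_axis(tn, 90), tn$Iyy, tolerance = 1e-12)
  expect_equal(second_moment_about_axis(tn, 180), tn$Ixx, tolerance = 1e-12)
})

test_that("tensor rotation equals brute-force per-pixel summation", {
  set.seed(42)
  for (trial in 1:25) {
    sp <- if (trial %% 2 == 0) c(1, 1) else c(0.6, 1.1)
    s <- random_section(sample(8:30, 1), spacing = sp)
    tn <- inertia_tensor(s)
    for (th in stats::runif(4, -180, 180)) {
      expect_equal(second_moment_about_axis(tn, th), brute_force_I(s, th),
                   tolerance = 1e-9)
    }
  }
})

test_that("parallel-axis theorem holds exactly under the pixel model", {
  set.seed(7)
  for (trial in 1:10) {
    s <- random_section(20)
    tn <- inertia_tensor(s)
    th <- stats::runif(1, 0, 180)
    d <- stats::runif(1, 0.5, 5)
    I_shifted <- brute_force_I(s, th, offset_mm = d)
    expect_equal(I_shifted, second_moment_about_axis(tn, th) + tn$area * d^2,
                 tolerance = 1e-12)
  }
})

test_that("J = Ixx + Iyy exactly and principal moments bound every I(theta)", {
  set.seed(19)
  for (trial in 1:10) {
    s <- random_section(24, spacing = c(0.8, 1.2))
    tn <- inertia_tensor(s)
    expect_identical(polar_moment(tn), tn$Ixx + tn$Iyy)
    pr <- principal_axes(tn)
    thetas <- seq(-90, 90, by = 3.7)
    Is <- vapply(thetas, function(th) second_moment_about_axis(tn, th),
                 numeric(1))
    expect_true(all(Is <= pr$I_about_minor_axis * (1 + 1e-12)))
    expect_true(all(Is >= pr$I_about_major_axis * (1 - 1e-12)))
  }
})

test_that("principal values are invariant under in-plane fixture rotation", {
  ref <- principal_axes(inertia_tensor(
    rasterize_section(shape_spec("box", list(w = 10, h = 20), pitch = 0.05))))
  rot <- principal_axes(inertia_tensor(
    rasterize_section(shape_spec("box", list(w = 10, h = 20), pitch = 0.05,
                                 rotate_deg = 30))))
  expect_lt(rel_err(rot$I_about_minor_axis, ref$I_about_minor_axis), 0.01)
  expect_lt(rel_err(rot$I_about_major_axis, ref$I_about_major_axis), 0.01)
  # upright major axis is at 90; rotated by +30 it wraps to -60
  expect_lt(abs(rot$theta_principal - (-60)), 1)
})

test_that("mean brightness averages intensity over foreground only", {
  m <- matrix(0L, 4, 4); m[2:3, 2:3] <- 1L
  intens <- matrix(999, 4, 4)
  intens[2:3, 2:3] <- c(0, 200, 0, 200)
  s <- slice_section(m, c(1, 1), intensity = intens)
  expect_equal(mean_brightness(s), 100)
  s2 <- slice_section(m, c(1, 1), intensity = matrix(100, 4, 4))
  expect_equal(mean_brightness(s2), 100)
  expect_true(is.na(mean_brightness(slice_section(m, c(1, 1)))))
})

test_that("isotropic scaling: CSA ~ s^2, Z ~ s^3, I and J ~ s^4", {
  base <- shape_spec("elliptical_beam", list(a = 6, b = 3), pitch = 0.06)
  big <- shape_spec("elliptical_beam", list(a = 12, b = 6), pitch = 0.12)
  t1 <- inertia_tensor(rasterize_section(base))
  t2 <- inertia_tensor(rasterize_section(big))
  expect_lt(rel_err(t2$area, 4 * t1$area), 0.01)
  expect_lt(rel_err(t2$Ixx, 16 * t1$Ixx), 0.01)
  expect_lt(rel_err(polar_moment(t2), 16 * polar_moment(t1)), 0.01)
  s1 <- rasterize_section(base); s2 <- rasterize_section(big)
  expect_lt(rel_err(section_modulus(s2, t2, 0),
                    8 * section_modulus(s1, t1, 0)), 0.01)
})

test_that("closed-form error shrinks as the pixel pitch halves", {
  errs <- vapply(c(0.8, 0.4, 0.2, 0.1), function(p) {
    tn <- inertia_tensor(rasterize_section(
      shape_spec("cylinder", list(r = 10), pitch = p)))
    rel_err(tn$Ixx, pi * 10^4 / 4)
  }, numeric(1))
  # shrinks with refinement, allowing for grid-phase noise at any one pitch
  expect_lt(errs[4], errs[1])
  expect_lt(mean(errs[3:4]), mean(errs[1:2]))
  expect_lt(errs[4], 0.005)
})

test_that("empty sections error in the math core but yield NA records", {
  s <- slice_section(matrix(0L, 4, 4))
  expect_error(inertia_tensor(s), "empty cross-section")
  expect_error(feret_max(s), "empty cross-section")
  rec <- section_properties(s)
  expect_true(rec$empty)
  expect_true(is.na(rec$CSA))
  expect_error(compactness(1, 0), "positive")
})

test_that("largest-island option drops satellite components", {
  m <- matrix(0L, 20, 20)
  m[2:12, 2:12] <- 1L   # main island, 121 px
  m[16:17, 16:17] <- 1L # satellite, 4 px
  s <- slice_section(m, c(1, 1))
  all_px <- section_properties(s)
  main_px <- section_properties(s, largest_island = TRUE)
  expect_equal(all_px$CSA, 125)
  expect_equal(main_px$CSA, 121)
})

test_that("section_properties assembles a consistent record", {
  s <- rasterize_section(shape_spec("tube", list(ro = 6, ri = 4),
                                    pitch = 0.1))
  rec <- section_properties(s, neutral_axis_deg = 30)
  expect_false(rec$empty)
  expect_equal(rec$J, rec$Ixx + rec$Iyy)
  expect_true(rec$I_about_major_axis <= rec$I_NA + 1e-9)
  expect_true(rec$I_NA <= rec$I_about_minor_axis + 1e-9)
  expect_true(rec$CSA <= rec$TCSA)
  expect_equal(rec$compactness, rec$CSA / rec$TCSA)
  rec2 <- section_properties(s)
  expect_true(is.na(rec2$I_NA) && is.na(rec2$Z_NA))
})
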