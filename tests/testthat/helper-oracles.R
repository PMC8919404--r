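# relative error against a reference value
rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# Independent brute-force oracle for the second moment of area about a
# centroidal axis at `angle_deg`: visits every foreground pixel and sums its
# rotated own-rectangle moment plus area times squared perpendicular
# distance. Shares no code with the tensor-rotation path.
brute_force_I <- function(section, angle_deg, offset_mm = 0) {
  p <- section$pixel_spacing
  idx <- which(section$pixels != 0L, arr.ind = TRUE)
  x <- (idx[, 1] - 0.5) * p[1]
  y <- (idx[, 2] - 0.5) * p[2]
  cx <- mean(x); cy <- mean(y)
  th <- angle_deg * pi / 180
  A <- p[1] * p[2]
  own <- p[1] * p[2]^3 / 12 * cos(th)^2 + p[1]^3 * p[2] / 12 * sin(th)^2
  total <- 0
  for (k in seq_along(x)) {
    d <- -(x[k] - cx) * sin(th) + (y[k] - cy) * cos(th) - offset_mm
    total <- total + own + A * d^2
  }
  total
}

# random blob section: union of a few random rectangles on a small grid
random_section <- function(n = 20, spacing = c(1, 1)) {
  m <- matrix(0L, n, n)
  for (b in seq_len(sample(2:4, 1))) {
    i0 <- sample(1:(n - 3), 1); j0 <- sample(1:(n - 3), 1)
    i1 <- min(n, i0 + sample(2:8, 1)); j1 <- min(n, j0 + sample(2:8, 1))
    m[i0:i1, j0:j1] <- 1L
  }
  slice_section(m, spacing)
}
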