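# Spherocylinder ("rod") geometry. A cell of total length L and width W is
# the set of points within R = W/2 of the axial segment
# [-(L/2 - R), +(L/2 - R)] x {0}; in 2D this is a rectangle with
# semicircular caps, in 3D a cylinder with hemispherical caps. The cell is
# centred at the origin with its long axis along x.

rod_half_axis <- function(length_um, width_um) {
  pmax(length_um / 2 - width_um / 2, 0)
}

# distance of (x, y) from the axial segment
rod_axis_dist <- function(x, y, length_um, width_um) {
  a <- rod_half_axis(length_um, width_um)
  cx <- pmin(pmax(x, -a), a)
  sqrt((x - cx)^2 + y^2)
}

rod_inside2d <- function(x, y, length_um, width_um, tol = 1e-9) {
  rod_axis_dist(x, y, length_um, width_um) <= width_um / 2 + tol
}

# uniform points in the 2D silhouette (rejection from the bounding box)
rod_sample_inside2d <- function(n, length_um, width_um) {
  out <- matrix(NA_real_, 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    x <- stats::runif(m, -length_um / 2, length_um / 2)
    y <- stats::runif(m, -width_um / 2, width_um / 2)
    keep <- rod_inside2d(x, y, length_um, width_um)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

# nearest point on the silhouette boundary, with outward unit normal
rod_boundary_project2d <- function(x, y, length_um, width_um) {
  a <- rod_half_axis(length_um, width_um)
  R <- width_um / 2
  cx <- pmin(pmax(x, -a), a)
  dx <- x - cx
  dy <- y
  d <- sqrt(dx^2 + dy^2)
  # points exactly on the axis: push out sideways
  on_axis <- d < 1e-12
  dx[on_axis] <- 0
  dy[on_axis] <- 1
  d[on_axis] <- 1
  nx <- dx / d
  ny <- dy / d
  list(bx = cx + R * nx, by = R * ny, nx = nx, ny = ny)
}

# specular reflection of points into the silhouette (iterated; large steps
# that remain outside after max_iter are clamped to the boundary)
rod_reflect_inside2d <- function(x, y, length_um, width_um, max_iter = 10L) {
  for (i in seq_len(max_iter)) {
    out <- !rod_inside2d(x, y, length_um, width_um)
    if (!any(out)) break
    b <- rod_boundary_project2d(x[out], y[out], length_um, width_um)
    x[out] <- 2 * b$bx - x[out]
    y[out] <- 2 * b$by - y[out]
  }
  out <- !rod_inside2d(x, y, length_um, width_um)
  if (any(out)) {
    b <- rod_boundary_project2d(x[out], y[out], length_um, width_um)
    x[out] <- b$bx
    y[out] <- b$by
  }
  cbind(x, y)
}

# uniform points on the 3D spherocylinder surface (area-weighted between the
# cylindrical wall and the two hemispherical caps)
rod_sample_surface3d <- function(n, length_um, width_um) {
  a <- rod_half_axis(length_um, width_um)
  R <- width_um / 2
  area_cyl <- 2 * pi * R * (2 * a)
  area_cap <- 4 * pi * R^2
  on_cyl <- stats::runif(n) < area_cyl / (area_cyl + area_cap)
  p <- matrix(NA_real_, n, 3L)
  n_cyl <- sum(on_cyl)
  if (n_cyl > 0L) {
    phi <- stats::runif(n_cyl, 0, 2 * pi)
    p[on_cyl, ] <- cbind(stats::runif(n_cyl, -a, a), R * cos(phi), R * sin(phi))
  }
  n_cap <- n - n_cyl
  if (n_cap > 0L) {
    d <- matrix(stats::rnorm(3L * n_cap), n_cap, 3L)
    d <- d / sqrt(rowSums(d^2))
    p[!on_cyl, ] <- cbind(sign(d[, 1L]) * a + R * d[, 1L], R * d[, 2L], R * d[, 3L])
  }
  p
}

# project 3D points onto the nearest spherocylinder surface point
rod_project_surface3d <- function(p, length_um, width_um) {
  a <- rod_half_axis(length_um, width_um)
  R <- width_um / 2
  cx <- pmin(pmax(p[, 1L], -a), a)
  dx <- p[, 1L] - cx
  dy <- p[, 2L]
  dz <- p[, 3L]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  bad <- d < 1e-12
  if (any(bad)) {
    dz[bad] <- 1
    d[bad] <- 1
    dx[bad] <- 0
    dy[bad] <- 0
  }
  cbind(cx + R * dx / d, R * dy / d, R * dz / d)
}

# point on the 2D silhouette boundary at arc-length parameter t in [0, P),
# measured counter-clockwise from (a, -R); returns point and outward normal
rod_boundary_at2d <- function(t, length_um, width_um) {
  a <- rod_half_axis(length_um, width_um)
  R <- width_um / 2
  seg <- 2 * a          # each straight flank
  cap <- pi * R         # each semicircular cap
  P <- 2 * seg + 2 * cap
  t <- t %% P
  x <- y <- nx <- ny <- numeric(length(t))
  # right cap: t in [0, cap), angle from -pi/2 to +pi/2 around (a, 0)
  i <- t < cap
  th <- -pi / 2 + t[i] / R
  x[i] <- a + R * cos(th); y[i] <- R * sin(th)
  nx[i] <- cos(th); ny[i] <- sin(th)
  # top flank: t in [cap, cap + seg), from (a, R) to (-a, R)
  i <- t >= cap & t < cap + seg
  x[i] <- a - (t[i] - cap); y[i] <- R
  nx[i] <- 0; ny[i] <- 1
  # left cap: angle from +pi/2 to 3pi/2 around (-a, 0)
  i <- t >= cap + seg & t < 2 * cap + seg
  th <- pi / 2 + (t[i] - cap - seg) / R
  x[i] <- -a + R * cos(th); y[i] <- R * sin(th)
  nx[i] <- cos(th); ny[i] <- sin(th)
  # bottom flank: from (-a, -R) to (a, -R)
  i <- t >= 2 * cap + seg
  x[i] <- -a + (t[i] - 2 * cap - seg); y[i] <- -R
  nx[i] <- 0; ny[i] <- -1
  list(x = x, y = y, nx = nx, ny = ny, perimeter = P)
}
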