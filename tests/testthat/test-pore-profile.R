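# on-axis probe geometry against closed forms

cylinder_structure <- function(radius = 10, nz = 11, per_ring = 12) {
  rows <- list()
  k <- 0L
  for (z in seq(0, 30, length.out = nz)) {
    th <- 2 * pi * seq_len(per_ring) / per_ring
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "A", resno = k * per_ring + seq_len(per_ring),
      x = radius * cos(th), y = radius * sin(th), z = z)
    k <- k + 1L
  }
  coarse_structure(do.call(rbind, rows))
}

test_that("a cylindrical wall gives radius minus probe radius", {
  s <- cylinder_structure(10)
  # sample planes aligned with the atom rings (ring spacing 3 A)
  p <- pore_radius_profile(s, axis = c(0, 0, 1), origin = c(0, 0, 15),
                           z_range = c(-9, 9), step = 3,
                           calpha_radius = 1.7)
  expect_equal(p$samples$radius, rep(8.3, nrow(p$samples)),
               tolerance = 1e-6)
})

test_that("a narrower ring creates the global constriction at its z", {
  s <- cylinder_structure(10)
  th <- 2 * pi * seq_len(12) / 12
  ring <- data.frame(chain = "B", resno = 1:12, icode = "",
                     resname = "ALA",
                     x = 6 * cos(th), y = 6 * sin(th), z = 14)
  s2 <- coarse_structure(rbind(s$residues, ring))
  p <- pore_radius_profile(s2, axis = c(0, 0, 1), origin = c(0, 0, 15),
                           z_range = c(-12, 12), step = 1,
                           calpha_radius = 1.7)
  cons <- pore_constriction(p)
  expect_equal(cons$z, -1)    # z = 14 absolute, origin at 15
  expect_equal(cons$radius, 6 - 1.7, tolerance = 1e-6)
})

test_that("profiles never exceed the distance to the nearest atom centre", {
  s <- make_helix_bundle_tetramer(20L, bundle_radius = 9)
  p <- pore_radius_profile(s, axis = c(0, 0, 1), step = 2)
  X <- coords(s)
  slab_half <- max(3, 2 * p$step)
  for (k in which(!p$samples$missing)) {
    z <- p$samples$z[k] + p$origin[3]
    lat <- sqrt((X[, 1] - p$origin[1])^2 + (X[, 2] - p$origin[2])^2)
    sel <- abs(X[, 3] - z) <= slab_half & lat <= 15
    dmin <- min(sqrt(X[sel, 1]^2 + X[sel, 2]^2 + (X[sel, 3] - z)^2))
    expect_lte(p$samples$radius[k], dmin + 1e-9)
  }
})

test_that("profiles are invariant under joint rigid rotation", {
  s <- make_helix_bundle_tetramer(20L, bundle_radius = 9)
  p1 <- pore_radius_profile(s, axis = c(0, 0, 1), step = 2)
  th <- 0.7
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  s2 <- s
  s2$residues[, c("x", "y", "z")] <- coords(s) %*% t(R)
  p2 <- pore_radius_profile(s2, axis = as.vector(R %*% c(0, 0, 1)),
                            origin = as.vector(R %*% colMeans(coords(s))),
                            step = 2, z_range = range(p1$samples$z))
  expect_equal(p2$samples$radius, p1$samples$radius, tolerance = 1e-6)
})

test_that("atom side stores use per-element van der Waals radii", {
  # one oxygen ring vs one carbon ring: O (1.52) leaves a wider pore than
  # the 2.3 A Calpha default
  th <- 2 * pi * seq_len(8) / 8
  res <- data.frame(chain = "A", resno = 1:8, icode = "", resname = "HOH",
                    x = 8 * cos(th), y = 8 * sin(th), z = 0)
  atoms <- data.frame(chain = "A", resno = 1:8, icode = "", resname = "HOH",
                      atom = "O", element = "O",
                      x = 8 * cos(th), y = 8 * sin(th), z = 0)
  s <- coarse_structure(res, atoms = atoms)
  p <- pore_radius_profile(s, axis = c(0, 0, 1), origin = c(0, 0, 0),
                           z_range = c(0, 0), step = 1)
  expect_equal(p$samples$radius[1], 8 - 1.52, tolerance = 1e-9)
})

test_that("comparing profiles reports per-z deltas and the constriction", {
  s <- cylinder_structure(10)
  p <- pore_radius_profile(s, axis = c(0, 0, 1), origin = c(0, 0, 15),
                           z_range = c(-9, 9), step = 3, calpha_radius = 1.7)
  cmp0 <- compare_profiles(p, p)
  expect_true(all(cmp0$per_z$delta == 0))
  expect_equal(cmp0$delta_at_constriction, 0)
  s2 <- cylinder_structure(11)   # uniformly dilated by 1 A
  p2 <- pore_radius_profile(s2, axis = c(0, 0, 1), origin = c(0, 0, 15),
                            z_range = c(-9, 9), step = 3, calpha_radius = 1.7)
  cmp <- compare_profiles(p, p2)
  expect_equal(cmp$per_z$delta, rep(1, nrow(cmp$per_z)), tolerance = 1e-6)
  # disjoint grids are rejected
  p3 <- pore_radius_profile(s, axis = c(0, 0, 1), origin = c(0, 0, 15),
                            z_range = c(40, 50), step = 2, calpha_radius = 1.7)
  expect_error(compare_profiles(p, p3), "disjoint")
})

test_that("in-plane refinement finds an off-axis pore", {
  s <- cylinder_structure(10)
  shifted <- s
  shifted$residues$x <- shifted$residues$x + 3   # pore centre at x = 3
  p0 <- pore_radius_profile(shifted, axis = c(0, 0, 1), origin = c(0, 0, 15),
                            z_range = c(0, 0), step = 1, calpha_radius = 1.7)
  pr <- pore_radius_profile(shifted, axis = c(0, 0, 1), origin = c(0, 0, 15),
                            z_range = c(0, 0), step = 1, calpha_radius = 1.7,
                            refine = TRUE)
  expect_lt(p0$samples$radius[1], 8.3 - 1)       # on-axis probe is off-centre
  expect_equal(pr$samples$radius[1], 8.3, tolerance = 0.05)
  expect_equal(pr$samples$center_x[1], 3, tolerance = 0.1)
})
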