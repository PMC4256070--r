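#' @title Simplified pore-radius profiles
#'
#' @description
#' A deterministic, HOLE-inspired (but deliberately much simpler) probe:
#' at each position z along the channel axis the pore radius is the largest
#' sphere centred on (or, with refinement, near) the axis that touches no
#' atom, i.e. `min over atoms of (distance to atom centre - vdW radius)`.
#' There is no Monte-Carlo sphere wandering; optional in-plane refinement
#' is a bounded grid search plus a fixed number of local polish steps, so
#' outputs are reproducible.  Calpha-only structures use a uniform
#' effective residue radius.
#' @name pore_profile
NULL

#' Default van der Waals radii by element (Angstrom)
#' @return named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
}

.pore_atoms <- function(s, vdw_radii, calpha_radius) {
  if (!is.null(s$atoms)) {
    X <- as.matrix(s$atoms[, c("x", "y", "z")])
    el <- toupper(s$atoms$element)
    r <- unname(vdw_radii[el])
    r[is.na(r)] <- vdw_radii["C"]
  } else {
    X <- coords(s)
    r <- rep(calpha_radius, nrow(X))
  }
  list(X = X, r = r)
}

#' Pore-radius profile along the channel axis
#'
#' @param s a [coarse_structure()]; the atom side store is used when
#'   present, otherwise Calpha spheres of radius `calpha_radius`.
#' @param axis channel axis 3-vector (default: [symmetry_axis()]).
#' @param origin point on the axis (default: structure centroid).
#' @param z_range numeric length-2 range along the axis, relative to
#'   `origin` (default: structure extent plus 5 A margin).
#' @param step probe spacing along the axis in Angstrom.
#' @param vdw_radii per-element radii table.
#' @param calpha_radius effective residue radius for Calpha-only input
#'   (default 2.3 A).
#' @param refine logical: locally re-centre the probe in each plane
#'   (deterministic grid + fixed-iteration polish) to track a pore that is
#'   not exactly on-axis.
#' @param lateral_reach atoms farther than this from the axis are ignored
#'   at every z (keeps slabs meaningful for wide assemblies).
#' @return A `pore_profile`: data.frame `samples` (`z`, `radius`,
#'   `center_x`, `center_y`, `missing`), plus axis metadata.  Radii that
#'   would be negative (blocked pore) are clamped to 0 and flagged.
#' @export
pore_radius_profile <- function(s, axis = NULL, origin = NULL,
                                z_range = NULL, step = 1,
                                vdw_radii = default_vdw_radii(),
                                calpha_radius = 2.3, refine = FALSE,
                                lateral_reach = 15) {
  stopifnot(step > 0)
  if (is.null(axis)) axis <- symmetry_axis(s)
  a <- axis / sqrt(sum(axis^2))
  if (is.null(origin)) origin <- colMeans(coords(s))
  pa <- .pore_atoms(s, vdw_radii, calpha_radius)
  Xc <- sweep(pa$X, 2, origin)
  zc <- drop(Xc %*% a)
  lat <- Xc - outer(zc, a)
  # in-plane orthonormal frame
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  u <- drop(lat %*% e1); v <- drop(lat %*% e2)
  rad_lat <- sqrt(u^2 + v^2)
  if (all(rad_lat > lateral_reach))
    stop("no atom within lateral reach of the axis")
  if (is.null(z_range)) z_range <- range(zc) + c(-5, 5)
  zs <- seq(z_range[1L], z_range[2L], by = step)
  slab_half <- max(3, 2 * step)
  n <- length(zs)
  radius <- cx <- cy <- rep(NA_real_, n)
  missing <- rep(TRUE, n)
  clamped <- FALSE
  probe_radius <- function(px, py, dz, uu, vv, rr) {
    min(sqrt((uu - px)^2 + (vv - py)^2 + dz^2) - rr)
  }
  for (k in seq_len(n)) {
    sel <- abs(zc - zs[k]) <= slab_half & rad_lat <= lateral_reach
    if (!any(sel)) next
    uu <- u[sel]; vv <- v[sel]; rr <- pa$r[sel]; dz <- zc[sel] - zs[k]
    best <- c(0, 0)
    best_r <- probe_radius(0, 0, dz, uu, vv, rr)
    if (refine) {
      for (g in seq(-3, 3, by = 1)) for (h in seq(-3, 3, by = 1)) {
        r0 <- probe_radius(g, h, dz, uu, vv, rr)
        if (r0 > best_r) { best_r <- r0; best <- c(g, h) }
      }
      stp <- 0.5
      for (it in seq_len(40L)) {   # fixed-iteration coordinate polish
        moved <- FALSE
        for (dd in list(c(stp, 0), c(-stp, 0), c(0, stp), c(0, -stp))) {
          cand <- best + dd
          r0 <- probe_radius(cand[1L], cand[2L], dz, uu, vv, rr)
          if (r0 > best_r) { best_r <- r0; best <- cand; moved <- TRUE }
        }
        if (!moved) stp <- stp / 2
        if (stp < 0.01) break
      }
    }
    if (best_r < 0) { best_r <- 0; clamped <- TRUE }
    radius[k] <- best_r; cx[k] <- best[1L]; cy[k] <- best[2L]
    missing[k] <- FALSE
  }
  if (clamped) warning("negative probe radii clamped to 0 (blocked pore)")
  structure(list(samples = data.frame(z = zs, radius = radius,
                                      center_x = cx, center_y = cy,
                                      missing = missing),
                 axis = a, origin = origin, step = step,
                 refined = refine, calpha_radius = calpha_radius),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  ok <- !x$samples$missing
  cat(sprintf("pore_profile: %d samples (step %.2f A), min radius %.2f A at z = %.1f\n",
              nrow(x$samples), x$step, min(x$samples$radius[ok]),
              x$samples$z[ok][which.min(x$samples$radius[ok])]))
  invisible(x)
}

#' Constriction (minimum radius) of a profile
#' @param p a `pore_profile`.
#' @return list with `z` and `radius` of the narrowest sample.
#' @export
pore_constriction <- function(p) {
  ok <- !p$samples$missing
  k <- which(ok)[which.min(p$samples$radius[ok])]
  list(z = p$samples$z[k], radius = p$samples$radius[k])
}

#' Compare two pore profiles on a common z grid
#'
#' Profile `b` minus profile `a` per z (b is linearly resampled onto a's
#' grid if the grids differ), plus a summary of the radius change at a's
#' constriction.  Used to ask whether a mode-displaced conformation widens
#' the gate.
#'
#' @param a,b `pore_profile` objects computed along the same axis.
#' @return list with `per_z` (data.frame `z`, `radius_a`, `radius_b`,
#'   `delta`), `constriction_z`, and `delta_at_constriction`.
#' @export
compare_profiles <- function(a, b) {
  sa <- a$samples[!a$samples$missing, ]
  sb <- b$samples[!b$samples$missing, ]
  if (nrow(sa) == 0L || nrow(sb) == 0L)
    stop("profiles cover disjoint z ranges (no overlapping samples)")
  lo <- max(min(sa$z), min(sb$z)); hi <- min(max(sa$z), max(sb$z))
  if (lo > hi) stop("profiles cover disjoint z ranges")
  sa <- sa[sa$z >= lo & sa$z <= hi, ]
  rb <- stats::approx(sb$z, sb$radius, xout = sa$z, rule = 2)$y
  per_z <- data.frame(z = sa$z, radius_a = sa$radius, radius_b = rb,
                      delta = rb - sa$radius)
  kz <- which.min(sa$radius)
  list(per_z = per_z, constriction_z = sa$z[kz],
       delta_at_constriction = per_z$delta[kz])
}
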