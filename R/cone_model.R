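#' @title Synthetic cone-channel heterotetramer (Model S1 stand-in)
#'
#' @description
#' A deterministic, fully synthetic Calpha-level model of a cone-type CNG
#' channel: two CNGA3-like chains (A, B) and two CNGB3-like chains (C, D;
#' residue numbering offset +42, matching the CNGA3 L361 / CNGB3 R403 and
#' F385 / F427 correspondence), alike subunits adjacent, C4-related
#' backbone geometry.  Each subunit carries the canonical architecture:
#' voltage-sensor domain (S1-S4, with S1 at 170-186), pore domain (S5,
#' pore helix, selectivity filter, pore-lining S6 ending in the bundle
#' crossing around residues 401-407), C-linker (elbow/shoulder helices)
#' and a compact CNBD, with the TM domain spanning residues 161-410 and
#' the cytosolic domain 410-610 (CNGA3 numbering).
#'
#' This object is a geometric stand-in, not a deposited model: helices are
#' ideal traces through hand-placed waypoints, chosen so that published
#' landmark Calpha distances of the cone-channel model (L361-F385 about
#' 10 A within a subunit, F385 to the adjacent subunit's R403 about 7 A,
#' R436-E467 and R436-D507 about 11 A) hold by construction.  Use it to
#' exercise and test the analysis machinery, not as structural evidence.
#' @name cone_model
NULL

# cylindrical helper
.pol <- function(r, th_deg, z) {
  th <- th_deg * pi / 180
  c(r * cos(th), r * sin(th), z)
}

# quadratic bezier loop through an optional control point.  A small helical
# wrap around the centreline keeps local neighbourhoods three-dimensional:
# pair springs along a straight rope leave transverse directions
# unsupported, which would flood an ANM with spurious near-zero modes.
.bezier_loop <- function(n, from, to, ctrl = NULL) {
  if (is.null(ctrl)) return(.loop_trace(n, from, to))
  t <- if (n == 1L) 0.5 else seq(0, 1, length.out = n + 2L)[2:(n + 1L)]
  base <- outer((1 - t)^2, from) + outer(2 * t * (1 - t), ctrl) + outer(t^2, to)
  .wrap_coil(base, radius = 1.8, turn_deg = 85)
}

# superimpose a helical offset around the local tangent of a path
.wrap_coil <- function(base, radius = 2.2, turn_deg = 85) {
  n <- nrow(base)
  if (n < 3L) return(base)
  tangent <- rbind(base[2L, ] - base[1L, ],
                   (base[3:n, , drop = FALSE] - base[1:(n - 2L), , drop = FALSE]) / 2,
                   base[n, ] - base[n - 1L, ])
  out <- base
  for (i in seq_len(n)) {
    u <- tangent[i, ] / max(sqrt(sum(tangent[i, ]^2)), 1e-9)
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    ang <- (i - 1L) * turn_deg * pi / 180
    out[i, ] <- base[i, ] + radius * (cos(ang) * e1 + sin(ang) * e2)
  }
  out
}

# wide flat coil for long loops: keeps ~3.8 A spacing without clumping
.coil_trace <- function(n, from, to) {
  .helix_trace(n, from, to, radius = 6, turn_deg = 36)
}

# segment table of the subunit template (chain sector centred on azimuth 0).
# Waypoints are (radius A, azimuth deg, z A); membrane spans z ~ 0..26.
.cone_segments <- function() {
  list(
    list(label = "NT",  start = 161L, end = 168L, type = "coil",
         from = .pol(27, -40, -11), to = .pol(27, -40, -4)),
    list(label = "S1",  start = 170L, end = 186L,
         from = .pol(27, -54, 0),   to = .pol(27, -48, 25)),
    list(label = "LP12", start = 190L, end = 213L, type = "coil",
         from = .pol(29, -41, 24),  to = .pol(29, -41, 35)),
    list(label = "S2",  start = 217L, end = 233L,
         from = .pol(27, -37, 25),  to = .pol(27, -31, 0)),
    list(label = "LP23", start = 237L, end = 260L, type = "coil",
         from = .pol(27, -24, -3),  to = .pol(27, -24, -13)),
    list(label = "S3",  start = 264L, end = 280L,
         from = .pol(27, -20, 0),   to = .pol(27, -14, 25)),
    list(label = "S4",  start = 288L, end = 304L,
         from = .pol(27, -3, 25),   to = .pol(27, 3, 0)),
    list(label = "L45", start = 306L, end = 314L,          # S4-S5 linker
         from = .pol(26, 8, -6),    to = .pol(18, 22, -7)),
    list(label = "S5",  start = 316L, end = 340L,
         from = .pol(16, 22, -5),   to = .pol(14, 45, 28)),
    list(label = "LP5P", start = 343L, end = 352L, type = "coil",
         from = .pol(11, 18, 31),   to = .pol(11, 18, 37)),
    list(label = "PH",  start = 355L, end = 368L,          # pore helix
         from = .pol(12, 2, 28),    to = .pol(7, -58, 13.2)),
    list(label = "S6a", start = 376L, end = 391L,
         from = .pol(8.5, 62, 28),  to = .pol(10.5, 37, 7)),
    list(label = "S6b", start = 392L, end = 407L,
         from = .pol(10.5, 37, 7),  to = .pol(4.6, 12, -10)),
    list(label = "CLA", start = 413L, end = 424L,          # C-linker A'
         from = .pol(12, 26, -21),  to = .pol(19, 58, -24)),
    list(label = "CLB", start = 427L, end = 438L,          # B' (elbow)
         from = .pol(20, 66, -26),  to = .pol(11, 96, -30)),
    list(label = "CLC", start = 443L, end = 454L,          # C' (shoulder)
         from = .pol(11, 94, -32),  to = .pol(19, 64, -36)),
    list(label = "CLD", start = 458L, end = 468L,
         from = .pol(16, 96, -35),  to = .pol(9, 72, -38))
  )
}

# bezier control points for the long connecting loops, keyed by the residue
# number of the preceding segment's last residue.  Long extramembrane loops
# hang outward as floppy arcs rather than packing against the helices.
.cone_loop_ctrl <- function() {
  list(`368` = .pol(10, 25, 22),   # selectivity-filter region
       `468` = .pol(46, 50, -30))   # C-linker to CNBD entry
}

# CNBD block: eight short helices snaking through a 3 x 3 local
# (up, tan) grid of axis slots, 9 A pitch: protein-like helix packing
.cnbd_segments <- function() {
  list(
    list(start = 481L, end = 494L, from = c(-10,  0,  9), to = c( 10,  0,  9)),
    list(start = 498L, end = 511L, from = c( 10,  8,  9), to = c(-10,  8,  9)),
    list(start = 515L, end = 528L, from = c(-10,  8,  0), to = c( 10,  8,  0)),
    list(start = 532L, end = 545L, from = c( 10,  0,  0), to = c(-10,  0,  0)),
    list(start = 549L, end = 562L, from = c(-10, -8,  0), to = c( 10, -8,  0)),
    list(start = 566L, end = 579L, from = c( 10, -8, -9), to = c(-10, -8, -9)),
    list(start = 583L, end = 596L, from = c(-10,  0, -9), to = c( 10,  0, -9)),
    list(start = 600L, end = 610L, from = c(  8,  8, -9), to = c( -7,  8, -9))
  )
}

.cnbd_centre <- c(20, 38, -44) # (radius, azimuth deg, z) of the CNBD

# residue names planted at structural positions (CNGA3 numbering);
# everything else is ALA.  The CNGB3 column reflects the +42 offset
# correspondences discussed for the cone channel (R403, F427, Y469, R478,
# D549 ...).
.cone_resnames <- function(subunit = c("CNGA3", "CNGB3")) {
  subunit <- match.arg(subunit)
  if (subunit == "CNGA3")
    c(`186` = "LEU", `361` = "LEU", `385` = "PHE", `427` = "ARG",
      `436` = "ARG", `453` = "GLU", `467` = "GLU", `507` = "ASP")
  else  # names by structural (CNGA3-equivalent) position
    c(`361` = "ARG", `385` = "PHE", `393` = "SER", `427` = "TYR",
      `436` = "ARG", `446` = "ASP", `453` = "GLU", `467` = "GLU",
      `507` = "ASP")
}

# build the template chain: one subunit, azimuth sector centred on 0
.build_cone_template <- function() {
  segs <- .cone_segments()
  cc <- .cnbd_centre
  th <- cc[2] * pi / 180
  centre <- c(cc[1] * cos(th), cc[1] * sin(th), cc[3])
  out_v <- c(cos(th), sin(th), 0)
  tan_v <- c(-sin(th), cos(th), 0)
  up_v <- c(0, 0, 1)
  for (h in .cnbd_segments()) {
    segs[[length(segs) + 1L]] <- list(
      label = "CNBD", start = h$start, end = h$end,
      from = centre + h$from[1] * out_v + h$from[2] * tan_v + h$from[3] * up_v,
      to = centre + h$to[1] * out_v + h$to[2] * tan_v + h$to[3] * up_v)
  }
  ctrl_map <- .cone_loop_ctrl()
  # trace every anchored segment first ...
  traces <- lapply(segs, function(sg) {
    n <- sg$end - sg$start + 1L
    if (identical(sg$type, "strand")) .loop_trace(n, sg$from, sg$to)
    else if (identical(sg$type, "coil")) .coil_trace(n, sg$from, sg$to)
    else .helix_trace(n, sg$from, sg$to)
  })
  # ... then bridge the realized endpoints with connector loops
  pts <- list(traces[[1L]])
  resno <- segs[[1L]]$start:segs[[1L]]$end
  for (k in seq_along(segs)[-1L]) {
    sg <- segs[[k]]
    prev_end <- segs[[k - 1L]]$end
    gap <- sg$start - prev_end - 1L
    if (gap > 0L) {
      prev_pt <- pts[[length(pts)]][nrow(pts[[length(pts)]]), ]
      next_pt <- traces[[k]][1L, ]
      ctrl <- ctrl_map[[as.character(prev_end)]]
      tr <- .bezier_loop(gap, prev_pt, next_pt, ctrl = ctrl)
      pts[[length(pts) + 1L]] <- tr
      resno <- c(resno, (prev_end + 1L):(sg$start - 1L))
    }
    pts[[length(pts) + 1L]] <- traces[[k]]
    resno <- c(resno, sg$start:sg$end)
  }
  X <- do.call(rbind, pts)
  data.frame(resno = resno, x = X[, 1], y = X[, 2], z = X[, 3])
}

#' Synthetic cone-channel heterotetramer
#'
#' Builds the synthetic stand-in for a cone CNG channel model: chains A and
#' B are CNGA3-like (residues 161-610), chains C and D are CNGB3-like
#' (residues 203-652, the +42 numbering offset), arranged A3-A3-B3-B3
#' around the pore so that alike subunits are adjacent.  Deterministic:
#' repeated calls are identical.
#'
#' Shipped annotations (overridable by re-annotating): `TM` (161-410),
#' `cytosolic` (411-610), `VSD` (S1-S4, 170-304), `pore` (316-410),
#' `S1` (170-186), `C-linker` (411-480), `CNBD` (481-610) and
#' `hinge_ref` (401-407), all per chain with the +42 shift on CNGB3
#' chains.
#'
#' @return A four-chain [coarse_structure()].
#' @export
synthetic_cone_channel <- function() {
  tmpl <- .build_cone_template()
  chains <- list(A = list(az = 0,   sub = "CNGA3", off = 0L),
                 B = list(az = 90,  sub = "CNGA3", off = 0L),
                 C = list(az = 180, sub = "CNGB3", off = 42L),
                 D = list(az = 270, sub = "CNGB3", off = 42L))
  res <- list()
  for (ch in names(chains)) {
    cf <- chains[[ch]]
    R <- .rotation_about(c(0, 0, 1), cf$az)
    xyz <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(R)
    rn <- rep("ALA", nrow(tmpl))
    special <- .cone_resnames(cf$sub)
    hit <- match(tmpl$resno, as.integer(names(special)))
    rn[!is.na(hit)] <- special[hit[!is.na(hit)]]
    res[[ch]] <- data.frame(chain = ch, resno = tmpl$resno + cf$off,
                            icode = "", resname = rn,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  s <- coarse_structure(do.call(rbind, res))
  doms <- list(TM = c(161L, 410L), cytosolic = c(411L, 610L),
               VSD = c(170L, 304L), pore = c(316L, 410L),
               S1 = c(170L, 186L), `C-linker` = c(411L, 480L),
               CNBD = c(481L, 610L), hinge_ref = c(401L, 407L))
  for (ch in names(chains)) {
    off <- chains[[ch]]$off
    for (dl in names(doms))
      s <- annotate_domain(s, dl, ch, doms[[dl]][1L] + off, doms[[dl]][2L] + off)
  }
  s
}

#' Subunit type of each chain of the synthetic cone channel
#' @return named character vector (chain -> "CNGA3"/"CNGB3").
#' @export
cone_channel_subunits <- function() {
  c(A = "CNGA3", B = "CNGA3", C = "CNGB3", D = "CNGB3")
}

#' Homotetramer of CNGA3-like subunits
#'
#' The dynamics analysis works on a symmetric channel of four identical
#' CNGA3 subunits.  One CNGA3 chain is taken from the synthetic
#' heterotetramer and C4-symmetrized about the z axis, giving an exactly
#' symmetric homotetramer with the same per-chain geometry.
#'
#' @param s optional heterotetramer (default [synthetic_cone_channel()]).
#' @param chain which CNGA3 chain to replicate.
#' @return A four-chain C4-symmetric [coarse_structure()].
#' @export
cnga3_homotetramer <- function(s = synthetic_cone_channel(), chain = "A") {
  keep <- s$residues$chain == chain
  mono <- coarse_structure(
    s$residues[keep, , drop = FALSE],
    annotations = s$annotations[s$annotations$chain == chain, , drop = FALSE])
  rownames(mono$residues) <- NULL
  assemble_homotetramer(mono, 4L, c(0, 0, 1))
}
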