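#' @title Interpreting the mode spectrum
#'
#' @description
#' Turns raw eigensystems into channel biology: per-mode fluctuation shapes
#' and their hinge (minimum) regions, association of GNM modes with the ANM
#' modes whose fluctuation profiles match, grouped "motions" (a
#' non-degenerate slow mode plus degenerate pairs), mode-displaced edge
#' conformations, domain rotation angles about the membrane normal, and the
#' comparison of a full channel against a domain-deleted variant.
#' @name mode_analysis
NULL

#' Per-mode fluctuation shape
#'
#' The per-residue squared fluctuation in one mode (or averaged over a
#' degenerate group of modes).  For GNM this is `u_k^2 / lambda_k`; for ANM
#' the squared 3-vector block norms `|u_k[i]|^2 / lambda_k`.
#'
#' @param d a `spectral_decomposition`.
#' @param modes non-zero mode index or vector (averaged).
#' @return numeric N-vector (non-negative).
#' @export
mode_shape <- function(d, modes) {
  shp <- 0
  for (k in modes) {
    col <- .mode_col(d, k)
    u <- d$vectors[, col]
    v <- if (d$kind == "ANM") colSums(matrix(u, nrow = 3L)^2) else u^2
    shp <- shp + v / d$values[col]
  }
  shp / length(modes)
}

#' Detect hinge regions as minima of a fluctuation profile
#'
#' The profile is smoothed with a running mean and, per chain, maximal runs
#' of residues lying below the `floor_quantile` of the smoothed profile and
#' containing a local minimum are reported as hinge ranges.  Hinges
#' coordinate the cooperative motion of the mobile elements on either side.
#'
#' @param shape numeric fluctuation profile (e.g. [mode_shape()]).
#' @param chains optional character vector assigning each entry to a chain;
#'   hinge detection is then per chain.
#' @param resno optional residue numbers (defaults to 1..N per chain).
#' @param window smoothing window in residues (odd; default 5).
#' @param floor_quantile quantile of the smoothed profile below which
#'   residues qualify (default 0.1).
#' @return data.frame (`chain`, `start`, `end`) of hinge ranges in residue
#'   numbering; zero rows (with a warning) for a flat profile.
#' @export
detect_hinges <- function(shape, chains = NULL, resno = NULL, window = 5L,
                          floor_quantile = 0.1) {
  n <- length(shape)
  if (n <= window) stop("profile shorter than the smoothing window")
  if (is.null(chains)) chains <- rep("A", n)
  if (is.null(resno)) resno <- stats::ave(seq_len(n), chains, FUN = seq_along)
  if (stats::sd(shape) < 1e-12 * max(abs(shape), 1e-300)) {
    warning("flat fluctuation profile: no hinges detectable")
    return(data.frame(chain = character(), start = integer(), end = integer()))
  }
  out <- list()
  for (ch in unique(chains)) {
    sel <- chains == ch
    y <- shape[sel]; rn <- resno[sel]
    m <- length(y)
    half <- window %/% 2L
    sm <- vapply(seq_len(m), function(i)
      mean(y[max(1L, i - half):min(m, i + half)]), numeric(1))
    thr <- stats::quantile(sm, floor_quantile, names = FALSE)
    low <- sm <= thr
    # maximal runs of low residues that contain a local minimum
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in which(r$values)) {
      i0 <- starts[b]; i1 <- ends[b]
      lo <- which.min(sm[i0:i1]) + i0 - 1L
      is_local_min <- (lo == 1L || sm[lo] <= sm[lo - 1L]) &&
        (lo == m || sm[lo] <= sm[lo + 1L])
      if (is_local_min)
        out[[length(out) + 1L]] <- data.frame(chain = ch, start = rn[i0],
                                              end = rn[i1],
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chain = character(), start = integer(), end = integer()))
  do.call(rbind, out)
}

#' Associate GNM modes with ANM modes by fluctuation-profile similarity
#'
#' For each GNM mode (or averaged degenerate group) the ANM mode whose
#' per-residue fluctuation profile has the greatest Pearson correlation is
#' reported; ties break towards the slower ANM mode.  This is how the
#' direction information of ANM is attached to the (more reliable) GNM
#' amplitudes.
#'
#' @param gnm_shapes N x K matrix (or list) of per-residue GNM mode shapes.
#' @param anm_shapes N x M matrix (or list) of per-residue ANM mode shapes.
#' @return data.frame (`gnm_mode`, `anm_mode`, `similarity`); a constant
#'   profile yields NA similarity and NA partner.
#' @export
associate_modes <- function(gnm_shapes, anm_shapes) {
  G <- if (is.list(gnm_shapes)) do.call(cbind, gnm_shapes) else as.matrix(gnm_shapes)
  A <- if (is.list(anm_shapes)) do.call(cbind, anm_shapes) else as.matrix(anm_shapes)
  if (ncol(G) < 1L || ncol(A) < 1L) stop("need at least one mode on each side")
  out <- data.frame(gnm_mode = seq_len(ncol(G)), anm_mode = NA_integer_,
                    similarity = NA_real_)
  for (g in seq_len(ncol(G))) {
    if (stats::sd(G[, g]) == 0) next
    sims <- vapply(seq_len(ncol(A)), function(a) {
      if (stats::sd(A[, a]) == 0) return(NA_real_)
      stats::cor(G[, g], A[, a])
    }, numeric(1))
    if (all(is.na(sims))) next
    best <- max(sims, na.rm = TRUE)
    out$anm_mode[g] <- which(sims >= best - 1e-12)[1L]  # tie -> slower mode
    out$similarity[g] <- best
  }
  out
}

#' Edge conformations of an ANM mode
#'
#' The two extreme structures sampled by a mode, obtained by adding and
#' subtracting the (per-residue reshaped) eigenvector to/from the
#' equilibrium coordinates.  When `amplitude` is omitted it is chosen so the
#' largest per-residue displacement is `max_displacement` Angstrom.
#'
#' @param s the equilibrium [coarse_structure()].
#' @param d the matching ANM `spectral_decomposition`.
#' @param mode non-zero mode index (1 = slowest).
#' @param amplitude scalar multiplier of the unit eigenvector; `NULL` for
#'   the default scaling.
#' @param max_displacement target maximum per-residue displacement (A) used
#'   when `amplitude` is `NULL`.
#' @return An `edge_conformations` object: `plus`, `minus` (structures),
#'   `mode`, `amplitude`.
#' @export
edge_conformations <- function(s, d, mode, amplitude = NULL,
                               max_displacement = 2) {
  stopifnot(d$kind == "ANM")
  col <- .mode_col(d, mode)
  u <- matrix(d$vectors[, col], ncol = 3L, byrow = TRUE)  # N x 3
  if (nrow(u) != n_residues(s))
    stop("decomposition does not match the structure")
  if (is.null(amplitude)) {
    amplitude <- max_displacement / max(sqrt(rowSums(u^2)))
  }
  if (!is.finite(amplitude)) stop("non-finite amplitude")
  plus <- s; minus <- s
  plus$residues[, c("x", "y", "z")] <- coords(s) + amplitude * u
  minus$residues[, c("x", "y", "z")] <- coords(s) - amplitude * u
  plus$atoms <- minus$atoms <- NULL   # side store no longer consistent
  structure(list(plus = plus, minus = minus, mode = mode,
                 amplitude = amplitude),
            class = "edge_conformations")
}

#' @export
print.edge_conformations <- function(x, ...) {
  cat(sprintf("edge_conformations: mode %d, amplitude %.3g\n", x$mode, x$amplitude))
  invisible(x)
}

#' Signed in-plane rotation of a domain about an axis
#'
#' Least-squares rotation angle, about `axis` through the origin, carrying
#' the domain's Calpha set of `reference` onto that of `displaced`
#' (projections onto the plane normal to the axis).  Positive angles are
#' right-handed about the axis.
#'
#' @param reference,displaced [coarse_structure()] objects over the same
#'   residue set.
#' @param domain annotation label (must be present in `reference`) or a
#'   logical residue mask.
#' @param axis 3-vector rotation axis.
#' @return angle in degrees (signed).
#' @export
domain_rotation_angle <- function(reference, displaced, domain,
                                  axis = c(0, 0, 1)) {
  mask <- if (is.logical(domain)) domain else domain_mask(reference, domain)
  if (sum(mask) < 3L) stop("domain has fewer than 3 residues")
  if (n_residues(reference) != n_residues(displaced) ||
      !identical(reference$residues$resno, displaced$residues$resno) ||
      !identical(reference$residues$chain, displaced$residues$chain))
    stop("reference and displaced structures must share the residue set")
  a <- axis / sqrt(sum(axis^2))
  P <- coords(reference)[mask, , drop = FALSE]
  Q <- coords(displaced)[mask, , drop = FALSE]
  # in-plane components (axis through the origin)
  P2 <- P - outer(drop(P %*% a), a)
  Q2 <- Q - outer(drop(Q %*% a), a)
  crossz <- sum((P2[, 1] * Q2[, 2] - P2[, 2] * Q2[, 1]) * a[3] +
                (P2[, 2] * Q2[, 3] - P2[, 3] * Q2[, 2]) * a[1] +
                (P2[, 3] * Q2[, 1] - P2[, 1] * Q2[, 3]) * a[2])
  dot <- sum(P2 * Q2)
  atan2(crossz, dot) * 180 / pi
}

#' Group slow modes into "motions"
#'
#' Channel dynamics are summarized as a handful of motions: by default
#' motion I is the slowest non-degenerate GNM mode, and motions II and III
#' are the next (averaged) degenerate groups, following the eigenvalue
#' clustering of a C4-symmetric assembly.  Each motion carries its shape,
#' hinge ranges and a domain-pair correlation summary.
#'
#' @param d a GNM `spectral_decomposition`.
#' @param s the underlying [coarse_structure()] (for chains/annotations).
#' @param n_motions how many motions to report.
#' @param groups optional list of non-zero mode index vectors overriding
#'   the default grouping.
#' @param window,floor_quantile hinge detection parameters.
#' @return list of `motion_group` objects (label, modes, shape, hinges,
#'   domain correlation summary).
#' @export
motion_groups <- function(d, s, n_motions = 3L, groups = NULL,
                          window = 5L, floor_quantile = 0.1) {
  if (is.null(groups)) {
    gl <- split(seq_len(n_modes(d)), degenerate_groups(d))
    # motion I: slowest non-degenerate group; then subsequent groups
    first_nondeg <- which(vapply(gl, length, integer(1)) == 1L)[1L]
    ord <- c(first_nondeg, setdiff(seq_along(gl), first_nondeg))
    groups <- gl[ord[seq_len(min(n_motions, length(gl)))]]
  }
  ncc <- normalized_cross_correlation(gnm_correlation(d, "all"))
  labels <- c("I", "II", "III", as.character(seq_len(max(0, length(groups) - 3L)) + 3L))
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    shp <- mode_shape(d, groups[[g]])
    hinges <- detect_hinges(shp, chains = s$residues$chain,
                            resno = s$residues$resno,
                            window = window, floor_quantile = floor_quantile)
    dom_sum <- .domain_correlation_summary(s, ncc)
    out[[g]] <- structure(list(label = labels[g], gnm_modes = groups[[g]],
                               shape = shp, hinge_ranges = hinges,
                               domain_correlation_summary = dom_sum),
                          class = "motion_group")
  }
  out
}

.domain_correlation_summary <- function(s, ncc) {
  labs <- unique(s$annotations$label)
  if (length(labs) < 2L) return(NULL)
  combos <- utils::combn(labs, 2L)
  data.frame(domain_a = combos[1L, ], domain_b = combos[2L, ],
             mean_correlation = vapply(seq_len(ncol(combos)), function(k) {
               ma <- domain_mask(s, combos[1L, k])
               mb <- domain_mask(s, combos[2L, k])
               mean(ncc[ma, mb], na.rm = TRUE)
             }, numeric(1)),
             stringsAsFactors = FALSE)
}

#' @export
print.motion_group <- function(x, ...) {
  cat(sprintf("motion %s: GNM mode(s) %s, %d hinge range(s)\n", x$label,
              paste(x$gnm_modes, collapse = ","), nrow(x$hinge_ranges)))
  invisible(x)
}

#' Compare the motions of a full structure and a reduced variant
#'
#' Used for domain-deletion experiments (e.g. removing the voltage-sensor
#' domains): for each motion of the full structure, the best-matching
#' motion of the variant is found by Pearson correlation of the shapes on
#' the shared residues; motions with no good counterpart are flagged as
#' variant-specific.
#'
#' @param full,reduced lists of `motion_group` objects (see
#'   [motion_groups()]).
#' @param full_residues,reduced_residues data.frames with `chain`, `resno`
#'   identifying the residues behind each shape vector.
#' @param min_similarity correlation below which a motion counts as
#'   unmatched.
#' @return data.frame (`full_motion`, `reduced_motion`, `similarity`,
#'   `matched`); attribute `"shared_residues"` gives the residue count
#'   compared.
#' @export
compare_variants <- function(full, reduced, full_residues, reduced_residues,
                             min_similarity = 0.5) {
  fk <- paste(full_residues$chain, full_residues$resno)
  rk <- paste(reduced_residues$chain, reduced_residues$resno)
  shared <- intersect(fk, rk)
  if (length(shared) == 0L) stop("no shared residues between variants")
  fi <- match(shared, fk); ri <- match(shared, rk)
  out <- data.frame(full_motion = vapply(full, `[[`, character(1), "label"),
                    reduced_motion = NA_character_,
                    similarity = NA_real_, matched = FALSE,
                    stringsAsFactors = FALSE)
  for (m in seq_along(full)) {
    sims <- vapply(reduced, function(r)
      stats::cor(full[[m]]$shape[fi], r$shape[ri]), numeric(1))
    b <- which.max(sims)
    out$reduced_motion[m] <- reduced[[b]]$label
    out$similarity[m] <- sims[b]
    out$matched[m] <- sims[b] >= min_similarity
  }
  attr(out, "shared_residues") <- length(shared)
  out
}
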