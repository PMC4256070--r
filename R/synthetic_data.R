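#' @title Deterministic synthetic fixtures
#'
#' @description
#' Generators for everything the test suite needs without downloads: toy
#' elastic networks with closed-form spectra (rings, chains), C4-symmetric
#' helix bundles standing in for a tetrameric channel, coupling tables with
#' a planted true-contact fraction, and conservation tracks with a planted
#' burial correlation.  Every generator derives a private RNG stream from
#' `(seed, kind)` so fixtures drawn from one master seed are independent and
#' bit-reproducible.
#' @name synthetic_data
NULL

# run code under a local RNG seeded from (seed, kind); global RNG untouched
.with_stream <- function(seed, kind, code) {
  stream <- (as.integer(seed) * 131L + sum(utf8ToInt(kind))) %% .Machine$integer.max
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream)
  force(code)
}

#' Ring of equally spaced Calpha nodes
#'
#' With a GNM cutoff just above `spacing` this is the circulant cycle graph,
#' whose Laplacian eigenvalues have the closed form `2 - 2 cos(2 pi k / n)`
#' -- the package's analytic oracle substrate.
#'
#' @param n number of nodes (>= 3).
#' @param spacing nearest-neighbour distance in Angstrom.
#' @return single-chain [coarse_structure()] lying in the z = 0 plane.
#' @export
make_ring <- function(n, spacing = 3.8) {
  if (n < 3L) stop("a ring needs n >= 3 nodes")
  R <- spacing / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1L) / n
  coarse_structure(data.frame(chain = "A", resno = seq_len(n), icode = "",
                              resname = "GLY",
                              x = R * cos(th), y = R * sin(th), z = 0,
                              stringsAsFactors = FALSE))
}

#' Straight chain of equally spaced Calpha nodes
#'
#' Nearest-neighbour GNM connectivity gives the path-graph Laplacian with
#' eigenvalues `2 - 2 cos(pi k / n)`, another closed-form oracle.
#'
#' @param n number of nodes (>= 2).
#' @param spacing inter-node distance in Angstrom.
#' @return single-chain [coarse_structure()] along x.
#' @export
make_chain <- function(n, spacing = 3.8) {
  if (n < 2L) stop("a chain needs n >= 2 nodes")
  coarse_structure(data.frame(chain = "A", resno = seq_len(n), icode = "",
                              resname = "GLY",
                              x = spacing * (seq_len(n) - 1L), y = 0, z = 0,
                              stringsAsFactors = FALSE))
}

#' Random globular Calpha cloud (testing substrate)
#'
#' Gaussian cloud scaled to a protein-like density; used by property tests
#' as a generic structure with no special symmetry.
#'
#' @param n residue count.
#' @param seed RNG seed.
#' @param radius cloud radius scale in Angstrom.
#' @return single-chain [coarse_structure()].
#' @export
make_cloud <- function(n, seed = 1L, radius = 3 * n^(1 / 3)) {
  .with_stream(seed, "cloud", {
    coarse_structure(data.frame(chain = "A", resno = seq_len(n), icode = "",
                                resname = "ALA",
                                x = stats::rnorm(n, sd = radius),
                                y = stats::rnorm(n, sd = radius),
                                z = stats::rnorm(n, sd = radius),
                                stringsAsFactors = FALSE))
  })
}

# ideal alpha-helix Calpha trace along the segment from `from` to `to`
.helix_trace <- function(n, from, to, radius = 2.3, turn_deg = 100,
                         phase = 0) {
  axis <- to - from
  len <- sqrt(sum(axis^2))
  u <- axis / len
  # orthonormal frame
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  t <- if (n == 1L) 0.5 else (seq_len(n) - 1L) / (n - 1L)
  ang <- (phase + turn_deg * (seq_len(n) - 1L)) * pi / 180
  base <- outer(t, axis) + matrix(from, n, 3, byrow = TRUE)
  base + radius * (outer(cos(ang), e1) + outer(sin(ang), e2))
}

# loop trace: linear interpolation with a small deterministic perpendicular
# bulge; endpoints are excluded (they belong to the flanking segments)
.loop_trace <- function(n, from, to, bulge = NULL) {
  t <- seq(0, 1, length.out = n + 2L)[2:(n + 1L)]
  span <- sqrt(sum((to - from)^2))
  # widen the detour when the gap is short relative to the residue count,
  # so connector loops do not clump onto their flanking segments
  if (is.null(bulge)) bulge <- max(2.5, 0.4 * (3.4 * (n + 1L) - span))
  base <- outer(t, to - from) + matrix(from, n, 3, byrow = TRUE)
  u <- (to - from) / max(span, 1e-9)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  base + bulge * outer(sin(pi * t) * cos(2 * pi * t), e1) +
    0.4 * bulge * outer(sin(pi * t) * sin(2 * pi * t), e2) +
    # slight corkscrew so that no stretch of the loop is locally straight
    0.8 * (outer(cos(2.2 * pi * t), e1) + outer(sin(2.2 * pi * t), e2))
}

#' C4-symmetric four-helix bundle tetramer
#'
#' Four ideal alpha-helical Calpha traces (rise 1.5 A/residue, helix radius
#' 2.3 A, 100 degrees/residue -- ideal alpha-helix constants) run parallel
#' to z at distance `bundle_radius` from the axis, related by exact 90-degree
#' rotations.  The upper half of each chain is annotated "TM" and the lower
#' half "cytosolic", mimicking a membrane channel's two-layer layout.
#'
#' @param residues_per_chain residues per helix (>= 10).
#' @param rise helical rise per residue in Angstrom.
#' @param radius helix radius in Angstrom.
#' @param bundle_radius distance of each helix axis from the C4 axis.
#' @param seed unused (the bundle is deterministic); kept so every generator
#'   shares one signature.
#' @return four-chain [coarse_structure()] with C4 symmetry about z.
#' @export
make_helix_bundle_tetramer <- function(residues_per_chain, rise = 1.5,
                                       radius = 2.3, bundle_radius = 8,
                                       seed = 1L) {
  if (residues_per_chain < 10L) stop("residues_per_chain must be >= 10")
  n <- residues_per_chain
  h <- rise * (n - 1L)
  mono <- .helix_trace(n, c(bundle_radius, 0, -h / 2),
                       c(bundle_radius, 0, h / 2), radius = radius)
  s <- coarse_structure(data.frame(chain = "A", resno = seq_len(n),
                                   icode = "", resname = "ALA",
                                   x = mono[, 1], y = mono[, 2], z = mono[, 3],
                                   stringsAsFactors = FALSE))
  tet <- assemble_homotetramer(s, 4L, c(0, 0, 1))
  d <- as.matrix(stats::dist(coords(tet)))
  inter <- outer(tet$residues$chain, tet$residues$chain, "!=")
  if (min(d[inter]) < 1)
    stop("geometric overlap: minimum inter-chain distance below 1 A; increase bundle_radius")
  half <- floor(n / 2)
  for (ch in c("A", "B", "C", "D")) {
    tet <- annotate_domain(tet, "TM", ch, half + 1L, n)
    tet <- annotate_domain(tet, "cytosolic", ch, 1L, half)
  }
  tet
}

#' Coupling table with planted contact precision
#'
#' Emulates a ranked evolutionary-coupling list: `round(p * n_pairs)` pairs
#' are drawn from the true contacts of `map` and the rest from non-contact
#' pairs, then assigned strictly decreasing strengths with rank-independent
#' noise so that top-fraction selection is non-trivially exercised.  Residue
#' pairs are reported in residue numbering (any chain realization counts as
#' the same pair), matching how couplings in query numbering are evaluated
#' against an oligomer.
#'
#' @param map a `contact_map` from [compute_contact_map()].
#' @param n_pairs number of coupling entries.
#' @param precision planted fraction of true contacts in `[0, 1]`.
#' @param L alignment/query length stored on the table (drives top-2L/3
#'   selection).
#' @param seed RNG seed.
#' @param min_separation minimum `|i - j|` for sampled pairs (applied to
#'   contacts and non-contacts alike).
#' @param domain_tag tag stored on the table ("TM", "cytosolic" or "other").
#' @return A `coupling_table` (see [read_coupling_table()]).
#' @export
make_coupling_table <- function(map, n_pairs, precision, L, seed = 1L,
                                min_separation = 5L, domain_tag = "other") {
  stopifnot(precision >= 0, precision <= 1)
  res <- map$residues
  # unordered residue-number pairs realized as contacts (any chain pair)
  pi_ <- res$resno[map$pairs$i]; pj <- res$resno[map$pairs$j]
  a <- pmin(pi_, pj); b <- pmax(pi_, pj)
  keep <- (b - a) >= min_separation
  contact_keys <- unique(paste(a[keep], b[keep]))
  nums <- sort(unique(res$resno))
  all_pairs <- utils::combn(nums, 2L)
  sep_ok <- (all_pairs[2L, ] - all_pairs[1L, ]) >= min_separation
  all_keys <- paste(all_pairs[1L, sep_ok], all_pairs[2L, sep_ok])
  noncontact_keys <- setdiff(all_keys, contact_keys)
  n_true <- round(precision * n_pairs)
  n_false <- n_pairs - n_true
  if (n_true > length(contact_keys) || n_false > length(noncontact_keys))
    stop(sprintf("infeasible request: need %d contacts (%d available) and %d non-contacts (%d available)",
                 n_true, length(contact_keys), n_false, length(noncontact_keys)))
  .with_stream(seed, "coupling_table", {
    chosen <- c(sample(contact_keys, n_true),
                if (n_false > 0) sample(noncontact_keys, n_false))
    chosen <- sample(chosen)  # shuffle so contact status is rank-independent
    ij <- do.call(rbind, lapply(strsplit(chosen, " "), as.integer))
    n <- nrow(ij)
    strength <- sort(stats::rexp(n, rate = 1), decreasing = TRUE) +
      stats::runif(n, 0, 1e-6)
    coupling_table(data.frame(i = ij[, 1L], j = ij[, 2L],
                              strength = strength, stringsAsFactors = FALSE),
                   L = L, domain_tag = domain_tag)
  })
}

#' Conservation track with planted burial correlation
#'
#' Grades 1-9 (9 = most conserved) are generated as a rank blend of the
#' burial profile and uniform noise targeting a Spearman correlation of
#' about `rho`, then binned into nine equal-frequency grades.  Because
#' binning introduces ties, a track made with `rho = 1` scores slightly
#' below +1 under a rank correlation.
#'
#' @param burial a `burial_profile` (see [burial_profile()]) or a numeric
#'   vector of burial values.
#' @param rho target Spearman correlation in `[-1, 1]`.
#' @param seed RNG seed.
#' @return A `residue_track` of kind "conservation".
#' @export
make_conservation_track <- function(burial, rho, seed = 1L) {
  stopifnot(rho >= -1, rho <= 1)
  values <- if (inherits(burial, "burial_profile")) burial$burial else burial
  n <- length(values)
  .with_stream(seed, "conservation_track", {
    rb <- rank(values, ties.method = "average")
    rn <- rank(stats::runif(n), ties.method = "average")
    z <- rho * scale(rb)[, 1] + sqrt(1 - rho^2) * scale(rn)[, 1]
    grades <- as.integer(cut(rank(z, ties.method = "first"),
                             breaks = stats::quantile(seq_len(n),
                                                      probs = seq(0, 1, by = 1 / 9)),
                             include.lowest = TRUE, labels = FALSE))
    residue_track(grades, kind = "conservation",
                  source = sprintf("synthetic rho=%g seed=%d", rho, seed))
  })
}
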