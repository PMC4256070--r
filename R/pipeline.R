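#' @title End-to-end analysis pipelines
#'
#' @description
#' Two orchestrated runs cover the package's workflow: [run_dynamics()]
#' (structure -> elastic networks -> modes, correlations, hinges, edge
#' conformations, pore profiles) and [run_model_evaluation()] (structure +
#' coupling tables / residue tracks -> overlay fractions, cutoff scans,
#' conservation-burial scores, model ranking).  All outputs are flat TSV
#' tables plus PDB files; every table carries a header naming the producing
#' operation and the configuration hash, so reruns with an identical config
#' are byte-identical.
#' @name pipeline_cli
NULL

#' Default pipeline configuration
#'
#' @return named list of all tunable parameters with their defaults:
#' `gnm_cutoff` (10 A), `anm_cutoff` (15 A), `kt_over_gamma` (1 A^2),
#' `zero_tolerance` (NULL = relative 1e-8), `contribution_convention`
#' ("inverse"), `contact_cutoff` (12 A), `coupling_min_separation` (5),
#' `hinge_window` (5), `hinge_floor_quantile` (0.1), `edge_max_displacement`
#' (2 A), `burial_radius` (10 A), `pore_step` (1 A), `pore_refine` (FALSE),
#' `seed` (1).
#' @export
default_config <- function() {
  list(gnm_cutoff = 10, anm_cutoff = 15, kt_over_gamma = 1,
       zero_tolerance = NULL, contribution_convention = "inverse",
       contact_cutoff = 12, coupling_min_separation = 5L,
       hinge_window = 5L, hinge_floor_quantile = 0.1,
       edge_max_displacement = 2, burial_radius = 10,
       pore_step = 1, pore_refine = FALSE, seed = 1L)
}

.merge_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

.config_hash <- function(config) {
  txt <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small deterministic polynomial hash; avoids a digest dependency.
  # All arithmetic stays below 2^53 so doubles are exact.
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_table <- function(df, path, operation, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# operation: %s", operation), con)
  writeLines(sprintf("# config: %s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.echo_config <- function(config, out_dir, hash) {
  lines <- c(sprintf("# config hash: %s", hash),
             vapply(names(config), function(k)
               sprintf("%s\t%s", k,
                       paste(format(config[[k]], digits = 15), collapse = ",")),
               character(1)))
  writeLines(lines, file.path(out_dir, "config.tsv"))
}

#' Run the coarse-grained dynamics pipeline
#'
#' Builds GNM and ANM networks for a structure, decomposes them, and writes:
#' spectra, mean-square fluctuations, normalized cross-correlation matrices,
#' per-mode contributions, motion groups with hinge ranges, two-model PDB
#' files of the edge conformations of the slowest non-degenerate ANM mode,
#' and pore-radius profiles for the equilibrium and both edge conformations.
#'
#' @param structure a [coarse_structure()] or path to a PDB file.
#' @param out_dir output directory (created if missing).
#' @param config named list overriding [default_config()] entries.
#' @param n_slow_modes how many slow modes to tabulate in detail.
#' @return (invisibly) a list with the main in-memory results (`gnm`,
#'   `anm`, `motions`, `edge`, `pore`).
#' @export
run_dynamics <- function(structure, out_dir, config = NULL,
                         n_slow_modes = 10L) {
  cfg <- .merge_config(config)
  hash <- .config_hash(cfg)
  if (is.character(structure)) {
    if (!file.exists(structure)) stop("structure file not found: ", structure)
    structure <- read_calpha_structure(structure)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .echo_config(cfg, out_dir, hash)
  s <- structure
  res_lab <- sprintf("%s%d", s$residues$chain, s$residues$resno)

  message("stage: GNM")
  gnet <- build_kirchhoff(s, cfg$gnm_cutoff, cfg$kt_over_gamma)
  gdec <- decompose(gnet, cfg$zero_tolerance)
  nm <- min(n_slow_modes, n_modes(gdec))
  spec <- data.frame(mode = seq_len(nm),
                     eigenvalue = mode_eigenvalue(gdec, seq_len(nm)),
                     degenerate_group = degenerate_groups(gdec)[seq_len(nm)],
                     contribution_pct = mode_contribution(
                       gdec, seq_len(nm), cfg$contribution_convention))
  .write_table(spec, file.path(out_dir, "gnm_spectrum.tsv"), "decompose/GNM", hash)
  msf <- data.frame(residue = res_lab,
                    msf = mean_square_fluctuation(gdec, "all"))
  .write_table(msf, file.path(out_dir, "gnm_msf.tsv"), "gnm_correlation", hash)
  ncc <- normalized_cross_correlation(gnm_correlation(gdec, "all"))
  ncc_df <- as.data.frame(round(ncc, 6))
  names(ncc_df) <- res_lab
  .write_table(cbind(residue = res_lab, ncc_df),
               file.path(out_dir, "gnm_cross_correlation.tsv"),
               "normalized_cross_correlation", hash)

  message("stage: motions")
  motions <- motion_groups(gdec, s, window = cfg$hinge_window,
                           floor_quantile = cfg$hinge_floor_quantile)
  mrep <- do.call(rbind, lapply(motions, function(m) {
    if (nrow(m$hinge_ranges) == 0L)
      return(data.frame(motion = m$label,
                        gnm_modes = paste(m$gnm_modes, collapse = ","),
                        chain = NA, hinge_start = NA, hinge_end = NA))
    data.frame(motion = m$label,
               gnm_modes = paste(m$gnm_modes, collapse = ","),
               chain = m$hinge_ranges$chain,
               hinge_start = m$hinge_ranges$start,
               hinge_end = m$hinge_ranges$end)
  }))
  .write_table(mrep, file.path(out_dir, "motions.tsv"), "motion_groups", hash)

  message("stage: ANM")
  anet <- build_hessian(s, cfg$anm_cutoff, cfg$kt_over_gamma)
  adec <- decompose(anet, cfg$zero_tolerance)
  agr <- degenerate_groups(adec)
  gl <- split(seq_along(agr), agr)
  nondeg <- gl[[which(vapply(gl, length, integer(1)) == 1L)[1L]]][1L]
  gnm_shapes <- vapply(seq_len(nm), function(k) mode_shape(gdec, k),
                       numeric(n_residues(s)))
  anm_nm <- min(max(n_slow_modes, 15L), n_modes(adec))
  anm_shapes <- vapply(seq_len(anm_nm), function(k) mode_shape(adec, k),
                       numeric(n_residues(s)))
  assoc <- associate_modes(gnm_shapes, anm_shapes)
  .write_table(assoc, file.path(out_dir, "gnm_anm_association.tsv"),
               "associate_modes", hash)

  message("stage: edge conformations (ANM mode ", nondeg, ")")
  edge <- edge_conformations(s, adec, nondeg,
                             max_displacement = cfg$edge_max_displacement)
  write_pdb(list(edge$plus, edge$minus),
            file.path(out_dir, "edge_conformations.pdb"))

  message("stage: pore profiles")
  axis <- symmetry_axis(s)
  origin <- colMeans(coords(s))
  zc <- drop(sweep(coords(s), 2, origin) %*% axis)
  zr <- range(zc) + c(-5, 5)    # one z grid for all three conformations
  p0 <- pore_radius_profile(s, axis = axis, origin = origin, z_range = zr,
                            step = cfg$pore_step, refine = cfg$pore_refine)
  pp <- pore_radius_profile(edge$plus, axis = axis, origin = origin,
                            z_range = zr, step = cfg$pore_step,
                            refine = cfg$pore_refine)
  pm <- pore_radius_profile(edge$minus, axis = axis, origin = origin,
                            z_range = zr, step = cfg$pore_step,
                            refine = cfg$pore_refine)
  prof <- data.frame(z = p0$samples$z,
                     radius_equilibrium = round(p0$samples$radius, 4),
                     radius_edge_plus = round(pp$samples$radius, 4),
                     radius_edge_minus = round(pm$samples$radius, 4))
  .write_table(prof, file.path(out_dir, "pore_profiles.tsv"),
               "pore_radius_profile", hash)

  invisible(list(gnm = gdec, anm = adec, motions = motions, edge = edge,
                 pore = list(equilibrium = p0, plus = pp, minus = pm),
                 config = cfg))
}

#' Run the model-evaluation pipeline
#'
#' Overlays coupling tables on one or more structural models (top-2L/3
#' selection, contact fraction at the configured cutoff, cutoff scan) and
#' scores conservation/hydrophobicity tracks against residue burial.
#'
#' @param structures named list of [coarse_structure()] objects (or PDB
#'   paths); the first is the reference model.
#' @param out_dir output directory.
#' @param coupling_tables named list of `coupling_table` objects (or TSV
#'   paths, in which case `coupling_L` must give L per table).
#' @param tracks optional named list of `residue_track` objects aligned to
#'   the reference structure's residues.
#' @param config named list overriding [default_config()].
#' @param coupling_L lengths for tables given as file paths.
#' @param cutoffs cutoffs for the scan (A).
#' @return (invisibly) list with `overlays`, `scan`, `ranking`, `scores`.
#' @export
run_model_evaluation <- function(structures, out_dir, coupling_tables = NULL,
                                 tracks = NULL, config = NULL,
                                 coupling_L = NULL, cutoffs = 10:15) {
  cfg <- .merge_config(config)
  hash <- .config_hash(cfg)
  if (inherits(structures, "coarse_structure")) structures <- list(model = structures)
  structures <- lapply(structures, function(s)
    if (is.character(s)) read_calpha_structure(s) else s)
  if (is.null(names(structures)))
    names(structures) <- paste0("model", seq_along(structures))
  if ((is.null(coupling_tables) || length(coupling_tables) == 0L) &&
      is.null(tracks))
    stop("need at least one coupling table or residue track")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .echo_config(cfg, out_dir, hash)
  ref <- structures[[1L]]

  overlays <- list(); scan <- NULL; ranking <- NULL
  if (!is.null(coupling_tables)) {
    table_names <- names(coupling_tables) %||%
      paste0("table", seq_along(coupling_tables))
    coupling_tables <- lapply(seq_along(coupling_tables), function(i) {
      t <- coupling_tables[[i]]
      if (is.character(t)) {
        if (is.null(coupling_L)) stop("coupling_L needed for file-path tables")
        t <- read_coupling_table(t, L = coupling_L[[i]])
      }
      t
    })
    names(coupling_tables) <- table_names
    maps <- lapply(structures, compute_contact_map, cutoff = cfg$contact_cutoff,
                   min_sequence_separation = cfg$coupling_min_separation)
    rows <- list(); scans <- list()
    for (tn in names(coupling_tables)) {
      sel <- select_top(coupling_tables[[tn]])
      ovs <- lapply(maps, function(m) overlay_contacts(sel, m))
      overlays[[tn]] <- ovs
      for (mn in names(ovs)) {
        o <- ovs[[mn]]
        rows[[length(rows) + 1L]] <- data.frame(
          table = tn, model = mn, selected = o$selected,
          in_contact = o$in_contact, fraction = o$fraction,
          fraction_intra_only = o$fraction_intra_only,
          unmapped = o$n_unmapped)
      }
      sc <- cutoff_scan(sel, ref, cutoffs,
                        min_sequence_separation = cfg$coupling_min_separation)
      sc$table <- tn
      scans[[tn]] <- sc
      if (length(maps) >= 2L)
        ranking <- compare_models(sel, maps)
    }
    .write_table(do.call(rbind, rows), file.path(out_dir, "overlay.tsv"),
                 "overlay_contacts", hash)
    scan <- do.call(rbind, scans)
    .write_table(scan, file.path(out_dir, "cutoff_scan.tsv"), "cutoff_scan", hash)
    if (!is.null(ranking))
      .write_table(ranking, file.path(out_dir, "model_ranking.tsv"),
                   "compare_models", hash)
  }

  scores <- NULL
  if (!is.null(tracks)) {
    burial <- burial_profile(ref, cfg$burial_radius)
    scores <- data.frame(
      track = names(tracks),
      kind = vapply(tracks, `[[`, character(1), "kind"),
      agreement = vapply(tracks, pattern_agreement_score,
                         numeric(1), burial = burial))
    .write_table(scores, file.path(out_dir, "track_scores.tsv"),
                 "pattern_agreement_score", hash)
  }
  invisible(list(overlays = overlays, scan = scan, ranking = ranking,
                 scores = scores, config = cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
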