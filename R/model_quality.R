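#' @title Conservation/hydrophobicity versus burial model scoring
#'
#' @description
#' Model quality assessment in the ConQuass spirit: protein cores are
#' typically conserved while residues facing lipid or water are variable, so
#' a good model buries its conserved residues.  At the Calpha level burial
#' is proxied by the neighbour count within a radius, and agreement with a
#' per-residue track (ConSurf-style conservation grades 1-9, or a
#' hydrophobicity scale) is measured by a Spearman rank correlation.  This
#' is a rank-correlation surrogate, not a numerical reimplementation of the
#' published ConQuass score.
#' @name model_quality
NULL

#' Construct a per-residue track
#'
#' @param values numeric vector, one value per scored residue (conservation
#'   grades must be integers in 1..9; hydrophobicity values are free scale
#'   units).
#' @param kind "conservation" or "hydrophobicity".
#' @param source free-text provenance tag.
#' @return A `residue_track`.
#' @export
residue_track <- function(values, kind = c("conservation", "hydrophobicity"),
                          source = "") {
  kind <- match.arg(kind)
  if (kind == "conservation") {
    if (any(values != as.integer(values) | values < 1 | values > 9))
      stop("conservation grades must be integers in 1..9")
    values <- as.integer(values)
  }
  structure(list(kind = kind, values = values, source = source),
            class = "residue_track")
}

#' Read a per-residue track from a two-column TSV (residue, value)
#' @param path file path.
#' @param kind "conservation" or "hydrophobicity".
#' @return A `residue_track`; residue numbers are kept as names.
#' @export
read_residue_track <- function(path, kind = "conservation") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("resno", "value"))
  tr <- residue_track(df$value, kind = kind, source = path)
  names(tr$values) <- df$resno
  tr
}

#' Calpha neighbour-count burial profile
#'
#' For each residue, the number of other Calpha atoms within `radius`.
#' A crude but serviceable burial proxy at the Calpha level: core residues
#' have many neighbours, surface residues few.
#'
#' @param s a [coarse_structure()].
#' @param radius neighbour radius in Angstrom (default 10).
#' @return A `burial_profile`: per-residue counts plus the radius.
#' @export
burial_profile <- function(s, radius = 10) {
  stopifnot(radius > 0)
  d <- as.matrix(stats::dist(coords(s)))
  counts <- as.integer(rowSums(d <= radius) - 1L)
  structure(list(burial = counts, radius = radius,
                 residues = s$residues[, c("chain", "resno", "icode")]),
            class = "burial_profile")
}

#' Agreement between a residue track and burial (ConQuass-style surrogate)
#'
#' Spearman rank correlation between track values and burial counts.
#' For conservation, higher grades buried deeper give a positive score
#' (+1 = perfect adherence to the conserved-core pattern).  Being
#' rank-based, the score is invariant under monotone transforms of either
#' input.
#'
#' @param track a `residue_track` (or numeric vector).
#' @param burial a `burial_profile` (or numeric vector) aligned to the same
#'   residues.
#' @return scalar in `[-1, 1]`, or NA (with a warning) when either input is
#'   constant.
#' @export
pattern_agreement_score <- function(track, burial) {
  tv <- if (inherits(track, "residue_track")) track$values else track
  bv <- if (inherits(burial, "burial_profile")) burial$burial else burial
  if (length(tv) != length(bv))
    stop(sprintf("track (%d) and burial (%d) lengths differ", length(tv), length(bv)))
  if (stats::sd(tv) == 0 || stats::sd(bv) == 0) {
    warning("constant track or burial: agreement score undefined")
    return(NA_real_)
  }
  stats::cor(tv, bv, method = "spearman")
}

#' Rank decoy structures by conservation-burial agreement
#'
#' Reproduces the decoy-selection step of loop refinement: each decoy is
#' scored by [pattern_agreement_score()] against the same track, and decoys
#' are sorted best-first.  Ties keep input order.
#'
#' @param decoys list of [coarse_structure()] objects over an identical
#'   residue set.
#' @param track a `residue_track` aligned to that residue set.
#' @param radius burial radius in Angstrom.
#' @return data.frame (`decoy`, `score`) sorted by descending score, with
#'   attribute `"order"` giving the input indices best-first.
#' @export
rank_decoys <- function(decoys, track, radius = 10) {
  if (length(decoys) < 1L) stop("need at least one decoy")
  ref <- paste(decoys[[1L]]$residues$chain, decoys[[1L]]$residues$resno)
  for (k in seq_along(decoys)) {
    kk <- paste(decoys[[k]]$residues$chain, decoys[[k]]$residues$resno)
    if (!identical(ref, kk))
      stop("decoy ", k, " has a different residue set than decoy 1")
  }
  scores <- vapply(decoys, function(d)
    pattern_agreement_score(track, burial_profile(d, radius)), numeric(1))
  ord <- order(-scores, seq_along(scores))
  nm <- if (!is.null(names(decoys))) names(decoys) else
    paste0("decoy", seq_along(decoys))
  out <- data.frame(decoy = nm[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  attr(out, "order") <- ord
  out
}

#' Entropy-based conservation grades from an MSA (ConSurf stand-in)
#'
#' When only an alignment is available, per-column normalized Shannon
#' entropy (log base 20, gaps excluded from the distribution) is mapped
#' linearly onto grades 9 (invariant) down to 1 (maximally variable).
#' Columns that are mostly gaps are flagged.  This is a crude fallback, not
#' the ConSurf Bayesian rate estimator.
#'
#' @param msa named character vector of equal-length aligned sequences, or
#'   path to an aligned FASTA file.
#' @param gap_flag_fraction columns with at least this gap fraction are
#'   flagged (attribute `"gap_majority"`).
#' @return A `residue_track` of kind "conservation", one grade per column.
#' @export
entropy_conservation_fallback <- function(msa, gap_flag_fraction = 0.5) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- .read_fasta(msa)
  if (length(msa) < 2L) stop("need at least two aligned sequences")
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  ncol_ <- ncol(mat)
  grades <- integer(ncol_)
  gap_major <- logical(ncol_)
  for (cidx in seq_len(ncol_)) {
    col <- mat[, cidx]
    gaps <- col %in% c("-", ".", "X")
    gap_major[cidx] <- mean(gaps) >= gap_flag_fraction
    col <- col[!gaps]
    if (length(col) == 0L) { grades[cidx] <- 1L; next }
    p <- table(col) / length(col)
    h <- -sum(p * log(p)) / log(20)          # normalized to [0, 1]
    grades[cidx] <- as.integer(pmax(1, pmin(9, round(9 - 8 * h))))
  }
  tr <- residue_track(grades, kind = "conservation", source = "entropy fallback")
  attr(tr, "gap_majority") <- gap_major
  tr
}

.read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA headers in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k)
    paste(lines[(hdr[k] + 1L):ends[k]], collapse = ""), character(1))
  names(seqs) <- sub("^>\\s*", "", lines[hdr])
  seqs
}

#' Read a hydrophobicity scale (residue name, value) from TSV
#'
#' The scale itself is user-supplied (e.g. the Kessel/Ben-Tal
#' water-to-membrane transfer free energies); none is bundled.
#'
#' @param path file path, two tab-separated columns: three-letter residue
#'   name, numeric value.
#' @return named numeric vector keyed by residue name.
#' @export
read_hydrophobicity_scale <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("resname", "value"))
  stats::setNames(df$value, toupper(df$resname))
}

#' Hydrophobicity track for a structure from a residue-name scale
#' @param s a [coarse_structure()].
#' @param scale named numeric vector keyed by three-letter residue name.
#' @return A `residue_track` of kind "hydrophobicity"; residues missing
#'   from the scale get NA.
#' @export
hydrophobicity_track <- function(s, scale) {
  residue_track(unname(scale[toupper(s$residues$resname)]),
                kind = "hydrophobicity", source = "scale lookup")
}

#' Lipid-facing agreement of hydrophobicity in an annotated TM region
#'
#' Within the TM annotation, radial distance from the pore axis classifies
#' residues as lipid-facing (far) versus core/pore-facing (near); a
#' membrane protein should put hydrophobic residues outside.  Reported as
#' the Spearman correlation between hydrophobicity and radial distance.
#'
#' @param s a [coarse_structure()] with a "TM" annotation.
#' @param track hydrophobicity `residue_track` aligned to all residues of
#'   `s`.
#' @param axis pore axis (default: [symmetry_axis()]).
#' @return scalar in `[-1, 1]` (positive = hydrophobics face the lipid).
#' @export
tm_hydrophobicity_agreement <- function(s, track, axis = NULL) {
  if (is.null(axis)) axis <- symmetry_axis(s)
  axis <- axis / sqrt(sum(axis^2))
  mask <- domain_mask(s, "TM")
  X <- sweep(coords(s), 2, colMeans(coords(s)))
  radial <- sqrt(rowSums((X - outer(drop(X %*% axis), axis))^2))
  tv <- if (inherits(track, "residue_track")) track$values else track
  ok <- mask & !is.na(tv)
  if (stats::sd(tv[ok]) == 0) {
    warning("constant hydrophobicity in TM region")
    return(NA_real_)
  }
  stats::cor(tv[ok], radial[ok], method = "spearman")
}
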