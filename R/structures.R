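#' @title Calpha-level coarse-grained structures
#'
#' @description
#' `coarse_structure` is the central container of the package: an ordered set
#' of residues, each identified by `(chain, resno, icode)` and carrying a
#' single Calpha coordinate, plus an optional all-atom side store (used only
#' for pore profiling) and optional named domain annotations.
#'
#' @param residues data.frame with columns `chain`, `resno`, `icode`,
#'   `resname`, `x`, `y`, `z` (one row per residue, Calpha coordinates in
#'   Angstrom).
#' @param atoms optional data.frame with columns `chain`, `resno`, `icode`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`; all atoms of the source
#'   model, retained for pore profiling.
#' @param annotations optional data.frame with columns `label`, `chain`,
#'   `start`, `end` mapping domain labels (e.g. "TM", "VSD") to residue
#'   number ranges per chain.
#' @return An object of class `coarse_structure`.
#' @export
coarse_structure <- function(residues, atoms = NULL, annotations = NULL) {
  stopifnot(is.data.frame(residues))
  needed <- c("chain", "resno", "x", "y", "z")
  if (!all(needed %in% names(residues)))
    stop("residues must have columns: ", paste(needed, collapse = ", "))
  if (is.null(residues$icode)) residues$icode <- ""
  if (is.null(residues$resname)) residues$resname <- "ALA"
  residues$chain <- as.character(residues$chain)
  residues$resno <- as.integer(residues$resno)
  if (nrow(residues) < 1L) stop("a coarse_structure needs at least one residue")
  if (any(!is.finite(as.matrix(residues[, c("x", "y", "z")]))))
    stop("non-finite Calpha coordinates")
  key <- paste(residues$chain, residues$resno, residues$icode)
  if (anyDuplicated(key)) {
    stop("duplicate residue identities: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (is.null(annotations)) {
    annotations <- data.frame(label = character(), chain = character(),
                              start = integer(), end = integer(),
                              stringsAsFactors = FALSE)
  }
  s <- structure(list(residues = residues, atoms = atoms,
                      annotations = annotations),
                 class = "coarse_structure")
  .check_annotations(s)
  s
}

.check_annotations <- function(s) {
  a <- s$annotations
  if (nrow(a) == 0L) return(invisible(TRUE))
  for (k in seq_len(nrow(a))) {
    in_chain <- s$residues$chain == a$chain[k]
    hit <- in_chain & s$residues$resno >= a$start[k] & s$residues$resno <= a$end[k]
    if (!any(hit))
      stop(sprintf("annotation '%s' range %d-%d references no residue of chain %s",
                   a$label[k], a$start[k], a$end[k], a$chain[k]))
  }
  invisible(TRUE)
}

#' @export
print.coarse_structure <- function(x, ...) {
  ch <- table(x$residues$chain)
  cat(sprintf("coarse_structure: %d residues, %d chain(s) [%s]\n",
              nrow(x$residues), length(ch),
              paste(sprintf("%s:%d", names(ch), as.integer(ch)), collapse = " ")))
  if (!is.null(x$atoms)) cat(sprintf("  atom side store: %d atoms\n", nrow(x$atoms)))
  if (nrow(x$annotations) > 0L)
    cat("  annotations:", paste(unique(x$annotations$label), collapse = ", "), "\n")
  invisible(x)
}

#' Number of residues of a coarse structure
#' @param s a `coarse_structure`.
#' @return integer residue count.
#' @export
n_residues <- function(s) nrow(s$residues)

#' Calpha coordinate matrix
#' @param s a `coarse_structure`.
#' @return numeric N x 3 matrix of Calpha positions (Angstrom).
#' @export
coords <- function(s) {
  m <- as.matrix(s$residues[, c("x", "y", "z")])
  dimnames(m) <- list(paste0(s$residues$chain, s$residues$resno), c("x", "y", "z"))
  m
}

# ---------------------------------------------------------------------------
# PDB input / output
# ---------------------------------------------------------------------------

.pdb_lines <- function(pdb_source) {
  if (length(pdb_source) == 1L && !grepl("\n", pdb_source) &&
      file.exists(pdb_source)) {
    return(readLines(pdb_source, warn = FALSE))
  }
  unlist(strsplit(pdb_source, "\n", fixed = TRUE), use.names = FALSE)
}

.parse_atom_records <- function(lines) {
  sel <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  rec <- lines[sel]
  if (length(rec) == 0L) return(NULL)
  rec <- formatC(rec, width = 80, flag = "-")
  data.frame(
    atom = trimws(substr(rec, 13, 16)),
    alt = substr(rec, 17, 17),
    resname = trimws(substr(rec, 18, 20)),
    chain = substr(rec, 22, 22),
    resno = as.integer(substr(rec, 23, 26)),
    icode = trimws(substr(rec, 27, 27)),
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(rec, 55, 60))),
    element = trimws(substr(rec, 77, 78)),
    stringsAsFactors = FALSE
  )
}

#' Read a Calpha-level structure from PDB text
#'
#' Parses standard `ATOM` records (fixed-width PDB format) of one `MODEL` of
#' a PDB file and coarse-grains the structure to one Calpha node per residue.
#' Residue identity is `(chain, resno, icode)`.  Alternate locations are
#' resolved by keeping the highest-occupancy record (ties: first encountered).
#' All atoms of the model, including side chains when present, are retained in
#' an atom side store so that pore profiles can use full van der Waals surfaces.
#'
#' @param pdb_source path to a PDB file, or a character scalar/vector holding
#'   PDB-formatted text.
#' @param model_index 1-based index of the `MODEL` block to read; files
#'   without `MODEL` records count as a single model.
#' @return A [coarse_structure()].
#' @export
read_calpha_structure <- function(pdb_source, model_index = 1L) {
  lines <- .pdb_lines(pdb_source)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    block <- lines
    if (model_index != 1L)
      stop(sprintf("model %d requested but the file has no MODEL records", model_index))
  } else {
    ends <- grep("^ENDMDL", lines)
    if (model_index > length(starts))
      stop(sprintf("model %d requested but only %d model(s) present",
                   model_index, length(starts)))
    to <- if (model_index <= length(ends)) ends[model_index] else length(lines)
    block <- lines[starts[model_index]:to]
  }
  at <- .parse_atom_records(block)
  if (is.null(at)) stop(sprintf("no ATOM records in model %d", model_index))
  # resolve altLocs: keep highest occupancy, first on ties
  at$occ[is.na(at$occ)] <- 1
  akey <- paste(at$chain, at$resno, at$icode, at$atom)
  if (anyDuplicated(akey)) {
    # genuine duplicates (same altLoc, including blank) are an error;
    # distinct altLocs resolve to the highest occupancy (ties: first wins)
    alt_key <- paste(akey, at$alt)
    if (anyDuplicated(alt_key)) {
      bad <- unique(akey[duplicated(alt_key)])
      stop("duplicate CA records for residue(s): ",
           paste(bad, collapse = "; "))
    }
    orig <- seq_len(nrow(at))
    ord <- order(akey, -at$occ, orig)
    keep_orig <- orig[ord][!duplicated(akey[ord])]
    at <- at[sort(keep_orig), , drop = FALSE]
  }
  ca <- at[at$atom == "CA", , drop = FALSE]
  if (nrow(ca) == 0L)
    stop(sprintf("no CA atoms in model %d", model_index))
  key <- paste(ca$chain, ca$resno, ca$icode)
  if (anyDuplicated(key))
    stop("duplicate CA records for residue(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  res <- data.frame(chain = ca$chain, resno = ca$resno, icode = ca$icode,
                    resname = ca$resname, x = ca$x, y = ca$y, z = ca$z,
                    stringsAsFactors = FALSE)
  atoms <- at[, c("chain", "resno", "icode", "resname", "atom", "element",
                  "x", "y", "z")]
  if (all(atoms$atom == "CA")) atoms <- NULL  # pure-Calpha input: no side store
  coarse_structure(res, atoms = atoms)
}

.format_atom_line <- function(serial, atom, resname, chain, resno, icode,
                              x, y, z, element) {
  name <- if (nchar(atom) < 4L) sprintf(" %-3s", atom) else substr(atom, 1, 4)
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name, resname, chain, resno, icode, x, y, z,
          1, 0, element)
}

#' Write one or more coarse structures as PDB text
#'
#' Calpha nodes are written as `CA` `ATOM` records; when an atom side store is
#' present it is written instead (it includes the Calphas).  A list of
#' structures is written as consecutive `MODEL`/`ENDMDL` blocks, which is how
#' mode edge conformations are exported.
#'
#' @param s a `coarse_structure` or a list of them.
#' @param path output file path; omit to return the lines invisibly only.
#' @return character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(s, path = NULL) {
  models <- if (inherits(s, "coarse_structure")) list(s) else s
  multi <- length(models) > 1L
  out <- character()
  for (m in seq_along(models)) {
    sm <- models[[m]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    if (!is.null(sm$atoms)) {
      a <- sm$atoms
      lines <- vapply(seq_len(nrow(a)), function(i) {
        ic <- if (is.na(a$icode[i]) || a$icode[i] == "") " " else a$icode[i]
        .format_atom_line(i, a$atom[i], a$resname[i], a$chain[i], a$resno[i],
                          ic, a$x[i], a$y[i], a$z[i], a$element[i])
      }, character(1))
    } else {
      r <- sm$residues
      lines <- vapply(seq_len(nrow(r)), function(i) {
        ic <- if (is.na(r$icode[i]) || r$icode[i] == "") " " else r$icode[i]
        .format_atom_line(i, "CA", r$resname[i], r$chain[i], r$resno[i],
                          ic, r$x[i], r$y[i], r$z[i], "C")
      }, character(1))
    }
    out <- c(out, lines, if (multi) "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

# ---------------------------------------------------------------------------
# selectors, distances, contact maps
# ---------------------------------------------------------------------------

.resolve_selector <- function(s, sel) {
  if (is.list(sel)) sel <- unlist(sel)
  if (length(sel) < 2L)
    stop("a residue selector is (chain, residue number)")
  chain <- as.character(sel[[1L]])
  resno <- as.integer(sel[[2L]])
  icode <- if (length(sel) >= 3L) as.character(sel[[3L]]) else ""
  idx <- which(s$residues$chain == chain & s$residues$resno == resno &
               s$residues$icode == icode)
  if (length(idx) != 1L)
    stop(sprintf("selector (%s, %d%s) resolves to %d residues",
                 chain, resno, icode, length(idx)))
  idx
}

#' Calpha-Calpha distance between two residues
#'
#' @param s a `coarse_structure`.
#' @param a,b residue selectors: `c(chain, residue_number)` (optionally a
#'   third element, the insertion code).
#' @return Euclidean distance in Angstrom.
#' @export
ca_distance <- function(s, a, b) {
  ia <- .resolve_selector(s, a)
  ib <- .resolve_selector(s, b)
  sqrt(sum((coords(s)[ia, ] - coords(s)[ib, ])^2))
}

#' Residue-residue contact map at a Calpha distance cutoff
#'
#' All unordered residue pairs whose Calpha distance is `<= cutoff` are
#' recorded.  Same-chain pairs must additionally satisfy
#' `|resno_i - resno_j| >= min_sequence_separation`; inter-chain pairs are
#' always eligible.  The boundary convention is inclusive (`<=`), applied
#' uniformly across the package.
#'
#' @param s a `coarse_structure`.
#' @param cutoff contact distance cutoff in Angstrom.
#' @param min_sequence_separation minimum `|i - j|` in residue numbering for
#'   same-chain pairs; 1 keeps all non-self pairs.
#' @return An object of class `contact_map`: a list with `pairs` (data.frame
#'   of residue indices `i < j` and `relation` intra/inter), `cutoff`,
#'   `min_sep`, intra/inter counts and the residue table of the source
#'   structure.
#' @export
compute_contact_map <- function(s, cutoff, min_sequence_separation = 1L) {
  stopifnot(cutoff > 0)
  X <- coords(s)
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  within <- d <= cutoff
  within[lower.tri(within, diag = TRUE)] <- FALSE
  idx <- which(within, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    i <- idx[, 1L]; j <- idx[, 2L]
    same <- s$residues$chain[i] == s$residues$chain[j]
    sep_ok <- !same | abs(s$residues$resno[i] - s$residues$resno[j]) >=
      min_sequence_separation
    i <- i[sep_ok]; j <- j[sep_ok]; same <- same[sep_ok]
  } else {
    i <- j <- integer(); same <- logical()
  }
  pairs <- data.frame(i = i, j = j,
                      relation = ifelse(same, "intra", "inter"),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, cutoff = cutoff,
                 min_sep = min_sequence_separation,
                 n_intra = sum(same), n_inter = sum(!same), n_res = n,
                 residues = s$residues[, c("chain", "resno", "icode")]),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d pairs (%d intra, %d inter) at cutoff %.1f A, min separation %d\n",
              nrow(x$pairs), x$n_intra, x$n_inter, x$cutoff, x$min_sep))
  invisible(x)
}

# ---------------------------------------------------------------------------
# annotations and derived structures
# ---------------------------------------------------------------------------

#' Add a domain annotation
#' @param s a `coarse_structure`.
#' @param label domain label, e.g. "TM", "VSD", "cytosolic".
#' @param chain chain identifier(s); recycled against `start`/`end`.
#' @param start,end residue-number range(s), inclusive.
#' @return the annotated structure.
#' @export
annotate_domain <- function(s, label, chain, start, end) {
  add <- data.frame(label = label, chain = chain,
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  s$annotations <- rbind(s$annotations, add)
  .check_annotations(s)
  s
}

#' Logical mask of the residues belonging to an annotated domain
#' @param s a `coarse_structure`.
#' @param label annotation label.
#' @param chain optional chain restriction.
#' @return logical vector over residues of `s`.
#' @export
domain_mask <- function(s, label, chain = NULL) {
  a <- s$annotations[s$annotations$label == label, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("no annotation with label '", label, "'")
  mask <- rep(FALSE, n_residues(s))
  for (k in seq_len(nrow(a))) {
    mask <- mask | (s$residues$chain == a$chain[k] &
                    s$residues$resno >= a$start[k] &
                    s$residues$resno <= a$end[k])
  }
  mask
}

#' Read domain annotations from a flat key-value file
#'
#' Format: one annotation per line, `label<TAB>chain<TAB>ranges`, where
#' `ranges` is a comma-separated list of `start-end` residue ranges.  Lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return data.frame with columns `label`, `chain`, `start`, `end`.
#' @export
read_annotation_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1L]]
    if (length(f) != 3L) stop("malformed annotation line: ", ln)
    for (rg in strsplit(f[3L], ",")[[1L]]) {
      se <- as.integer(strsplit(trimws(rg), "-")[[1L]])
      if (length(se) != 2L || any(is.na(se)))
        stop("malformed range '", rg, "' in line: ", ln)
      out[[length(out) + 1L]] <- data.frame(label = f[1L], chain = f[2L],
                                            start = se[1L], end = se[2L],
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Delete residue ranges (e.g. a whole domain) from a structure
#'
#' @param s a `coarse_structure`.
#' @param ranges either an annotation label present in `s`, or a data.frame
#'   with columns `chain`, `start`, `end`.
#' @return the reduced structure; surviving residues keep their order,
#'   identity and coordinates.  Annotations are retained where they still
#'   reference at least one surviving residue.
#' @export
delete_domain <- function(s, ranges) {
  if (is.character(ranges) && length(ranges) == 1L) {
    mask <- domain_mask(s, ranges)
  } else {
    if (!is.data.frame(ranges) || nrow(ranges) == 0L)
      stop("ranges must be a non-empty data.frame (chain, start, end) or an annotation label")
    mask <- rep(FALSE, n_residues(s))
    for (k in seq_len(nrow(ranges))) {
      mask <- mask | (s$residues$chain == ranges$chain[k] &
                      s$residues$resno >= ranges$start[k] &
                      s$residues$resno <= ranges$end[k])
    }
  }
  keep <- !mask
  if (!any(keep)) stop("deletion would remove every residue")
  dropped_chains <- setdiff(unique(s$residues$chain),
                            unique(s$residues$chain[keep]))
  if (length(dropped_chains) > 0L)
    warning("deletion empties chain(s): ", paste(dropped_chains, collapse = ", "))
  res <- s$residues[keep, , drop = FALSE]
  rownames(res) <- NULL
  atoms <- s$atoms
  if (!is.null(atoms)) {
    akey <- paste(atoms$chain, atoms$resno, atoms$icode)
    rkey <- paste(res$chain, res$resno, res$icode)
    atoms <- atoms[akey %in% rkey, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  ann <- s$annotations
  if (nrow(ann) > 0L) {
    ok <- vapply(seq_len(nrow(ann)), function(k) {
      any(res$chain == ann$chain[k] & res$resno >= ann$start[k] &
          res$resno <= ann$end[k])
    }, logical(1))
    ann <- ann[ok, , drop = FALSE]
    rownames(ann) <- NULL
  }
  coarse_structure(res, atoms = atoms, annotations = ann)
}

.rotation_about <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Assemble a Cn-symmetric homo-oligomer from a single-chain structure
#'
#' Copies of the monomer are related by rotations of `360 / symmetry_order`
#' degrees about `axis` (through the origin).  Output chains are labelled
#' `A`, `B`, `C`, ... in rotation order.
#'
#' @param monomer a single-chain `coarse_structure`.
#' @param symmetry_order number of chains (>= 2); 4 builds the usual channel
#'   homotetramer.
#' @param axis 3-vector, the symmetry axis (default z).
#' @return a `coarse_structure` of `symmetry_order` chains.  Annotations of
#'   the monomer are replicated per chain.
#' @export
assemble_homotetramer <- function(monomer, symmetry_order = 4L,
                                  axis = c(0, 0, 1)) {
  if (length(unique(monomer$residues$chain)) != 1L)
    stop("assemble_homotetramer needs a single-chain monomer")
  if (symmetry_order < 2L) stop("symmetry_order must be >= 2")
  out <- list(); ann <- list(); atoms <- list()
  for (k in seq_len(symmetry_order)) {
    R <- .rotation_about(axis, 360 * (k - 1L) / symmetry_order)
    r <- monomer$residues
    xyz <- as.matrix(r[, c("x", "y", "z")]) %*% t(R)
    r$x <- xyz[, 1L]; r$y <- xyz[, 2L]; r$z <- xyz[, 3L]
    r$chain <- LETTERS[k]
    out[[k]] <- r
    if (!is.null(monomer$atoms)) {
      a <- monomer$atoms
      axyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
      a$x <- axyz[, 1L]; a$y <- axyz[, 2L]; a$z <- axyz[, 3L]
      a$chain <- LETTERS[k]
      atoms[[k]] <- a
    }
    if (nrow(monomer$annotations) > 0L) {
      ak <- monomer$annotations
      ak$chain <- LETTERS[k]
      ann[[k]] <- ak
    }
  }
  coarse_structure(do.call(rbind, out),
                   atoms = if (length(atoms)) do.call(rbind, atoms) else NULL,
                   annotations = if (length(ann)) do.call(rbind, ann) else NULL)
}

#' Principal symmetry axis of an assembly
#'
#' For a Cn-symmetric assembly the gyration tensor has two (nearly) equal
#' eigenvalues; the symmetry axis is the eigenvector of the remaining,
#' distinct eigenvalue.  Used as the default membrane normal.
#'
#' @param s a `coarse_structure`.
#' @return unit 3-vector (oriented with a non-negative z component).
#' @export
symmetry_axis <- function(s) {
  X <- scale(coords(s), scale = FALSE)
  G <- crossprod(X) / nrow(X)
  e <- eigen(G, symmetric = TRUE)
  # pick the eigenvalue farthest from the mean of the other two
  sep <- vapply(1:3, function(k) abs(e$values[k] - mean(e$values[-k])),
                numeric(1))
  a <- e$vectors[, which.max(sep)]
  if (a[3] < 0) a <- -a
  a / sqrt(sum(a^2))
}
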