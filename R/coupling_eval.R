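#' @title Evolutionary-coupling contact overlay
#'
#' @description
#' Evaluates a structural model against a ranked list of evolutionary
#' couplings (ECs), in the EVcouplings/plmDCA spirit: the strongest 2L/3
#' couplings (L = domain sequence length) are overlaid on the model's
#' Calpha contact map, and the fraction found in contact measures model
#' quality.  Inter-chain realizations matter for an oligomer: a coupling in
#' query numbering counts as "in contact" if any chain-pair realization is.
#' @name coupling_eval
NULL

#' Construct a coupling table
#'
#' @param entries data.frame with columns `i`, `j` (residue numbers, query
#'   numbering) and `strength`.
#' @param L alignment/query length of the domain the couplings cover; drives
#'   top-2L/3 selection.  The TM and cytosolic domains of the cone channel
#'   use L = 240 and L = 197 respectively.
#' @param domain_tag "TM", "cytosolic" or "other".
#' @return An object of class `coupling_table`.
#' @export
coupling_table <- function(entries, L, domain_tag = "other") {
  stopifnot(is.data.frame(entries),
            all(c("i", "j", "strength") %in% names(entries)))
  if (any(entries$i == entries$j)) stop("self-couplings (i == j) not allowed")
  if (any(!is.finite(entries$strength))) stop("non-finite coupling strengths")
  if (L <= 0) stop("L must be positive")
  a <- pmin(entries$i, entries$j); b <- pmax(entries$i, entries$j)
  entries$i <- as.integer(a); entries$j <- as.integer(b)
  if (anyDuplicated(paste(entries$i, entries$j)))
    stop("duplicate unordered pairs in coupling table")
  rownames(entries) <- NULL
  structure(list(entries = entries, L = as.integer(L),
                 domain_tag = domain_tag),
            class = "coupling_table")
}

#' @export
print.coupling_table <- function(x, ...) {
  cat(sprintf("coupling_table (%s): %d pairs, L = %d\n",
              x$domain_tag, nrow(x$entries), x$L))
  invisible(x)
}

#' Read a coupling table from a tab-separated file
#'
#' Expects three columns (residue i, residue j, coupling strength), with an
#' optional header line.  Duplicate unordered pairs are collapsed keeping
#' the maximum strength, with a warning.
#'
#' @param tsv_source file path or character vector of lines.
#' @param L domain length (see [coupling_table()]).
#' @param numbering_offset integer added to both residue columns to map
#'   alignment numbering onto model numbering.
#' @param domain_tag "TM", "cytosolic" or "other".
#' @return A `coupling_table`.
#' @export
read_coupling_table <- function(tsv_source, L, numbering_offset = 0L,
                                domain_tag = "other") {
  lines <- if (length(tsv_source) == 1L && !grepl("\n", tsv_source) &&
               file.exists(tsv_source)) readLines(tsv_source, warn = FALSE)
  else unlist(strsplit(tsv_source, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty coupling table")
  first <- strsplit(lines[1L], "\t")[[1L]]
  # a header line has non-numeric residue columns; a malformed data row
  # (numeric i, j but junk strength) is an error, not a header
  has_header <- all(is.na(suppressWarnings(
    as.numeric(first[seq_len(min(2L, length(first)))]))))
  body <- if (has_header) lines[-1L] else lines
  if (length(body) == 0L) stop("empty coupling table")
  rows <- lapply(seq_along(body), function(k) {
    f <- strsplit(body[k], "\t")[[1L]]
    if (length(f) < 3L)
      stop(sprintf("row %d: expected 3 tab-separated fields, got %d",
                   k + has_header, length(f)))
    v <- suppressWarnings(as.numeric(f[1:3]))
    if (any(is.na(v)))
      stop(sprintf("row %d: non-numeric value in '%s'", k + has_header, body[k]))
    v
  })
  m <- do.call(rbind, rows)
  df <- data.frame(i = as.integer(m[, 1L]) + numbering_offset,
                   j = as.integer(m[, 2L]) + numbering_offset,
                   strength = m[, 3L])
  a <- pmin(df$i, df$j); b <- pmax(df$i, df$j)
  key <- paste(a, b)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate pair(s) collapsed keeping max strength")
    df <- do.call(rbind, lapply(split(df, key), function(g)
      g[which.max(g$strength), , drop = FALSE]))
  }
  coupling_table(df, L = L, domain_tag = domain_tag)
}

#' Select the top 2L/3 strongest couplings
#'
#' Keeps the `floor(fraction_numerator * L / fraction_denominator)` entries
#' of greatest strength (for L = 240 this is 160 pairs).  Ties at the
#' selection boundary are broken deterministically towards smaller `i`,
#' then smaller `j`.
#'
#' @param t a `coupling_table`.
#' @param fraction_numerator,fraction_denominator selection fraction,
#'   default 2/3.
#' @return A `coupling_table` with the selected entries, strongest first.
#' @export
select_top <- function(t, fraction_numerator = 2L, fraction_denominator = 3L) {
  stopifnot(inherits(t, "coupling_table"))
  n_keep <- floor(fraction_numerator * t$L / fraction_denominator)
  if (nrow(t$entries) < n_keep)
    stop(sprintf("coupling table has %d entries; top-%d/%d selection for L = %d needs %d",
                 nrow(t$entries), fraction_numerator, fraction_denominator,
                 t$L, n_keep))
  e <- t$entries
  ord <- order(-e$strength, e$i, e$j)
  out <- t
  out$entries <- e[ord[seq_len(n_keep)], , drop = FALSE]
  rownames(out$entries) <- NULL
  out
}

# unordered residue-number pair keys realized in a contact map, split by
# relation
.map_pair_keys <- function(map, relation = c("intra", "inter")) {
  sel <- map$pairs$relation %in% relation
  i <- map$pairs$i[sel]; j <- map$pairs$j[sel]
  ni <- map$residues$resno[i]; nj <- map$residues$resno[j]
  unique(paste(pmin(ni, nj), pmax(ni, nj)))
}

#' Overlay couplings on a contact map
#'
#' Each coupling pair `(i, j)` in residue numbering counts as in contact if
#' any chain-pair realization is present in `map`: intra-chain in any chain
#' for `pairing = "monomer"`, and additionally inter-chain realizations for
#' `pairing = "tetramer"`.  Coupling residues absent from the structure are
#' flagged "unmapped" and excluded from the denominator.
#'
#' @param t a `coupling_table` (typically after [select_top()]).
#' @param map a `contact_map`.
#' @param pairing "tetramer" (default) or "monomer".
#' @return An `overlay_result`: counts, the in-contact `fraction`, a
#'   per-pair classification (`contact_intra`, `contact_inter`,
#'   `non_contact`, `unmapped`) and the cutoff used.  The intra-chain-only
#'   fraction is reported alongside, whichever pairing was requested.
#' @export
overlay_contacts <- function(t, map, pairing = c("tetramer", "monomer")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(t, "coupling_table"), inherits(map, "contact_map"))
  intra_keys <- .map_pair_keys(map, "intra")
  inter_keys <- .map_pair_keys(map, "inter")
  present <- unique(map$residues$resno)
  e <- t$entries
  key <- paste(pmin(e$i, e$j), pmax(e$i, e$j))
  mapped <- e$i %in% present & e$j %in% present
  cls <- rep("non_contact", nrow(e))
  cls[key %in% inter_keys & pairing == "tetramer"] <- "contact_inter"
  cls[key %in% intra_keys] <- "contact_intra"   # intra takes precedence
  cls[!mapped] <- "unmapped"
  n_sel <- sum(mapped)
  in_contact <- sum(cls %in% c("contact_intra", "contact_inter"))
  in_contact_intra_only <- sum(key %in% intra_keys & mapped)
  structure(list(selected = n_sel, in_contact = in_contact,
                 fraction = if (n_sel > 0) in_contact / n_sel else NA_real_,
                 fraction_intra_only = if (n_sel > 0)
                   in_contact_intra_only / n_sel else NA_real_,
                 classification = data.frame(i = e$i, j = e$j,
                                             strength = e$strength,
                                             class = cls,
                                             stringsAsFactors = FALSE),
                 n_unmapped = sum(!mapped),
                 cutoff = map$cutoff, pairing = pairing),
            class = "overlay_result")
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf("overlay_result: %d/%d couplings in contact (%.1f%%) at cutoff %.1f A [%s pairing]%s\n",
              x$in_contact, x$selected, 100 * x$fraction, x$cutoff, x$pairing,
              if (x$n_unmapped > 0) sprintf(", %d unmapped", x$n_unmapped) else ""))
  invisible(x)
}

#' Overlay fraction as a function of the contact cutoff
#'
#' Recomputes the contact map of `s` at each cutoff and reports the
#' in-contact fraction; because contact sets grow with the cutoff the
#' fractions are non-decreasing.  The analysis of the cone-channel model
#' used cutoffs between 10 and 15 A, settling on 12 A.
#'
#' @param t a `coupling_table`.
#' @param s a [coarse_structure()].
#' @param cutoffs ascending positive cutoffs in Angstrom.
#' @param pairing passed to [overlay_contacts()].
#' @param min_sequence_separation same-chain separation filter for the
#'   contact maps (EVcouplings practice is `|i - j| >= 5`).
#' @return data.frame with columns `cutoff` and `fraction`.
#' @export
cutoff_scan <- function(t, s, cutoffs = 10:15,
                        pairing = "tetramer", min_sequence_separation = 5L) {
  stopifnot(all(cutoffs > 0))
  if (is.unsorted(cutoffs)) stop("cutoffs must be ascending")
  frac <- vapply(cutoffs, function(cc) {
    map <- compute_contact_map(s, cc, min_sequence_separation)
    overlay_contacts(t, map, pairing)$fraction
  }, numeric(1))
  data.frame(cutoff = cutoffs, fraction = frac)
}

#' Rank alternative structural models by coupling-overlay fraction
#'
#' Mirrors the discrimination test between a final model and its
#' alternatives: the model whose contact map captures the greatest fraction
#' of the couplings ranks first.  For each non-best model the couplings
#' that are in contact in the best model but not in that model are listed.
#'
#' @param t a `coupling_table`.
#' @param maps named list (>= 2) of `contact_map` objects.
#' @param pairing passed to [overlay_contacts()].
#' @return data.frame ranking (`model`, `fraction`, `in_contact`,
#'   `selected`), with attribute `"distinguishing_pairs"`: per non-best
#'   model, the coupled pairs in contact only in the best model.
#' @export
compare_models <- function(t, maps, pairing = "tetramer") {
  if (!is.list(maps) || length(maps) < 2L)
    stop("compare_models needs at least two contact maps")
  if (is.null(names(maps)) || any(!nzchar(names(maps))))
    names(maps) <- paste0("model", seq_along(maps))
  res <- lapply(maps, function(m) overlay_contacts(t, m, pairing))
  df <- data.frame(model = names(maps),
                   fraction = vapply(res, `[[`, numeric(1), "fraction"),
                   in_contact = vapply(res, `[[`, numeric(1), "in_contact"),
                   selected = vapply(res, `[[`, numeric(1), "selected"),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$fraction, seq_len(nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  best <- res[[df$model[1L]]]$classification
  best_key <- paste(best$i, best$j)[best$class %in% c("contact_intra", "contact_inter")]
  distinguishing <- lapply(df$model[-1L], function(mn) {
    cl <- res[[mn]]$classification
    key <- paste(cl$i, cl$j)
    cl[cl$class == "non_contact" & key %in% best_key, c("i", "j", "strength")]
  })
  names(distinguishing) <- df$model[-1L]
  attr(df, "distinguishing_pairs") <- distinguishing
  df
}
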