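# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written against different primitives (svd, brute
# force loops, numeric differentiation) than the implementation they check.

# minimal PDB text from a residue table
pdb_text <- function(df) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    sprintf("ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, df$resname[i] %||% "ALA", df$chain[i], df$resno[i],
            df$x[i], df$y[i], df$z[i], df$occ[i] %||% 1, 0)
  }, character(1))
  c(lines, "END")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_residue_pdb <- function() {
  pdb_text(data.frame(chain = "A", resno = 1:2, x = c(0, 3.8), y = 0, z = 0))
}

# Moore-Penrose pseudoinverse via SVD (independent of the eigen route)
pinv_svd <- function(M, tol = 1e-9) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# O(N^2) brute-force contact scan
brute_contacts <- function(s, cutoff, min_sep = 1L) {
  X <- coords(s)
  r <- s$residues
  out <- list()
  for (i in seq_len(nrow(X) - 1L)) for (j in (i + 1L):nrow(X)) {
    d <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (d > cutoff) next
    if (r$chain[i] == r$chain[j] && abs(r$resno[i] - r$resno[j]) < min_sep) next
    out[[length(out) + 1L]] <- c(i, j)
  }
  if (length(out) == 0L) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

# harmonic pair energy of an ANM network with the contact set frozen at the
# reference geometry; used for numeric-Hessian checks
anm_pair_energy <- function(xvec, X0, cutoff) {
  X <- matrix(xvec, ncol = 3, byrow = TRUE)
  n <- nrow(X0)
  e <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d0 <- sqrt(sum((X0[i, ] - X0[j, ])^2))
    if (d0 > cutoff) next
    d <- sqrt(sum((X[i, ] - X[j, ])^2))
    e <- e + 0.5 * (d - d0)^2
  }
  e
}

numeric_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in a:n) {
    xa <- x; xa[a] <- xa[a] + h; xa[b] <- xa[b] + h; epp <- f(xa)
    xa <- x; xa[a] <- xa[a] + h; xa[b] <- xa[b] - h; epm <- f(xa)
    xa <- x; xa[a] <- xa[a] - h; xa[b] <- xa[b] + h; emp <- f(xa)
    xa <- x; xa[a] <- xa[a] - h; xa[b] <- xa[b] - h; emm <- f(xa)
    H[a, b] <- H[b, a] <- (epp - epm - emp + emm) / (4 * h^2)
  }
  H
}

# rewire a fraction of a contact map (decoy construction).  Rewiring acts
# on residue-number contact keys -- the level the overlay evaluates -- so a
# dropped contact loses ALL of its chain realizations and each added
# contact introduces a genuinely new key.
rewire_map <- function(map, frac, seed) {
  set.seed(seed)
  res <- map$residues
  na <- res$resno[map$pairs$i]; nb <- res$resno[map$pairs$j]
  key <- paste(pmin(na, nb), pmax(na, nb))
  ukeys <- unique(key)
  k <- round(frac * length(ukeys))
  drop_keys <- sample(ukeys, k)
  kept <- map$pairs[!(key %in% drop_keys), , drop = FALSE]
  nums <- sort(unique(res$resno))
  all_pairs <- t(combn(nums, 2L))
  all_pairs <- all_pairs[all_pairs[, 2] - all_pairs[, 1] >= 5L, , drop = FALSE]
  all_keys <- paste(all_pairs[, 1], all_pairs[, 2])
  pool <- setdiff(all_keys, ukeys)
  new_keys <- sample(pool, k)
  ij <- do.call(rbind, lapply(strsplit(new_keys, " "), as.integer))
  chainA <- which(res$chain == res$chain[1])
  idx_of <- function(rn) chainA[match(rn, res$resno[chainA])]
  added <- data.frame(i = idx_of(ij[, 1]), j = idx_of(ij[, 2]),
                      relation = "intra", stringsAsFactors = FALSE)
  out <- map
  out$pairs <- rbind(kept, added)
  out
}

# small shared structures (built once per test file load)
bundle40 <- make_helix_bundle_tetramer(40L, bundle_radius = 8)
bundle80 <- make_helix_bundle_tetramer(80L, bundle_radius = 8)   # richer contact set
cloud30 <- make_cloud(30L, seed = 7, radius = 4)  # dense: connected at 10 A
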