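test_that("burial profiles count Calpha neighbours", {
  s <- coarse_structure(data.frame(chain = "A", resno = 1:3,
                                   x = c(0, 5, 100), y = 0, z = 0))
  b <- burial_profile(s, 10)
  expect_equal(b$burial, c(1L, 1L, 0L))
  # centre of a dense cluster is more buried than its hull
  grid <- expand.grid(x = seq(-8, 8, 4), y = seq(-8, 8, 4), z = seq(-8, 8, 4))
  sc <- coarse_structure(data.frame(chain = "A", resno = seq_len(nrow(grid)),
                                    grid))
  bc <- burial_profile(sc, 10)
  centre <- which(grid$x == 0 & grid$y == 0 & grid$z == 0)
  hull <- which(abs(grid$x) == 8 & abs(grid$y) == 8 & abs(grid$z) == 8)
  expect_true(all(bc$burial[centre] > bc$burial[hull]))
  # brute-force oracle on a random structure
  s3 <- make_cloud(40L, seed = 21)
  b3 <- burial_profile(s3, 9)
  X <- coords(s3)
  oracle <- sapply(seq_len(40), function(i)
    sum(sqrt(colSums((t(X) - X[i, ])^2)) <= 9) - 1L)
  expect_equal(b3$burial, oracle, ignore_attr = TRUE)
  # C4 symmetry: identical burial across symmetry-equivalent residues
  bb <- burial_profile(bundle40, 10)
  per_chain <- matrix(bb$burial, ncol = 4L)
  expect_true(all(per_chain == per_chain[, 1]))
})

test_that("pattern agreement is a rank correlation with the right sign", {
  b <- burial_profile(make_cloud(30L, seed = 2), 10)
  # identical tie structure gives exactly +1 / -1
  tr_match <- residue_track(as.numeric(b$burial), kind = "hydrophobicity")
  expect_equal(pattern_agreement_score(tr_match, b), 1)
  tr_rev <- residue_track(-as.numeric(b$burial), kind = "hydrophobicity")
  expect_equal(pattern_agreement_score(tr_rev, b), -1)
  expect_warning(sc <- pattern_agreement_score(rep(5, 30), b), "constant")
  expect_true(is.na(sc))
  # invariant under monotone transforms of either side
  v <- as.numeric(b$burial)
  expect_equal(pattern_agreement_score(exp(v), b),
               pattern_agreement_score(v, b))
  expect_error(pattern_agreement_score(v[1:10], b), "lengths differ")
})

test_that("random tracks rarely beat the permutation null", {
  set.seed(31)
  b <- burial_profile(make_cloud(60L, seed = 3), 10)
  obs <- replicate(200, pattern_agreement_score(sample(1:9, 60, TRUE), b))
  expect_lt(abs(mean(obs)), 0.05)
  expect_lt(mean(abs(obs) > quantile(abs(obs), 0.95)), 0.10)
})

test_that("decoy ranking prefers structures that bury conserved residues", {
  # decoy A buries the conserved residues; decoy B swaps their coordinates
  # with the exposed ones, exposing them
  base <- make_cloud(30L, seed = 4, radius = 4)
  bur <- burial_profile(base, 10)$burial
  ord <- order(-bur)
  buried_half <- ord[1:15]
  exposed_half <- ord[16:30]
  grades <- rep(1L, 30)
  grades[buried_half] <- 9L
  track <- residue_track(grades, "conservation")
  decoyA <- base
  decoyB <- base
  decoyB$residues[c(buried_half, exposed_half), c("x", "y", "z")] <-
    coords(base)[c(exposed_half, buried_half), ]
  rk <- rank_decoys(list(A = decoyA, B = decoyB), track)
  expect_equal(rk$decoy[1], "A")
  # single decoy and exact ties
  expect_equal(nrow(rank_decoys(list(only = decoyA), track)), 1L)
  tie <- rank_decoys(list(x = decoyA, y = decoyA), track)
  expect_equal(tie$decoy, c("x", "y"))
  bad <- decoyA; bad$residues$resno[1] <- 999L
  expect_error(rank_decoys(list(decoyA, bad), track), "different residue set")
})

test_that("entropy fallback maps column variability onto grades 1-9", {
  msa <- c(a = "AAAA", b = "AAAC", c = "AACG", d = "AATT")
  tr <- entropy_conservation_fallback(msa)
  expect_equal(tr$values[1], 9L)                    # invariant column
  expect_true(tr$values[4] < tr$values[2])          # more variable -> lower
  # uniform 20-letter column scores the minimum grade
  msa20 <- setNames(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                    paste0("s", 1:20))
  expect_equal(entropy_conservation_fallback(msa20)$values, 1L)
  # 50/50 two-state column: normalized entropy log2/log20 -> grade 7
  msa2 <- c(rep("A", 5), rep("C", 5))
  expect_equal(entropy_conservation_fallback(msa2)$values,
               as.integer(round(9 - 8 * log(2) / log(20))))
  expect_error(entropy_conservation_fallback(c("AA", "AAA")), "ragged")
  gappy <- c("A-", "A-", "AC")
  expect_true(attr(entropy_conservation_fallback(gappy), "gap_majority")[2])
})

test_that("hydrophobicity tracks and TM agreement work end to end", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ALA\t1.5", "GLY\t0.5"), tmp)
  scale <- read_hydrophobicity_scale(tmp)
  tr <- hydrophobicity_track(bundle40, scale)
  expect_equal(tr$values, rep(1.5, n_residues(bundle40)))  # poly-ALA bundle
  expect_warning(out <- tm_hydrophobicity_agreement(bundle40, tr, c(0, 0, 1)),
                 "constant")
  expect_true(is.na(out))
})

test_that("planted burial correlation is recovered monotonically", {
  b <- burial_profile(bundle40, 10)
  scores <- sapply(c(0.3, 0.6, 0.9), function(rho) {
    mean(sapply(1:10, function(seed)
      pattern_agreement_score(make_conservation_track(b, rho, seed), b)))
  })
  expect_true(all(diff(scores) > 0))
  # near-perfect planting scores close to (but below, due to grade ties) 1
  tr1 <- make_conservation_track(b, 1, seed = 1)
  expect_gt(pattern_agreement_score(tr1, b), 0.95)
})
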