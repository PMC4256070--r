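test_that("read_calpha_structure parses minimal PDB text", {
  s <- read_calpha_structure(two_residue_pdb())
  expect_equal(n_residues(s), 2L)
  expect_equal(ca_distance(s, c("A", 1), c("A", 2)), 3.8, tolerance = 1e-6)
})

test_that("degenerate PDB inputs give structured errors", {
  expect_error(read_calpha_structure("REMARK nothing here\nEND"), "no ATOM")
  no_ca <- "ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
  expect_error(read_calpha_structure(no_ca), "no CA atoms in model 1")
  dup <- pdb_text(data.frame(chain = "A", resno = c(1, 1), x = c(0, 1),
                             y = 0, z = 0))
  expect_error(read_calpha_structure(dup), "duplicate CA")
  expect_error(read_calpha_structure(two_residue_pdb(), model_index = 2),
               "no MODEL records")
})

test_that("alternate locations keep the highest-occupancy record", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.70  0.00           C",
    "ATOM      3  CA  ALA A   2       9.000   0.000   0.000  1.00  0.00           C",
    "END")
  s <- read_calpha_structure(lines)
  expect_equal(n_residues(s), 2L)
  expect_equal(coords(s)[1, "x"], 5)   # the 0.70-occupancy altLoc wins
})

test_that("PDB round trip preserves residues to fixed-width precision", {
  s <- make_helix_bundle_tetramer(12L)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, tmp)
  s2 <- read_calpha_structure(tmp)
  expect_identical(s2$residues$chain, s$residues$chain)
  expect_identical(s2$residues$resno, s$residues$resno)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)
})

test_that("multi-MODEL files are read per model", {
  s <- make_ring(8L)
  s2 <- s
  s2$residues$x <- s2$residues$x + 1
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(list(s, s2), tmp)
  m1 <- read_calpha_structure(tmp, 1L)
  m2 <- read_calpha_structure(tmp, 2L)
  expect_equal(coords(m2)[, "x"] - coords(m1)[, "x"], rep(1, 8),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_error(read_calpha_structure(tmp, 3L), "only 2 model")
})

test_that("contact maps match the brute-force all-pairs oracle", {
  for (seed in c(1, 2, 3)) {
    s <- make_cloud(50L, seed = seed)
    map <- compute_contact_map(s, 12)
    oracle <- brute_contacts(s, 12)
    got <- as.matrix(map$pairs[, c("i", "j")])
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
  # sequence-separation filter applies to same-chain pairs only
  s <- bundle40
  map5 <- compute_contact_map(s, 9, min_sequence_separation = 5L)
  oracle5 <- brute_contacts(s, 9, 5L)
  expect_equal(nrow(map5$pairs), nrow(oracle5))
  expect_equal(map5$n_intra + map5$n_inter, nrow(map5$pairs))
})

test_that("simple collinear contact examples behave", {
  s <- coarse_structure(data.frame(chain = "A", resno = 1:3,
                                   x = c(0, 8, 16), y = 0, z = 0))
  m10 <- compute_contact_map(s, 10)
  expect_equal(nrow(m10$pairs), 2L)
  m20 <- compute_contact_map(s, 20)
  expect_equal(nrow(m20$pairs), 3L)
})

test_that("ca_distance is a metric on random triples", {
  set.seed(42)
  s <- make_cloud(20L, seed = 9)
  for (rep in 1:20) {
    ijk <- sample(20L, 3L)
    sel <- lapply(ijk, function(i) c("A", i))
    dab <- ca_distance(s, sel[[1]], sel[[2]])
    dba <- ca_distance(s, sel[[2]], sel[[1]])
    dac <- ca_distance(s, sel[[1]], sel[[3]])
    dcb <- ca_distance(s, sel[[3]], sel[[2]])
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
  }
  expect_equal(ca_distance(s, c("A", 5), c("A", 5)), 0)
  expect_error(ca_distance(s, c("B", 1), c("A", 2)), "resolves to 0")
})

test_that("delete_domain removes exactly the listed residues", {
  s <- coarse_structure(data.frame(chain = "A", resno = 1:10,
                                   x = (1:10) * 3.8, y = 0, z = 0))
  expect_error(delete_domain(s, data.frame()), "non-empty")
  s2 <- delete_domain(s, data.frame(chain = "A", start = 1, end = 4))
  expect_equal(s2$residues$resno, 5:10)
  expect_error(delete_domain(s, data.frame(chain = "A", start = 1, end = 10)),
               "every residue")
})

test_that("deleting a whole chain drops it with a warning", {
  s <- bundle40
  expect_warning(
    s2 <- delete_domain(s, data.frame(chain = "A", start = 1, end = 40)),
    "empties chain")
  expect_equal(sort(unique(s2$residues$chain)), c("B", "C", "D"))
  # survivors keep identity and the contact map matches brute force
  map <- compute_contact_map(s2, 10)
  expect_equal(nrow(map$pairs), nrow(brute_contacts(s2, 10)))
})

test_that("VSD deletion on the annotated channel reduces counts consistently", {
  s <- synthetic_cone_channel()
  vsd_n <- sum(domain_mask(s, "VSD"))
  s2 <- delete_domain(s, "VSD")
  expect_equal(n_residues(s2), n_residues(s) - vsd_n)
  expect_equal(vsd_n, 4L * 135L)   # residues 170-304 per chain
})

test_that("assemble_homotetramer builds exact Cn symmetry", {
  mono <- coarse_structure(data.frame(chain = "X", resno = 1:12,
                                      x = 8 + (1:12) * 0.3,
                                      y = 2, z = (1:12) * 1.5))
  tet <- assemble_homotetramer(mono, 4L)
  expect_equal(sort(unique(tet$residues$chain)), LETTERS[1:4])
  expect_equal(n_residues(tet), 48L)
  # back-rotating chain k must land exactly on chain A
  XA <- coords(tet)[tet$residues$chain == "A", ]
  for (k in 2:4) {
    Xk <- coords(tet)[tet$residues$chain == LETTERS[k], ]
    th <- -2 * pi * (k - 1) / 4
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
    expect_lt(max(abs(Xk %*% t(R) - XA)), 1e-9)
  }
  expect_error(assemble_homotetramer(mono, 1L), "symmetry_order")
  expect_error(assemble_homotetramer(tet, 4L), "single-chain")
})

test_that("symmetry axis of a C4 assembly is the rotation axis", {
  ax <- symmetry_axis(bundle40)
  expect_equal(abs(ax[3]), 1, tolerance = 1e-6)
})

test_that("annotation config files round-trip through domain_mask", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "TM\tA\t21-40", "cytosolic\tA\t1-20,41-40"), tmp)
  ann <- read_annotation_config(tmp)
  expect_equal(nrow(ann), 3L)
  s <- coarse_structure(
    data.frame(chain = "A", resno = 1:40, x = (1:40) * 3.8, y = 0, z = 0),
    annotations = ann[1, , drop = FALSE])
  expect_equal(sum(domain_mask(s, "TM")), 20L)
  expect_error(domain_mask(s, "nope"), "no annotation")
  writeLines("TM only-two-fields", tmp)
  expect_error(read_annotation_config(tmp), "malformed")
})
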