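test_that("surface_distance subtracts the van der Waals radii", {
  a <- typed_atoms("C", 0, 0, 0, "protein")
  b <- typed_atoms("C", 3.8, 0, 0, "ligand")
  expect_equal(surface_distance(a, b), 0)
  expect_equal(surface_distance(a, typed_atoms("C", 0, 0, 0, "ligand")), -3.8)
  # random pairs against direct recomputation
  set.seed(5)
  for (i in 1:20) {
    e1 <- sample(c("C", "N", "O", "S"), 1); e2 <- sample(c("C", "O", "Cl"), 1)
    p1 <- rnorm(3, sd = 5); p2 <- rnorm(3, sd = 5)
    a <- typed_atoms(e1, p1[1], p1[2], p1[3], "protein")
    b <- typed_atoms(e2, p2[1], p2[2], p2[3], "ligand")
    cfg <- vf_config()
    expect_equal(surface_distance(a, b),
                 sqrt(sum((p1 - p2)^2)) - cfg$radii[[e1]] - cfg$radii[[e2]])
  }
})

test_that("vina_pair_terms reproduces the closed-form values", {
  expect_equal(vina_pair_terms(0)[[1, "gauss1"]], 1)
  expect_equal(vina_pair_terms(3)[[1, "gauss2"]], 1)
  expect_equal(vina_pair_terms(-1)[[1, "repulsion"]], 1)
  expect_equal(vina_pair_terms(1, hydrophobic_pair = TRUE)[[1, "hydrophobic"]], 0.5)
  expect_equal(vina_pair_terms(-0.35, donor_acceptor_pair = TRUE)[[1, "hbond"]], 0.5)
  # ineligible pairs contribute nothing to the ramps
  expect_equal(vina_pair_terms(1)[[1, "hydrophobic"]], 0)
  expect_equal(vina_pair_terms(-0.35)[[1, "hbond"]], 0)
})

test_that("vina_pair_terms respects its ranges", {
  d <- seq(-4, 8, by = 0.05)
  tm <- vina_pair_terms(d, hydrophobic_pair = TRUE, donor_acceptor_pair = TRUE)
  expect_true(all(tm[, "gauss1"] > 0 & tm[, "gauss1"] <= 1))
  expect_true(all(tm[, "gauss2"] > 0 & tm[, "gauss2"] <= 1))
  expect_true(all(tm[, "repulsion"] >= 0))
  expect_true(all(tm[, "hydrophobic"] >= 0 & tm[, "hydrophobic"] <= 1))
  expect_true(all(tm[, "hbond"] >= 0 & tm[, "hbond"] <= 1))
  expect_true(all(tm[d >= 0, "repulsion"] == 0))
})

test_that("vina_features applies the cutoff and reduces to single-pair terms", {
  far <- toy_pair_complex(9, nrot = 3)
  f <- vina_features(far)
  expect_equal(unname(f[1:5]), rep(0, 5))
  expect_equal(unname(f["nrot"]), 3)
  near <- toy_pair_complex(1.0, nrot = 2)
  f2 <- vina_features(near)
  expect_equal(unname(f2[1:5]),
               unname(vina_pair_terms(1.0, hydrophobic_pair = TRUE)[1, ]))
  expect_equal(unname(f2["nrot"]), 2)
})

test_that("vina_features matches the brute-force oracle on a random complex", {
  cx <- gen_complex(complex_gen_spec(n_protein_atoms = 45, n_ligand_atoms = 15),
                    seed = 11)
  expect_lt(max(abs(vina_features(cx) - oracle_vina_features(cx))), 1e-10)
})

test_that("rf_counts counts element pairs within the cutoff", {
  cx <- toy_pair_complex(0, el_p = "C", el_l = "N")  # centers ~3.7 A apart
  counts <- rf_counts(cx)
  expect_equal(unname(counts["C.N"]), 1L)
  expect_equal(sum(counts), 1L)
  # ligand elements outside the canonical set are ignored
  zn <- molecular_complex("zn",
                          typed_atoms("C", 0, 0, 0, "protein"),
                          typed_atoms("Zn", 3, 0, 0, "ligand",
                                      is_hydrophobic = FALSE,
                                      is_hbond_acceptor = FALSE), 0)
  expect_equal(sum(rf_counts(zn)), 0L)
  # exact integer agreement with the double-loop oracle
  cx2 <- gen_complex(complex_gen_spec(n_protein_atoms = 60, n_ligand_atoms = 20),
                     seed = 12)
  expect_identical(rf_counts(cx2), oracle_rf_counts(cx2))
})

test_that("enlarging the rf_counts cutoff never decreases any entry", {
  cx <- gen_complex(seed = 13)
  prev <- rf_counts(cx, cutoff = 4)
  for (cut in c(6, 8, 10, 12, 15)) {
    cur <- rf_counts(cx, cutoff = cut)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("vina_score converts the weighted terms to the pK scale", {
  far <- toy_pair_complex(9, nrot = 5)
  expect_equal(vina_score(far), 0)
  # single C-C pair at d = 1.0, Nrot = 0: hand-computed weighted sum
  cx <- toy_pair_complex(1.0, nrot = 0)
  cfg <- vf_config()
  w <- cfg$vina$weights
  e <- w[["gauss1"]] * exp(-(1 / 0.5)^2) + w[["gauss2"]] * exp(-((1 - 3) / 2)^2) +
    w[["hydrophobic"]] * 0.5
  expect_equal(vina_score(cx), -e / 1.3637, tolerance = 1e-12)
  # doubling all five weights doubles the energy at fixed Nrot
  cfg2 <- vf_config(vina = list(weights = cfg$vina$weights * 2))
  expect_equal(vina_score(cx, config = cfg2), 2 * vina_score(cx), tolerance = 1e-12)
})

test_that("baseline descriptors are ligand size and heavy-atom mass", {
  ring <- molecular_complex(
    "ring", typed_atoms("C", 10, 0, 0, "protein"),
    typed_atoms(rep("C", 6), cos(1:6), sin(1:6), rep(0, 6), "ligand"), 0)
  b <- baseline_descriptors(ring)
  expect_equal(b$nha, 6L)
  expect_equal(b$mwt, 6 * 12.011)
  one <- toy_pair_complex(2)
  expect_equal(baseline_descriptors(one)$mwt, 12.011)
  cx <- gen_complex(seed = 3)
  expect_equal(baseline_descriptors(cx)$nha, nrow(cx$ligand))
})

test_that("featurize_set builds ordered tables and reports rejects", {
  cxs <- gen_complex_set(3, complex_gen_spec(n_protein_atoms = 30,
                                             n_ligand_atoms = 10), seed = 2)
  f6 <- featurize_set(cxs, "vina6")
  expect_equal(dim(f6), c(3L, 7L))
  expect_equal(names(f6), c("id", feature_names("vina6")))
  expect_equal(f6$id, vapply(cxs, `[[`, character(1), "id"))
  f42 <- featurize_set(cxs, "vinaelem42")
  expect_equal(f42[names(f6)], f6, ignore_attr = TRUE)
  expect_equal(nrow(attr(f42, "rejects")), 0L)
  # a corrupt complex is reported, not dropped silently
  broken <- cxs[[1]]
  broken$ligand <- broken$ligand[0, ]
  broken$id <- "broken"
  fb <- featurize_set(c(cxs[2], list(broken)), "vina6")
  expect_equal(nrow(fb), 1L)
  rej <- attr(fb, "rejects")
  expect_equal(rej$id, "broken")
  expect_match(rej$message, "empty atom list")
})

test_that("feature tables round-trip through CSV", {
  cxs <- gen_complex_set(4, seed = 9)
  f <- featurize_set(cxs, "vinaelem42")
  tf <- tempfile(fileext = ".csv")
  write_features(f, tf)
  g <- read_features(tf)
  expect_equal(g, f, ignore_attr = TRUE)
})

test_that("all 42 features are invariant under rigid motions", {
  set.seed(21)
  cx <- gen_complex(seed = 21)
  f0 <- c(vina_features(cx), rf_counts(cx))
  for (i in 1:5) {
    cx2 <- rigid_transform(cx, random_rotation(), rnorm(3, sd = 20))
    expect_lt(max(abs(vina_features(cx2) - f0[1:6])), 1e-9)
    expect_equal(unname(as.numeric(rf_counts(cx2))), unname(f0[7:42]))
  }
})

test_that("role swap of identical atom sets preserves symmetric descriptors", {
  set.seed(31)
  coords_a <- matrix(rnorm(30, sd = 3), ncol = 3)
  coords_b <- matrix(rnorm(30, sd = 3) + 5, ncol = 3)
  els <- sample(c("C", "N", "O", "S"), 10, replace = TRUE)
  mk <- function(coords, els, role)
    typed_atoms(els, coords[, 1], coords[, 2], coords[, 3], role,
                is_hbond_donor = els == "N")
  cx <- molecular_complex("ab", mk(coords_a, els, "protein"),
                          mk(coords_b, els, "ligand"), 0)
  xc <- molecular_complex("ba", mk(coords_b, els, "protein"),
                          mk(coords_a, els, "ligand"), 0)
  f1 <- vina_features(cx); f2 <- vina_features(xc)
  for (term in c("gauss1", "gauss2", "repulsion", "hydrophobic", "hbond"))
    expect_equal(f1[[term]], f2[[term]], tolerance = 1e-12)
  # count grid transposes on the shared elements
  c1 <- matrix(rf_counts(cx), 4, 9, byrow = TRUE,
               dimnames = list(c("C", "N", "O", "S"),
                               c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")))
  c2 <- matrix(rf_counts(xc), 4, 9, byrow = TRUE,
               dimnames = dimnames(c1))
  shared <- c("C", "N", "O", "S")
  expect_identical(c1[shared, shared], t(c2[shared, shared]))
})
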