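test_that("gen_complex is a pure function of seed and spec", {
  a <- gen_complex(seed = 99)
  b <- gen_complex(seed = 99)
  expect_identical(a, b)
  # and leaves the caller's RNG stream untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(gen_complex(seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated complexes respect geometry and composition", {
  spec <- complex_gen_spec(n_protein_atoms = 40, n_ligand_atoms = 12,
                           min_separation = 1.5)
  cx <- gen_complex(spec, seed = 3)
  all_xyz <- as.matrix(rbind(cx$protein[, c("x", "y", "z")],
                             cx$ligand[, c("x", "y", "z")]))
  d <- as.matrix(dist(all_xyz))
  diag(d) <- Inf
  expect_gte(min(d), 1.5)
  expect_lte(max(sqrt(rowSums(as.matrix(cx$ligand[, c("x", "y", "z")])^2))),
             spec$pocket_radius)
  expect_true(cx$n_rotatable_bonds >= 0 && cx$n_rotatable_bonds <= 12)
  # all-carbon ligand populates only the (., C) count entries
  spec_c <- complex_gen_spec(n_ligand_atoms = 8, ligand_freqs = c(C = 1))
  cx_c <- gen_complex(spec_c, seed = 4)
  counts <- rf_counts(cx_c)
  non_c <- counts[!grepl("\\.C$", names(counts))]
  expect_true(all(non_c == 0L))
  expect_gt(sum(counts), 0L)
})

test_that("an impossible packing fails with actionable advice", {
  spec <- complex_gen_spec(n_ligand_atoms = 500, pocket_radius = 3,
                           min_separation = 2.5)
  expect_error(gen_complex(spec, seed = 1), "enlarge the box")
})

test_that("linear noise-free labels are exactly recoverable", {
  cxs <- gen_complex_set(80, complex_gen_spec(n_protein_atoms = 40,
                                              n_ligand_atoms = 12), seed = 15)
  f <- featurize_set(cxs, "vina6")
  y <- gen_labels(f, label_gen_spec("linear", noise_sd = 0, seed = 2))
  gen <- attr(y, "generator")
  m <- fit_mlr(f, as.numeric(y))
  expect_lt(max(abs(m$coefficients - gen$beta)), 1e-8)
  # same spec, same labels
  y2 <- gen_labels(f, label_gen_spec("linear", noise_sd = 0, seed = 2))
  expect_identical(as.numeric(y), as.numeric(y2))
})

test_that("nonlinear labels defeat the linear model but not the forest", {
  cxs <- gen_complex_set(260, complex_gen_spec(n_protein_atoms = 50,
                                               n_ligand_atoms = 14), seed = 16)
  f <- featurize_set(cxs, "vina6")
  y <- as.numeric(gen_labels(f, label_gen_spec("nonlinear", noise_sd = 0.3,
                                               seed = 3)))
  tr <- 1:200; te <- 201:260
  mlr <- fit_mlr(f[tr, ], y[tr])
  rmse_mlr <- sqrt(mean((predict(mlr, f[te, ]) - y[te])^2))
  rf <- fit_rf(f[tr, ], y[tr], seed = 1,
               rf_config(6, n_trees = 200, seeds = 1))
  rmse_rf <- sqrt(mean((predict(rf, f[te, ]) - y[te])^2))
  expect_lt(rmse_rf, rmse_mlr)
})

test_that("degrade is identity at zero strength and annotates quality tiers", {
  cxs <- gen_complex_set(6, complex_gen_spec(n_protein_atoms = 30,
                                             n_ligand_atoms = 10), seed = 17)
  y <- seq(3, 8, along.with = cxs)
  null_spec <- degrade_spec(jitter_sd = 0, label_bias_sd = 0, label_noise_sd = 0)
  out0 <- degrade(cxs, y, null_spec, seed = 1)
  expect_identical(out0$complexes, cxs)
  expect_identical(out0$labels, y)
  # degraded records carry a >2.5 A resolution and IC50 kind, failing
  # refined quality; the tier machinery consumes the annotations directly
  spec <- degrade_spec(jitter_sd = 0.35, fraction = 0.5)
  out <- degrade(cxs, y, spec, seed = 2)
  ann <- out$annotations
  expect_equal(sum(ann$degraded), 3L)
  expect_equal(ann$resolution[ann$degraded], rep(0.35 / 0.1, 3))
  expect_true(all(ann$measure_kind[ann$degraded] == "IC50"))
  expect_false(any(is_refined_quality(ann[ann$degraded, ])))
  expect_true(all(is_refined_quality(ann[!ann$degraded, ])))
  kdki <- make_tier(ann, tier_spec(kdki_only = TRUE))
  expect_setequal(kdki$code, ann$code[!ann$degraded])
})

test_that("coordinate jitter only perturbs counts near the distance cutoff", {
  cxs <- gen_complex_set(5, seed = 18)
  y <- rep(5, 5)
  sigma <- 0.3
  out <- degrade(cxs, y, degrade_spec(jitter_sd = sigma, label_bias_sd = 0,
                                      label_noise_sd = 0), seed = 3)
  for (i in seq_along(cxs)) {
    before <- rf_counts(cxs[[i]])
    after <- rf_counts(out$complexes[[i]])
    delta <- sum(abs(after - before))
    # pairs can only flip in/out if they started near 12 A; each atom moves
    # ~N(0, sigma) per coordinate, so a 6-sigma pairwise band is generous
    g <- vinaforest:::.pair_geometry(cxs[[i]])
    band <- sum(abs(g$r - 12) <= 6 * sigma)
    expect_lte(delta, band)
  }
})

test_that("gen_index emits the requested composition, shuffled but parseable", {
  comp <- c(clean = 12, approximate = 3, nmr = 2, covalent = 2,
            uncommon_element = 1, peptide_ge10 = 1, nucleotide_ge4 = 1,
            incomplete = 1, multi_ligand = 1, non_protein_ligand = 2,
            conversion_failed = 1)
  idx <- gen_index(comp, seed = 19)
  expect_equal(nrow(idx$records), sum(comp))
  cls <- table(idx$bookkeeping$class)
  expect_equal(as.integer(cls[names(comp)]), unname(as.integer(comp)))
  # every defect class is flagged on its own records
  bk <- idx$bookkeeping
  rec <- idx$records[match(bk$code, idx$records$code), ]
  for (f in c("covalent", "uncommon_element", "peptide_ge10", "nucleotide_ge4",
              "incomplete", "multi_ligand", "non_protein_ligand",
              "conversion_failed"))
    expect_true(all(rec[[f]][bk$class == f]), label = f)
  expect_true(all(rec$nmr[bk$class == "nmr"]))
  expect_false(any(rec$exact[bk$class == "approximate"]))
  # determinism
  expect_identical(gen_index(comp, seed = 19)$text, idx$text)
  # codes unique
  expect_equal(anyDuplicated(idx$records$code), 0L)
})

test_that("the full pipeline preserves linear signal end to end", {
  n <- 200
  cxs <- gen_complex_set(n + 50, complex_gen_spec(n_protein_atoms = 40,
                                                  n_ligand_atoms = 12), seed = 20)
  f <- featurize_set(cxs, "vina6")
  y <- as.numeric(gen_labels(f, label_gen_spec("linear", noise_sd = 0, seed = 4)))
  m <- fit_mlr(f[1:n, ], y[1:n])
  p <- predict(m, f[(n + 1):(n + 50), ])
  expect_lt(sqrt(mean((p - y[(n + 1):(n + 50)])^2)), 1e-6)
})
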