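test_that("parse_index reads the whitespace-column dialect", {
  txt <- c("# ==== header comment ====",
           "3zzf  2.20  2012  0.40  Ki=400mM",
           "1abc  NMR   1999  5.00  Kd~10uM",
           "4xyz  1.90  2010  8.30  IC50=5nM   flags=covalent;incomplete",
           "2def  2.80  2005  6.10  Kd<=100uM  -")
  rec <- parse_index(txt)
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$code[1], "3zzf")
  expect_equal(rec$resolution[1], 2.20)
  expect_equal(rec$year[1], 2012L)
  expect_equal(rec$p_affinity[1], 0.40)
  expect_equal(rec$measure_kind[1], "Ki")
  expect_true(rec$exact[1])
  # NMR marker sets the flag and NA resolution; '~' is approximate
  expect_true(rec$nmr[2])
  expect_true(is.na(rec$resolution[2]))
  expect_false(rec$exact[2])
  # trailing annotation column carries defect flags
  expect_true(rec$covalent[3])
  expect_true(rec$incomplete[3])
  expect_false(rec$covalent[4])
  # '<=' qualifier is approximate
  expect_false(rec$exact[4])
  expect_equal(rec$measure_kind[3], "IC50")
})

test_that("parse_index rejects malformed lines and unknown units", {
  expect_error(parse_index("1abc 2.2 2001"), "malformed line 1")
  expect_error(parse_index("1abc  2.20  2001  5.00  Kd=10XX"), "unknown affinity unit")
  expect_error(parse_index("1abc  deep  2001  5.00  Kd=10uM"), "malformed resolution")
  expect_equal(nrow(parse_index("# only comments")), 0L)
})

test_that("general filters remove in order with full accounting", {
  idx <- gen_index(c(clean = 30, non_protein_ligand = 5, conversion_failed = 2,
                     approximate = 4, nmr = 3), seed = 5)
  res <- apply_general_filters(idx$records)
  expect_equal(nrow(res$retained), 30L)
  expect_equal(res$removed$n, c(5L, 2L, 4L, 3L))
  expect_equal(nrow(res$retained) + sum(res$removed$n), nrow(idx$records))
  # each class is removed under its own reason
  bk <- idx$bookkeeping
  expect_setequal(res$retained$code, bk$code[bk$class == "clean"])
  # a clean exact record is retained; an approximate one removed
  expect_true(all(res$retained$exact))
  expect_false(any(res$retained$nmr))
})

test_that("sequential-filter accounting holds for random compositions", {
  set.seed(41)
  for (i in 1:5) {
    comp <- c(clean = sample(5:40, 1), non_protein_ligand = sample(0:10, 1),
              conversion_failed = sample(0:3, 1), approximate = sample(0:8, 1),
              nmr = sample(0:6, 1))
    idx <- gen_index(comp, seed = i)
    res <- apply_general_filters(idx$records)
    expect_equal(nrow(res$retained) + sum(res$removed$n), sum(comp))
    expect_equal(res$removed$n,
                 unname(comp[c("non_protein_ligand", "conversion_failed",
                               "approximate", "nmr")]))
  }
})

test_that("refined-set quality needs good resolution, X-ray, exact Kd/Ki, no defects", {
  mk <- function(res, kind, exact = TRUE, flag = NULL) {
    txt <- sprintf("1abc  %s  2010  5.00  %s%s10uM%s",
                   res, kind, if (exact) "=" else "~",
                   if (is.null(flag)) "" else paste0("  flags=", flag))
    parse_index(txt)
  }
  expect_true(is_refined_quality(mk("2.40", "Ki")))
  expect_false(is_refined_quality(mk("2.40", "IC50")))   # IC50 is not Kd/Ki
  expect_false(is_refined_quality(mk("2.80", "Kd")))     # resolution above the cap
  expect_true(is_refined_quality(mk("2.50", "Kd")))      # inclusive by default
  expect_false(is_refined_quality(mk("2.50", "Kd"),
                                  config = vf_config(refined = list(strict = TRUE))))
  expect_false(is_refined_quality(mk("NMR", "Kd")))      # not an X-ray structure
  expect_false(is_refined_quality(mk("2.00", "Kd", exact = FALSE)))
  for (f in c("covalent", "uncommon_element", "peptide_ge10", "nucleotide_ge4",
              "incomplete", "multi_ligand", "non_protein_ligand"))
    expect_false(is_refined_quality(mk("2.00", "Kd", flag = f)))
})

test_that("refined-quality records always survive the general filters", {
  idx <- gen_index(c(clean = 60, non_protein_ligand = 10, approximate = 10,
                     nmr = 5, covalent = 5, incomplete = 5), seed = 6)
  rec <- idx$records
  refined <- rec[is_refined_quality(rec), ]
  res <- apply_general_filters(rec)
  expect_true(all(refined$code %in% res$retained$code))
})

test_that("tiers nest and match generator bookkeeping", {
  idx <- gen_index(c(clean = 300), seed = 7)
  rec <- apply_general_filters(idx$records)$retained
  t_all <- make_tier(rec, tier_spec())
  t30 <- make_tier(rec, tier_spec(resolution_max = 3.0))
  t25 <- make_tier(rec, tier_spec(resolution_max = 2.5))
  k_all <- make_tier(rec, tier_spec(kdki_only = TRUE))
  k30 <- make_tier(rec, tier_spec(resolution_max = 3.0, kdki_only = TRUE))
  k25 <- make_tier(rec, tier_spec(resolution_max = 2.5, kdki_only = TRUE))
  expect_equal(nrow(t_all), nrow(rec))       # no-max keeps all
  expect_true(all(t25$code %in% t30$code))
  expect_true(all(t30$code %in% t_all$code))
  expect_true(all(k25$code %in% k30$code))
  expect_true(all(k30$code %in% k_all$code))
  expect_true(all(k30$code %in% t30$code))
  # subset sizes equal direct stratum sums from the records
  expect_equal(nrow(t30), sum(rec$resolution <= 3.0))
  expect_equal(nrow(k25), sum(rec$resolution <= 2.5 &
                              rec$measure_kind %in% c("Kd", "Ki")))
  # refined tier applies the full criteria
  t_ref <- make_tier(rec, tier_spec(refined_only = TRUE))
  expect_equal(t_ref$code, rec$code[is_refined_quality(rec)])
  expect_error(tier_spec(resolution_max = 3.0, refined_only = TRUE), "<= 2.5")
})

test_that("blind splits are set differences disjoint from the old release", {
  new <- c("1abc", "2DEF", "3ghi", "4jkl")
  old <- c("2def", "4JKL")
  test <- blind_split(new, old)
  expect_setequal(test, c("1abc", "3ghi"))
  expect_length(intersect(test, tolower(old)), 0L)
  expect_length(blind_split(old, old), 0L)
  expect_setequal(blind_split(new, character()), tolower(new))
  # brute-force membership oracle on random code sets
  set.seed(43)
  pool <- sprintf("%dx%02d", sample(1:9, 50, TRUE), 1:50)
  a <- sample(pool, 30); b <- sample(pool, 25)
  expect_setequal(blind_split(a, b), a[!vapply(a, `%in%`, logical(1), b)])
})

test_that("subtract_codes has plain set semantics", {
  idx <- gen_index(c(clean = 20), seed = 8)
  rec <- idx$records
  expect_equal(subtract_codes(rec, character()), rec)
  expect_equal(nrow(subtract_codes(rec, rec$code)), 0L)
  drop <- rec$code[c(3, 7, 11)]
  out <- subtract_codes(rec, toupper(drop))
  expect_equal(out$code, setdiff(rec$code, drop))
})

test_that("sidecar annotations merge into records by code", {
  idx <- gen_index(c(clean = 10), seed = 9)
  rec <- idx$records
  ann <- data.frame(code = toupper(rec$code[c(2, 5)]), covalent = c(TRUE, FALSE),
                    incomplete = c(FALSE, TRUE))
  out <- apply_annotations(rec, ann)
  expect_true(out$covalent[2])
  expect_true(out$incomplete[5])
  expect_false(any(out$covalent[-2]))
  # a covalent annotation disqualifies the record from refined quality
  expect_false(is_refined_quality(out)[2])
})
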