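# Synthetic data generators: 3-D protein-ligand complexes with realistic
# element composition and interatomic separations, affinity labels that
# are linear or nonlinear functions of the features with tunable noise,
# quality degradation (coordinate jitter + label noise emulating worse
# resolution and IC50-grade measurements), and index-file fixtures with
# controlled counts of each quality defect. All generators are pure
# functions of their seed and spec.

#' Specification of a synthetic complex
#'
#' Geometry: ligand heavy atoms are placed uniformly inside a spherical
#' binding pocket; protein heavy atoms in a shell around it; all
#' placements are rejection-sampled to respect a minimum interatomic
#' separation. Elements are drawn from per-role frequency tables chosen
#' to populate all 36 element-pair count features at moderate n.
#'
#' @param n_protein_atoms,n_ligand_atoms heavy-atom counts.
#' @param protein_freqs,ligand_freqs named element frequencies (sum 1).
#' @param pocket_radius ligand sphere radius, Angstrom.
#' @param shell_inner,shell_outer protein shell radii, Angstrom.
#' @param min_separation minimum interatomic distance, Angstrom.
#' @param nrot_range integer range (inclusive) for the ligand
#'   rotatable-bond count.
#' @param acceptor_prob,donor_prob probabilities that an N/O atom is
#'   flagged H-bond acceptor / donor.
#' @return a list of class `complex_gen_spec`.
#' @export
complex_gen_spec <- function(n_protein_atoms = 80L, n_ligand_atoms = 22L,
                             protein_freqs = c(C = 0.60, N = 0.16, O = 0.22, S = 0.02),
                             ligand_freqs = c(C = 0.70, N = 0.12, O = 0.13, S = 0.02,
                                              F = 0.01, P = 0.005, Cl = 0.01,
                                              Br = 0.0025, I = 0.0025),
                             pocket_radius = 5, shell_inner = 6.5,
                             shell_outer = 13, min_separation = 2.2,
                             nrot_range = c(0L, 12L),
                             acceptor_prob = 0.8, donor_prob = 0.5) {
  stopifnot(n_protein_atoms >= 1, n_ligand_atoms >= 1, min_separation > 0,
            abs(sum(protein_freqs) - 1) < 1e-6, abs(sum(ligand_freqs) - 1) < 1e-6)
  structure(as.list(environment()), class = "complex_gen_spec")
}

# uniform points in a sphere / spherical shell
.runif_sphere <- function(n, r_inner, r_outer) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- (runif(n, r_inner^3 / r_outer^3, 1))^(1 / 3) * r_outer
  u * r
}

# greedy min-separation placement with a retry cap
.place_points <- function(n, sampler, existing, min_sep, max_tries = 200L) {
  ref <- rbind(existing, matrix(NA_real_, n, 3))
  n_ref <- nrow(existing)
  n_have <- 0L
  min2 <- min_sep^2
  for (try in seq_len(max_tries)) {
    cand <- sampler(2L * n)
    # distances to all already-accepted points, batch-computed
    d2 <- if (n_ref + n_have > 0L)
      .cross_dist2(cand, ref[seq_len(n_ref + n_have), , drop = FALSE])
    else matrix(Inf, nrow(cand), 1)
    ok_prev <- rowSums(d2 < min2) == 0L
    for (i in which(ok_prev)) {
      if (n_have > 0L) {  # also check against points accepted this batch
        new <- ref[n_ref + seq_len(n_have), , drop = FALSE]
        if (min(.cross_dist2(cand[i, , drop = FALSE], new)) < min2) next
      }
      n_have <- n_have + 1L
      ref[n_ref + n_have, ] <- cand[i, ]
      if (n_have == n)
        return(ref[n_ref + seq_len(n), , drop = FALSE])
    }
  }
  stop("rejection sampling failed; enlarge the box or reduce min_separation",
       call. = FALSE)
}

.gen_atoms <- function(n, freqs, coords, role, spec, config) {
  el <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  no <- el %in% c("N", "O")
  typed_atoms(el, coords[, 1], coords[, 2], coords[, 3], role = role,
              is_hydrophobic = el == "C",
              is_hbond_acceptor = no & runif(n) < spec$acceptor_prob,
              is_hbond_donor = no & runif(n) < spec$donor_prob,
              config = config)
}

#' Generate one synthetic protein-ligand complex
#'
#' Deterministic given `seed` and `spec` (the caller's RNG state is left
#' untouched).
#'
#' @param spec a [complex_gen_spec()].
#' @param seed integer seed, or `NULL` to consume the current RNG stream.
#' @param id complex identifier.
#' @param config configuration list from [vf_config()].
#' @return a [molecular_complex()].
#' @export
gen_complex <- function(spec = complex_gen_spec(), seed = NULL, id = "syn1",
                        config = vf_config()) {
  with_seed(seed, {
    lig_xyz <- .place_points(spec$n_ligand_atoms,
                             function(m) .runif_sphere(m, 0, spec$pocket_radius),
                             matrix(numeric(0), 0, 3), spec$min_separation)
    prot_xyz <- .place_points(spec$n_protein_atoms,
                              function(m) .runif_sphere(m, spec$shell_inner,
                                                        spec$shell_outer),
                              lig_xyz, spec$min_separation)
    lig <- .gen_atoms(spec$n_ligand_atoms, spec$ligand_freqs, lig_xyz,
                      "ligand", spec, config)
    prot <- .gen_atoms(spec$n_protein_atoms, spec$protein_freqs, prot_xyz,
                       "protein", spec, config)
    nrot <- sample(seq(spec$nrot_range[1], spec$nrot_range[2]), 1L)
    molecular_complex(id, prot, lig, nrot)
  })
}

#' Generate a set of synthetic complexes
#'
#' @inheritParams gen_complex
#' @param n number of complexes.
#' @param id_prefix prefix for the generated ids (`syn00001`, ...).
#' @return a list of [molecular_complex()] objects.
#' @export
gen_complex_set <- function(n, spec = complex_gen_spec(), seed = 1L,
                            id_prefix = "syn", config = vf_config()) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      gen_complex(spec, seed = NULL,
                  id = sprintf("%s%05d", id_prefix, i), config = config)
    })
  })
}

#' Specification of synthetic affinity labels
#'
#' Linear mechanism: `y = beta0 + beta . x + eps` on the raw features.
#' Nonlinear mechanism: the features are z-scored, a linear part is
#' combined with pairwise products and sign-threshold terms of randomly
#' chosen feature columns, each part scaled to unit standard deviation
#' (the nonlinear part to `nonlinear_strength`), plus Gaussian noise.
#' Coefficients left `NULL` are drawn from the spec seed and stored with
#' the labels, so generation is reproducible and recoverable.
#'
#' @param mechanism `"linear"` or `"nonlinear"`.
#' @param beta0 intercept (pKd units).
#' @param beta coefficient vector, or `NULL` to draw from the seed.
#' @param noise_sd Gaussian noise s.d., pKd units.
#' @param nonlinear_strength s.d. of the nonlinear part relative to the
#'   (unit-s.d.) linear part.
#' @param n_pairs,n_thresholds number of pairwise-product and threshold
#'   terms of the nonlinear recipe.
#' @param seed integer seed for coefficient draws and noise.
#' @return a list of class `label_gen_spec`.
#' @export
label_gen_spec <- function(mechanism = c("linear", "nonlinear"),
                           beta0 = 6, beta = NULL, noise_sd = 0.5,
                           nonlinear_strength = 1, n_pairs = 6L,
                           n_thresholds = 3L, seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(noise_sd >= 0)
  structure(as.list(environment()), class = "label_gen_spec")
}

#' Generate affinity labels from a feature table
#'
#' Applies the generating mechanism of a [label_gen_spec()] to a feature
#' table (train and test rows should be passed together so that the
#' nonlinear recipe's z-scoring is shared). The generating parameters are
#' attached as the `"generator"` attribute.
#'
#' @param features a feature table from [featurize_set()] (an `id`
#'   column is ignored).
#' @param spec a [label_gen_spec()].
#' @return numeric vector of p-affinities, one per row.
#' @export
gen_labels <- function(features, spec = label_gen_spec()) {
  X <- as.matrix(.drop_id(features))
  n <- nrow(X); p <- ncol(X)
  with_seed(spec$seed, {
    if (spec$mechanism == "linear") {
      beta <- spec$beta %||% rnorm(p)
      stopifnot(length(beta) == p)
      y <- spec$beta0 + as.vector(X %*% beta) +
        (if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0)
      gen <- list(spec = spec, beta = setNames(beta, colnames(X)))
    } else {
      sds <- apply(X, 2, sd)
      usable <- which(sds > 0)
      Z <- scale(X[, usable, drop = FALSE])
      beta <- spec$beta %||% rnorm(length(usable))
      lp <- as.vector(Z %*% beta)
      lp <- lp / max(sd(lp), 1e-12)
      pairs <- matrix(sample(length(usable), 2L * spec$n_pairs, replace = TRUE),
                      ncol = 2)
      gamma <- rnorm(spec$n_pairs)
      thr_cols <- sample(length(usable), spec$n_thresholds, replace = TRUE)
      delta <- rnorm(spec$n_thresholds)
      nl <- as.vector((Z[, pairs[, 1], drop = FALSE] *
                         Z[, pairs[, 2], drop = FALSE]) %*% gamma) +
        as.vector((Z[, thr_cols, drop = FALSE] > 0) %*% delta)
      nl <- nl / max(sd(nl), 1e-12) * spec$nonlinear_strength
      y <- spec$beta0 + lp + nl +
        (if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0)
      gen <- list(spec = spec, beta = beta, pairs = pairs, gamma = gamma,
                  thr_cols = thr_cols, delta = delta,
                  center = attr(Z, "scaled:center"),
                  scale = attr(Z, "scaled:scale"), usable = usable)
    }
    attr(y, "generator") <- gen
    y
  })
}

#' Specification of quality degradation
#'
#' Emulates low-quality data: i.i.d. Gaussian coordinate jitter stands in
#' for worse crystallographic resolution (annotated resolution is
#' `jitter_sd / 0.1`, i.e. 0.1 Angstrom of jitter per Angstrom of
#' resolution), and a per-record bias plus extra noise on the labels
#' stands in for IC50-grade measurement heterogeneity (degraded records
#' are annotated `IC50`).
#'
#' @param jitter_sd coordinate jitter s.d., Angstrom.
#' @param label_bias_sd s.d. of the per-record label bias, pKd units.
#' @param label_noise_sd extra label noise s.d., pKd units.
#' @param fraction fraction of records degraded, in `[0, 1]`.
#' @return a list of class `degrade_spec`.
#' @export
degrade_spec <- function(jitter_sd = 0.35, label_bias_sd = 0.5,
                         label_noise_sd = 0.5, fraction = 1) {
  stopifnot(jitter_sd >= 0, label_bias_sd >= 0, label_noise_sd >= 0,
            fraction >= 0, fraction <= 1)
  structure(as.list(environment()), class = "degrade_spec")
}

#' Degrade complexes and labels
#'
#' Applies a [degrade_spec()] to a set of complexes and their labels.
#' The returned annotations table is index-record shaped (consumable by
#' [is_refined_quality()] and [make_tier()]): degraded records carry the
#' jitter-implied resolution and `IC50` measurement kind, clean records a
#' 2.0 Angstrom resolution and exact `Kd`.
#'
#' @param complexes list of [molecular_complex()] objects.
#' @param labels numeric labels, one per complex.
#' @param spec a [degrade_spec()].
#' @param seed integer seed.
#' @param year annotation year for the emitted records.
#' @return a list with `complexes`, `labels`, and `annotations` (a
#'   `data.frame` with a `degraded` column appended).
#' @export
degrade <- function(complexes, labels, spec = degrade_spec(), seed = 1L,
                    year = 2012L) {
  n <- length(complexes)
  stopifnot(length(labels) == n)
  with_seed(seed, {
    n_deg <- round(spec$fraction * n)
    deg <- sort(sample(n, n_deg))
    is_deg <- seq_len(n) %in% deg
    out_cx <- complexes
    out_y <- as.numeric(labels)
    for (i in deg) {
      cx <- out_cx[[i]]
      if (spec$jitter_sd > 0) {
        jit <- function(df) {
          df$x <- df$x + rnorm(nrow(df), 0, spec$jitter_sd)
          df$y <- df$y + rnorm(nrow(df), 0, spec$jitter_sd)
          df$z <- df$z + rnorm(nrow(df), 0, spec$jitter_sd)
          df
        }
        cx$protein <- jit(cx$protein)
        cx$ligand <- jit(cx$ligand)
      }
      out_cx[[i]] <- cx
      out_y[i] <- out_y[i] +
        (if (spec$label_bias_sd > 0) rnorm(1, 0, spec$label_bias_sd) else 0) +
        (if (spec$label_noise_sd > 0) rnorm(1, 0, spec$label_noise_sd) else 0)
    }
    ids <- vapply(out_cx, `[[`, character(1), "id")
    ann <- .index_df(
      code = ids,
      resolution = ifelse(is_deg, spec$jitter_sd / 0.1, 2.0),
      nmr = FALSE, year = year, p_affinity = out_y,
      measure_kind = ifelse(is_deg, "IC50", "Kd"),
      exact = TRUE)
    ann$degraded <- is_deg
    list(complexes = out_cx, labels = out_y, annotations = ann)
  })
}

# unique 4-character PDB-like codes: digit + three letters
.make_codes <- function(n) {
  stopifnot(n <= 9 * 26^3)
  i <- seq_len(n) - 1L
  paste0((i %% 9) + 1,
         letters[(i %/% 9) %% 26 + 1],
         letters[(i %/% (9 * 26)) %% 26 + 1],
         letters[(i %/% (9 * 26^2)) %% 26 + 1])
}

.molar_string <- function(p_affinity, kind, qualifier) {
  molar <- 10^(-p_affinity)
  unit <- vapply(molar, function(m) {
    names(.affinity_units)[max(1L, findInterval(m, .affinity_units))]
  }, character(1))
  val <- molar / .affinity_units[unit]
  sprintf("%s%s%.4g%s", kind, qualifier, val, unit)
}

#' Generate a synthetic index fixture
#'
#' Emits a PDBbind-style index with exactly the requested number of
#' records per quality class (classes disjoint), deterministically
#' shuffled, parseable by [parse_index()]. Recognized classes: `clean`
#' (survives the general filters; resolutions up to 4.6 Angstrom and
#' Kd/Ki/IC50 kinds so the quality tiers are populated), `approximate`,
#' `nmr`, and every defect code (`non_protein_ligand`,
#' `conversion_failed`, `covalent`, `uncommon_element`, `peptide_ge10`,
#' `nucleotide_ge4`, `incomplete`, `multi_ligand`).
#'
#' @param composition named integer vector of per-class counts.
#' @param seed integer seed.
#' @param year index year stamp.
#' @return a list with `text` (index lines), `records` (the parsed
#'   records) and `bookkeeping` (`data.frame` of code / class).
#' @export
gen_index <- function(composition = c(clean = 50, approximate = 3, nmr = 2),
                      seed = 1L, year = 2012L) {
  classes <- names(composition)
  known <- c("clean", "approximate", "nmr", .defect_codes)
  if (is.null(classes) || !all(classes %in% known))
    stop("unknown index classes: ",
         paste(setdiff(classes, known), collapse = ", "), call. = FALSE)
  stopifnot(all(composition >= 0))
  n <- sum(composition)
  with_seed(seed, {
    class_of <- rep(classes, composition)
    codes <- .make_codes(n)
    resolution <- round(runif(n, 1.2, 4.6), 2)
    kind <- sample(c("Kd", "Ki", "IC50"), n, replace = TRUE,
                   prob = c(0.33, 0.32, 0.35))
    qualifier <- rep("=", n)
    paff <- round(runif(n, 2, 11), 2)
    res_tok <- sprintf("%.2f", resolution)
    is_nmr <- class_of == "nmr"
    res_tok[is_nmr] <- "NMR"
    approx <- class_of == "approximate"
    qualifier[approx] <- sample(c("~", "<", ">"), sum(approx), replace = TRUE)
    kind[is_nmr] <- "Kd"
    flags <- rep("-", n)
    defect <- class_of %in% .defect_codes
    flags[defect] <- paste0("flags=", class_of[defect])
    ord <- sample(n)
    lines <- sprintf("%s  %s  %d  %5.2f  %-14s %s",
                     codes, res_tok, year, paff,
                     .molar_string(paff, kind, qualifier), flags)[ord]
    header <- sprintf("# synthetic index fixture (%d records)", n)
    text <- c(header, lines)
    list(text = text,
         records = parse_index(text, source = "gen_index"),
         bookkeeping = data.frame(code = codes, class = class_of,
                                  stringsAsFactors = FALSE)[ord, ])
  })
}
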