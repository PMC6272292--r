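# Descriptors of a protein-ligand pose: the five Vina intermolecular
# terms (+ Nrot -> "vina6"), the 36 element-pair occurrence counts within
# 12 A ("vinaelem42" appends them to vina6), the Vina composite score, and
# the NHA/MWT baselines.

.vina6_names <- c("gauss1", "gauss2", "repulsion", "hydrophobic", "hbond", "nrot")

#' Frozen feature orderings
#'
#' Returns the frozen, versioned column order of a feature scheme:
#' `vina6` is gauss1, gauss2, repulsion, hydrophobic, hbond, nrot;
#' `vinaelem42` appends the 36 element-pair counts named
#' `<protein element>.<ligand element>` in protein-major order over
#' protein elements C, N, O, S and ligand elements C, N, O, F, P, S, Cl,
#' Br, I. Trained models are only portable across tables that use this
#' exact order.
#'
#' @param scheme `"vina6"` or `"vinaelem42"`.
#' @param config configuration list from [vf_config()].
#' @return character vector of feature names.
#' @export
feature_names <- function(scheme = c("vina6", "vinaelem42"),
                          config = vf_config()) {
  scheme <- match.arg(scheme)
  if (scheme == "vina6") return(.vina6_names)
  pairs <- as.vector(t(outer(config$rf_counts$protein_elements,
                             config$rf_counts$ligand_elements, paste, sep = ".")))
  c(.vina6_names, pairs)
}

#' Surface distance between two atoms
#'
#' Euclidean distance minus the two van der Waals radii; negative when the
#' spheres overlap. This is the argument of all five Vina term functions.
#'
#' @param atom_i,atom_j single rows of a typed-atom table.
#' @return numeric scalar, in Angstrom.
#' @examples
#' a <- typed_atoms("C", 0, 0, 0, "ligand")
#' b <- typed_atoms("C", 3.8, 0, 0, "protein")
#' surface_distance(a, b)  # 3.8 - 1.9 - 1.9 = 0
#' @export
surface_distance <- function(atom_i, atom_j) {
  r <- sqrt((atom_i$x - atom_j$x)^2 + (atom_i$y - atom_j$y)^2 +
            (atom_i$z - atom_j$z)^2)
  r - atom_i$vdw_radius - atom_j$vdw_radius
}

#' The five Vina pair potentials
#'
#' Evaluates gauss1 `exp(-(d/0.5)^2)`, gauss2 `exp(-((d-3)/2)^2)`,
#' repulsion `d^2` for `d < 0` (else 0), and the two linear ramps:
#' hydrophobic 1 -> 0 over d in \[0.5, 1.5\] (hydrophobic-hydrophobic
#' pairs only) and hbond 1 -> 0 over d in \[-0.7, 0\] (donor-acceptor
#' pairs only). Vectorized over `d`.
#'
#' @param d surface distance(s), Angstrom.
#' @param hydrophobic_pair,donor_acceptor_pair logical, recycled along `d`:
#'   eligibility of the pair for the hydrophobic / hbond ramps.
#' @param config configuration list from [vf_config()].
#' @return a matrix with one row per `d` and columns gauss1, gauss2,
#'   repulsion, hydrophobic, hbond.
#' @export
vina_pair_terms <- function(d, hydrophobic_pair = FALSE,
                            donor_acceptor_pair = FALSE,
                            config = vf_config()) {
  v <- config$vina
  n <- length(d)
  hydrophobic_pair <- rep_len(hydrophobic_pair, n)
  donor_acceptor_pair <- rep_len(donor_acceptor_pair, n)
  ramp <- function(d, lo, hi) {  # 1 below lo, 0 above hi, linear between
    pmin(1, pmax(0, (hi - d) / (hi - lo)))
  }
  cbind(
    gauss1 = exp(-(d / v$gauss1_width)^2),
    gauss2 = exp(-((d - v$gauss2_offset) / v$gauss2_width)^2),
    repulsion = ifelse(d < 0, d^2, 0),
    hydrophobic = ifelse(hydrophobic_pair,
                         ramp(d, v$hydrophobic_range[1], v$hydrophobic_range[2]), 0),
    hbond = ifelse(donor_acceptor_pair,
                   ramp(d, v$hbond_range[1], v$hbond_range[2]), 0)
  )
}

# pairwise intermolecular geometry shared by the featurizers
.pair_geometry <- function(cx) {
  p <- cx$protein; l <- cx$ligand
  pc <- as.matrix(p[, c("x", "y", "z")])
  lc <- as.matrix(l[, c("x", "y", "z")])
  r <- sqrt(.cross_dist2(pc, lc))           # protein x ligand distances
  list(r = r,
       d = r - outer(p$vdw_radius, l$vdw_radius, "+"),
       hydrophobic_pair = outer(p$is_hydrophobic, l$is_hydrophobic, "&"),
       donor_acceptor_pair =
         outer(p$is_hbond_donor, l$is_hbond_acceptor, "&") |
         outer(p$is_hbond_acceptor, l$is_hbond_donor, "&"))
}

#' Vina feature vector of a complex
#'
#' Sums each of the five Vina pair potentials over all intermolecular
#' heavy-atom pairs whose surface distance is at most the cutoff
#' (8 Angstrom by default), and appends the ligand rotatable-bond count.
#'
#' @param cx a [molecular_complex()].
#' @param config configuration list from [vf_config()].
#' @return named numeric vector of length 6 (scheme `vina6`).
#' @export
vina_features <- function(cx, config = vf_config()) {
  stopifnot(inherits(cx, "molecular_complex"))
  if (nrow(cx$protein) == 0L || nrow(cx$ligand) == 0L)
    stop("vina_features: empty atom list", call. = FALSE)
  g <- .pair_geometry(cx)
  sel <- g$d <= config$vina$cutoff
  out <- c(0, 0, 0, 0, 0)
  if (any(sel)) {
    terms <- vina_pair_terms(g$d[sel], g$hydrophobic_pair[sel],
                             g$donor_acceptor_pair[sel], config = config)
    out <- colSums(terms)
  }
  setNames(c(out, cx$n_rotatable_bonds), .vina6_names)
}

#' Element-pair occurrence counts
#'
#' Counts, for each (protein element, ligand element) pair over protein
#' elements C, N, O, S and ligand elements C, N, O, F, P, S, Cl, Br, I,
#' the number of intermolecular heavy-atom pairs within `cutoff` Angstrom
#' plain Euclidean distance (pairs at exactly the cutoff are included).
#' Atoms of other elements are ignored by this descriptor.
#'
#' @param cx a [molecular_complex()].
#' @param cutoff distance cutoff in Angstrom (default 12).
#' @param config configuration list from [vf_config()].
#' @return named integer vector of length 36, in the frozen
#'   [feature_names()] order.
#' @export
rf_counts <- function(cx, cutoff = NULL, config = vf_config()) {
  stopifnot(inherits(cx, "molecular_complex"))
  if (is.null(cutoff)) cutoff <- config$rf_counts$cutoff
  pe <- config$rf_counts$protein_elements
  le <- config$rf_counts$ligand_elements
  g <- .pair_geometry(cx)
  within <- g$r <= cutoff
  pf <- factor(cx$protein$element, levels = pe)
  lf <- factor(cx$ligand$element, levels = le)
  counts <- matrix(0L, length(pe), length(le), dimnames = list(pe, le))
  ok <- which(within, arr.ind = TRUE)
  if (nrow(ok)) {
    keep <- !is.na(pf[ok[, 1]]) & !is.na(lf[ok[, 2]])
    ok <- ok[keep, , drop = FALSE]
  }
  if (nrow(ok)) {
    tab <- table(pf[ok[, 1]], lf[ok[, 2]])  # complete over factor levels
    counts[] <- as.integer(tab)
  }
  setNames(as.integer(t(counts)), as.vector(t(outer(pe, le, paste, sep = "."))))
}

#' Vina composite score of a complex
#'
#' The off-the-shelf classical scoring function: the weighted sum of the
#' five term sums divided by `1 + w_nrot * Nrot` gives an intermolecular
#' energy e (kcal/mol); the returned prediction is `-e / 1.3637` so that
#' outputs are on the pKd scale (RT ln 10 at ~298 K).
#'
#' @param cx a [molecular_complex()].
#' @param config configuration list from [vf_config()]; `config$vina$weights`
#'   and `config$vina$w_nrot` are the model's parameters.
#' @return predicted pKd (numeric scalar).
#' @export
vina_score <- function(cx, config = vf_config()) {
  f <- vina_features(cx, config = config)
  vina_score_from_features(rbind(f), config = config)[1]
}

#' Vina score from a vina6 feature table
#'
#' Applies the Vina composite to precomputed features; the first five
#' columns must be the term sums and the sixth the rotatable-bond count
#' (any extra columns are ignored).
#'
#' @param X a matrix/data.frame whose first 6 columns follow the `vina6`
#'   ordering of [feature_names()].
#' @param config configuration list from [vf_config()].
#' @return numeric vector of predicted pKd, one per row.
#' @export
vina_score_from_features <- function(X, config = vf_config()) {
  X <- as.matrix(X[, seq_len(6), drop = FALSE])
  v <- config$vina
  e <- as.vector(X[, 1:5] %*% v$weights) / (1 + v$w_nrot * X[, 6])
  -e / v$kcal_per_pk
}

#' Size baselines of a ligand
#'
#' NHA is the number of ligand heavy atoms; MWT the sum of their standard
#' atomic weights (a hydrogen-free approximation of molecular weight).
#' Both serve as trivial baseline scoring functions.
#'
#' @param cx a [molecular_complex()].
#' @param config configuration list from [vf_config()].
#' @return a list with `nha` (integer) and `mwt` (numeric, Dalton).
#' @export
baseline_descriptors <- function(cx, config = vf_config()) {
  el <- cx$ligand$element
  m <- config$masses[el]
  if (anyNA(m))
    stop(structure(class = c("vf_unknown_element", "error", "condition"),
                   list(message = paste0("unknown element: ",
                                         paste(unique(el[is.na(m)]), collapse = ", ")),
                        call = sys.call(-1))))
  list(nha = nrow(cx$ligand), mwt = unname(sum(m)))
}

#' Featurize a set of complexes
#'
#' Builds a feature table with one row per complex, in input order, under
#' scheme `vina6` (6 columns) or `vinaelem42` (the 6 Vina features
#' followed by the 36 element-pair counts). Complexes that fail to
#' featurize are reported in the `rejects` attribute (id + message), never
#' silently dropped.
#'
#' @param complexes a list of [molecular_complex()] objects.
#' @param scheme `"vina6"` or `"vinaelem42"`.
#' @param config configuration list from [vf_config()].
#' @return a `data.frame` with an `id` column followed by the named
#'   features; attribute `rejects` is a data.frame of failures.
#' @export
featurize_set <- function(complexes, scheme = c("vina6", "vinaelem42"),
                          config = vf_config()) {
  scheme <- match.arg(scheme)
  fn <- feature_names(scheme, config)
  vals <- matrix(NA_real_, length(complexes), length(fn),
                 dimnames = list(NULL, fn))
  ids <- character(length(complexes))
  rejects <- list()
  for (i in seq_along(complexes)) {
    cx <- complexes[[i]]
    ids[i] <- cx$id
    res <- tryCatch({
      v <- vina_features(cx, config = config)
      if (scheme == "vinaelem42") v <- c(v, rf_counts(cx, config = config))
      v
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(id = cx$id, message = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      vals[i, ] <- res
    }
  }
  keep <- !is.na(vals[, 1])
  out <- cbind(data.frame(id = ids[keep], stringsAsFactors = FALSE),
               as.data.frame(vals[keep, , drop = FALSE]))
  attr(out, "rejects") <- if (length(rejects)) do.call(rbind, rejects)
    else data.frame(id = character(), message = character())
  out
}

#' Write / read a feature table as CSV
#'
#' Plain CSV with a header row carrying the frozen feature names; a
#' round-trip reproduces the table.
#'
#' @param features a feature table from [featurize_set()].
#' @param path file path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the table.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$id <- as.character(df$id)
  df
}

#' Apply a rigid motion to a complex
#'
#' Rotates and translates every atom of both molecules by the same rigid
#' transform. All descriptors of this package are invariant under such
#' motions.
#'
#' @param cx a [molecular_complex()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return the transformed `molecular_complex`.
#' @export
rigid_transform <- function(cx, rotation = diag(3), translation = c(0, 0, 0)) {
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rotation)
    df$x <- xyz[, 1] + translation[1]
    df$y <- xyz[, 2] + translation[2]
    df$z <- xyz[, 3] + translation[3]
    df
  }
  cx$protein <- move(cx$protein)
  cx$ligand <- move(cx$ligand)
  cx
}
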