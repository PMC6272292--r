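# Independent brute-force oracles, deliberately written as plain double
# loops / textbook formulas so they share no code with the package's
# vectorized implementations. Atom columns are pulled into local vectors
# first so the loops stay affordable at a few hundred atoms.

oracle_vina_features <- function(cx, cutoff = 8) {
  p <- cx$protein; l <- cx$ligand
  px <- p$x; py <- p$y; pz <- p$z; pr <- p$vdw_radius
  ph <- p$is_hydrophobic; pd <- p$is_hbond_donor; pa <- p$is_hbond_acceptor
  lx <- l$x; ly <- l$y; lz <- l$z; lr <- l$vdw_radius
  lh <- l$is_hydrophobic; ld <- l$is_hbond_donor; la <- l$is_hbond_acceptor
  sums <- c(gauss1 = 0, gauss2 = 0, repulsion = 0, hydrophobic = 0, hbond = 0)
  for (i in seq_along(px)) {
    for (j in seq_along(lx)) {
      r <- sqrt((px[i] - lx[j])^2 + (py[i] - ly[j])^2 + (pz[i] - lz[j])^2)
      d <- r - pr[i] - lr[j]
      if (d > cutoff) next
      sums["gauss1"] <- sums["gauss1"] + exp(-(d / 0.5)^2)
      sums["gauss2"] <- sums["gauss2"] + exp(-((d - 3) / 2)^2)
      if (d < 0) sums["repulsion"] <- sums["repulsion"] + d^2
      if (ph[i] && lh[j]) {
        h <- if (d <= 0.5) 1 else if (d >= 1.5) 0 else (1.5 - d) / 1
        sums["hydrophobic"] <- sums["hydrophobic"] + h
      }
      if ((pd[i] && la[j]) || (pa[i] && ld[j])) {
        h <- if (d <= -0.7) 1 else if (d >= 0) 0 else -d / 0.7
        sums["hbond"] <- sums["hbond"] + h
      }
    }
  }
  c(sums, nrot = cx$n_rotatable_bonds)
}

oracle_rf_counts <- function(cx, cutoff = 12) {
  pe <- c("C", "N", "O", "S")
  le <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
  p <- cx$protein; l <- cx$ligand
  px <- p$x; py <- p$y; pz <- p$z; pel <- p$element
  lx <- l$x; ly <- l$y; lz <- l$z; lel <- l$element
  counts <- matrix(0L, length(pe), length(le), dimnames = list(pe, le))
  for (i in seq_along(px)) {
    if (!(pel[i] %in% pe)) next
    for (j in seq_along(lx)) {
      if (!(lel[j] %in% le)) next
      r <- sqrt((px[i] - lx[j])^2 + (py[i] - ly[j])^2 + (pz[i] - lz[j])^2)
      if (r <= cutoff)
        counts[pel[i], lel[j]] <- counts[pel[i], lel[j]] + 1L
    }
  }
  out <- integer(0)
  nms <- character(0)
  for (pp in pe) for (ll in le) {
    out <- c(out, counts[pp, ll]); nms <- c(nms, paste0(pp, ".", ll))
  }
  setNames(out, nms)
}

# textbook scoring-power metrics, sum-formula style
oracle_metrics <- function(p, y) {
  N <- length(y)
  rmse <- sqrt(sum((y - p)^2) / N)
  b <- (sum(p * y) - sum(p) * sum(y) / N) / (sum(p^2) - sum(p)^2 / N)
  a <- sum(y) / N - b * sum(p) / N
  sdv <- sqrt(sum((y - a - b * p)^2) / (N - 1))
  rp <- (sum(p * y) - sum(p) * sum(y) / N) /
    sqrt((sum(p^2) - sum(p)^2 / N) * (sum(y^2) - sum(y)^2 / N))
  pr <- rank(p); yr <- rank(y)
  rs <- (sum(pr * yr) - sum(pr) * sum(yr) / N) /
    sqrt((sum(pr^2) - sum(pr)^2 / N) * (sum(yr^2) - sum(yr)^2 / N))
  list(rmse = rmse, sd = sdv, rp = rp, rs = rs, a = a, b = b)
}

random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# two-atom toy complex at a chosen surface distance along x
toy_pair_complex <- function(d, el_p = "C", el_l = "C", nrot = 0,
                             donor_p = FALSE, acceptor_l = FALSE,
                             hydrophobic = el_p == "C" && el_l == "C") {
  cfg <- vf_config()
  rp <- unname(cfg$radii[el_p]); rl <- unname(cfg$radii[el_l])
  prot <- typed_atoms(el_p, 0, 0, 0, "protein",
                      is_hydrophobic = hydrophobic && el_p == "C",
                      is_hbond_donor = donor_p,
                      is_hbond_acceptor = FALSE)
  lig <- typed_atoms(el_l, d + rp + rl, 0, 0, "ligand",
                     is_hydrophobic = hydrophobic && el_l == "C",
                     is_hbond_donor = FALSE,
                     is_hbond_acceptor = acceptor_l)
  molecular_complex("toy", prot, lig, nrot)
}

# small hand-written PDBQT fixture: 3 heavy atoms + 1 polar hydrogen,
# 2 active torsions declared, 2 BRANCH records
fixture_pdbqt <- function() {
  c("REMARK  2 active torsions",
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  0.00  0.00    +0.000 C ",
    "ATOM      2  N1  LIG A   1       3.500   0.000   0.000  0.00  0.00    +0.000 NA",
    "ATOM      3  H1  LIG A   1       4.300   0.000   0.000  0.00  0.00    +0.000 HD",
    "ENDROOT",
    "BRANCH   1   4",
    "ATOM      4  O1  LIG A   1       0.000   4.200   0.000  0.00  0.00    +0.000 OA",
    "ENDBRANCH   1   4",
    "BRANCH   1   5",
    "ATOM      5  C2  LIG A   1       0.000   0.000   4.100  0.00  0.00    +0.000 A ",
    "ENDBRANCH   1   5",
    "TORSDOF 2")
}
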