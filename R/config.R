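# All numeric conventions of the scoring pipeline live here so that any of
# them can be revisited from one place (or overridden from a YAML file).

.vf_default_config <- function() {
  list(
    vina = list(
      # published Vina weights (Trott & Olson parameterization)
      weights = c(
        gauss1      = -0.035579,
        gauss2      = -0.005156,
        repulsion   =  0.840245,
        hydrophobic = -0.035069,
        hbond       = -0.587439
      ),
      w_nrot = 0.05846,
      gauss1_width = 0.5,        # exp(-(d/0.5)^2)
      gauss2_offset = 3,         # exp(-((d-3)/2)^2)
      gauss2_width = 2,
      hydrophobic_range = c(0.5, 1.5),  # linear 1 -> 0 ramp on d
      hbond_range = c(-0.7, 0),         # linear 1 -> 0 ramp on d
      cutoff = 8,                # Angstrom, on surface distance
      kcal_per_pk = 1.3637       # RT*ln(10) at ~298 K, kcal/mol per pK unit
    ),
    rf_counts = list(
      cutoff = 12,               # Angstrom, plain Euclidean distance
      protein_elements = c("C", "N", "O", "S"),
      ligand_elements  = c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
    ),
    # van der Waals radii (Angstrom) used for surface distances
    radii = c(
      C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1,
      F = 1.5, Cl = 1.8, Br = 2.0, I = 2.2
    ),
    default_radius = 1.2,        # metals and anything not in the table
    # standard atomic weights for the heavy-atom MWT baseline
    masses = c(
      C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
      F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904,
      B = 10.81, Se = 78.971, Si = 28.085,
      Na = 22.990, K = 39.098, Mg = 24.305, Ca = 40.078,
      Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693,
      Cu = 63.546, Zn = 65.38, Cd = 112.414, Hg = 200.592
    ),
    # distance (Angstrom) within which a polar heavy atom disqualifies a
    # carbon from being hydrophobic when no connectivity is available
    hydrophobic_fallback_dist = 1.9,
    # max distance (Angstrom) from a polar hydrogen for N/O donor detection
    polar_h_dist = 1.3,
    refined = list(
      resolution_max = 2.5,      # "better than 2.5 A", inclusive by default
      strict = FALSE             # TRUE switches <= 2.5 to < 2.5
    ),
    sd_denominator = "n-1"       # residual-SD convention; "n" also supported
  )
}

#' Configuration of scoring conventions
#'
#' Returns the list of numeric conventions used throughout the package:
#' Vina term constants and weights, the 8 Angstrom surface-distance cutoff,
#' the 12 Angstrom element-pair count cutoff and its element sets, van der
#' Waals radii, atomic masses, the kcal/mol-to-pK conversion, refined-set
#' resolution handling and the residual-SD denominator. Any element can be
#' overridden; nested lists are merged recursively.
#'
#' @param ... named overrides, e.g. `vina = list(cutoff = 10)`.
#' @return a named list of settings.
#' @examples
#' cfg <- vf_config()
#' cfg$vina$weights
#' vf_config(rf_counts = list(cutoff = 10))$rf_counts$cutoff
#' @export
vf_config <- function(...) {
  cfg <- .vf_default_config()
  dots <- list(...)
  if (length(dots) == 0L) return(cfg)
  if (is.null(names(dots)) || any(names(dots) == "")) {
    stop("vf_config() overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown vf_config() settings: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(cfg, dots)
}

#' Load configuration overrides from a YAML file
#'
#' Reads a YAML file whose top-level keys mirror [vf_config()] settings and
#' merges it over the defaults.
#'
#' @param path path to a YAML file.
#' @return a configuration list as from [vf_config()].
#' @export
vf_config_yaml <- function(path) {
  ov <- yaml::read_yaml(path)
  if (!is.list(ov)) stop("config file must contain a YAML mapping", call. = FALSE)
  # yaml reads numeric vectors as lists; flatten leaf lists of scalars
  ov <- rapply(ov, function(x) x, how = "replace")
  do.call(vf_config, ov)
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
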