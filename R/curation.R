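# PDBbind-style index parsing and the data-quality machinery: general-set
# filters, refined-set criteria, resolution / Kd-Ki quality tiers, blind
# time-stamped splits.

.defect_codes <- c("non_protein_ligand", "conversion_failed", "covalent",
                   "uncommon_element", "peptide_ge10", "nucleotide_ge4",
                   "incomplete", "multi_ligand")

.affinity_units <- c(fM = 1e-15, pM = 1e-12, nM = 1e-9, uM = 1e-6,
                     mM = 1e-3, M = 1)

# shared constructor so parsed indices and synthetic annotations agree
.index_df <- function(code, resolution, nmr, year, p_affinity,
                      measure_kind, exact, flags = NULL) {
  df <- data.frame(code = tolower(code), resolution = resolution, nmr = nmr,
                   year = as.integer(year), p_affinity = p_affinity,
                   measure_kind = measure_kind, exact = exact,
                   stringsAsFactors = FALSE)
  for (f in .defect_codes) {
    df[[f]] <- if (is.null(flags)) rep(FALSE, nrow(df))
      else f == flags | grepl(f, flags, fixed = TRUE)
  }
  df
}

#' Parse a PDBbind-style index file
#'
#' Whitespace-column dialect: PDB code, resolution (`"2.50"` or `"NMR"`),
#' year, p-affinity (-log10 of molar Kd/Ki/IC50), and an affinity string
#' such as `Ki=400mM`, `Kd~10uM` or `IC50=25nM`. Lines starting with `#`
#' are comments. A sixth column may carry defect annotations for
#' synthetic fixtures, as `flags=code1;code2` (or `-` for none). The
#' qualifier character of the affinity string sets `exact`: `=` is exact;
#' `~`, `<`, `>`, `<=`, `>=` (and the Unicode variants) are approximate.
#'
#' @param text file content: a single string or a character vector of lines.
#' @param source label for error messages.
#' @return a `data.frame` with one row per record: `code`, `resolution`
#'   (numeric, `NA` for NMR entries), `nmr`, `year`, `p_affinity`,
#'   `measure_kind` (`Kd`/`Ki`/`IC50`), `exact`, and one logical column
#'   per defect code.
#' @export
parse_index <- function(text, source = "index") {
  lines <- .as_lines(text)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(.index_df(character(), numeric(), logical(), integer(),
                     numeric(), character(), logical()))
  }
  toks <- strsplit(lines, "\\s+")
  nt <- lengths(toks)
  if (any(nt < 5L)) {
    bad <- which(nt < 5L)[1]
    stop(sprintf("%s: malformed line %d: '%s'", source, bad, lines[bad]),
         call. = FALSE)
  }
  code <- vapply(toks, `[[`, character(1), 1L)
  res_tok <- vapply(toks, `[[`, character(1), 2L)
  nmr <- toupper(res_tok) == "NMR"
  resolution <- suppressWarnings(as.numeric(res_tok))
  if (any(!nmr & !is.finite(resolution))) {
    bad <- which(!nmr & !is.finite(resolution))[1]
    stop(sprintf("%s: malformed resolution at line %d: '%s'", source, bad, lines[bad]),
         call. = FALSE)
  }
  year <- suppressWarnings(as.integer(vapply(toks, `[[`, character(1), 3L)))
  paff <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 4L)))
  if (any(!is.finite(paff)) || any(is.na(year))) {
    bad <- which(!is.finite(paff) | is.na(year))[1]
    stop(sprintf("%s: malformed line %d: '%s'", source, bad, lines[bad]),
         call. = FALSE)
  }
  aff <- vapply(toks, `[[`, character(1), 5L)
  m <- regexec("^(Kd|Ki|IC50)(<=|>=|[=~<>≤≥])([0-9.eE+-]+)([a-zA-Z]+)$",
               aff, ignore.case = TRUE)
  parts <- regmatches(aff, m)
  bad <- which(lengths(parts) != 5L)
  if (length(bad)) {
    stop(sprintf("%s: unparseable affinity '%s' at line %d", source, aff[bad[1]], bad[1]),
         call. = FALSE)
  }
  kind_raw <- vapply(parts, `[[`, character(1), 2L)
  kind <- c(kd = "Kd", ki = "Ki", ic50 = "IC50")[tolower(kind_raw)]
  qual <- vapply(parts, `[[`, character(1), 3L)
  unit <- vapply(parts, `[[`, character(1), 5L)
  if (any(!unit %in% names(.affinity_units))) {
    bad <- which(!unit %in% names(.affinity_units))[1]
    stop(sprintf("%s: unknown affinity unit '%s' at line %d", source, unit[bad], bad),
         call. = FALSE)
  }
  flags <- rep(NA_character_, length(lines))
  has6 <- nt >= 6L
  f6 <- vapply(toks[has6], `[[`, character(1), 6L)
  is_flag <- startsWith(f6, "flags=")
  flags[which(has6)[is_flag]] <- sub("^flags=", "", f6[is_flag])
  flags[is.na(flags) | flags == "-"] <- ""
  df <- .index_df(code, resolution, nmr, year, paff, unname(kind),
                  qual == "=", flags)
  df
}

#' Sequential general-set quality filters
#'
#' Applies, in this fixed order, the four filters that turn a raw
#' general-set index into usable X-ray protein-ligand complexes: remove
#' (1) non-protein-ligand complexes, (2) complexes whose PDB-to-PDBQT
#' conversion failed, (3) approximate binding measurements (qualifier
#' other than `=`), (4) NMR structures. The first matching reason wins,
#' so the per-reason removal counts always sum with the retained count to
#' the input count.
#'
#' @param records an index `data.frame` from [parse_index()].
#' @return a list with `retained` (the surviving records) and `removed`
#'   (a `data.frame` of reason / n, in filter order).
#' @export
apply_general_filters <- function(records) {
  reasons <- c("non_protein_ligand", "conversion_failed", "approximate", "nmr")
  removed <- setNames(integer(4), reasons)
  keep <- rep(TRUE, nrow(records))
  crit <- list(records$non_protein_ligand,
               records$conversion_failed,
               !records$exact,
               records$nmr)
  for (i in seq_along(reasons)) {
    hit <- keep & crit[[i]]
    removed[i] <- sum(hit)
    keep <- keep & !hit
  }
  list(retained = records[keep, , drop = FALSE],
       removed = data.frame(reason = reasons, n = unname(removed),
                            stringsAsFactors = FALSE))
}

#' Refined-set quality test
#'
#' A record is refined-set quality iff its resolution is at most 2.5
#' Angstrom (inclusive by default, switchable to strict `<`), the
#' structure is not NMR, the measurement is an exact Kd or Ki, and none
#' of the structural defect flags (covalent binding, uncommon elements,
#' long peptide or nucleotide ligand, incomplete structure, multiple
#' ligands, non-protein-ligand) is set. Flags that cannot be computed
#' from an index line (completeness, covalency, ...) are expected to come
#' from annotations.
#'
#' @param records an index `data.frame`.
#' @param config configuration list from [vf_config()];
#'   `config$refined$resolution_max` and `config$refined$strict` control
#'   the resolution rule.
#' @return logical vector, one per record.
#' @export
is_refined_quality <- function(records, config = vf_config()) {
  rmax <- config$refined$resolution_max
  res_ok <- !records$nmr & is.finite(records$resolution) &
    if (isTRUE(config$refined$strict)) records$resolution < rmax
    else records$resolution <= rmax
  defects <- c("covalent", "uncommon_element", "peptide_ge10",
               "nucleotide_ge4", "incomplete", "multi_ligand",
               "non_protein_ligand")
  no_defect <- !Reduce(`|`, records[defects])
  res_ok & records$measure_kind %in% c("Kd", "Ki") & records$exact & no_defect
}

#' Quality-tier specification
#'
#' A training-set tier is defined by an optional maximum resolution, an
#' optional restriction to Kd/Ki measurements, and optionally the full
#' refined-set criteria. `refined_only` implies `kdki_only` and a
#' resolution cap of at most 2.5 Angstrom.
#'
#' @param resolution_max numeric (Angstrom) or `NULL` for no cap.
#' @param kdki_only keep only Kd/Ki records?
#' @param refined_only additionally require [is_refined_quality()]?
#' @return a list of class `tier_spec`.
#' @export
tier_spec <- function(resolution_max = NULL, kdki_only = FALSE,
                      refined_only = FALSE) {
  if (refined_only) {
    kdki_only <- TRUE
    if (is.null(resolution_max)) resolution_max <- 2.5
    if (resolution_max > 2.5)
      stop("refined_only implies resolution_max <= 2.5", call. = FALSE)
  }
  structure(list(resolution_max = resolution_max, kdki_only = kdki_only,
                 refined_only = refined_only),
            class = "tier_spec")
}

#' Extract a quality tier from filtered records
#'
#' Keeps records whose numeric resolution is at most the tier's cap (no
#' cap keeps everything), whose measurement kind is Kd/Ki when the tier
#' demands it, and, for refined tiers, which pass [is_refined_quality()].
#' Tiers are nested: relaxing the cap or the Kd/Ki restriction never
#' shrinks the subset.
#'
#' @param records an index `data.frame`, already general-filtered.
#' @param tier a [tier_spec()].
#' @param config configuration list from [vf_config()].
#' @return the subset of `records`, original order preserved.
#' @export
make_tier <- function(records, tier, config = vf_config()) {
  stopifnot(inherits(tier, "tier_spec"))
  keep <- rep(TRUE, nrow(records))
  if (!is.null(tier$resolution_max)) {
    keep <- keep & !records$nmr & is.finite(records$resolution) &
      records$resolution <= tier$resolution_max
  }
  if (tier$kdki_only) keep <- keep & records$measure_kind %in% c("Kd", "Ki")
  if (tier$refined_only) keep <- keep & is_refined_quality(records, config)
  records[keep, , drop = FALSE]
}

#' Blind time-stamped test split
#'
#' The test codes are the set difference new release minus old release,
#' guaranteeing that a model trained on the old release has never seen a
#' test complex. Codes are normalized to lowercase.
#'
#' @param new_release,old_release character vectors of PDB codes.
#' @return character vector of test codes.
#' @export
blind_split <- function(new_release, old_release) {
  setdiff(tolower(new_release), tolower(old_release))
}

#' Remove records by PDB code
#'
#' @param records an index `data.frame`.
#' @param codes character vector of codes to drop (case-insensitive).
#' @return `records` minus those codes, order preserved.
#' @export
subtract_codes <- function(records, codes) {
  records[!records$code %in% tolower(codes), , drop = FALSE]
}

#' Merge sidecar defect annotations into index records
#'
#' For real PDBbind-style data the defect flags that cannot be derived
#' from an index line (covalency, completeness, ...) come from a sidecar
#' CSV with a `code` column and one logical/0-1 column per defect code;
#' this merges them (logical OR) into the records.
#'
#' @param records an index `data.frame`.
#' @param annotations a `data.frame` with `code` plus defect columns, or
#'   a path to such a CSV.
#' @return the annotated records.
#' @export
apply_annotations <- function(records, annotations) {
  if (is.character(annotations))
    annotations <- read.csv(annotations, stringsAsFactors = FALSE)
  annotations$code <- tolower(annotations$code)
  idx <- match(records$code, annotations$code)
  for (f in intersect(.defect_codes, names(annotations))) {
    ann <- as.logical(annotations[[f]])[idx]
    ann[is.na(ann)] <- FALSE
    records[[f]] <- records[[f]] | ann
  }
  records
}

#' Write a code list, one per line
#'
#' @param codes character vector of PDB codes.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_codes <- function(codes, path) {
  writeLines(tolower(codes), path)
  invisible(path)
}
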