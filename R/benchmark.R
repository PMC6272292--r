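# Benchmark orchestration: run a panel of scoring functions (Vina,
# MLR::Vina, RF::Vina, RF::VinaElem) over one test set and an ordered
# list of training sets, evaluate every seeded RF instance, and summarize
# by per-metric medians. Self-contained synthetic presets reproduce the
# study designs (data-volume trend, RF-vs-MLR, low-quality benefit)
# without any external data.

.all_models <- c("vina", "mlr_vina", "rf_vina", "rf_vinaelem")

#' Benchmark specification
#'
#' Names one test set and an ordered list of training sets (as complex
#' ids resolvable in a feature table), the models to run, and the RF
#' protocol. The test set must be disjoint from every training set;
#' this is asserted here and again before any training.
#'
#' @param name benchmark label.
#' @param test_ids character vector of test complex ids.
#' @param training_sets named list of character id vectors, in display
#'   order.
#' @param models subset of `"vina"`, `"mlr_vina"`, `"rf_vina"`,
#'   `"rf_vinaelem"`.
#' @param seeds RF seeds (default `1:10`).
#' @param n_trees trees per forest (default 500).
#' @param mtry_grid_vina6,mtry_grid_vinaelem42 optional mtry grids;
#'   default 1..6 and 1..42.
#' @return a list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(name, test_ids, training_sets,
                           models = .all_models, seeds = 1:10,
                           n_trees = 500L,
                           mtry_grid_vina6 = NULL,
                           mtry_grid_vinaelem42 = NULL) {
  models <- match.arg(models, .all_models, several.ok = TRUE)
  if (length(training_sets) < 1L) stop("need at least one training set", call. = FALSE)
  if (is.null(names(training_sets)) || any(names(training_sets) == ""))
    stop("training_sets must be named", call. = FALSE)
  for (lab in names(training_sets)) {
    ov <- intersect(tolower(test_ids), tolower(training_sets[[lab]]))
    if (length(ov))
      stop(sprintf("test set overlaps training set '%s' (%d shared ids)",
                   lab, length(ov)), call. = FALSE)
  }
  structure(list(name = name, test_ids = test_ids,
                 training_sets = training_sets, models = models,
                 seeds = as.integer(seeds), n_trees = as.integer(n_trees),
                 mtry_grid_vina6 = mtry_grid_vina6,
                 mtry_grid_vinaelem42 = mtry_grid_vinaelem42),
            class = "benchmark_spec")
}

.resolve_rows <- function(ids, features, labels, what, allow_missing) {
  miss <- setdiff(ids, intersect(features$id, names(labels)))
  if (length(miss)) {
    msg <- sprintf("%s: %d unresolvable id(s): %s", what, length(miss),
                   paste(head(miss, 5), collapse = ", "))
    if (!allow_missing) stop(msg, call. = FALSE)
    warning(paste0(msg, " (dropped)"), call. = FALSE)
    ids <- setdiff(ids, miss)
  }
  ids
}

#' Run a benchmark
#'
#' For each training set and model: train (Vina is applied off-the-shelf,
#' without training), predict the test set, and compute the scoring-power
#' metrics. RF models contribute one row per seed; Vina and MLR one
#' deterministic row each. All stochastic stages are seeded, so rerunning
#' with the same spec reproduces the table bit-for-bit.
#'
#' @param spec a [benchmark_spec()].
#' @param features feature table from [featurize_set()] (scheme
#'   `vinaelem42` when `rf_vinaelem` is among the models).
#' @param labels named numeric vector of measured affinities, indexed by
#'   complex id.
#' @param config configuration list from [vf_config()].
#' @param allow_missing drop unresolvable ids with a warning instead of
#'   aborting.
#' @return a `data.frame` of class `vf_results`: one row per (model,
#'   training set, seed) with the metric columns.
#' @export
run_benchmark <- function(spec, features, labels, config = vf_config(),
                          allow_missing = FALSE) {
  stopifnot(inherits(spec, "benchmark_spec"))
  test_ids <- .resolve_rows(spec$test_ids, features, labels, "test set",
                            allow_missing)
  v6 <- feature_names("vina6", config)
  need42 <- "rf_vinaelem" %in% spec$models
  v42 <- if (need42) feature_names("vinaelem42", config) else NULL
  if (need42 && !all(v42 %in% names(features)))
    stop("rf_vinaelem requires a vinaelem42 feature table", call. = FALSE)
  rowix <- setNames(seq_len(nrow(features)), features$id)
  Xtest6 <- features[rowix[test_ids], v6, drop = FALSE]
  ytest <- unname(labels[test_ids])
  rows <- list()
  add <- function(model, lab, train_n, seed, rep) {
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(benchmark = spec$name, model = model, training_label = lab,
                 train_n = train_n, seed = seed, stringsAsFactors = FALSE),
      as.data.frame(rep))
  }
  for (lab in names(spec$training_sets)) {
    tr_ids <- .resolve_rows(spec$training_sets[[lab]], features, labels,
                            paste0("training set '", lab, "'"), allow_missing)
    stopifnot(length(intersect(tr_ids, test_ids)) == 0L)
    Xtr6 <- features[rowix[tr_ids], v6, drop = FALSE]
    ytr <- unname(labels[tr_ids])
    n_tr <- length(tr_ids)
    for (model in spec$models) {
      if (model == "vina") {
        p <- vina_score_from_features(Xtest6, config = config)
        add(model, lab, n_tr, NA_integer_, compute_metrics(p, ytest, config))
      } else if (model == "mlr_vina") {
        fit <- fit_mlr(Xtr6, ytr)
        add(model, lab, n_tr, NA_integer_,
            compute_metrics(predict(fit, Xtest6), ytest, config))
      } else {
        if (model == "rf_vina") {
          Xtr <- Xtr6; Xte <- Xtest6
          rfc <- rf_config(length(v6), spec$n_trees,
                           spec$mtry_grid_vina6 %||% seq_along(v6), spec$seeds)
        } else {
          Xtr <- features[rowix[tr_ids], v42, drop = FALSE]
          Xte <- features[rowix[test_ids], v42, drop = FALSE]
          rfc <- rf_config(length(v42), spec$n_trees,
                           spec$mtry_grid_vinaelem42 %||% seq_along(v42),
                           spec$seeds)
        }
        ens <- fit_rf_ensemble(Xtr, ytr, rfc)
        for (m in ens$models) {
          add(model, lab, n_tr, m$seed,
              compute_metrics(predict(m, Xte), ytest, config))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vf_results", "data.frame")
  out
}

#' Median summary of benchmark results
#'
#' Collapses per-seed RF rows to the componentwise median per (benchmark,
#' model, training set); deterministic models pass through unchanged.
#' Rows are ordered by training label (in first-appearance order) then
#' model.
#'
#' @param results a `vf_results` table from [run_benchmark()].
#' @return a `data.frame` with one row per (benchmark, model, training
#'   set) and the median metric columns plus `n_seeds`.
#' @export
summarize_benchmark <- function(results) {
  if (nrow(results) == 0L) stop("empty results table", call. = FALSE)
  key <- interaction(results$benchmark, results$model,
                     results$training_label, drop = TRUE, lex.order = FALSE)
  parts <- split(seq_len(nrow(results)), key)
  out <- do.call(rbind, lapply(parts, function(ix) {
    g <- results[ix, , drop = FALSE]
    med <- median_summary(g[, c("rmse", "sd", "rp", "rs", "n", "a", "b")])
    cbind(data.frame(benchmark = g$benchmark[1], model = g$model[1],
                     training_label = g$training_label[1],
                     train_n = g$train_n[1], n_seeds = sum(!is.na(g$seed)),
                     stringsAsFactors = FALSE),
          as.data.frame(med))
  }))
  lab_order <- unique(results$training_label)
  mod_order <- unique(results$model)
  out <- out[order(match(out$training_label, lab_order),
                   match(out$model, mod_order)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge own results with published scoring-function values
#'
#' Stacks the package's evaluated models with a user-supplied table of
#' literature values (columns name, n, rp, sd) and ranks all rows by
#' Pearson correlation (descending; ties broken by SD ascending). Rows
#' that scored fewer complexes than the full test set are flagged.
#'
#' @param own `data.frame` with columns `name`, `n`, `rp`, `sd`.
#' @param external like `own`, printed literature values (optional).
#' @param test_n full test-set size; defaults to the largest `n` seen.
#' @return the merged, ranked `data.frame` with an `incomplete` flag.
#' @export
comparison_report <- function(own, external = NULL, test_n = NULL) {
  norm <- function(df) {
    names(df) <- tolower(names(df))
    df[, c("name", "n", "rp", "sd")]
  }
  tab <- norm(own)
  if (!is.null(external) && nrow(external)) tab <- rbind(tab, norm(external))
  if (is.null(test_n)) test_n <- max(tab$n)
  tab <- tab[order(-tab$rp, tab$sd), , drop = FALSE]
  tab$incomplete <- tab$n < test_n
  rownames(tab) <- NULL
  tab
}

#' Boxplots of per-seed benchmark results
#'
#' One box per (model, training set) group of the chosen metric; standard
#' quartile boxes with 1.5 IQR whiskers. The CSV tables remain the
#' canonical artifact; this is an optional visual.
#'
#' @param results a `vf_results` table.
#' @param metric one of `"rmse"`, `"sd"`, `"rp"`, `"rs"`.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot stats.
#' @export
plot_benchmark <- function(results, metric = c("rmse", "sd", "rp", "rs"), ...) {
  metric <- match.arg(metric)
  grp <- factor(paste(results$training_label, results$model, sep = "\n"),
                levels = unique(paste(results$training_label, results$model,
                                      sep = "\n")))
  invisible(graphics::boxplot(results[[metric]] ~ grp, ylab = toupper(metric),
                              xlab = "", las = 2, ...))
}

# ---- synthetic presets ------------------------------------------------

#' Load a synthetic benchmark preset
#'
#' Presets are YAML files shipped under `inst/presets/` (or any path):
#' `volume-trend` (nested training sizes from one generator),
#' `rf-vs-mlr` (single training size, 10 RF seeds),
#' `low-quality-benefit` (clean training set vs clean plus degraded),
#' `small-demo` (a fast miniature of `volume-trend`).
#'
#' @param preset preset name or a YAML file path.
#' @return the preset as a named list.
#' @export
load_preset <- function(preset) {
  path <- if (file.exists(preset)) preset
    else system.file("presets", paste0(preset, ".yaml"), package = "vinaforest")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown preset: ", preset, call. = FALSE)
  yaml::read_yaml(path)
}

.preset_generator <- function(p) {
  g <- p$generator %||% list()
  do.call(complex_gen_spec, g)
}

.preset_label_spec <- function(p, seed) {
  l <- p$labels %||% list()
  l$seed <- seed
  do.call(label_gen_spec, l)
}

#' Run a self-contained synthetic benchmark preset
#'
#' Generates complexes, features and labels from the preset's generator
#' settings, assembles the training/test design, and runs the model
#' panel. Everything derives from `seed`, so two runs with the same
#' preset and seed reproduce the results table exactly.
#'
#' Preset kinds: `volume` draws one pool and uses nested prefixes of it
#' as increasingly-sized training sets; `low_quality` trains once on a
#' clean set and once on clean plus quality-degraded complexes
#' (coordinate jitter, label bias/noise, per its `degrade` block).
#'
#' @param preset a preset name/path (see [load_preset()]) or a preset
#'   list.
#' @param seed master integer seed for data generation.
#' @param out_dir optional directory; when given, `results.csv` and
#'   `summary.csv` are written there.
#' @param config configuration list from [vf_config()].
#' @return a list with `results`, `summary`, `spec`, and `data`
#'   (features, labels, id sets, and for low-quality presets the
#'   degradation annotations).
#' @export
run_preset <- function(preset, seed = 1L, out_dir = NULL,
                       config = vf_config()) {
  p <- if (is.character(preset)) load_preset(preset) else preset
  kind <- p$kind %||% "volume"
  models <- unlist(p$models %||% c("vina", "mlr_vina", "rf_vina"))
  scheme <- if ("rf_vinaelem" %in% models) "vinaelem42" else "vina6"
  gspec <- .preset_generator(p)
  n_test <- p$n_test %||% 400L
  seeds <- seq_len(p$n_seeds %||% 10L)
  n_trees <- p$n_trees %||% 500L
  if (kind == "volume") {
    sizes <- sort(unlist(p$training_sizes %||% c(500L, 1000L, 2000L, 4000L)))
    n_pool <- max(sizes) + n_test
    cxs <- gen_complex_set(n_pool, gspec, seed = seed, config = config)
    feats <- featurize_set(cxs, scheme, config = config)
    y <- gen_labels(feats, .preset_label_spec(p, seed + 1L))
    names(y) <- feats$id
    ids <- feats$id
    test_ids <- ids[seq(max(sizes) + 1L, n_pool)]
    training <- setNames(lapply(sizes, function(s) ids[seq_len(s)]),
                         paste0("n", sizes))
    ann <- NULL
  } else if (kind == "low_quality") {
    n_clean <- p$n_clean %||% 800L
    n_deg <- p$n_degraded %||% 2400L
    n_pool <- n_clean + n_deg + n_test
    cxs <- gen_complex_set(n_pool, gspec, seed = seed, config = config)
    feats0 <- featurize_set(cxs, scheme, config = config)
    y0 <- gen_labels(feats0, .preset_label_spec(p, seed + 1L))
    deg_ix <- seq(n_clean + 1L, n_clean + n_deg)
    dspec <- do.call(degrade_spec, p$degrade %||% list())
    dg <- degrade(cxs[deg_ix], y0[deg_ix], dspec, seed = seed + 2L)
    feats_deg <- featurize_set(dg$complexes, scheme, config = config)
    feats <- feats0
    feats[deg_ix, ] <- feats_deg
    y <- as.numeric(y0)
    y[deg_ix] <- dg$labels
    names(y) <- feats$id
    ids <- feats$id
    test_ids <- ids[seq(n_clean + n_deg + 1L, n_pool)]
    training <- list(clean = ids[seq_len(n_clean)],
                     clean_plus_degraded = ids[seq_len(n_clean + n_deg)])
    ann <- dg$annotations
  } else stop("unknown preset kind: ", kind, call. = FALSE)
  spec <- benchmark_spec(p$name %||% "synthetic", test_ids, training,
                         models = models, seeds = seeds, n_trees = n_trees,
                         mtry_grid_vina6 = unlist(p$mtry_grid_vina6),
                         mtry_grid_vinaelem42 = unlist(p$mtry_grid_vinaelem42))
  results <- run_benchmark(spec, feats, y, config = config)
  summary <- summarize_benchmark(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  list(results = results, summary = summary, spec = spec,
       data = list(features = feats, labels = y, test_ids = test_ids,
                   training_sets = training, annotations = ann))
}
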