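#' Read and validate a pipeline configuration
#'
#' One YAML file drives the whole pipeline: the disease vocabulary, the
#' per-setting prevalences, the input mode (published counts or a simulated
#' cohort), the per-model operating points for simulation, the analysis
#' switches and the seed. Validation happens here, before any stage runs.
#'
#' Expected layout:
#' \preformatted{
#' seed: 1
#' input: counts            # or "simulate"
#' counts_file: counts.csv  # counts mode: model,class,correct,total
#' cohort:
#'   diseases: [AMD, DR, PM]
#'   size: 100000           # simulate mode
#'   settings:
#'     urban: {AMD: 0.026, DR: 0.018, PM: 0.010}
#'     rural: {AMD: 0.019, DR: 0.013, PM: 0.005}
#' models:                  # simulate mode operating points
#'   RETFound: {sensitivity: {AMD: 0.7596, DR: 0.9525, PM: 1.0},
#'              specificity: 0.9247}
#' analysis:
#'   positive_rule: exact_class
#'   alpha: 0.05
#'   k_pairwise: 3
#'   thresholds: {from: 0.01, to: 0.99, by: 0.01}
#' }
#'
#' @param path YAML file path.
#' @param base_dir directory against which relative file paths in the
#'   config are resolved; defaults to the config's own directory.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) abort_sdca("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, base_dir = base_dir)
}

required_key <- function(cfg, key, where = "config") {
  val <- cfg[[key]]
  if (is.null(val)) abort_sdca("missing required key '", key, "' in ", where)
  val
}

validate_run_config <- function(cfg, base_dir = ".") {
  seed <- check_seed(required_key(cfg, "seed"))
  input <- required_key(cfg, "input")
  if (!input %in% c("counts", "simulate"))
    abort_sdca("`input` must be 'counts' or 'simulate'")
  cohort <- required_key(cfg, "cohort")
  diseases <- as.character(required_key(cohort, "diseases", "cohort"))
  settings <- required_key(cohort, "settings", "cohort")
  if (!length(settings) || is.null(names(settings)))
    abort_sdca("cohort$settings must map setting names to prevalence tables")
  settings <- lapply(names(settings), function(s) {
    prev <- unlist(settings[[s]])
    for (d in diseases)
      if (is.null(settings[[s]][[d]]))
        abort_sdca("missing prevalence for disease '", d, "' in setting '", s, "'")
    # full invariant check (sum < 1 etc.) via the cohort constructor
    cohort_spec(diseases, prev[diseases],
                size = if (is.null(cohort$size)) 100000 else cohort$size,
                setting_label = s)
  })
  names(settings) <- names(cfg$cohort$settings)

  if (input == "counts") {
    cf <- required_key(cfg, "counts_file")
    if (!file.exists(cf)) cf <- file.path(base_dir, cfg$counts_file)
    if (!file.exists(cf)) abort_sdca("counts_file not found: ", cfg$counts_file)
    cfg$counts_file <- cf
  } else {
    models <- required_key(cfg, "models")
    if (is.null(names(models))) abort_sdca("`models` must be a named mapping")
    for (m in names(models)) {
      sens <- unlist(required_key(models[[m]], "sensitivity", paste0("models$", m)))
      for (d in diseases)
        if (is.null(models[[m]]$sensitivity[[d]]))
          abort_sdca("model '", m, "' lacks a sensitivity for '", d, "'")
      classifier_spec(sens[diseases],
                      required_key(models[[m]], "specificity", paste0("models$", m)))
    }
  }

  an <- cfg$analysis
  analysis <- list(
    positive_rule = if (is.null(an$positive_rule)) "exact_class" else an$positive_rule,
    alpha = if (is.null(an$alpha)) 0.05 else an$alpha,
    k_pairwise = if (is.null(an$k_pairwise)) 3 else an$k_pairwise,
    thresholds = if (is.null(an$thresholds)) seq(0.01, 0.99, by = 0.01)
                 else seq(an$thresholds$from, an$thresholds$to, by = an$thresholds$by)
  )
  if (!analysis$positive_rule %in% c("exact_class", "any_disease"))
    abort_sdca("analysis$positive_rule must be exact_class or any_disease")
  check_thresholds(analysis$thresholds)

  structure(list(seed = seed, input = input, counts_file = cfg$counts_file,
                 diseases = diseases, settings = settings,
                 models = cfg$models, analysis = analysis, raw = cfg),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config$raw, tf)
  unname(tools::md5sum(tf))
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE, quote = FALSE)
  path
}

#' Read a pipeline output table
#'
#' Reads a CSV written by [run_pipeline()], skipping the `#` provenance
#' header line.
#'
#' @param path CSV path.
#' @export
read_stamped_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

metrics_from_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    cc <- confusion_counts(counts$correct[i], counts$total[i],
                           class = counts$class[i])
    pct <- sensitivity_pct(cc)
    praw <- attr(pct, "unrounded")
    tibble::tibble(model = counts$model[i], class = counts$class[i],
                   metric = if (counts$class[i] == NORMAL_CLASS) "specificity"
                            else "sensitivity",
                   correct = cc$correct, total = cc$total,
                   pct = as.numeric(pct), pct_raw = praw,
                   youden = NA_real_)
  })
  out <- do.call(rbind, rows)
  # pair each disease sensitivity with its model's normal-class specificity
  for (m in unique(out$model)) {
    sp <- out$pct_raw[out$model == m & out$class == NORMAL_CLASS] / 100
    if (length(sp) == 1L) {
      i <- which(out$model == m & out$class != NORMAL_CLASS)
      out$youden[i] <- vapply(out$pct_raw[i] / 100, youden_index, numeric(1),
                              spec = sp)
    }
  }
  out
}

#' Run the full screening-evaluation pipeline
#'
#' Executes the stages end to end — obtain per-model counts (from a counts
#' file or by simulating a screened cohort), compute the accuracy metrics,
#' run the omnibus and Bonferroni-corrected pairwise comparisons for every
#' class, and build decision curves plus dominance intervals for every
#' setting (each disease singly and the combined multi-disease screen).
#' Every output CSV starts with a `#` provenance line embedding the seed
#' and the config hash; a rerun with the same config and seed is
#' byte-identical. If a stage fails, the partial outputs are removed and
#' the error names the failing stage.
#'
#' @param config a `run_config` (from [read_run_config()]) or a path to a
#'   YAML config file.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a named list of the written file paths plus the
#'   in-memory `metrics`, `comparison`, `curves` and `dominance` tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- paste0("screendca seed=", config$seed, " config=", config_hash(config))
  written <- character()
  fail <- function(stage, e) {
    unlink(written)
    abort_sdca("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  }
  emit <- function(df, name) {
    p <- write_stamped_csv(df, file.path(out_dir, name), stamp)
    written <<- c(written, p)
    p
  }

  ## stage: counts (load or simulate)
  records <- NULL
  counts <- tryCatch({
    if (config$input == "counts") {
      cts <- tibble::as_tibble(utils::read.csv(config$counts_file,
                                               stringsAsFactors = FALSE))
      stopifnot(all(c("model", "class", "correct", "total") %in% names(cts)))
      cts
    } else {
      sim_spec <- config$settings[[1L]]
      truth <- draw_true_classes(sim_spec, config$seed)
      recs <- lapply(seq_along(config$models), function(i) {
        m <- names(config$models)[i]
        clf <- classifier_spec(
          unlist(config$models[[m]]$sensitivity)[config$diseases],
          config$models[[m]]$specificity)
        scored <- apply_classifier(truth, clf,
                         seed = (config$seed * 7919L + i) %% .Machine$integer.max,
                         model_name = m)
        # ids stay unique when several models' tables are stacked
        scored$record_id <- paste0(m, ":", scored$record_id)
        scored
      })
      records <- do.call(rbind, recs)
      emit(records, "records.csv")
      met <- screening_metrics(records,
                               classes = c(config$diseases, NORMAL_CLASS),
                               positive_rule = config$analysis$positive_rule)
      met[, c("model", "class", "correct", "total")]
    }
  }, error = function(e) fail("counts", e))

  ## stage: metrics
  metrics <- tryCatch({
    met <- metrics_from_counts(counts)
    emit(met, "metrics.csv")
    met
  }, error = function(e) fail("metrics", e))

  ## stage: comparison
  comparison <- tryCatch({
    rows <- list()
    for (tab in counts_by_class(counts[, c("model", "class", "correct", "total")])) {
      res <- compare_models(tab, alpha = config$analysis$alpha,
                            k_pairwise = config$analysis$k_pairwise)
      om <- res$omnibus
      rows[[length(rows) + 1L]] <- tibble::tibble(
        class = NA_character_, comparison = "omnibus",
        model_a = tab$model[1L], model_b = paste(tab$model[-1L], collapse = "|"),
        method = om$method, statistic = round_half_up(om$statistic, 2),
        df = om$df, p_value = om$p_value, alpha = om$alpha_prime,
        significant = om$significant)
      if (nrow(res$pairwise)) {
        pw <- res$pairwise
        rows[[length(rows) + 1L]] <- tibble::tibble(
          class = NA_character_, comparison = "pairwise",
          model_a = pw$model_a, model_b = pw$model_b, method = pw$method,
          statistic = round_half_up(pw$statistic, 2), df = pw$df,
          p_value = pw$p_value, alpha = pw$alpha_prime,
          significant = pw$significant)
      }
    }
    out <- do.call(rbind, rows)
    # recover the class label per block in declared order
    classes <- unique(counts$class)
    blocks <- cumsum(out$comparison == "omnibus")
    out$class <- classes[blocks]
    emit(out, "comparison.csv")
    out
  }, error = function(e) fail("comparison", e))

  ## stage: dca
  dca <- tryCatch({
    ops <- lapply(unique(metrics$model), function(m) {
      sub <- metrics[metrics$model == m, ]
      sens <- sub$correct[sub$class != NORMAL_CLASS] /
              sub$total[sub$class != NORMAL_CLASS]
      names(sens) <- sub$class[sub$class != NORMAL_CLASS]
      spec <- sub$correct[sub$class == NORMAL_CLASS] /
              sub$total[sub$class == NORMAL_CLASS]
      list(sens = sens, spec = spec)
    })
    names(ops) <- unique(metrics$model)
    all_curves <- list(); all_dom <- list()
    for (s in names(config$settings)) {
      spec_s <- config$settings[[s]]
      for (d in config$diseases) {
        single <- lapply(ops, function(op)
          list(sens = unname(op$sens[[d]]), spec = op$spec))
        cur <- build_curves(single, spec_s$prevalence[[d]],
                            thresholds = config$analysis$thresholds,
                            n = spec_s$size,
                            setting_label = paste0(s, ":", d))
        all_curves[[length(all_curves) + 1L]] <- cur
        dom <- dominance_intervals(cur)
        if (nrow(dom))
          all_dom[[length(all_dom) + 1L]] <-
            cbind(setting = paste0(s, ":", d), dom)
      }
      cur <- build_curves(ops, spec_s$prevalence,
                          thresholds = config$analysis$thresholds,
                          n = spec_s$size,
                          setting_label = paste0(s, ":combined"))
      all_curves[[length(all_curves) + 1L]] <- cur
      dom <- dominance_intervals(cur)
      if (nrow(dom))
        all_dom[[length(all_dom) + 1L]] <- cbind(setting = paste0(s, ":combined"), dom)
    }
    curves <- do.call(rbind, all_curves)
    dominance <- if (length(all_dom)) tibble::as_tibble(do.call(rbind, all_dom))
                 else tibble::tibble(setting = character(), strategy = character(),
                                     lower = numeric(), upper = numeric())
    emit(curves, "curves.csv")
    emit(dominance, "dominance.csv")
    list(curves = curves, dominance = dominance)
  }, error = function(e) fail("dca", e))

  ## stage: report
  tryCatch({
    summary_lines <- c(
      paste0("# ", stamp),
      "",
      "Performance table:",
      utils::capture.output(print(as.data.frame(
        render_table1_style(metrics)), row.names = FALSE)),
      "",
      "Comparisons (statistic at 2 dp, uncorrected Pearson unless Fisher):",
      utils::capture.output(print(as.data.frame(comparison), row.names = FALSE)),
      "",
      "Dominant strategies by threshold interval:",
      utils::capture.output(print(as.data.frame(dca$dominance), row.names = FALSE))
    )
    p <- file.path(out_dir, "summary.txt")
    writeLines(summary_lines, p, useBytes = TRUE)
    written <- c(written, p)
    yaml::write_yaml(config$raw, file.path(out_dir, "config_used.yaml"))
  }, error = function(e) fail("report", e))

  invisible(list(files = written, metrics = metrics, comparison = comparison,
                 curves = dca$curves, dominance = dca$dominance))
}

#' Render a screening performance table
#'
#' Formats a metrics table the way clinical screening tables print: one row
#' per model and metric, one column per class, each cell
#' `"percentage (count)"` to two decimals, and `"/"` where a metric does not
#' apply to a class (specificity for disease columns and vice versa).
#'
#' @param metrics a metrics tibble ([screening_metrics()] or the pipeline's
#'   metrics stage).
#' @return Tibble: `model`, `metric`, then one character column per class.
#' @examples
#' met <- metrics_from_published(fundus_screening_counts())
#' render_table1_style(met)
#' @export
render_table1_style <- function(metrics) {
  stopifnot(is.data.frame(metrics),
            all(c("model", "class", "metric", "correct", "pct") %in% names(metrics)))
  classes <- unique(metrics$class)
  models <- unique(metrics$model)
  rows <- list()
  for (m in models) {
    for (met in c("sensitivity", "specificity")) {
      cells <- vapply(classes, function(cl) {
        i <- which(metrics$model == m & metrics$class == cl & metrics$metric == met)
        if (!length(i)) return("/")
        sprintf("%.2f (%d)", metrics$pct[i[1L]], metrics$correct[i[1L]])
      }, character(1))
      row <- c(list(model = m, metric = met), as.list(cells))
      names(row) <- c("model", "metric", classes)
      rows[[length(rows) + 1L]] <- tibble::as_tibble(row)
    }
  }
  do.call(rbind, rows)
}

#' Metrics table from published counts
#'
#' Entry point for count-level input: turns a `model, class, correct,
#' total` table into the same metrics tibble the record-level route
#' produces (display percentages, raw percentages, per-disease Youden's
#' index paired with the model's normal-class specificity).
#'
#' @param counts tibble with columns `model`, `class`, `correct`, `total`.
#' @export
metrics_from_published <- function(counts) metrics_from_counts(counts)
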