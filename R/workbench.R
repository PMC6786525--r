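# Command-line workbench: ties the modules into reproducible subcommands with
# a YAML config, conventional artifact names, and line-delimited JSON logs.
# A thin Rscript wrapper lives in inst/scripts/apt-workbench.R.

WORKBENCH_COMMANDS <- c("simulate", "score", "profile", "train", "calibrate",
                        "predict", "evaluate", "edit", "plot")

# Named substream seeds derived from the one top-level seed.
sub_seed <- function(seed, name) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(name))) %% 2147483647L
}

wb_default_config <- function() {
  list(
    seed = 1L,
    corpus = list(n_articles = 2000L, year_range = c(2000L, 2011L)),
    window_years = 2L,
    exclude_clinical = FALSE,
    model = list(num_trees = 100L, downsample_factor = 2),
    calibration_split = 0.25,
    plot = list(grid_size = 256L, sigma = 2)
  )
}

wb_read_config <- function(path) {
  cfg <- wb_default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) {
      cfg[[k]] <- if (is.list(user[[k]]) && is.list(cfg[[k]])) {
        utils::modifyList(cfg[[k]], user[[k]])
      } else user[[k]]
    }
  }
  cfg
}

wb_log <- function(out_dir, command, ...) {
  rec <- c(list(command = command), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "",
      file = file.path(out_dir, "log.jsonl"), append = TRUE)
}

wb_path <- function(out_dir, name) file.path(out_dir, name)

#' Run a workbench subcommand
#'
#' Subcommands (all deterministic given the config seed):
#' \describe{
#'   \item{simulate}{Generate a synthetic corpus; writes `articles.jsonl`,
#'     `vocab.tsv`, `edges.tsv`, `scores.tsv`, `truth.tsv`.}
#'   \item{score}{Score `articles.jsonl` against `vocab.tsv`; writes
#'     `scores.tsv` and `coords.tsv`.}
#'   \item{profile}{Build 22-feature profiles from `scores.tsv` +
#'     `edges.tsv` at the configured window; writes `profiles.tsv`.}
#'   \item{train}{Split off a calibration fraction, train the forest, fit the
#'     bin calibration; writes `model.rds`/`model.json` and
#'     `calibration.json`.}
#'   \item{calibrate}{Refit the bin calibration for an existing model on the
#'     current profiles; rewrites `calibration.json`.}
#'   \item{predict}{Score profiles with the saved model; writes
#'     `predictions.tsv` (raw, bin, bin_center).}
#'   \item{evaluate}{Held-out metrics; writes `metrics.tsv`, `roc.tsv`,
#'     `pr.tsv`.}
#'   \item{edit}{Citation-editing experiment on APT-up articles; writes
#'     `editing_results.tsv`, `editing_summary.tsv`.}
#'   \item{plot}{Density map of `coords.tsv`; writes `density.tsv` and
#'     `density.png`.}
#' }
#' Every run writes the resolved configuration (`resolved-config.yaml`) and
#' appends structured records to `log.jsonl` in the output directory.
#'
#' @param args Character vector: `c(command, "--config", path, "--out", dir)`;
#'   `--config` is optional (defaults apply), `--out` defaults to `"."`.
#' @return Integer exit status (0 on success), invisibly.
#' @export
apt_run <- function(args) {
  status <- tryCatch({
    .apt_run(args)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.apt_run <- function(args) {
  if (length(args) < 1L || !args[1L] %in% WORKBENCH_COMMANDS) {
    stop("usage: apt-workbench <",
         paste(WORKBENCH_COMMANDS, collapse = "|"),
         "> [--config FILE] [--out DIR]")
  }
  command <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  out_dir <- opt("--out", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- wb_read_config(opt("--config"))
  yaml::write_yaml(cfg, wb_path(out_dir, "resolved-config.yaml"))

  switch(command,
    simulate = wb_simulate(cfg, out_dir),
    score = wb_score(cfg, out_dir),
    profile = wb_profile(cfg, out_dir),
    train = wb_train(cfg, out_dir),
    calibrate = wb_calibrate(cfg, out_dir),
    predict = wb_predict(cfg, out_dir),
    evaluate = wb_evaluate(cfg, out_dir),
    edit = wb_edit(cfg, out_dir),
    plot = wb_plot(cfg, out_dir)
  )
  invisible(NULL)
}

wb_simulate <- function(cfg, out_dir) {
  cc <- do.call(corpus_config,
                c(cfg$corpus, list(seed = sub_seed(cfg$seed, "corpus"))))
  corpus <- generate_corpus(cc)
  write_articles_jsonl(corpus$articles, wb_path(out_dir, "articles.jsonl"))
  write_mesh_tsv(toy_mesh_vocabulary(), wb_path(out_dir, "vocab.tsv"))
  write_edges_tsv(corpus$edges, wb_path(out_dir, "edges.tsv"))
  data.table::fwrite(corpus$scores, wb_path(out_dir, "scores.tsv"), sep = "\t")
  data.table::fwrite(corpus$truth, wb_path(out_dir, "truth.tsv"), sep = "\t")
  wb_log(out_dir, "simulate", n_articles = nrow(corpus$articles),
         n_edges = nrow(corpus$edges),
         prevalence = mean(corpus$truth$clinically_cited))
}

wb_read_scores <- function(out_dir) {
  data.table::fread(wb_path(out_dir, "scores.tsv"),
                    colClasses = list(character = "article_id"))
}

wb_score <- function(cfg, out_dir) {
  vocab <- read_mesh_tsv(wb_path(out_dir, "vocab.tsv"))
  articles <- read_articles_jsonl(wb_path(out_dir, "articles.jsonl"))
  scores <- score_articles(articles, vocab)
  data.table::fwrite(scores, wb_path(out_dir, "scores.tsv"), sep = "\t")
  write_coords_tsv(scores, wb_path(out_dir, "coords.tsv"))
  wb_log(out_dir, "score", n_articles = nrow(scores),
         n_defined = sum(scores$defined))
}

wb_profile <- function(cfg, out_dir) {
  scores <- wb_read_scores(out_dir)
  edges <- read_edges_tsv(wb_path(out_dir, "edges.tsv"))
  prof <- build_profiles(scores, edges, window_years = cfg$window_years,
                         exclude_clinical = isTRUE(cfg$exclude_clinical))
  write_profiles_tsv(prof, wb_path(out_dir, "profiles.tsv"))
  wb_log(out_dir, "profile", n_profiles = nrow(prof),
         window_years = cfg$window_years)
}

wb_labels <- function(out_dir, prof) {
  truth <- data.table::fread(wb_path(out_dir, "truth.tsv"),
                             colClasses = list(character = "article_id"))
  lab <- truth[match(prof$article_id, truth$article_id)]
  stopifnot(!anyNA(lab$clinically_cited))
  lab$clinically_cited
}

wb_train <- function(cfg, out_dir) {
  prof <- read_profiles_tsv(wb_path(out_dir, "profiles.tsv"))
  y <- wb_labels(out_dir, prof)
  set.seed(sub_seed(cfg$seed, "split"))
  n_cal <- floor(cfg$calibration_split * nrow(prof))
  cal_idx <- sample.int(nrow(prof), n_cal)
  clf <- apt_train(prof[-cal_idx], y[-cal_idx],
                   seed = sub_seed(cfg$seed, "forest"),
                   downsample_factor = cfg$model$downsample_factor,
                   num_trees = cfg$model$num_trees)
  calib <- apt_calibrate_bins(apt_predict_raw(clf, prof[cal_idx]), y[cal_idx])
  save_classifier(clf, wb_path(out_dir, "model"))
  jsonlite::write_json(list(thresholds = calib$thresholds,
                            bin_rates = calib$bin_rates,
                            bin_counts = calib$bin_counts, n = calib$n),
                       wb_path(out_dir, "calibration.json"), digits = NA)
  wb_log(out_dir, "train", n_train = clf$n_train, n_calibration = n_cal,
         class_balance = mean(y))
}

wb_read_calibration <- function(out_dir) {
  j <- jsonlite::read_json(wb_path(out_dir, "calibration.json"),
                           simplifyVector = TRUE)
  structure(list(thresholds = j$thresholds, targets = unname(apt_bin_centers()),
                 bin_rates = j$bin_rates, bin_counts = j$bin_counts, n = j$n),
            class = "apt_calibration")
}

wb_calibrate <- function(cfg, out_dir) {
  prof <- read_profiles_tsv(wb_path(out_dir, "profiles.tsv"))
  y <- wb_labels(out_dir, prof)
  clf <- load_classifier(wb_path(out_dir, "model"))
  calib <- apt_calibrate_bins(apt_predict_raw(clf, prof), y)
  jsonlite::write_json(list(thresholds = calib$thresholds,
                            bin_rates = calib$bin_rates,
                            bin_counts = calib$bin_counts, n = calib$n),
                       wb_path(out_dir, "calibration.json"), digits = NA)
  wb_log(out_dir, "calibrate", n = calib$n)
}

wb_predict <- function(cfg, out_dir) {
  prof <- read_profiles_tsv(wb_path(out_dir, "profiles.tsv"))
  clf <- load_classifier(wb_path(out_dir, "model"))
  calib <- wb_read_calibration(out_dir)
  sc <- apt_score(clf, calib, prof)
  data.table::fwrite(sc, wb_path(out_dir, "predictions.tsv"), sep = "\t")
  wb_log(out_dir, "predict", n = nrow(sc))
}

wb_evaluate <- function(cfg, out_dir) {
  prof <- read_profiles_tsv(wb_path(out_dir, "profiles.tsv"))
  y <- wb_labels(out_dir, prof)
  clf <- load_classifier(wb_path(out_dir, "model"))
  ev <- apt_evaluate(clf, prof, y)
  metrics <- data.table::data.table(
    metric = c("accuracy", "precision", "recall", "f1", "auc", "chance_rate"),
    value = c(ev$accuracy, ev$precision, ev$recall, ev$f1, ev$auc,
              ev$chance_rate))
  data.table::fwrite(metrics, wb_path(out_dir, "metrics.tsv"), sep = "\t")
  data.table::fwrite(ev$roc, wb_path(out_dir, "roc.tsv"), sep = "\t")
  data.table::fwrite(ev$pr, wb_path(out_dir, "pr.tsv"), sep = "\t")
  wb_log(out_dir, "evaluate", accuracy = ev$accuracy, f1 = ev$f1,
         auc = ev$auc, chance_rate = ev$chance_rate)
}

wb_edit <- function(cfg, out_dir) {
  scores <- wb_read_scores(out_dir)
  edges <- read_edges_tsv(wb_path(out_dir, "edges.tsv"))
  clf <- load_classifier(wb_path(out_dir, "model"))
  calib <- wb_read_calibration(out_dir)
  ids <- select_apt_up(scores, edges, clf, calib)
  if (length(ids) == 0L) stop("no articles moved up between the two windows")
  exp <- run_editing_experiment(scores, edges, ids, clf, calib,
                                seed = sub_seed(cfg$seed, "edits"))
  write_editing_tsv(exp, wb_path(out_dir, "editing_results.tsv"),
                    wb_path(out_dir, "editing_summary.tsv"))
  wb_log(out_dir, "edit", n_articles = length(ids),
         n_results = nrow(exp$results))
}

wb_plot <- function(cfg, out_dir) {
  coords <- data.table::fread(wb_path(out_dir, "coords.tsv"))
  grid <- triangle_accumulate(coords$x, coords$y,
                              grid_size = cfg$plot$grid_size)
  sm <- triangle_smooth(grid, cfg$plot$sigma)
  write_grid_tsv(sm, wb_path(out_dir, "density.tsv"))
  plot_triangle(sm, file = wb_path(out_dir, "density.png"))
  wb_log(out_dir, "plot", n_points = nrow(coords),
         grid_size = cfg$plot$grid_size, sigma = cfg$plot$sigma)
}
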