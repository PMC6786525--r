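# Random-forest prediction of eventual clinical citation, calibration of the
# raw vote fraction into the five APT bins, evaluation, importance ranking and
# the temporal experiments.

#' APT bin levels and centers
#'
#' The five calibrated bins `<5%`, `25%`, `50%`, `75%`, `>95%` of odds of
#' clinical citation.
#'
#' @return `apt_bin_levels()`: ordered character vector; `apt_bin_centers()`:
#'   named numeric vector of bin center values.
#' @export
apt_bin_levels <- function() c("LT5", "P25", "P50", "P75", "GT95")

#' @rdname apt_bin_levels
#' @export
apt_bin_centers <- function() {
  stats::setNames(c(0.05, 0.25, 0.50, 0.75, 0.95), apt_bin_levels())
}

#' Train the clinical-citation random forest
#'
#' Randomly downsamples the majority class (without replacement, seeded) to
#' `downsample_factor` times the minority count, then fits a probability
#' random forest whose output is the fraction of trees voting that an article
#' will be cited by a clinical article. Feature importance is recorded as mean
#' decrease in Gini impurity.
#'
#' @param profiles Data-profile table containing the 22 canonical feature
#'   columns (see [APT_FEATURES]); extra columns are ignored.
#' @param labels Binary vector (0/1 or logical): eventually clinically cited.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param downsample_factor Majority:minority ratio after downsampling.
#' @param num_trees Number of trees in the forest.
#' @return An `apt_classifier` object.
#' @export
apt_train <- function(profiles, labels, seed, downsample_factor = 2,
                      num_trees = 100) {
  x <- profile_features(profiles)
  y <- as.integer(as.logical(labels))
  stopifnot(length(y) == nrow(x), !anyNA(y))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  stopifnot(downsample_factor >= 1)

  set.seed(as.integer(seed))
  pos <- which(y == 1L); neg <- which(y == 0L)
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- if (length(pos) <= length(neg)) neg else pos
  keep_major <- if (length(majority) > downsample_factor * length(minority)) {
    sample(majority, size = floor(downsample_factor * length(minority)))
  } else majority
  idx <- c(minority, keep_major)

  fit <- ranger::ranger(
    x = x[idx, , drop = FALSE],
    y = factor(y[idx], levels = c("0", "1")),
    num.trees = num_trees,
    probability = TRUE,
    importance = "impurity",
    seed = as.integer(seed),
    num.threads = 1L
  )
  structure(
    list(forest = fit, features = APT_FEATURES, seed = as.integer(seed),
         n_train = length(idx), downsample_factor = downsample_factor,
         num_trees = num_trees, format_version = 1L),
    class = "apt_classifier"
  )
}

#' @export
print.apt_classifier <- function(x, ...) {
  cat("<apt_classifier>", x$num_trees, "trees, trained on", x$n_train,
      "articles (downsample factor", paste0(x$downsample_factor, ","),
      "seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Raw APT vote fractions
#'
#' The ensemble vote fraction in `[0, 1]` for the positive (clinically cited)
#' class. Feature columns are aligned by name against the classifier's
#' canonical list; a missing feature is an error.
#'
#' @param clf An `apt_classifier`.
#' @param profiles Profile table (see [apt_train()]).
#' @return Numeric vector of vote fractions.
#' @export
apt_predict_raw <- function(clf, profiles) {
  stopifnot(inherits(clf, "apt_classifier"))
  x <- profile_features(profiles, required = clf$features)
  as.numeric(stats::predict(clf$forest, data = x, num.threads = 1L)$predictions[, "1"])
}

#' Calibrate raw scores into the five APT bins
#'
#' Finds four strictly increasing thresholds on the raw score that cut a
#' calibration set into five contiguous bins whose empirical positive rates
#' are as close as possible (least squares, via an exact dynamic program over
#' a quantile grid of candidate cuts) to the target rates 0.05, 0.25, 0.50,
#' 0.75, 0.95.
#'
#' @param raw Raw vote fractions from [apt_predict_raw()].
#' @param labels Binary outcome vector, same length.
#' @param n_grid Number of candidate cut positions along the sorted scores.
#' @return An `apt_calibration`: thresholds `t1 < t2 < t3 < t4`, per-bin
#'   achieved positive rates and counts.
#' @export
apt_calibrate_bins <- function(raw, labels, n_grid = 256L) {
  y <- as.integer(as.logical(labels))
  stopifnot(length(raw) == length(y), !anyNA(raw), !anyNA(y))
  n <- length(raw)
  if (n < 10L) stop("too few observations to calibrate five bins")
  if (diff(range(raw)) == 0) stop("degenerate raw score distribution (all equal)")
  targets <- unname(apt_bin_centers())

  ord <- order(raw)
  r <- raw[ord]; ys <- y[ord]
  cum <- c(0L, cumsum(ys))
  # candidate boundary indices: quantile grid, only at valid split points
  # (strictly increasing raw value across the cut)
  cand <- unique(round(seq(0, n, length.out = n_grid + 1L)))
  interior <- cand[cand > 0L & cand < n]
  interior <- interior[r[interior] < r[interior + 1L]]
  cand <- c(0L, interior, n)
  k <- length(cand)
  if (k < 6L) stop("not enough distinct raw values to form five bins")

  seg_cost <- function(i, j, target) {
    # cost of a bin spanning sorted positions (cand[i]+1) .. cand[j]
    cnt <- cand[j] - cand[i]
    rate <- (cum[cand[j] + 1L] - cum[cand[i] + 1L]) / cnt
    (rate - target)^2
  }
  INF <- Inf
  best <- matrix(INF, nrow = 5L, ncol = k)
  back <- matrix(NA_integer_, nrow = 5L, ncol = k)
  for (j in 2:k) best[1L, j] <- seg_cost(1L, j, targets[1L])
  for (s in 2:5) {
    for (j in (s + 1L):k) {
      costs <- vapply(s:(j - 1L), function(i) {
        if (!is.finite(best[s - 1L, i])) return(INF)
        best[s - 1L, i] + seg_cost(i, j, targets[s])
      }, numeric(1L))
      w <- which.min(costs)
      best[s, j] <- costs[w]
      back[s, j] <- (s:(j - 1L))[w]
    }
  }
  cuts <- integer(4L)
  j <- k
  for (s in 5:2) {
    i <- back[s, j]
    cuts[s - 1L] <- cand[i]
    j <- i
  }
  thresholds <- (r[cuts] + r[cuts + 1L]) / 2
  stopifnot(all(diff(thresholds) > 0))

  bin <- cut(raw, breaks = c(-Inf, thresholds, Inf), labels = apt_bin_levels())
  achieved <- tapply(y, bin, mean)
  counts <- as.integer(table(bin))
  structure(
    list(thresholds = thresholds, targets = targets,
         bin_rates = as.numeric(achieved), bin_counts = counts, n = n),
    class = "apt_calibration"
  )
}

#' @export
print.apt_calibration <- function(x, ...) {
  cat("<apt_calibration> thresholds:",
      paste(sprintf("%.3f", x$thresholds), collapse = ", "), "\n")
  cat("  bin positive rates:",
      paste(sprintf("%s=%.3f", apt_bin_levels(), x$bin_rates), collapse = " "), "\n")
  invisible(x)
}

#' Bin raw scores by a fitted calibration
#'
#' @param raw Numeric raw scores.
#' @param calib An `apt_calibration`.
#' @return Ordered factor over [apt_bin_levels()].
#' @export
apt_bin <- function(raw, calib) {
  stopifnot(inherits(calib, "apt_calibration"))
  cut(raw, breaks = c(-Inf, calib$thresholds, Inf), labels = apt_bin_levels(),
      ordered_result = TRUE)
}

#' APT scores (raw vote fraction plus calibrated bin)
#'
#' @param clf An `apt_classifier`.
#' @param calib An `apt_calibration`.
#' @param profiles Profile table.
#' @return `data.table` with `raw`, `bin`, `bin_center` (and `article_id` when
#'   present in `profiles`).
#' @export
apt_score <- function(clf, calib, profiles) {
  raw <- apt_predict_raw(clf, profiles)
  bin <- apt_bin(raw, calib)
  out <- data.table::data.table(raw = raw, bin = bin,
                                bin_center = unname(apt_bin_centers()[as.integer(bin)]))
  pf <- as.data.frame(profiles)
  if ("article_id" %in% names(pf)) {
    out <- data.table::data.table(article_id = pf$article_id, out)
  }
  out
}

#' Evaluate a classifier on a held-out test set
#'
#' Accuracy, F1 (positive class = clinically cited), ROC curve with AUC,
#' precision-recall curve, and the chance rate (positive prevalence of the
#' test set).
#'
#' @param clf An `apt_classifier`.
#' @param profiles Held-out profile table (disjoint from training).
#' @param labels Binary outcomes.
#' @param threshold Raw-score cut for the hard prediction (default 0.5).
#' @return List: `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `chance_rate`, `roc` (`data.table` fpr/tpr), `pr` (`data.table`
#'   recall/precision).
#' @export
apt_evaluate <- function(clf, profiles, labels, threshold = 0.5) {
  raw <- apt_predict_raw(clf, profiles)
  y <- as.integer(as.logical(labels))
  pred <- as.integer(raw >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)

  roc_obj <- pROC::roc(response = y, predictor = raw, quiet = TRUE,
                       direction = "<", levels = c(0, 1))
  roc_dt <- data.table::data.table(
    fpr = rev(1 - roc_obj$specificities), tpr = rev(roc_obj$sensitivities))

  ord <- order(raw, decreasing = TRUE)
  cum_tp <- cumsum(y[ord])
  pr_dt <- data.table::data.table(
    recall = cum_tp / sum(y),
    precision = cum_tp / seq_along(cum_tp)
  )
  list(accuracy = mean(pred == y), precision = precision, recall = recall,
       f1 = f1, auc = as.numeric(pROC::auc(roc_obj)), chance_rate = mean(y),
       roc = roc_dt, pr = pr_dt)
}

#' Ranked Gini feature importance
#'
#' Mean decrease in Gini impurity per feature, normalised to sum 1 and sorted
#' in decreasing order. For the focus-class variants of the ranking, retrain
#' on the `FUNDAMENTAL` or `HUMAN_FOCUSED` subset and call this again.
#'
#' @param clf An `apt_classifier`.
#' @return `data.table` with `feature`, `importance` (22 rows, descending).
#' @export
apt_feature_importance <- function(clf) {
  stopifnot(inherits(clf, "apt_classifier"))
  imp <- clf$forest$variable.importance
  imp <- imp / sum(imp)
  out <- data.table::data.table(feature = names(imp), importance = as.numeric(imp))
  data.table::setorder(out, -importance)
  out[]
}

#' APT trajectory of articles over growing citing networks
#'
#' Scores each article with one fixed classifier at a sequence of yearly
#' network snapshots (cumulative by construction of [restrict_network()]),
#' mirroring the fixed-classifier/growing-network experiment.
#'
#' @param scores Article table.
#' @param edges Edge table.
#' @param article_ids Articles to follow.
#' @param as_of_years Increasing vector of calendar snapshot years.
#' @param clf,calib Fixed classifier and calibration.
#' @param freeze_network_year When set, the citing network *and* the
#'   citation-rate clock are frozen at this year: every snapshot re-scores the
#'   identical data profile, the fixed-network control in which any APT change
#'   can come only from the classifier.
#' @param ... Passed to [build_profiles()] (e.g. `exclude_clinical`).
#' @return `data.table`: `article_id`, `as_of_year`, `raw`, `bin`,
#'   `bin_center`.
#' @export
apt_trajectory <- function(scores, edges, article_ids, as_of_years, clf, calib,
                           freeze_network_year = NULL, ...) {
  stopifnot(length(as_of_years) >= 1L, !is.unsorted(as_of_years))
  scores <- data.table::as.data.table(scores)
  rows <- lapply(as_of_years, function(yr) {
    eff_yr <- if (is.null(freeze_network_year)) yr else
      min(yr, freeze_network_year)
    prof <- build_profiles(scores, edges, as_of_year = eff_yr, ...)
    prof <- prof[article_id %in% article_ids]
    sc <- apt_score(clf, calib, prof)
    sc[, as_of_year := yr]
    sc
  })
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("article_id", "as_of_year"))
  out[]
}

#' Predicted-versus-actual clinical citation rates by bin
#'
#' Groups a test set by APT bin, compares the mean raw prediction in each bin
#' (predicted rate) with the empirical positive rate (actual rate), and fits a
#' least-squares line of actual on predicted.
#'
#' @param raw Raw scores on the test set.
#' @param labels Binary outcomes.
#' @param calib An `apt_calibration`.
#' @return List: `table` (per-bin predicted/actual/count), `slope`,
#'   `intercept`, `r_squared`.
#' @export
predicted_vs_actual <- function(raw, labels, calib) {
  y <- as.integer(as.logical(labels))
  bin <- apt_bin(raw, calib)
  tab <- data.table::data.table(bin = bin, raw = raw, y = y)[
    , .(n = .N, predicted = mean(raw), actual = mean(y)), by = bin]
  data.table::setorder(tab, bin)
  if (nrow(tab) < 2L) stop("fewer than two non-empty bins")
  if (stats::var(tab$actual) == 0) stop("actual per-bin rates are constant; r-squared undefined")
  fit <- stats::lm(actual ~ predicted, data = tab)
  list(table = tab[], slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}

# ---- persistence ----------------------------------------------------------

feature_checksum <- function(features) paste(features, collapse = "|")

#' Save / load a trained classifier
#'
#' `save_classifier()` writes the fitted ensemble as an RDS blob alongside a
#' JSON sidecar carrying the canonical feature list, a feature checksum, the
#' training seed and metadata. `load_classifier()` refuses to load when the
#' sidecar does not match the blob.
#'
#' @param clf An `apt_classifier`.
#' @param path Path stem; `<path>.rds` and `<path>.json` are written.
#' @return `save_classifier()`: the path stem, invisibly;
#'   `load_classifier()`: the `apt_classifier`.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "apt_classifier"))
  saveRDS(clf, paste0(path, ".rds"))
  sidecar <- list(features = clf$features,
                  checksum = feature_checksum(clf$features),
                  seed = clf$seed, num_trees = clf$num_trees,
                  downsample_factor = clf$downsample_factor,
                  n_train = clf$n_train, format_version = clf$format_version)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(paste0(path, ".rds"))
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(as.character(sidecar$features), clf$features) ||
      !identical(sidecar$checksum, feature_checksum(clf$features))) {
    stop("model sidecar does not match the stored classifier; refusing to load")
  }
  clf
}
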