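# Training protocol (downsampling, determinism), raw votes, bin calibration,
# evaluation metrics, importance ranking, trajectories, persistence.

# Profiles with a planted separable rule label = [meanH > 0.5].
separable_profiles <- function(n, seed) {
  set.seed(seed)
  prof <- data.table::as.data.table(
    matrix(stats::runif(n * 22), ncol = 22, dimnames = list(NULL, APT_FEATURES)))
  prof[, D := round(D)][, E := round(E)][, CD := round(CD)]
  list(profiles = prof, labels = as.integer(prof$meanH > 0.5))
}

test_that("training downsamples the majority class and is seed-deterministic", {
  fx <- separable_profiles(2000, 1)
  y <- as.integer(fx$profiles$meanH > 0.8)  # ~20% positive
  clf <- apt_train(fx$profiles, y, seed = 5)
  n_min <- sum(y)
  expect_identical(clf$n_train, n_min + 2L * n_min)  # 2:1 after downsampling
  # determinism: same seed, same predictions
  clf2 <- apt_train(fx$profiles, y, seed = 5)
  held <- separable_profiles(200, 2)$profiles
  expect_identical(apt_predict_raw(clf, held), apt_predict_raw(clf2, held))
  # single-class input errors
  expect_error(apt_train(fx$profiles, rep(1, 2000), seed = 1), "single class")
})

test_that("downsampling never removes minority examples", {
  fx <- separable_profiles(500, 3)
  y <- c(rep(1L, 40), rep(0L, 460))
  clf <- apt_train(fx$profiles, y, seed = 9, downsample_factor = 2)
  expect_identical(clf$n_train, 40L + 80L)
  # majority smaller than factor * minority: nothing removed
  y2 <- c(rep(1L, 200), rep(0L, 300))
  clf2 <- apt_train(fx$profiles, y2, seed = 9, downsample_factor = 2)
  expect_identical(clf2$n_train, 500L)
})

test_that("a planted separable rule is learned almost perfectly", {
  fx <- separable_profiles(4000, 7)
  clf <- apt_train(fx$profiles, fx$labels, seed = 11)
  raw <- apt_predict_raw(clf, fx$profiles)
  expect_true(all(raw >= 0 & raw <= 1))
  acc <- mean((raw >= 0.5) == (fx$labels == 1))
  expect_gte(acc, 0.99)
  # a deep-in-class point gets a confident vote
  probe <- fx$profiles[1][, meanH := 0.99]
  expect_gt(apt_predict_raw(clf, probe), 0.9)
})

test_that("prediction aligns feature columns by name and rejects mismatches", {
  fx <- separable_profiles(1000, 13)
  clf <- apt_train(fx$profiles, fx$labels, seed = 2)
  held <- separable_profiles(50, 14)$profiles
  shuffled <- held[, rev(names(held)), with = FALSE]
  expect_identical(apt_predict_raw(clf, held), apt_predict_raw(clf, shuffled))
  expect_error(apt_predict_raw(clf, held[, -"CPY"]), "missing feature")
})

test_that("bin calibration recovers the target positive rates on calibrated scores", {
  set.seed(17)
  n <- 100000
  raw <- stats::runif(n)
  y <- stats::rbinom(n, 1, raw)
  calib <- apt_calibrate_bins(raw, y)
  expect_length(calib$thresholds, 4L)
  expect_true(all(diff(calib$thresholds) > 0))
  expect_length(calib$bin_rates, 5L)
  targets <- c(0.05, 0.25, 0.50, 0.75, 0.95)
  expect_true(all(abs(calib$bin_rates - targets) <= 0.05))
  expect_lte(calib$bin_rates[1], 0.05 + 0.05)
  expect_gte(calib$bin_rates[5], 0.95 - 0.05)
  # five non-empty bins
  expect_true(all(calib$bin_counts > 0))
  expect_equal(sum(calib$bin_counts), n)
})

test_that("calibration is invariant to rank-preserving transforms of raw", {
  set.seed(19)
  raw <- stats::runif(5000)
  y <- stats::rbinom(5000, 1, raw)
  c1 <- apt_calibrate_bins(raw, y)
  c2 <- apt_calibrate_bins(stats::qlogis(raw * 0.98 + 0.01), y)
  expect_identical(as.integer(apt_bin(raw, c1)),
                   as.integer(apt_bin(stats::qlogis(raw * 0.98 + 0.01), c2)))
  expect_error(apt_calibrate_bins(rep(0.5, 100), stats::rbinom(100, 1, 0.5)),
               "degenerate")
})

test_that("bins are a monotone function of raw and map extremes to the ends", {
  set.seed(23)
  raw <- stats::runif(20000)
  y <- stats::rbinom(20000, 1, raw)
  calib <- apt_calibrate_bins(raw, y)
  b <- apt_bin(sort(stats::runif(100)), calib)
  expect_true(!is.unsorted(as.integer(b)))
  expect_identical(as.character(apt_bin(0, calib)), "LT5")
  expect_identical(as.character(apt_bin(1, calib)), "GT95")
  # empirical rate non-decreasing from LT5 to GT95
  rates <- tapply(y, apt_bin(raw, calib), mean)
  expect_true(!is.unsorted(as.numeric(rates)))
})

test_that("evaluation metrics match closed-form confusion-matrix values", {
  # hand-built 2x2 confusion at threshold 0.5: TP=3, FP=1, FN=1, TN=5
  raw <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1)
  y <-   c(1,   1,   1,   0,   1,   0,   0,   0,   0,   0)
  fake_clf <- structure(list(features = "ignored"), class = "apt_classifier")
  with_mocked_bindings(
    apt_predict_raw = function(clf, profiles) raw,
    {
      ev <- apt_evaluate(fake_clf, data.frame(), y)
      expect_equal(ev$accuracy, 0.8)
      expect_equal(ev$precision, 3 / 4)
      expect_equal(ev$recall, 3 / 4)
      expect_equal(ev$f1, 0.75)  # harmonic mean of 0.75 and 0.75
      expect_equal(ev$chance_rate, 0.4)
      # perfect and inverted predictors
      ev_perfect <- local({
        raw <<- y; apt_evaluate(fake_clf, data.frame(), y)
      })
      expect_equal(ev_perfect$accuracy, 1)
      expect_equal(ev_perfect$f1, 1)
      ev_flipped <- local({
        raw <<- 1 - y; apt_evaluate(fake_clf, data.frame(), y)
      })
      expect_equal(ev_flipped$accuracy, 0)
      expect_equal(ev_flipped$f1, 0)
    }
  )
})

test_that("AUC from evaluate agrees with the rank-formula cross-check", {
  fx <- separable_profiles(1500, 29)
  y <- as.integer(fx$profiles$meanH + stats::rnorm(1500, 0, 0.3) > 0.5)
  if (length(unique(y)) < 2) skip("degenerate draw")
  clf <- apt_train(fx$profiles, y, seed = 31)
  held <- separable_profiles(800, 30)
  yh <- as.integer(held$profiles$meanH + stats::rnorm(800, 0, 0.3) > 0.5)
  ev <- apt_evaluate(clf, held$profiles, yh)
  raw <- apt_predict_raw(clf, held$profiles)
  auc_rank <- bayes_auc(list(true_prob = raw, clinically_cited = yh))
  expect_equal(ev$auc, auc_rank, tolerance = 1e-10)
})

test_that("Gini importances are normalised and recover a planted signal", {
  fx <- separable_profiles(4000, 37)
  clf <- apt_train(fx$profiles, fx$labels, seed = 41)
  imp <- apt_feature_importance(clf)
  expect_identical(nrow(imp), 22L)
  expect_true(all(imp$importance >= 0))
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(-imp$importance))
  expect_identical(imp$feature[1], "meanH")
})

test_that("pure-noise labels spread importance roughly evenly", {
  set.seed(43)
  fx <- separable_profiles(10000, 47)
  y <- stats::rbinom(10000, 1, 0.3)
  clf <- apt_train(fx$profiles, y, seed = 53)
  imp <- apt_feature_importance(clf)
  expect_lt(max(imp$importance), 3 * mean(imp$importance))
})

test_that("APT scores compose prediction and binning", {
  fx <- separable_profiles(3000, 59)
  clf <- apt_train(fx$profiles, fx$labels, seed = 61)
  raw <- apt_predict_raw(clf, fx$profiles)
  calib <- apt_calibrate_bins(raw, fx$labels)
  sc <- apt_score(clf, calib, fx$profiles[1:20])
  expect_identical(nrow(sc), 20L)
  expect_identical(as.integer(sc$bin), as.integer(apt_bin(sc$raw, calib)))
  expect_equal(sc$bin_center, unname(apt_bin_centers()[as.integer(sc$bin)]))
})

test_that("predicted-vs-actual regression is near the identity for calibrated scores", {
  set.seed(67)
  n <- 100000
  raw <- stats::runif(n)
  y <- stats::rbinom(n, 1, raw)
  calib <- apt_calibrate_bins(raw, y)
  pva <- predicted_vs_actual(raw, y, calib)
  expect_identical(nrow(pva$table), 5L)
  expect_true(pva$slope >= 0.9 && pva$slope <= 1.1)
  expect_gt(pva$r_squared, 0.95)
  # per-bin points lying exactly on the identity give slope 1, r^2 1
  raw3 <- c(rep(0.2, 40), rep(0.5, 40), rep(0.8, 40))
  y3 <- c(rep(c(1, 0, 0, 0, 0), 8), rep(c(1, 0), 20), rep(c(1, 1, 1, 1, 0), 8))
  pva3 <- suppressWarnings(predicted_vs_actual(raw3, y3, calib))
  expect_equal(pva3$slope, 1, tolerance = 1e-9)
  expect_equal(pva3$r_squared, 1, tolerance = 1e-9)
  # constant actual rates are flagged as undefined
  expect_error(predicted_vs_actual(stats::runif(100), rep(0, 100), calib),
               "constant")
})

test_that("trajectories are constant on frozen or empty networks", {
  corp <- small_corpus()
  prof <- build_profiles(corp$scores, corp$edges, window_years = 2)
  y <- corp$truth$clinically_cited
  clf <- apt_train(prof, y, seed = 71)
  calib <- apt_calibrate_bins(apt_predict_raw(clf, prof), y)
  ids <- corp$scores$article_id[corp$scores$pub_year == 2001][1:20]
  # fixed-network control: profile frozen at 2005, later snapshots identical
  traj <- apt_trajectory(corp$scores, corp$edges, ids, 2005:2008, clf, calib,
                         freeze_network_year = 2005)
  per_art <- split(traj$raw, traj$article_id)
  expect_true(all(vapply(per_art, function(v) max(v) - min(v), numeric(1)) == 0))
  # empty networks all years: constant too (all-zero network block, CPY 0)
  no_edges <- corp$edges[0]
  traj0 <- apt_trajectory(corp$scores, no_edges, ids, 2005:2007, clf, calib)
  expect_true(all(tapply(traj0$raw, traj0$article_id,
                         function(v) max(v) - min(v)) == 0))
})

test_that("growing, increasingly human networks push raw scores up", {
  corp <- small_corpus()
  prof <- build_profiles(corp$scores, corp$edges, window_years = 2)
  y <- corp$truth$clinically_cited
  clf <- apt_train(prof, y, seed = 73)
  calib <- apt_calibrate_bins(apt_predict_raw(clf, prof), y)
  art <- data.table::data.table(article_id = "T", pub_year = 2000L,
                                defined = TRUE, h = 0.2, a = 0.8, mc = 0,
                                d = 1L, e = 0L, cd = 0L)
  # citers added over time become increasingly human-focused with disease terms
  hs <- seq(0.1, 1, length.out = 10)
  med <- vapply(seq_along(hs), function(k) {
    citers <- data.table::data.table(h = hs[1:k], a = 1 - hs[1:k], mc = 0,
                                     d = as.integer(hs[1:k] > 0.4), e = 0L,
                                     cd = 0L, defined = TRUE)
    apt_predict_raw(clf, profile_from_citers(art, citers, 2000L + k))
  }, numeric(1))
  fit <- stats::lm(med ~ seq_along(med))
  expect_gt(stats::coef(fit)[2], 0)
  expect_gt(med[10], med[1])
})

test_that("classifier persistence round-trips and detects sidecar tampering", {
  fx <- separable_profiles(1000, 79)
  clf <- apt_train(fx$profiles, fx$labels, seed = 83)
  stem <- withr::local_tempfile()
  save_classifier(clf, stem)
  back <- load_classifier(stem)
  held <- separable_profiles(100, 80)$profiles
  expect_identical(apt_predict_raw(back, held), apt_predict_raw(clf, held))
  # tamper with the sidecar feature list
  sidecar <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  sidecar$features[1] <- "NOT_A_FEATURE"
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE)
  expect_error(load_classifier(stem), "sidecar")
})
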