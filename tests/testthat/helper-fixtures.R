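# Shared fixtures. Corpora are generated once per test run and memoised; the
# large planted-mechanism corpus backs both the recovery properties and the
# acceptance checks.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

toy_vocab <- function() memoise_fixture("vocab", toy_mesh_vocabulary())

# Desk-scale corpus used by most integration tests.
small_corpus <- function() {
  memoise_fixture("small_corpus",
                  generate_corpus(corpus_config(n_articles = 3000, seed = 101)))
}

# Planted-mechanism corpus at the study scale used by the recovery checks.
big_corpus <- function() {
  memoise_fixture("big_corpus",
                  generate_corpus(corpus_config(n_articles = 50000, seed = 202)))
}

big_profiles <- function() {
  memoise_fixture("big_profiles", {
    corp <- big_corpus()
    build_profiles(corp$scores, corp$edges,
                   as_of_year = corp$config$year_range[2L])
  })
}

# Classifier + calibration trained on half the big corpus (train rows split
# again internally for calibration), used by several acceptance checks.
big_fit <- function() {
  memoise_fixture("big_fit", {
    corp <- big_corpus()
    prof <- big_profiles()
    y <- corp$truth$clinically_cited
    n <- nrow(prof)
    set.seed(303)
    train_idx <- sample.int(n, n %/% 2)
    cal_idx <- sample(train_idx, length(train_idx) %/% 4)
    fit_idx <- setdiff(train_idx, cal_idx)
    clf <- apt_train(prof[fit_idx], y[fit_idx], seed = 404)
    calib <- apt_calibrate_bins(apt_predict_raw(clf, prof[cal_idx]), y[cal_idx])
    list(clf = clf, calib = calib, train_idx = train_idx,
         test_idx = setdiff(seq_len(n), train_idx))
  })
}

# Random citer tables for oracle-equivalence checks.
random_citers <- function(n) {
  data.table::data.table(
    h = stats::runif(n), a = stats::runif(n), mc = stats::runif(n),
    d = stats::rbinom(n, 1, 0.4), e = stats::rbinom(n, 1, 0.3),
    cd = stats::rbinom(n, 1, 0.5),
    defined = stats::runif(n) > 0.1
  )
}
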