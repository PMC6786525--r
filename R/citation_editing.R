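# Gain/loss-of-function perturbation of citing networks: delete the natural
# citation increment between two snapshots, replace it with homogeneous
# synthetic citers, and re-score.

#' Citation edit types
#'
#' `ORIGINALS` resamples the earlier network (size-only control); `MOLCELL`,
#' `ANIMAL`, `HUMAN` append citers with the named HAMC score equal to 1 and
#' everything else 0; `HUMAN_PLUS` appends citers with Human, Disease,
#' Therapeutic/Diagnostic and Chemical/Drug scores all equal to 1.
#'
#' @format Character vector of length five.
#' @export
EDIT_TYPES <- c("ORIGINALS", "MOLCELL", "ANIMAL", "HUMAN", "HUMAN_PLUS")

# One synthetic citer row per edit type.
synthetic_citer <- function(edit) {
  switch(edit,
    MOLCELL = data.table::data.table(h = 0, a = 0, mc = 1, d = 0, e = 0, cd = 0, defined = TRUE),
    ANIMAL = data.table::data.table(h = 0, a = 1, mc = 0, d = 0, e = 0, cd = 0, defined = TRUE),
    HUMAN = data.table::data.table(h = 1, a = 0, mc = 0, d = 0, e = 0, cd = 0, defined = TRUE),
    HUMAN_PLUS = data.table::data.table(h = 1, a = 0, mc = 0, d = 1, e = 1, cd = 1, defined = TRUE),
    stop("no synthetic citer for edit type ", edit)
  )
}

#' Select articles whose APT score moved up between two windows
#'
#' Articles whose bin at the earlier window equals `from_bin` and whose bin at
#' the later window is strictly higher.
#'
#' @param scores,edges Corpus tables.
#' @param clf,calib Classifier and calibration.
#' @param window_a,window_b Years post publication for the two snapshots
#'   (`window_b > window_a`).
#' @param from_bin Starting bin (default `"P25"`).
#' @return Character vector of article ids.
#' @export
select_apt_up <- function(scores, edges, clf, calib, window_a = 2, window_b = 3,
                          from_bin = "P25") {
  stopifnot(window_b > window_a, from_bin %in% apt_bin_levels())
  prof_a <- build_profiles(scores, edges, window_years = window_a)
  prof_b <- build_profiles(scores, edges, window_years = window_b)
  bin_a <- apt_bin(apt_predict_raw(clf, prof_a), calib)
  bin_b <- apt_bin(apt_predict_raw(clf, prof_b), calib)
  sel <- bin_a == from_bin & as.integer(bin_b) > as.integer(bin_a)
  prof_a$article_id[sel]
}

#' Edit one citing network
#'
#' Deletes the citation increment between the year-a and year-b snapshots and
#' appends an equal number of artificial citers of the requested type, so the
#' edited network always has the natural year-b size. With
#' `replace_all = TRUE` the whole year-b network is replaced instead.
#'
#' @param citers_a,citers_b Citer score tables (columns `h`, `a`, `mc`, `d`,
#'   `e`, `cd`, optionally `defined`) at the two cumulative snapshots;
#'   `nrow(citers_b) > nrow(citers_a)` unless `replace_all`.
#' @param edit One of [EDIT_TYPES].
#' @param seed Integer seed (used by `ORIGINALS` resampling).
#' @param replace_all Replace the entire network with synthetic citers.
#' @return Edited citer `data.table` with `nrow(citers_b)` rows.
#' @export
edit_network <- function(citers_a, citers_b, edit, seed, replace_all = FALSE) {
  edit <- match.arg(edit, EDIT_TYPES)
  citers_a <- data.table::as.data.table(citers_a)
  citers_b <- data.table::as.data.table(citers_b)
  cols <- c("h", "a", "mc", "d", "e", "cd")
  if (!"defined" %in% names(citers_b)) citers_b[, defined := TRUE]
  if (!"defined" %in% names(citers_a)) citers_a[, defined := rep(TRUE, nrow(citers_a))]
  n_b <- nrow(citers_b)
  if (replace_all) {
    base <- citers_b[0L, c(cols, "defined"), with = FALSE]
    k <- n_b
  } else {
    if (n_b <= nrow(citers_a)) stop("later snapshot must be larger than the earlier one")
    base <- citers_a[, c(cols, "defined"), with = FALSE]
    k <- n_b - nrow(citers_a)
  }
  set.seed(as.integer(seed))
  if (edit == "ORIGINALS") {
    pool <- if (replace_all) citers_a else base
    if (nrow(pool) == 0L) stop("ORIGINALS edit needs a non-empty earlier network")
    add <- pool[sample.int(nrow(pool), k, replace = TRUE),
                c(cols, "defined"), with = FALSE]
  } else {
    add <- synthetic_citer(edit)[rep(1L, k)]
  }
  out <- data.table::rbindlist(list(base, add), use.names = TRUE)
  stopifnot(nrow(out) == n_b)
  out[]
}

# Vertex stratum of an article: H/A/MC when >= `threshold` of its HAMC content
# sits in one category, otherwise "interior".
vertex_stratum <- function(h, a, mc, defined, threshold = 0.95) {
  out <- rep("interior", length(h))
  out[defined & h >= threshold] <- "H"
  out[defined & a >= threshold] <- "A"
  out[defined & mc >= threshold] <- "MC"
  out
}

#' Run the citation-editing experiment
#'
#' For each selected article, scores the natural year-b network ("before"),
#' then rebuilds and re-scores the profile under each requested edit,
#' reporting the change in raw vote fraction and in bin-center value. Results
#' are stratified by triangle-vertex membership of the edited article (at
#' least 95% of HAMC content in one category).
#'
#' @param scores,edges Corpus tables.
#' @param article_ids Articles to edit (e.g. from [select_apt_up()]).
#' @param clf,calib Classifier and calibration.
#' @param window_a,window_b Years post publication of the two snapshots.
#' @param edits Subset of [EDIT_TYPES].
#' @param seed Integer seed; per-article edit seeds are derived from it.
#' @param replace_all Passed to [edit_network()].
#' @param vertex_threshold HAMC fraction defining vertex membership.
#' @return List with `results` (one row per article x edit: bins and raw
#'   scores before/after, `delta_raw`, `delta_bin_center`, `vertex_stratum`)
#'   and `summary` (per edit x stratum means and the proportion moving to a
#'   higher bin).
#' @export
run_editing_experiment <- function(scores, edges, article_ids, clf, calib,
                                   window_a = 2, window_b = 3,
                                   edits = EDIT_TYPES, seed = 1L,
                                   replace_all = FALSE,
                                   vertex_threshold = 0.95) {
  stopifnot(all(edits %in% EDIT_TYPES), length(article_ids) > 0L)
  scores <- data.table::as.data.table(scores)
  e_a <- restrict_network(edges, scores, window_years = window_a)
  e_b <- restrict_network(edges, scores, window_years = window_b)
  citer_tab <- scores[, .(citing_id = article_id, h, a, mc, d, e, cd, defined)]
  centers <- apt_bin_centers()

  rows <- list()
  for (i in seq_along(article_ids)) {
    id <- article_ids[i]
    art <- scores[article_id == id]
    if (nrow(art) != 1L) stop("article not found: ", id)
    citers_a <- citer_tab[e_a[cited_id == id], on = "citing_id", nomatch = NULL]
    citers_b <- citer_tab[e_b[cited_id == id], on = "citing_id", nomatch = NULL]
    if (!replace_all && nrow(citers_b) <= nrow(citers_a)) next
    asof <- art$pub_year + window_b
    before <- apt_score(clf, calib, profile_from_citers(art, citers_b, asof))
    stratum <- vertex_stratum(art$h, art$a, art$mc, art$defined, vertex_threshold)
    for (ed in edits) {
      edited <- edit_network(citers_a, citers_b, ed,
                             seed = as.integer(seed) + i, replace_all = replace_all)
      after <- apt_score(clf, calib, profile_from_citers(art, edited, asof))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        article_id = id, vertex_stratum = stratum, edit = ed,
        raw_before = before$raw, raw_after = after$raw,
        bin_before = as.character(before$bin), bin_after = as.character(after$bin),
        delta_raw = after$raw - before$raw,
        delta_bin_center = unname(centers[as.character(after$bin)] -
                                    centers[as.character(before$bin)])
      )
    }
  }
  if (length(rows) == 0L) stop("no editable articles (no network growth between snapshots)")
  results <- data.table::rbindlist(rows)
  lev <- apt_bin_levels()
  summary <- results[, .(
    n = .N,
    mean_delta_raw = mean(delta_raw),
    mean_delta_bin_center = mean(delta_bin_center),
    prop_moved_up = mean(match(bin_after, lev) > match(bin_before, lev))
  ), by = .(edit, vertex_stratum)]
  list(results = results[], summary = summary[])
}

#' Write citation-editing results to TSV
#'
#' @param experiment Output of [run_editing_experiment()].
#' @param results_path,summary_path Output file paths (`NULL` to skip one).
#' @return Invisibly, the paths written.
#' @export
write_editing_tsv <- function(experiment, results_path = NULL, summary_path = NULL) {
  if (!is.null(results_path)) data.table::fwrite(experiment$results, results_path, sep = "\t")
  if (!is.null(summary_path)) data.table::fwrite(experiment$summary, summary_path, sep = "\t")
  invisible(c(results_path, summary_path))
}
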