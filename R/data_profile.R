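# The 22-feature data profile: 7 article features plus 15 citing-network
# summary statistics, in a fixed canonical order shared by training and
# prediction.

#' Canonical data-profile feature names
#'
#' Seven article features (`H`, `A`, `MC` fractional content; `D`, `E`, `CD`
#' binary modifier flags; `CPY` citations per year) followed by fifteen
#' citing-network summaries (max/mean/SD of the citing Human, Animal and
#' Molecular/Cellular scores; mean/SD of the citing Disease, Therapeutic/
#' Diagnostic and Chemical/Drug flags).
#'
#' @format Character vector of length 22.
#' @export
APT_FEATURES <- c(
  "H", "A", "MC", "D", "E", "CD", "CPY",
  "maxH", "meanH", "sdH",
  "maxA", "meanA", "sdA",
  "maxMC", "meanMC", "sdMC",
  "meanD", "sdD", "meanE", "sdE", "meanCD", "sdCD"
)

# Population standard deviation; 0 for n <= 1 so singleton and empty networks
# stay finite.
pop_sd <- function(x) {
  n <- length(x)
  if (n <= 1L) return(0)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / n)
}

#' Restrict a citation-edge table to an information window
#'
#' Keeps edges whose citation year is at most `window_years` after the cited
#' article's publication year (boundary inclusive: a 2-year window retains
#' citation years `pub_year .. pub_year + 2`), or at most `as_of_year` in
#' calendar time. Optionally drops edges whose citing article is clinical — the
#' robustness control for clinical signal already present in the network.
#'
#' @param edges Edge table with `citing_id`, `cited_id`, `year`.
#' @param scores Article table from [score_articles()] (supplies cited
#'   `pub_year` and citing `is_clinical`).
#' @param window_years Non-negative window relative to each cited article, or
#'   `NULL`.
#' @param as_of_year Absolute calendar cut, or `NULL`. Exactly one of
#'   `window_years`/`as_of_year` must be given.
#' @param exclude_clinical Drop edges from clinical citing articles.
#' @param strict If `TRUE`, edges citing before the cited article's
#'   publication year are an error; otherwise they are kept with a warning.
#' @return Filtered edge `data.table`.
#' @export
restrict_network <- function(edges, scores, window_years = NULL, as_of_year = NULL,
                             exclude_clinical = FALSE, strict = FALSE) {
  if (is.null(window_years) == is.null(as_of_year)) {
    stop("give exactly one of window_years or as_of_year")
  }
  edges <- data.table::as.data.table(edges)
  scores <- data.table::as.data.table(scores)
  e <- scores[, .(cited_id = article_id, cited_pub_year = pub_year)][edges, on = "cited_id"]
  if (anyNA(e$cited_pub_year)) stop("edges cite unknown article ids")
  backwards <- e$year < e$cited_pub_year
  if (any(backwards)) {
    if (strict) stop(sum(backwards), " edge(s) predate the cited article")
    warning(sum(backwards), " edge(s) predate the cited article; kept",
            call. = FALSE)
  }
  if (!is.null(window_years)) {
    stopifnot(window_years >= 0)
    e <- e[year - cited_pub_year <= window_years]
  } else {
    e <- e[year <= as_of_year]
  }
  if (isTRUE(exclude_clinical)) {
    clin <- scores$article_id[scores$is_clinical]
    e <- e[!citing_id %in% clin]
  }
  e[, cited_pub_year := NULL]
  e[]
}

#' Citation rate (citations per year)
#'
#' `n_citations / max(1, as_of_year - pub_year + 1)`: elapsed calendar years
#' plus one, floored at one so articles cited in their publication year have a
#' finite rate.
#'
#' @param n_citations Non-negative citation count(s).
#' @param pub_year Publication year(s).
#' @param as_of_year Year at which the rate is assessed (`>= pub_year`).
#' @return Numeric vector of rates.
#' @export
citation_rate <- function(n_citations, pub_year, as_of_year) {
  stopifnot(all(n_citations >= 0), all(as_of_year >= pub_year))
  n_citations / pmax(1, as_of_year - pub_year + 1)
}

#' Summarise a citing network
#'
#' Max, mean and population SD of the citing articles' Human, Animal and
#' Molecular/Cellular scores, and mean and SD of their binary Disease,
#' Therapeutic/Diagnostic and Chemical/Drug flags. Citers with an undefined
#' HAMC score contribute `(0, 0, 0)` to the HAMC columns but still count in
#' every denominator. An empty network yields all zeros with attribute
#' `is_empty`.
#'
#' @param citers `data.frame` with columns `h`, `a`, `mc`, `d`, `e`, `cd` and
#'   optionally `defined` (default all `TRUE`); zero rows allowed.
#' @return Named numeric vector of the 15 network features, with attributes
#'   `n` (number of citers) and `is_empty`.
#' @export
summarize_network <- function(citers) {
  citers <- as.data.frame(citers)
  n <- nrow(citers)
  empty <- stats::setNames(numeric(15L), APT_FEATURES[8:22])
  if (n == 0L) {
    attr(empty, "n") <- 0L
    attr(empty, "is_empty") <- TRUE
    return(empty)
  }
  stopifnot(all(c("h", "a", "mc", "d", "e", "cd") %in% names(citers)))
  def <- if ("defined" %in% names(citers)) as.logical(citers$defined) else rep(TRUE, n)
  h <- ifelse(def, citers$h, 0)
  a <- ifelse(def, citers$a, 0)
  mc <- ifelse(def, citers$mc, 0)
  out <- c(
    maxH = max(h), meanH = mean(h), sdH = pop_sd(h),
    maxA = max(a), meanA = mean(a), sdA = pop_sd(a),
    maxMC = max(mc), meanMC = mean(mc), sdMC = pop_sd(mc),
    meanD = mean(citers$d), sdD = pop_sd(citers$d),
    meanE = mean(citers$e), sdE = pop_sd(citers$e),
    meanCD = mean(citers$cd), sdCD = pop_sd(citers$cd)
  )
  attr(out, "n") <- n
  attr(out, "is_empty") <- FALSE
  out
}

#' Build data profiles for every article in a corpus
#'
#' Composes the article content features with the time-restricted citing
#' network summaries and the citation rate over the same window. Articles with
#' no retained citations get an all-zero network block and `CPY = 0`.
#'
#' @param scores Article table from [score_articles()].
#' @param edges Edge table (`citing_id`, `cited_id`, `year`).
#' @param window_years,as_of_year,exclude_clinical,strict Passed to
#'   [restrict_network()].
#' @param rate_full_history If `TRUE`, `CPY` uses the full (unrestricted)
#'   citation count and the full elapsed time to the last corpus year instead
#'   of the restricted window.
#' @param lenient Dangling citing ids (citers absent from `scores`) are
#'   dropped with a warning instead of erroring.
#' @return `data.table`: `article_id`, the 22 canonical feature columns, and a
#'   bookkeeping column `n_citers`.
#' @export
build_profiles <- function(scores, edges, window_years = NULL, as_of_year = NULL,
                           exclude_clinical = FALSE, rate_full_history = FALSE,
                           strict = FALSE, lenient = FALSE) {
  scores <- data.table::as.data.table(scores)
  e <- restrict_network(edges, scores, window_years = window_years,
                        as_of_year = as_of_year,
                        exclude_clinical = exclude_clinical, strict = strict)
  citer_cols <- scores[, .(citing_id = article_id, ch = ifelse(defined, h, 0),
                           ca = ifelse(defined, a, 0), cmc = ifelse(defined, mc, 0),
                           cd_ = as.numeric(d), ce_ = as.numeric(e),
                           ccd_ = as.numeric(cd))]
  e2 <- citer_cols[e, on = "citing_id"]
  dangling <- is.na(e2$ch)
  if (any(dangling)) {
    if (lenient) {
      warning("dropping ", sum(dangling), " edge(s) with unknown citing ids",
              call. = FALSE)
      e2 <- e2[!dangling]
    } else {
      stop(sum(dangling), " edge(s) have citing ids absent from the article table")
    }
  }
  psd <- function(v) { m <- mean(v); sqrt(mean((v - m)^2)) }
  if (nrow(e2) == 0L) {
    net <- data.table::data.table(article_id = character(0), n_citers = integer(0))
    for (nm in APT_FEATURES[8:22]) data.table::set(net, j = nm, value = numeric(0))
  } else {
  net <- e2[, .(
    n_citers = .N,
    maxH = max(ch), meanH = mean(ch), sdH = if (.N <= 1L) 0 else psd(ch),
    maxA = max(ca), meanA = mean(ca), sdA = if (.N <= 1L) 0 else psd(ca),
    maxMC = max(cmc), meanMC = mean(cmc), sdMC = if (.N <= 1L) 0 else psd(cmc),
    meanD = mean(cd_), sdD = if (.N <= 1L) 0 else psd(cd_),
    meanE = mean(ce_), sdE = if (.N <= 1L) 0 else psd(ce_),
    meanCD = mean(ccd_), sdCD = if (.N <= 1L) 0 else psd(ccd_)
  ), by = .(article_id = cited_id)]
  }

  prof <- scores[, .(article_id, pub_year,
                     H = ifelse(defined, h, 0), A = ifelse(defined, a, 0),
                     MC = ifelse(defined, mc, 0),
                     D = as.numeric(d), E = as.numeric(e), CD = as.numeric(cd))]
  prof <- net[prof, on = "article_id"]
  for (col in c("n_citers", APT_FEATURES[8:22])) {
    data.table::set(prof, which(is.na(prof[[col]])), col, 0)
  }
  if (isTRUE(rate_full_history)) {
    full <- data.table::as.data.table(edges)[, .(n_full = .N), by = .(article_id = cited_id)]
    prof <- full[prof, on = "article_id"]
    data.table::set(prof, which(is.na(prof$n_full)), "n_full", 0)
    last_year <- max(scores$pub_year, data.table::as.data.table(edges)$year)
    prof[, CPY := citation_rate(n_full, pub_year, pmax(pub_year, last_year))]
    prof[, n_full := NULL]
  } else {
    asof <- if (!is.null(window_years)) prof$pub_year + window_years else
      pmax(prof$pub_year, as_of_year)
    prof[, CPY := citation_rate(n_citers, pub_year, asof)]
  }
  prof[, pub_year := NULL]
  data.table::setcolorder(prof, c("article_id", APT_FEATURES, "n_citers"))
  prof[]
}

#' Build the data profile of a single article
#'
#' @inheritParams build_profiles
#' @param article_id Id of the article of interest.
#' @return One-row `data.table` (see [build_profiles()]).
#' @export
build_profile <- function(article_id, scores, edges, window_years = NULL,
                          as_of_year = NULL, ...) {
  prof <- build_profiles(scores, edges, window_years = window_years,
                         as_of_year = as_of_year, ...)
  row <- prof[prof$article_id == article_id]
  if (nrow(row) == 0L) stop("article not found: ", article_id)
  row
}

# Extract/validate the canonical 22 feature columns, by name, in order.
profile_features <- function(profiles, required = APT_FEATURES) {
  profiles <- as.data.frame(profiles)
  missing <- setdiff(required, names(profiles))
  if (length(missing) > 0L) {
    stop("profile is missing feature column(s): ", paste(missing, collapse = ", "))
  }
  out <- profiles[, required, drop = FALSE]
  stopifnot(ncol(out) == 22L)
  out
}

#' Assemble a profile row from an explicit citer table
#'
#' Used by trajectory and citation-editing computations, where the citing
#' network is manipulated directly rather than read from the edge table.
#'
#' @param article One-row article table (from [score_articles()]) supplying
#'   the seven article features and `pub_year`.
#' @param citers Citer score table for [summarize_network()] (zero rows
#'   allowed).
#' @param as_of_year Year at which `CPY` is assessed.
#' @return One-row `data.table` with `article_id`, the 22 features, `n_citers`.
#' @export
profile_from_citers <- function(article, citers, as_of_year) {
  article <- data.table::as.data.table(article)
  stopifnot(nrow(article) == 1L)
  net <- summarize_network(citers)
  n <- attr(net, "n")
  row <- data.table::data.table(
    article_id = article$article_id,
    H = ifelse(article$defined, article$h, 0),
    A = ifelse(article$defined, article$a, 0),
    MC = ifelse(article$defined, article$mc, 0),
    D = as.numeric(article$d), E = as.numeric(article$e),
    CD = as.numeric(article$cd),
    CPY = citation_rate(n, article$pub_year, max(article$pub_year, as_of_year))
  )
  for (nm in names(net)) data.table::set(row, j = nm, value = net[[nm]])
  row[, n_citers := n]
  data.table::setcolorder(row, c("article_id", APT_FEATURES, "n_citers"))
  row[]
}
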