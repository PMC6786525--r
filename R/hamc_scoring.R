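# Fractional HAMC content scores, trilinear (ternary) coordinates, focus
# classes, and cumulative clinical-citation curves.

#' Fractional HAMC score
#'
#' Divides the number of Human, Animal and Molecular/Cellular terms by the
#' total across the three categories. With no HAMC terms the score is
#' undefined (`defined = FALSE`) and all fractions are zero.
#'
#' @param counts Named numeric vector with at least `HUMAN`, `ANIMAL`,
#'   `MOLCELL` entries (as from [category_counts()]); missing entries count 0.
#' @return A `hamc_score`: list with `h`, `a`, `mc`, `defined`.
#' @examples
#' fractional_hamc(c(HUMAN = 1, ANIMAL = 3, MOLCELL = 0))  # h = 0.25
#' @export
fractional_hamc <- function(counts) {
  cnt <- .hamc_counts(counts)
  if (any(cnt < 0)) stop("category counts must be non-negative")
  denom <- sum(cnt)
  if (denom == 0) {
    return(structure(list(h = 0, a = 0, mc = 0, defined = FALSE),
                     class = "hamc_score"))
  }
  structure(list(h = cnt[["HUMAN"]] / denom, a = cnt[["ANIMAL"]] / denom,
                 mc = cnt[["MOLCELL"]] / denom, defined = TRUE),
            class = "hamc_score")
}

#' Binary HAMC score
#'
#' The coarser baseline: each category contributes 1 if any term is present,
#' then present categories are normalised to sum 1. An article with 1 Human and
#' 3 Animal terms sits at the centre of the Human-Animal axis under binary
#' counting, where fractional counting shifts it toward the Animal vertex.
#'
#' @inheritParams fractional_hamc
#' @return A `hamc_score`.
#' @export
binary_hamc <- function(counts) {
  cnt <- .hamc_counts(counts)
  if (any(cnt < 0)) stop("category counts must be non-negative")
  fractional_hamc(as.integer(cnt > 0) * c(HUMAN = 1, ANIMAL = 1, MOLCELL = 1))
}

.hamc_counts <- function(counts) {
  if (inherits(counts, "hamc_score")) stop("expected counts, not a hamc_score")
  nm <- names(counts)
  if (is.null(nm)) stop("counts must be named by category")
  out <- c(HUMAN = 0, ANIMAL = 0, MOLCELL = 0)
  for (k in names(out)) if (k %in% nm) out[[k]] <- as.numeric(counts[[k]])
  out
}

#' @export
print.hamc_score <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<hamc_score> h=%.3f a=%.3f mc=%.3f\n", x$h, x$a, x$mc))
  } else {
    cat("<hamc_score> undefined (no HAMC terms)\n")
  }
  invisible(x)
}

# Vectorised trilinear transform; the constants are the vertex coordinates of
# the equilateral triangle: Human (0, 1), Animal (sqrt(3)/2, -1/2),
# Molecular/Cellular (-sqrt(3)/2, -1/2).
trilinear_xy <- function(h, a, mc) {
  s <- sqrt(3) / 2
  list(x = h * 0 + a * s + mc * (-s), y = h * 1 + a * (-0.5) + mc * (-0.5))
}

#' Trilinear coordinates of a HAMC score
#'
#' Maps simplex coordinates `(h, a, mc)` onto the equilateral triangle with
#' vertices `(0, 1)` for Human, `(sqrt(3)/2, -0.5)` for Animal and
#' `(-sqrt(3)/2, -0.5)` for Molecular/Cellular.
#'
#' @param score A `hamc_score` (see [fractional_hamc()]), or a named list or
#'   vector with `h`, `a`, `mc` summing to 1.
#' @return Named numeric vector `c(x = , y = )`.
#' @export
trilinear_coords <- function(score) {
  if (inherits(score, "hamc_score") && !score$defined) {
    stop("trilinear coordinates are undefined for an article with no HAMC terms")
  }
  h <- score[["h"]]; a <- score[["a"]]; mc <- score[["mc"]]
  if (abs(h + a + mc - 1) > 1e-9) {
    stop("h + a + mc must equal 1 (within 1e-9)")
  }
  xy <- trilinear_xy(h, a, mc)
  c(x = xy$x, y = xy$y)
}

article_focus_vec <- function(nH, nA, nMC) {
  out <- rep("MIXED", length(nH))
  out[nH == 0 & (nA > 0 | nMC > 0)] <- "FUNDAMENTAL"
  out[nH > 0 & nA == 0 & nMC == 0] <- "HUMAN_FOCUSED"
  out[nH == 0 & nA == 0 & nMC == 0] <- "UNCLASSIFIED"
  factor(out, levels = c("FUNDAMENTAL", "HUMAN_FOCUSED", "MIXED", "UNCLASSIFIED"))
}

#' Article focus class
#'
#' `FUNDAMENTAL`: at least one Animal or Molecular/Cellular term and no Human
#' terms. `HUMAN_FOCUSED`: at least one Human term and no Animal or
#' Molecular/Cellular terms. `UNCLASSIFIED`: no HAMC terms at all. `MIXED`
#' otherwise.
#'
#' @inheritParams fractional_hamc
#' @return Length-1 factor.
#' @export
article_focus <- function(counts) {
  cnt <- .hamc_counts(counts)
  article_focus_vec(cnt[["HUMAN"]], cnt[["ANIMAL"]], cnt[["MOLCELL"]])
}

#' Human-fraction band of an intermediate article
#'
#' For articles with a Human fraction strictly between 0 and 1: `LOW` when
#' `h <= 1/3`, `MID` when `1/3 < h <= 2/3`, `HIGH` when `h > 2/3`.
#'
#' @param score A `hamc_score` or a numeric Human fraction in (0, 1).
#' @return Length-1 factor with levels `LOW`, `MID`, `HIGH`.
#' @export
human_fraction_band <- function(score) {
  h <- if (inherits(score, "hamc_score")) score$h else as.numeric(score)
  stopifnot(length(h) == 1L, is.finite(h))
  if (h <= 0 || h >= 1) {
    stop("human_fraction_band is defined only for 0 < h < 1 (got h = ", h, ")")
  }
  band <- if (h <= 1 / 3) "LOW" else if (h <= 2 / 3) "MID" else "HIGH"
  factor(band, levels = c("LOW", "MID", "HIGH"))
}

#' Cumulative proportion of articles clinically cited over time
#'
#' For each horizon `t = 1..horizon_years`, the proportion of group articles
#' whose first citation by a clinical article occurred within `t` calendar
#' years of publication (`citation_year - pub_year <= t`). Monotone
#' non-decreasing in `t`.
#'
#' @param scores Article table (as from [score_articles()]) with `article_id`,
#'   `pub_year`, `is_clinical`.
#' @param edges Citation edge table with `citing_id`, `cited_id`, `year`.
#' @param horizon_years Positive integer horizon.
#' @param ids Optional character vector restricting the group of cited
#'   articles; defaults to every article in `scores`.
#' @param denominator `"all"` (every group article) or `"with_any_citation"`
#'   (only group articles with at least one citation of any kind).
#' @return `data.table` with columns `t_years`, `proportion`.
#' @export
cumulative_clinical_curve <- function(scores, edges, horizon_years, ids = NULL,
                                      denominator = c("all", "with_any_citation")) {
  denominator <- match.arg(denominator)
  stopifnot(horizon_years >= 1)
  scores <- data.table::as.data.table(scores)
  edges <- data.table::as.data.table(edges)
  if (is.null(ids)) ids <- scores$article_id
  group <- scores[article_id %in% ids]
  if (nrow(group) == 0L) stop("empty article group")
  if (denominator == "with_any_citation") {
    group <- group[article_id %in% edges$cited_id]
    if (nrow(group) == 0L) stop("no group article has any citation")
  }
  clin_ids <- scores$article_id[scores$is_clinical]
  ce <- edges[citing_id %in% clin_ids & cited_id %in% group$article_id]
  ce <- ce[group[, .(article_id, pub_year)], on = c(cited_id = "article_id"), nomatch = NULL]
  offs <- if (nrow(ce) == 0L) integer(0) else
    ce[, .(first_offset = min(year - pub_year)), by = cited_id]$first_offset
  data.table::data.table(
    t_years = seq_len(horizon_years),
    proportion = vapply(seq_len(horizon_years),
                        function(t) sum(offs <= t) / nrow(group), numeric(1L))
  )
}

#' Write trilinear coordinates to TSV
#'
#' Exports `article_id`, `h`, `a`, `mc`, `x`, `y` for articles with a defined
#' HAMC score (undefined articles cannot be placed on the triangle and are
#' dropped).
#'
#' @param scores Article table from [score_articles()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coords_tsv <- function(scores, path) {
  scores <- data.table::as.data.table(scores)
  out <- scores[defined == TRUE, .(article_id, h, a, mc, x, y)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
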