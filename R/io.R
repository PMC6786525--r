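# Readers and writers for the plain-text exchange formats: NLM ASCII MeSH
# descriptors, a two-column TSV vocabulary dialect, JSON-lines article
# records, and TSV edge/profile tables.

#' Read a MeSH vocabulary in NLM ASCII descriptor format
#'
#' Parses records delimited by `*NEWRECORD`, taking the descriptor name from
#' `MH = ` lines and tree addresses from `MN = ` lines. Descriptors without
#' any tree address (e.g. check tags in some vocabularies) are dropped with a
#' warning.
#'
#' @param path Path to the ASCII descriptor file.
#' @param lenient Passed to [mesh_vocabulary()].
#' @return A `mesh_vocabulary`.
#' @export
read_mesh_ascii <- function(path, lenient = FALSE) {
  lines <- readLines(path, warn = FALSE)
  rec_starts <- grepl("^\\*NEWRECORD", lines)
  rec_id <- cumsum(rec_starts)
  keep <- rec_id > 0L
  lines <- lines[keep]; rec_id <- rec_id[keep]
  mh <- sub("^MH = ", "", lines)
  is_mh <- startsWith(lines, "MH = ")
  mn <- sub("^MN = ", "", lines)
  is_mn <- startsWith(lines, "MN = ")
  out <- list()
  dropped <- 0L
  for (r in unique(rec_id)) {
    in_r <- rec_id == r
    name <- mh[in_r & is_mh]
    addr <- mn[in_r & is_mn]
    if (length(name) != 1L) next
    if (length(addr) == 0L) {
      dropped <- dropped + 1L
      next
    }
    out[[trimws(name)]] <- trimws(addr)
  }
  if (dropped > 0L) {
    warning("dropped ", dropped, " descriptor(s) without tree addresses",
            call. = FALSE)
  }
  mesh_vocabulary(out, lenient = lenient)
}

#' Read / write a two-column TSV vocabulary
#'
#' Fixture dialect: header `descriptor<TAB>address`, one row per
#' (descriptor, address) pair; descriptors with several addresses repeat.
#'
#' @param path File path.
#' @param lenient Passed to [mesh_vocabulary()].
#' @param vocab A `mesh_vocabulary` (for writing).
#' @return `read_mesh_tsv()`: a `mesh_vocabulary`; `write_mesh_tsv()`: `path`
#'   invisibly.
#' @export
read_mesh_tsv <- function(path, lenient = FALSE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  stopifnot(all(c("descriptor", "address") %in% names(dt)))
  mesh_vocabulary(split(dt$address, dt$descriptor), lenient = lenient)
}

#' @rdname read_mesh_tsv
#' @export
write_mesh_tsv <- function(vocab, path) {
  stopifnot(inherits(vocab, "mesh_vocabulary"))
  dt <- data.table::data.table(
    descriptor = rep(names(vocab$addresses), lengths(vocab$addresses)),
    address = unlist(vocab$addresses, use.names = FALSE))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write article records as JSON lines
#'
#' One JSON object per line with keys `article_id`, `pub_year`, `mesh_terms`,
#' `pub_types` (and optionally `is_clinical`, which must agree with the
#' publication-type rule). Values round-trip exactly through
#' `write_articles_jsonl()` / `read_articles_jsonl()`.
#'
#' @param path File path.
#' @param year_range Optional corpus year range enforced on `pub_year`.
#' @param articles Article `data.table` (for writing), with list-columns
#'   `mesh_terms` and `pub_types`.
#' @return `read_articles_jsonl()`: `data.table` with columns `article_id`,
#'   `pub_year`, `mesh_terms`, `pub_types`, `is_clinical`;
#'   `write_articles_jsonl()`: `path` invisibly.
#' @export
read_articles_jsonl <- function(path, year_range = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  need <- c("article_id", "pub_year", "mesh_terms", "pub_types")
  for (r in recs) {
    if (!all(need %in% names(r))) {
      stop("article record missing key(s): ",
           paste(setdiff(need, names(r)), collapse = ", "))
    }
  }
  pub_year <- vapply(recs, function(r) as.integer(r$pub_year), integer(1L))
  if (!is.null(year_range) &&
      any(pub_year < year_range[1L] | pub_year > year_range[2L])) {
    stop("article pub_year outside corpus range [",
         year_range[1L], ", ", year_range[2L], "]")
  }
  derived <- vapply(recs, function(r) is_clinical_article(as.character(r$pub_types)),
                    logical(1L))
  supplied <- vapply(recs, function(r)
    if (is.null(r$is_clinical)) NA else as.logical(r$is_clinical), logical(1L))
  bad <- !is.na(supplied) & supplied != derived
  if (any(bad)) {
    stop("is_clinical flag contradicts pub_types for article(s): ",
         paste(utils::head(vapply(recs[bad], `[[`, "", "article_id"), 5L),
               collapse = ", "))
  }
  data.table::data.table(
    article_id = vapply(recs, function(r) as.character(r$article_id), character(1L)),
    pub_year = pub_year,
    mesh_terms = lapply(recs, function(r) as.character(r$mesh_terms)),
    pub_types = lapply(recs, function(r) as.character(r$pub_types)),
    is_clinical = derived
  )
}

#' @rdname read_articles_jsonl
#' @export
write_articles_jsonl <- function(articles, path) {
  articles <- data.table::as.data.table(articles)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(articles))) {
    rec <- list(article_id = articles$article_id[i],
                pub_year = articles$pub_year[i],
                mesh_terms = as.character(articles$mesh_terms[[i]]),
                pub_types = as.character(articles$pub_types[[i]]),
                is_clinical = articles$is_clinical[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read / write citation edges as three-column TSV
#'
#' Columns `citing_id`, `cited_id`, `year`.
#'
#' @param path File path.
#' @param edges Edge table (for writing).
#' @return `read_edges_tsv()`: edge `data.table`; `write_edges_tsv()`: `path`
#'   invisibly.
#' @export
read_edges_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("citing_id", "cited_id"),
                                            integer = "year"))
  stopifnot(all(c("citing_id", "cited_id", "year") %in% names(dt)))
  dt
}

#' @rdname read_edges_tsv
#' @export
write_edges_tsv <- function(edges, path) {
  edges <- data.table::as.data.table(edges)
  data.table::fwrite(edges[, .(citing_id, cited_id, year)], path, sep = "\t")
  invisible(path)
}

#' Read / write data-profile tables as TSV
#'
#' The canonical 22 feature columns plus `article_id` and any label columns.
#' Reading validates that every canonical feature is present.
#'
#' @param path File path.
#' @param profiles Profile table (for writing).
#' @return `read_profiles_tsv()`: profile `data.table`;
#'   `write_profiles_tsv()`: `path` invisibly.
#' @export
read_profiles_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  missing <- setdiff(APT_FEATURES, names(dt))
  if (length(missing) > 0L) {
    stop("profile TSV is missing feature column(s): ",
         paste(missing, collapse = ", "))
  }
  dt
}

#' @rdname read_profiles_tsv
#' @export
write_profiles_tsv <- function(profiles, path) {
  data.table::fwrite(data.table::as.data.table(profiles), path, sep = "\t")
  invisible(path)
}
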