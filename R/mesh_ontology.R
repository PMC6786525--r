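# MeSH tree-address classification into the six category systems used by the
# triangle of biomedicine and the data-profile features.

#' The six content category systems
#'
#' `HUMAN`, `ANIMAL` and `MOLCELL` are the HAMC triangle categories; `DISEASE`,
#' `THERAP` and `CHEMDRUG` drive the binary D/E/CD modifier flags.
#'
#' @format Character vector of length six.
#' @export
MESH_CATEGORIES <- c("HUMAN", "ANIMAL", "MOLCELL", "DISEASE", "THERAP", "CHEMDRUG")

# The single tree address of the "Humans" descriptor; the one B01 address that
# is Human rather than Animal.
HUMANS_ADDRESS <- "B01.050.150.900.649.801.400.112.400.400"

# Roots of the Molecular/Cellular Biology category: Cells, Archaea, Bacteria,
# Viruses, Molecular Structure, Chemical Processes.
MOLCELL_ROOTS <- c("A11", "B02", "B03", "B04", "G02.111.570", "G02.149")

# Publication types that make an article "clinical" (lower-case, canonical).
CLINICAL_PUB_TYPES <- c(
  "clinical trial",
  paste0("clinical trial, phase ", c("i", "ii", "iii", "iv")),
  "clinical study",
  "guideline"
)

#' Validate MeSH tree addresses
#'
#' A tree address is a dot-separated path whose first segment is an upper-case
#' letter followed by digits (e.g. `"B01.050"`); later segments are
#' alphanumeric.
#'
#' @param address Character vector of candidate addresses.
#' @return Logical vector.
#' @export
is_valid_address <- function(address) {
  !is.na(address) & grepl("^[A-Z][0-9]+(\\.[0-9A-Za-z]+)*$", address)
}

#' Tree-address descent
#'
#' `a` is-or-descends-from `b` iff `a == b` or `a` starts with `b` followed by
#' a dot. Both arguments are recycled.
#'
#' @param address,ancestor Character vectors of tree addresses.
#' @return Logical vector.
#' @export
address_descends_from <- function(address, ancestor) {
  address == ancestor | startsWith(address, paste0(ancestor, "."))
}

# Vectorised rule engine: one row per address, one logical column per category.
.classify_address_matrix <- function(addresses) {
  bad <- !is_valid_address(addresses)
  if (any(bad)) {
    stop("malformed MeSH tree address(es): ",
         paste(utils::head(addresses[bad], 5L), collapse = ", "))
  }
  branch <- substr(addresses, 1L, 1L)
  human <- addresses == HUMANS_ADDRESS | address_descends_from(addresses, "M01")
  animal <- address_descends_from(addresses, "B01") & addresses != HUMANS_ADDRESS
  molcell <- Reduce(`|`, lapply(MOLCELL_ROOTS, address_descends_from, address = addresses))
  disease <- branch == "C" & !address_descends_from(addresses, "C22")
  therap <- branch == "E" & !address_descends_from(addresses, "E07")
  chemdrug <- branch == "D"
  m <- cbind(HUMAN = human, ANIMAL = animal, MOLCELL = molcell,
             DISEASE = disease, THERAP = therap, CHEMDRUG = chemdrug)
  rownames(m) <- NULL
  m
}

#' Classify one tree address
#'
#' Applies the address rules: Human is the single `Humans` address or anything
#' under `M01` (Persons); Animal is anything under `B01` except the Humans
#' address; Molecular/Cellular is anything under `A11`, `B02`, `B03`, `B04`,
#' `G02.111.570` or `G02.149`; Disease is the `C` branch except `C22` (Animal
#' Diseases); Therapeutic/Diagnostic is the `E` branch except `E07` (Equipment
#' and Supplies); Chemical/Drug is the `D` branch.
#'
#' @param address A single tree address string.
#' @return Character vector: the (possibly empty) subset of [MESH_CATEGORIES]
#'   triggered by this address.
#' @examples
#' classify_address("B01.050")  # ANIMAL
#' classify_address("Z99.123")  # none
#' @export
classify_address <- function(address) {
  stopifnot(is.character(address), length(address) == 1L)
  m <- .classify_address_matrix(address)
  MESH_CATEGORIES[m[1L, ]]
}

#' Construct a MeSH vocabulary
#'
#' @param addresses Named list; each element a character vector of one or more
#'   tree addresses for that descriptor.
#' @param lenient If `TRUE`, lookups of unknown descriptors warn and return no
#'   addresses instead of erroring.
#' @return An object of class `mesh_vocabulary`.
#' @export
mesh_vocabulary <- function(addresses, lenient = FALSE) {
  stopifnot(is.list(addresses), length(addresses) > 0L)
  if (is.null(names(addresses)) || any(!nzchar(names(addresses)))) {
    stop("every descriptor must be named")
  }
  n_addr <- lengths(addresses)
  if (any(n_addr == 0L)) {
    stop("descriptor(s) without any tree address: ",
         paste(utils::head(names(addresses)[n_addr == 0L], 5L), collapse = ", "))
  }
  all_addr <- unlist(addresses, use.names = FALSE)
  if (any(!is_valid_address(all_addr))) {
    stop("vocabulary contains malformed tree addresses")
  }
  structure(list(addresses = addresses, lenient = isTRUE(lenient)),
            class = "mesh_vocabulary")
}

#' @export
print.mesh_vocabulary <- function(x, ...) {
  cat("<mesh_vocabulary>", length(x$addresses), "descriptors,",
      sum(lengths(x$addresses)), "tree addresses,",
      if (x$lenient) "lenient" else "strict", "lookup\n")
  invisible(x)
}

# Qualifier (subheading) strings like "Neoplasms/drug therapy" are attached to
# descriptors in indexed records; classification is by descriptor only.
strip_qualifier <- function(descriptor) {
  trimws(sub("/.*$", "", descriptor))
}

vocab_addresses <- function(vocab, descriptor) {
  stopifnot(inherits(vocab, "mesh_vocabulary"))
  key <- strip_qualifier(descriptor)
  addr <- vocab$addresses[[key]]
  if (is.null(addr)) {
    if (vocab$lenient) {
      warning("unknown MeSH descriptor (lenient mode): ", key, call. = FALSE)
      return(character(0))
    }
    stop("unknown MeSH descriptor: ", key)
  }
  addr
}

#' Classify a descriptor through a vocabulary
#'
#' The union of [classify_address()] over all tree addresses of the descriptor;
#' a descriptor counts at most once per category however many of its addresses
#' match, and may fall in several categories.
#'
#' @param descriptor Descriptor name (an attached `/qualifier` is stripped).
#' @param vocab A [mesh_vocabulary()].
#' @return Character vector, subset of [MESH_CATEGORIES].
#' @export
classify_term <- function(descriptor, vocab) {
  addr <- vocab_addresses(vocab, descriptor)
  if (length(addr) == 0L) return(character(0))
  m <- .classify_address_matrix(addr)
  MESH_CATEGORIES[colSums(m) > 0L]
}

#' Count an article's distinct descriptors per category
#'
#' Set semantics: duplicate descriptors (after qualifier stripping) are counted
#' once; one descriptor may contribute to several categories.
#'
#' @param mesh_terms Character vector of descriptor names, or an
#'   `article_record` (its `mesh_terms` are used).
#' @param vocab A [mesh_vocabulary()].
#' @return Named integer vector over [MESH_CATEGORIES].
#' @export
category_counts <- function(mesh_terms, vocab) {
  if (inherits(mesh_terms, "article_record")) mesh_terms <- mesh_terms$mesh_terms
  stopifnot(is.character(mesh_terms) || length(mesh_terms) == 0L)
  terms <- unique(strip_qualifier(mesh_terms))
  counts <- stats::setNames(integer(length(MESH_CATEGORIES)), MESH_CATEGORIES)
  for (tm in terms) {
    cats <- classify_term(tm, vocab)
    counts[cats] <- counts[cats] + 1L
  }
  counts
}

#' Is a publication-type list clinical?
#'
#' True iff any publication type is a clinical trial (any phase), a clinical
#' study, or a guideline. Matching is case-insensitive and whitespace-trimmed.
#'
#' @param pub_types Character vector of publication-type strings.
#' @return Logical scalar.
#' @export
is_clinical_article <- function(pub_types) {
  any(tolower(trimws(pub_types)) %in% CLINICAL_PUB_TYPES)
}

#' Construct an article record
#'
#' @param article_id Opaque identifier string.
#' @param pub_year Integer publication year.
#' @param mesh_terms Character vector of MeSH descriptor names.
#' @param pub_types Character vector of publication-type strings.
#' @param is_clinical Optional logical; when supplied it must agree with the
#'   clinical-type rule applied to `pub_types`.
#' @param year_range Optional length-2 integer vector; `pub_year` must fall
#'   inside it.
#' @return An object of class `article_record`.
#' @export
article_record <- function(article_id, pub_year, mesh_terms = character(0),
                           pub_types = character(0), is_clinical = NULL,
                           year_range = NULL) {
  stopifnot(length(article_id) == 1L, nzchar(article_id),
            length(pub_year) == 1L, is.finite(pub_year))
  pub_year <- as.integer(pub_year)
  if (!is.null(year_range) &&
      (pub_year < year_range[1L] || pub_year > year_range[2L])) {
    stop("pub_year ", pub_year, " outside corpus range [",
         year_range[1L], ", ", year_range[2L], "]")
  }
  derived <- is_clinical_article(pub_types)
  if (!is.null(is_clinical) && !identical(as.logical(is_clinical), derived)) {
    stop("is_clinical flag contradicts pub_types for article ", article_id)
  }
  structure(
    list(article_id = as.character(article_id), pub_year = pub_year,
         mesh_terms = as.character(mesh_terms),
         pub_types = as.character(pub_types), is_clinical = derived),
    class = "article_record"
  )
}

#' Score an article table through the category rules
#'
#' Vectorised scoring of many articles at once: distinct-descriptor counts per
#' category, fractional HAMC scores, D/E/CD flags, focus class and triangle
#' coordinates.
#'
#' @param articles `data.frame`/`data.table` with columns `article_id`,
#'   `pub_year`, list-column `mesh_terms`, and either `is_clinical` or a
#'   list-column `pub_types`.
#' @param vocab A [mesh_vocabulary()].
#' @return A `data.table` with one row per article: `article_id`, `pub_year`,
#'   `is_clinical`, counts `nH`/`nA`/`nMC`/`nD`/`nE`/`nCD`, fractions
#'   `h`/`a`/`mc`, `defined`, flags `d`/`e`/`cd`, `focus`, coordinates `x`/`y`
#'   (NA when undefined).
#' @export
score_articles <- function(articles, vocab) {
  stopifnot(inherits(vocab, "mesh_vocabulary"))
  articles <- data.table::as.data.table(articles)
  stopifnot(all(c("article_id", "pub_year", "mesh_terms") %in% names(articles)))
  if (!"is_clinical" %in% names(articles)) {
    stopifnot("pub_types" %in% names(articles))
    articles[, is_clinical := vapply(pub_types, is_clinical_article, logical(1L))]
  }

  # descriptor -> category incidence for the whole vocabulary, computed once
  desc <- names(vocab$addresses)
  addr_long <- data.table::data.table(
    descriptor = rep(desc, lengths(vocab$addresses)),
    address = unlist(vocab$addresses, use.names = FALSE)
  )
  cat_mat <- .classify_address_matrix(addr_long$address)
  desc_cats <- data.table::as.data.table(cat_mat)[
    , lapply(.SD, any), by = .(descriptor = addr_long$descriptor)]

  long <- articles[, .(descriptor = unique(strip_qualifier(unlist(mesh_terms)))),
                   by = article_id]
  long <- long[!is.na(descriptor) & nzchar(descriptor)]
  unknown <- setdiff(unique(long$descriptor), desc)
  if (length(unknown) > 0L) {
    if (vocab$lenient) {
      warning("dropping ", length(unknown), " unknown descriptor(s) in lenient mode",
              call. = FALSE)
      long <- long[!descriptor %in% unknown]
    } else {
      stop("unknown MeSH descriptor(s): ", paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  long <- desc_cats[long, on = "descriptor"]
  counts <- long[, .(nH = sum(HUMAN), nA = sum(ANIMAL), nMC = sum(MOLCELL),
                     nD = sum(DISEASE), nE = sum(THERAP), nCD = sum(CHEMDRUG)),
                 by = article_id]

  out <- counts[articles[, .(article_id, pub_year, is_clinical)], on = "article_id"]
  for (col in c("nH", "nA", "nMC", "nD", "nE", "nCD")) {
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  }
  denom <- out$nH + out$nA + out$nMC
  out[, defined := denom > 0L]
  out[, h := ifelse(defined, nH / denom, 0)]
  out[, a := ifelse(defined, nA / denom, 0)]
  out[, mc := ifelse(defined, nMC / denom, 0)]
  out[, d := as.integer(nD > 0L)]
  out[, e := as.integer(nE > 0L)]
  out[, cd := as.integer(nCD > 0L)]
  out[, focus := article_focus_vec(nH, nA, nMC)]
  xy <- trilinear_xy(out$h, out$a, out$mc)
  out[, x := ifelse(defined, xy$x, NA_real_)]
  out[, y := ifelse(defined, xy$y, NA_real_)]
  data.table::setcolorder(out, c("article_id", "pub_year", "is_clinical"))
  out[]
}
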