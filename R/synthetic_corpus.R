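# Seeded synthetic literature corpora: MeSH-profiled articles, a year-by-year
# citation network with preferential attachment and content-similarity
# weighting, clinical-type citers, and a planted logistic clinical-citation
# mechanism with known per-article probabilities.

#' Miniature MeSH vocabulary fixture
#'
#' About fifty descriptors spanning all six category systems, including the
#' Humans/Persons addresses, B01 animals, the Molecular/Cellular roots, C
#' (with a C22 animal-disease exclusion case), E (with an E07 exclusion case)
#' and D branches, plus multi-category and unclassified descriptors. Used by
#' the corpus generator and as a test substrate; real analyses load a full
#' NLM vocabulary with [read_mesh_ascii()].
#'
#' @param lenient Passed to [mesh_vocabulary()].
#' @return A `mesh_vocabulary`.
#' @export
toy_mesh_vocabulary <- function(lenient = FALSE) {
  mesh_vocabulary(list(
    # Human
    "Humans" = "B01.050.150.900.649.801.400.112.400.400",
    "Persons" = "M01",
    "Adult" = "M01.060.116",
    "Child" = "M01.060.406",
    "Aged" = "M01.060.116.100",
    "Infant" = "M01.060.703",
    "Pregnant Women" = "M01.975",
    "Health Personnel" = "M01.526.485",
    # Animal (B01 except Humans)
    "Animals" = "B01.050",
    "Mice" = "B01.050.150.900.649.313.992.635.505.500",
    "Rats" = "B01.050.150.900.649.313.992.635.505.700",
    "Dogs" = "B01.050.150.900.649.313.750.377.250",
    "Zebrafish" = "B01.050.150.900.493.817.986",
    "Drosophila melanogaster" = "B01.050.500.131.365.265.310.200",
    "Caenorhabditis elegans" = "B01.050.500.500.294.400.875.500.200",
    "Macaca mulatta" = "B01.050.150.900.649.801.400.112.199.500",
    "Swine" = "B01.050.150.900.649.313.875.141.819",
    # Molecular/Cellular
    "Cells, Cultured" = "A11.251.210",
    "HeLa Cells" = "A11.251.860.180.370",
    "Fibroblasts" = "A11.329.228",
    "Neurons" = "A11.671",
    "Stem Cells" = "A11.872",
    "Archaea" = "B02",
    "Escherichia coli" = "B03.440.450.425.325.300",
    "Bacteria" = "B03",
    "Viruses" = "B04",
    "HIV-1" = "B04.820.650.589.650.350.350",
    "Protein Conformation" = "G02.111.570.820.709.610",
    "Base Sequence" = "G02.111.570.080.708.100",
    "Phosphorylation" = "G02.149.704",
    "Glycolysis" = "G02.149.440",
    # Disease (C, except C22)
    "Neoplasms" = "C04",
    "Breast Neoplasms" = "C04.588.180",
    "Diabetes Mellitus" = "C18.452.394.750",
    "Cardiovascular Diseases" = "C14",
    "Alzheimer Disease" = "C10.228.140.380.100",
    "Hypertension" = "C14.907.489",
    "Asthma" = "C08.127.108",
    "Rodent Diseases" = "C22.795",
    "Foot-and-Mouth Disease" = "C22.005",
    # Therapeutic/Diagnostic (E, except E07)
    "Drug Therapy" = "E02.319",
    "Surgical Procedures, Operative" = "E04",
    "Magnetic Resonance Imaging" = "E01.370.350.825.500",
    "Immunotherapy" = "E02.095.520",
    "Biopsy" = "E01.370.225.500.098",
    "Transplantation" = "E04.936",
    "Equipment and Supplies" = "E07",
    "Surgical Instruments" = "E07.858",
    # Chemical/Drug
    "Antineoplastic Agents" = "D27.505.954.248",
    "Proteins" = "D12.776",
    "DNA" = "D13.444.308",
    "Antibodies, Monoclonal" = "D12.776.124.486.485.114.224",
    "Glucose" = "D09.400.105.450",
    # Multi-category / none
    "Disease Models, Animal" = c("C22.196", "E05.598.500.496"),
    "Tumor Cells, Cultured" = c("A11.251.860.900", "C04.557.337"),
    "Geographic Locations" = "Z01"
  ), lenient = lenient)
}

#' Synthetic corpus configuration
#'
#' Documented defaults draw a small PubMed-like corpus: a mixture of
#' human-focused, animal, molecular/cellular and mixed content regions on the
#' HAMC simplex; Poisson term counts; modifier-flag probabilities that rise
#' with human (and, for Disease, animal) content; a citation process with
#' preferential attachment and an exponential content-similarity kernel on
#' trilinear distance; and a logistic clinical-citation mechanism on the mean
#' Human score of the citing network, log citations per year, and the mean
#' Disease flag of the citing network. The default coefficients put the
#' prevalence of clinically cited articles near 0.2-0.3.
#'
#' @param n_articles Number of articles (>= 10).
#' @param year_range Two-element integer vector of publication years.
#' @param region_weights Mixture weights over the four content regions.
#' @param region_alpha Dirichlet concentrations (H, A, MC) per region.
#' @param mean_hamc_terms Poisson mean of HAMC term draws (plus one).
#' @param p_no_hamc Probability an article carries no HAMC term at all.
#' @param flag_probs Coefficients of the D/E/CD flag probabilities:
#'   `p_d = d0 + dh*h + da*a`, `p_e = e0 + eh*h`, `p_cd = cd0 + cdh*h +
#'   cdm*mc`, all clamped to `[0, 1]`.
#' @param mean_refs Poisson mean of references made per new article.
#' @param attachment_exponent Preferential-attachment exponent on
#'   `1 + prior citations`.
#' @param similarity_width Width of the exponential similarity kernel on
#'   trilinear Euclidean distance.
#' @param n_candidates Candidate references sampled per reference slot.
#' @param beta0,beta_meanH,beta_cpy,beta_meanD Logit-scale outcome
#'   coefficients of the planted mechanism.
#' @param clinical_frac Baseline scale of the clinical-article flag
#'   probability (`p = clinical_frac * (0.4 + 1.2 h)`).
#' @param seed Integer seed.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_articles = 5000,
                          year_range = c(2000L, 2011L),
                          region_weights = c(human = 0.30, animal = 0.20,
                                             molcell = 0.30, mixed = 0.20),
                          region_alpha = list(human = c(8, 1, 1),
                                              animal = c(1, 8, 1),
                                              molcell = c(1, 1, 8),
                                              mixed = c(3, 3, 3)),
                          mean_hamc_terms = 5,
                          p_no_hamc = 0.02,
                          flag_probs = c(d0 = 0.15, dh = 0.55, da = 0.35,
                                         e0 = 0.10, eh = 0.60,
                                         cd0 = 0.20, cdh = 0.30, cdm = 0.20),
                          mean_refs = 8,
                          attachment_exponent = 0.8,
                          similarity_width = 0.6,
                          n_candidates = 8L,
                          beta0 = -3.9, beta_meanH = 4.0, beta_cpy = 1.5,
                          beta_meanD = 1.5,
                          clinical_frac = 0.08,
                          seed = 1L) {
  stopifnot(n_articles >= 10, length(year_range) == 2L,
            year_range[2L] > year_range[1L],
            abs(sum(region_weights) - 1) < 1e-8, all(region_weights >= 0),
            length(region_alpha) == length(region_weights),
            mean_hamc_terms > 0, p_no_hamc >= 0, p_no_hamc <= 1,
            mean_refs >= 0, similarity_width > 0, n_candidates >= 1,
            clinical_frac >= 0, clinical_frac <= 1)
  structure(
    list(n_articles = as.integer(n_articles),
         year_range = as.integer(year_range),
         region_weights = region_weights, region_alpha = region_alpha,
         mean_hamc_terms = mean_hamc_terms, p_no_hamc = p_no_hamc,
         flag_probs = flag_probs, mean_refs = mean_refs,
         attachment_exponent = attachment_exponent,
         similarity_width = similarity_width,
         n_candidates = as.integer(n_candidates),
         beta0 = beta0, beta_meanH = beta_meanH, beta_cpy = beta_cpy,
         beta_meanD = beta_meanD, clinical_frac = clinical_frac,
         seed = as.integer(seed)),
    class = "corpus_config"
  )
}

rdirichlet_rows <- function(alpha_matrix) {
  g <- matrix(stats::rgamma(length(alpha_matrix), shape = alpha_matrix),
              nrow = nrow(alpha_matrix))
  g / rowSums(g)
}

# Pools of vocabulary descriptors per category (single-category HAMC pools so
# intended category counts translate into terms cleanly; flags use pure
# modifier pools).
.vocab_pools <- function(vocab) {
  desc <- names(vocab$addresses)
  cats <- lapply(desc, function(d) classify_term(d, vocab))
  names(cats) <- desc
  in_cat <- function(k) desc[vapply(cats, function(cc) k %in% cc, logical(1L))]
  hamc <- c("HUMAN", "ANIMAL", "MOLCELL")
  only <- function(k) {
    others <- setdiff(hamc, k)
    desc[vapply(cats, function(cc) k %in% cc && !any(others %in% cc), logical(1L))]
  }
  list(HUMAN = only("HUMAN"), ANIMAL = only("ANIMAL"), MOLCELL = only("MOLCELL"),
       DISEASE = setdiff(in_cat("DISEASE"), unlist(lapply(hamc, in_cat))),
       THERAP = setdiff(in_cat("THERAP"), unlist(lapply(hamc, in_cat))),
       CHEMDRUG = setdiff(in_cat("CHEMDRUG"), unlist(lapply(hamc, in_cat))))
}

#' Generate a synthetic literature corpus
#'
#' Deterministic given `config$seed`. Draws per-article HAMC simplex
#' positions from the configured region mixture, realises them as MeSH
#' descriptor lists from [toy_mesh_vocabulary()], grows a citation network
#' year by year with attachment probability proportional to
#' `(1 + prior citations)^alpha * exp(-distance / width)`, flags clinical
#' articles with probability increasing in human content, and assigns the
#' clinical-citation outcome `Bernoulli(plogis(beta0 + beta_meanH*meanH +
#' beta_cpy*log1p(cpy) + beta_meanD*meanD))` from each article's realised
#' full-history network.
#'
#' @param config A [corpus_config()].
#' @param vocab Vocabulary used to realise descriptor lists (defaults to the
#'   packaged miniature vocabulary).
#' @return A `synthetic_corpus` list: `articles` (records with `mesh_terms`,
#'   `pub_types`), `scores` (from [score_articles()]), `edges`, and `truth`
#'   (`article_id`, `true_prob`, `clinically_cited`).
#' @export
generate_corpus <- function(config, vocab = toy_mesh_vocabulary()) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  n <- config$n_articles
  years <- seq(config$year_range[1L], config$year_range[2L])

  pub_year <- sample(years, n, replace = TRUE)
  region <- sample(names(config$region_weights), n, replace = TRUE,
                   prob = config$region_weights)
  alpha <- do.call(rbind, config$region_alpha[region])
  frac <- rdirichlet_rows(alpha)  # intended (h, a, mc)

  no_hamc <- stats::runif(n) < config$p_no_hamc
  n_terms <- stats::rpois(n, config$mean_hamc_terms) + 1L
  n_terms[no_hamc] <- 0L

  # realise HAMC terms: category of each term drawn from the intended simplex
  # position, then a descriptor from that category's pool (duplicates collapse
  # under set semantics, so realised counts can be below the draw)
  pools <- .vocab_pools(vocab)
  art_idx <- rep.int(seq_len(n), n_terms)
  u <- stats::runif(length(art_idx))
  c1 <- frac[art_idx, 1L]; c2 <- c1 + frac[art_idx, 2L]
  term_cat <- c("HUMAN", "ANIMAL", "MOLCELL")[1L + (u > c1) + (u > c2)]
  term_desc <- character(length(art_idx))
  for (k in c("HUMAN", "ANIMAL", "MOLCELL")) {
    sel <- term_cat == k
    term_desc[sel] <- pools[[k]][sample.int(length(pools[[k]]), sum(sel), replace = TRUE)]
  }

  # modifier flags -> one descriptor each from the pure modifier pools
  fp <- config$flag_probs
  clamp01 <- function(p) pmin(1, pmax(0, p))
  p_d <- clamp01(fp[["d0"]] + fp[["dh"]] * frac[, 1L] + fp[["da"]] * frac[, 2L])
  p_e <- clamp01(fp[["e0"]] + fp[["eh"]] * frac[, 1L])
  p_cd <- clamp01(fp[["cd0"]] + fp[["cdh"]] * frac[, 1L] + fp[["cdm"]] * frac[, 3L])
  flag_terms <- function(p, pool) {
    has <- stats::runif(n) < p
    out <- rep(NA_character_, n)
    out[has] <- pool[sample.int(length(pool), sum(has), replace = TRUE)]
    out
  }
  d_term <- flag_terms(p_d, pools$DISEASE)
  e_term <- flag_terms(p_e, pools$THERAP)
  cd_term <- flag_terms(p_cd, pools$CHEMDRUG)

  ids <- sprintf("A%06d", seq_len(n))
  term_dt <- data.table::data.table(idx = art_idx, descriptor = term_desc)
  flag_dt <- data.table::data.table(
    idx = rep(seq_len(n), 3L),
    descriptor = c(d_term, e_term, cd_term))[!is.na(descriptor)]
  all_terms <- data.table::rbindlist(list(term_dt, flag_dt))
  mesh_terms <- vector("list", n)
  if (nrow(all_terms) > 0L) {
    grouped <- all_terms[, .(terms = list(unique(descriptor))), keyby = idx]
    mesh_terms[grouped$idx] <- grouped$terms
  }
  mesh_terms[vapply(mesh_terms, is.null, logical(1L))] <- list(character(0))

  # clinical-article flags, probability increasing in human content
  p_clin <- clamp01(config$clinical_frac * (0.4 + 1.2 * frac[, 1L]))
  is_clin <- stats::runif(n) < p_clin
  clin_types <- c("clinical trial", "clinical trial, phase ii", "clinical study",
                  "guideline")
  pub_types <- vector("list", n)
  pub_types[is_clin] <- as.list(sample(clin_types, sum(is_clin), replace = TRUE))
  pub_types[!is_clin] <- as.list(sample(c("journal article", "review"),
                                        sum(!is_clin), replace = TRUE,
                                        prob = c(0.9, 0.1)))

  articles <- data.table::data.table(
    article_id = ids, pub_year = pub_year, mesh_terms = mesh_terms,
    pub_types = pub_types, is_clinical = is_clin)
  scores <- score_articles(articles, vocab)
  data.table::setkey(scores, article_id)
  scores <- scores[ids]  # original order

  # citation network: similarity measured at trilinear coordinates, undefined
  # articles sit at the centroid for the similarity kernel only
  cx <- ifelse(scores$defined, scores$x, 0)
  cy <- ifelse(scores$defined, scores$y, 0)
  cites <- integer(n)
  edges_list <- list()
  for (yy in years[-1L]) {
    citers <- which(pub_year == yy)
    elig <- which(pub_year < yy)
    if (length(citers) == 0L || length(elig) == 0L) next
    refs <- stats::rpois(length(citers), config$mean_refs)
    refs <- pmin(refs, length(elig))
    total_slots <- sum(refs)
    if (total_slots == 0L) next
    w_pref <- (1 + cites[elig])^config$attachment_exponent
    cand <- sample(elig, total_slots * config$n_candidates, replace = TRUE,
                   prob = w_pref)
    cand_mat <- matrix(cand, ncol = config$n_candidates)
    slot_citer <- rep.int(citers, refs)
    # exact weighted choice among each slot's candidates via the Gumbel-max
    # trick (vectorised over all slots)
    dd <- sqrt((matrix(cx[cand], ncol = config$n_candidates) - cx[slot_citer])^2 +
                 (matrix(cy[cand], ncol = config$n_candidates) - cy[slot_citer])^2)
    gumbel <- -log(-log(matrix(stats::runif(length(dd)), nrow = nrow(dd))))
    pick_col <- max.col(-dd / config$similarity_width + gumbel)
    picked <- cand_mat[cbind(seq_len(total_slots), pick_col)]
    edges_list[[length(edges_list) + 1L]] <- data.table::data.table(
      citing_id = ids[slot_citer], cited_id = ids[picked], year = yy)
    tab <- tabulate(picked, nbins = n)
    cites <- cites + tab
  }
  edges <- if (length(edges_list) > 0L) data.table::rbindlist(edges_list) else
    data.table::data.table(citing_id = character(0), cited_id = character(0),
                           year = integer(0))
  # drop duplicate references from the same citer (an article cites a
  # reference once)
  edges <- unique(edges, by = c("citing_id", "cited_id"))

  # planted outcome from the realised full-history network
  prof <- build_profiles(scores, edges, as_of_year = config$year_range[2L])
  data.table::setkey(prof, article_id)
  prof <- prof[ids]
  logit <- config$beta0 + config$beta_meanH * prof$meanH +
    config$beta_cpy * log1p(prof$CPY) + config$beta_meanD * prof$meanD
  true_prob <- stats::plogis(logit)
  truth <- data.table::data.table(
    article_id = ids, true_prob = true_prob,
    clinically_cited = stats::rbinom(n, 1L, true_prob))

  structure(list(articles = articles, scores = scores, edges = edges,
                 truth = truth, config = config),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus>", nrow(x$articles), "articles,", nrow(x$edges),
      "citation edges, years", x$config$year_range[1L], "-",
      x$config$year_range[2L], "\n")
  cat("  clinical-citation prevalence:",
      sprintf("%.3f", mean(x$truth$clinically_cited)), "\n")
  invisible(x)
}

#' Bayes AUC of a synthetic corpus
#'
#' The AUC of the known generative probabilities against the realised labels:
#' the discrimination ceiling no classifier trained on the corpus features can
#' exceed in expectation. Computed by the rank (Mann-Whitney) formula.
#'
#' @param corpus A `synthetic_corpus`, or a list with `true_prob` and
#'   `clinically_cited`.
#' @return AUC in `[0, 1]`; 0.5 when `true_prob` is constant.
#' @export
bayes_auc <- function(corpus) {
  tr <- if (inherits(corpus, "synthetic_corpus")) corpus$truth else corpus
  p <- tr$true_prob
  y <- tr$clinically_cited
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes required")
  r <- rank(p)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
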