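# Address-rule classification, term/article aggregation, clinical-type rule,
# vocabulary readers.

test_that("single-address classification follows the category rules", {
  expect_identical(classify_address("B01.050.150.900.649.801.400.112.400.400"),
                   "HUMAN")
  expect_identical(classify_address("M01"), "HUMAN")
  expect_identical(classify_address("M01.060"), "HUMAN")
  expect_identical(classify_address("B01.050"), "ANIMAL")
  expect_identical(classify_address("B01"), "ANIMAL")
  # Mol/Cell roots, boundary inclusive
  expect_identical(classify_address("A11.251"), "MOLCELL")
  expect_identical(classify_address("B02"), "MOLCELL")
  expect_identical(classify_address("G02.111.570.820"), "MOLCELL")
  expect_identical(classify_address("G02.149"), "MOLCELL")
  # near-miss prefixes must not match
  expect_identical(classify_address("G02.111.571"), character(0))
  expect_identical(classify_address("A112.100"), character(0))
  # branch rules with carve-outs
  expect_identical(classify_address("C04.557"), "DISEASE")
  expect_identical(classify_address("C22.005"), character(0))
  expect_identical(classify_address("E02.319"), "THERAP")
  expect_identical(classify_address("E07.858"), character(0))
  expect_identical(classify_address("D12.776"), "CHEMDRUG")
  expect_identical(classify_address("Z99.123"), character(0))
})

test_that("malformed addresses are a parse error", {
  expect_error(classify_address("b01.050"), "malformed")
  expect_error(classify_address("01.050"), "malformed")
  expect_error(classify_address(""), "malformed")
  expect_error(classify_address("B01..050"), "malformed")
})

test_that("no single address is both HUMAN and ANIMAL", {
  set.seed(42)
  # random B01-subtree addresses plus the Humans address itself
  rand <- replicate(500, paste(
    c("B01", sprintf("%03d", sample(999, sample(0:8, 1), replace = TRUE))),
    collapse = "."))
  addrs <- c(rand, "B01.050.150.900.649.801.400.112.400.400", "M01.060")
  m <- aptscore:::.classify_address_matrix(addrs)
  expect_false(any(m[, "HUMAN"] & m[, "ANIMAL"]))
})

test_that("term classification is the union over addresses, once per category", {
  v <- mesh_vocabulary(list(
    multi = c("B01.050", "A11.251"),
    persons = "M01.060",
    drug2 = c("D02.092", "D26.255"),
    mixed_cd = c("C04.100", "D12.776")
  ))
  expect_setequal(classify_term("multi", v), c("ANIMAL", "MOLCELL"))
  expect_identical(classify_term("persons", v), "HUMAN")
  # two D addresses still count the category once
  expect_identical(classify_term("drug2", v), "CHEMDRUG")
  expect_setequal(classify_term("mixed_cd", v), c("DISEASE", "CHEMDRUG"))
  # qualifier strings are stripped before lookup
  expect_identical(classify_term("drug2/pharmacology", v), "CHEMDRUG")
})

test_that("classify_term equals the per-address union oracle on random vocabularies", {
  set.seed(7)
  letters_pool <- c("A11", "B01", "B03", "C04", "C22", "D06", "E02", "E07",
                    "G02.149", "M01", "Z01")
  for (rep in 1:50) {
    n_addr <- sample(1:4, 1)
    addrs <- vapply(seq_len(n_addr), function(i) {
      paste(c(sample(letters_pool, 1),
              sprintf("%03d", sample(999, sample(0:3, 1), replace = TRUE))),
            collapse = ".")
    }, character(1))
    v <- mesh_vocabulary(list(tm = addrs))
    oracle <- sort(unique(unlist(lapply(addrs, classify_address))))
    expect_identical(sort(classify_term("tm", v)), oracle)
  }
})

test_that("category counts use distinct-descriptor set semantics", {
  v <- toy_vocab()
  counts <- category_counts(c("Humans", "Mice", "Rats", "Dogs", "Mice"), v)
  expect_identical(counts[["HUMAN"]], 1L)
  expect_identical(counts[["ANIMAL"]], 3L)  # duplicate Mice counted once
  expect_true(all(counts[c("MOLCELL", "DISEASE", "THERAP", "CHEMDRUG")] == 0L))

  # a multi-category descriptor contributes once to each of its categories
  counts2 <- category_counts("Tumor Cells, Cultured", v)
  expect_identical(counts2[["MOLCELL"]], 1L)
  expect_identical(counts2[["DISEASE"]], 1L)

  expect_true(all(category_counts(character(0), v) == 0L))
})

test_that("unknown descriptors error in strict mode and warn in lenient mode", {
  strict <- toy_mesh_vocabulary(lenient = FALSE)
  lenient <- toy_mesh_vocabulary(lenient = TRUE)
  expect_error(classify_term("Not A Descriptor", strict), "unknown")
  expect_warning(res <- classify_term("Not A Descriptor", lenient), "unknown")
  expect_identical(res, character(0))
})

test_that("clinical-article rule matches the publication-type set", {
  expect_true(is_clinical_article(c("journal article", "clinical trial, phase ii")))
  expect_true(is_clinical_article("guideline"))
  expect_true(is_clinical_article("Clinical Trial"))  # case-insensitive
  expect_true(is_clinical_article("clinical study"))
  expect_false(is_clinical_article("review"))
  expect_false(is_clinical_article(c("journal article", "editorial")))
  expect_false(is_clinical_article(character(0)))
  # "clinical trial, phase v" is not in the query set
  expect_false(is_clinical_article("clinical trial, phase v"))
})

test_that("article records validate the clinical flag and year range", {
  rec <- article_record("X1", 2001, c("Humans"), c("clinical trial"))
  expect_true(rec$is_clinical)
  expect_error(article_record("X1", 2001, pub_types = "review", is_clinical = TRUE),
               "contradicts")
  expect_error(article_record("X1", 1990, year_range = c(2000, 2010)),
               "outside corpus range")
})

test_that("vocabulary readers parse the ASCII and TSV dialects", {
  ascii <- system.file("extdata", "mini_mesh_ascii.txt", package = "aptscore")
  expect_warning(v <- read_mesh_ascii(ascii), "without tree addresses")
  expect_identical(sort(names(v$addresses)),
                   sort(c("Humans", "Mice", "Neoplasms", "Tumor Cells, Cultured")))
  expect_length(v$addresses[["Tumor Cells, Cultured"]], 2L)
  expect_identical(classify_term("Humans", v), "HUMAN")

  tsv <- system.file("extdata", "mini_mesh.tsv", package = "aptscore")
  v2 <- read_mesh_tsv(tsv)
  full <- toy_vocab()
  expect_setequal(names(v2$addresses), names(full$addresses))
  expect_identical(sort(v2$addresses[["Tumor Cells, Cultured"]]),
                   sort(full$addresses[["Tumor Cells, Cultured"]]))

  # TSV round-trip through a temp file
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_mesh_tsv(v2, tmp)
  v3 <- read_mesh_tsv(tmp)
  expect_identical(v3$addresses[order(names(v3$addresses))],
                   v2$addresses[order(names(v2$addresses))])
})

test_that("article JSON-lines round-trips exactly", {
  arts <- data.table::data.table(
    article_id = c("A1", "A2"),
    pub_year = c(2001L, 2005L),
    mesh_terms = list(c("Humans", "Neoplasms"), character(0)),
    pub_types = list("journal article", c("clinical trial", "journal article")),
    is_clinical = c(FALSE, TRUE)
  )
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_articles_jsonl(arts, tmp)
  back <- read_articles_jsonl(tmp)
  expect_identical(back$article_id, arts$article_id)
  expect_identical(back$pub_year, arts$pub_year)
  expect_identical(back$mesh_terms, arts$mesh_terms)
  expect_identical(back$pub_types, arts$pub_types)
  expect_identical(back$is_clinical, arts$is_clinical)
  # byte-stable writer: writing the parsed records again gives identical bytes
  tmp2 <- withr::local_tempfile(fileext = ".jsonl")
  write_articles_jsonl(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("vectorised article scoring agrees with per-article aggregation", {
  v <- toy_vocab()
  arts <- data.table::data.table(
    article_id = c("P1", "P2", "P3"),
    pub_year = c(2000L, 2001L, 2002L),
    mesh_terms = list(c("Humans", "Mice", "Rats", "Neoplasms"),
                      c("HeLa Cells", "Drug Therapy/methods"),
                      character(0)),
    pub_types = list("journal article", "clinical trial", "review")
  )
  sc <- score_articles(arts, v)
  expect_identical(sc$article_id, arts$article_id)
  expect_identical(sc$is_clinical, c(FALSE, TRUE, FALSE))
  cc1 <- category_counts(arts$mesh_terms[[1]], v)
  s1 <- fractional_hamc(cc1)
  expect_equal(sc$h[1], s1$h)
  expect_equal(sc$a[1], s1$a)
  expect_identical(sc$d[1], 1L)
  expect_identical(sc$focus[2], factor("FUNDAMENTAL",
    levels = c("FUNDAMENTAL", "HUMAN_FOCUSED", "MIXED", "UNCLASSIFIED")))
  expect_false(sc$defined[3])
  expect_true(is.na(sc$x[3]))
})
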