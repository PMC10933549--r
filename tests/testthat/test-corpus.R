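test_that("term index applies length and stopword filters and resolves aliases", {
  genes <- data.frame(
    symbol = c("WAS", "TP53", "SERPINA3"),
    aliases = c("was-like", "p53|p5", "ACT|was|can"),
    locus_group = "protein-coding gene", location = c("Xp", "17p", "14q"),
    stringsAsFactors = FALSE)
  methods <- data.frame(term = "immunostaining",
                        category = "immunofluorescence",
                        stringsAsFactors = FALSE)
  idx <- build_term_index(genes, methods, min_length = 3,
                          stopwords = c("was", "can"))
  surf <- tolower(idx$entries$surface)
  expect_false("was" %in% surf)    # stopword, case-insensitive: kills "WAS"
  expect_false("can" %in% surf)
  expect_false("p5" %in% surf)     # shorter than 3 characters
  expect_true("p53" %in% surf)
  expect_true("was-like" %in% surf)
  # every retained surface passes both filters
  expect_true(all(nchar(idx$entries$surface) >= idx$min_length))
  expect_false(any(tolower(idx$entries$surface) %in% idx$stopwords))
  # alias resolves to its canonical symbol
  expect_identical(
    idx$entries$canonical[idx$entries$surface == "p53"], "TP53")
})

test_that("a minimal gene+method vocabulary yields exactly two index entries", {
  genes <- data.frame(symbol = "TP53", aliases = "",
                      locus_group = "protein-coding gene",
                      location = "17p", stringsAsFactors = FALSE)
  methods <- data.frame(term = "immunostaining",
                        category = "immunofluorescence",
                        stringsAsFactors = FALSE)
  idx <- build_term_index(genes, methods)
  expect_identical(nrow(idx$entries), 2L)
})

test_that("ambiguous surfaces mapping to two genes are excluded with a warning", {
  genes <- data.frame(
    symbol = c("GENE1", "GENE2"), aliases = c("shared", "SHARED"),
    locus_group = "protein-coding gene", location = c("1p", "2q"),
    stringsAsFactors = FALSE)
  methods <- tiny_method_table()
  expect_warning(idx <- build_term_index(genes, methods),
                 "ambiguous")
  expect_identical(idx$n_ambiguous, 1L)
  expect_false("shared" %in% tolower(idx$entries$surface))
  expect_true("GENE1" %in% idx$entries$surface)  # symbols themselves stay
})

test_that("candidate generation returns the gene x method cross product", {
  idx <- tiny_index()
  # one method, two genes
  c1 <- find_candidates(centriole_sentence(), idx)
  expect_identical(nrow(c1), 2L)
  expect_setequal(c1$gene_symbol, c("PLK1", "HsSAS6"))
  expect_true(all(c1$method_name == "inhibition"))
  # no methods
  expect_identical(nrow(find_candidates("PLK1 binds CEP63.", idx)), 0L)
  # 2 genes x 2 methods = 4, ordered by (gene_start, method_start)
  c4 <- find_candidates(
    "Inhibition of PLK1 and immunostaining of TP53 were done.", idx)
  expect_identical(nrow(c4), 4L)
  expect_identical(c4[, c("gene_symbol", "method_name")],
                   data.frame(gene_symbol = c("PLK1", "PLK1", "TP53", "TP53"),
                              method_name = c("inhibition", "immunostaining",
                                              "inhibition", "immunostaining"),
                              stringsAsFactors = FALSE))
  expect_false(is.unsorted(c4$gene_start))
  # spans are in bounds, half-open, non-overlapping
  n <- nchar(centriole_sentence())
  expect_true(all(c1$gene_end > c1$gene_start & c1$gene_end <= n + 1))
  expect_true(all(c1$gene_end <= c1$method_start |
                  c1$method_end <= c1$gene_start))
})

test_that("matching is case-insensitive and word-boundary anchored", {
  idx <- tiny_index()
  expect_identical(find_candidates("inhibition of plk1 worked.", idx)$gene_symbol,
                   "PLK1")
  # PLK1 inside a longer token must not match
  expect_identical(nrow(find_candidates("Inhibition of PLK1X failed.", idx)), 0L)
})

test_that("overlapping dictionary hits resolve to the longest match", {
  genes <- data.frame(symbol = c("ABC", "ABCD1"), aliases = c("", "ABC DEF"),
                      locus_group = "protein-coding gene",
                      location = c("1p", "1q"), stringsAsFactors = FALSE)
  idx <- build_term_index(genes, tiny_method_table())
  cands <- find_candidates("Inhibition of ABC DEF was clear.", idx)
  expect_identical(cands$gene_symbol, "ABCD1")  # longer alias wins over ABC
})

test_that("masking replaces exactly the two spans and round-trips", {
  idx <- tiny_index()
  cands <- find_candidates(centriole_sentence(), idx)
  m_plk1 <- mask_candidate(cands[cands$gene_symbol == "PLK1", ])
  m_sas6 <- mask_candidate(cands[cands$gene_symbol == "HsSAS6", ])
  expect_identical(m_plk1$text,
    "[EXPE] of [GENE] suppressed loss of HsSAS6 from the centrioles.")
  expect_identical(m_sas6$text,
    "[EXPE] of Plk1 suppressed loss of [GENE] from the centrioles.")
  for (m in list(m_plk1, m_sas6)) {
    expect_identical(lengths(regmatches(m$text,
      gregexpr("[GENE]", m$text, fixed = TRUE))), 1L)
    expect_identical(lengths(regmatches(m$text,
      gregexpr("[EXPE]", m$text, fixed = TRUE))), 1L)
    expect_identical(unmask(m), centriole_sentence())
  }
  # malformed overlap errors
  bad <- cands[1, ]
  bad$method_start <- bad$gene_start
  bad$method_end <- bad$gene_end + 1L
  expect_error(mask_candidate(bad), "overlap")
})

test_that("baseline relation classifiers score as specified", {
  idx <- tiny_index()
  cands <- find_candidates(centriole_sentence(), idx)
  allpos <- classifier_all_positive()
  nearest <- classifier_nearest_method()
  m_plk1 <- mask_candidate(cands[cands$gene_symbol == "PLK1", ])
  m_sas6 <- mask_candidate(cands[cands$gene_symbol == "HsSAS6", ])
  expect_identical(classify_relation(m_plk1, allpos), 1.0)
  expect_identical(classify_relation(m_plk1, nearest, context = cands), 1.0)
  expect_identical(classify_relation(m_sas6, nearest, context = cands), 0.0)
})

test_that("the all-positive baseline has recall 1 and precision = positive rate", {
  w <- small_world()
  idx <- build_term_index(w$genes, w$methods)
  sentences <- unlist(lapply(w$corpus[1:20], function(a) a$sentences))
  cands <- do.call(rbind, lapply(sentences, find_candidates, index = idx))
  allpos <- classifier_all_positive()
  preds <- vapply(seq_len(nrow(cands)), function(i)
    classify_relation(mask_candidate(cands[i, ]), allpos), numeric(1))
  labels <- nextgene:::with_seed(5, stats::rbinom(nrow(cands), 1, 0.6))
  accepted <- preds >= 0.5
  recall <- sum(labels == 1 & accepted) / sum(labels == 1)
  precision <- sum(labels == 1 & accepted) / sum(accepted)
  expect_identical(recall, 1.0)
  expect_equal(precision, mean(labels))
})

test_that("candidate counts equal gene matches times method matches", {
  w <- small_world()
  idx <- build_term_index(w$genes, w$methods)
  sentences <- c(
    unlist(lapply(w$corpus[1:10], function(a) a$sentences)),
    "Inhibition of GS001 and GS002 altered GS003.",
    "We saw nothing at all.")
  idx2 <- build_term_index(w$genes, rbind(w$methods, data.frame(
    term = "inhibition", category = "knockdown/knockout")))
  for (s in sentences) {
    m <- nextgene:::resolve_overlaps(nextgene:::match_all_terms(s, idx2))
    expected <- sum(m$kind == "gene") * sum(m$kind == "method")
    expect_identical(nrow(find_candidates(s, idx2)), as.integer(expected))
  }
})

test_that("extraction orders accepted mentions by document position", {
  idx <- tiny_index()
  art <- list(list(
    article_id = "A1", year = 2020,
    sentences = c("Immunostaining of TP53 was clear.",
                  "No experiment here.",
                  "Inhibition of PLK1 suppressed loss of HsSAS6 from the centrioles.")))
  mm <- extract_experiments(art, idx, classifier_all_positive(), 0.5)
  expect_identical(nrow(mm), 3L)
  expect_identical(mm$order_index, 0:2)
  expect_identical(mm$gene, c("TP53", "PLK1", "HsSAS6"))
  expect_identical(mm$sentence_index, c(0L, 2L, 2L))
  expect_false(is.unsorted(mm$sentence_index))
  # nothing passes an impossible threshold
  expect_identical(nrow(extract_experiments(art, idx,
    classifier_all_positive(), 1.1)), 0L)
})

test_that("sentence splitter cuts on terminal punctuation before capitals", {
  txt <- "We depleted PLK1. Depletion was lethal! Was it specific? Yes."
  expect_identical(length(split_sentences(txt)), 4L)
  expect_identical(split_sentences("One sentence only"), "One sentence only")
})

test_that("corpus and table files round-trip through their readers", {
  w <- small_world()
  d <- withr::local_tempdir()
  write_gene_table(w$genes, file.path(d, "g.tsv"))
  expect_identical(read_gene_table(file.path(d, "g.tsv")), w$genes)
  write_method_table(w$methods, file.path(d, "m.tsv"))
  expect_identical(read_method_table(file.path(d, "m.tsv")), w$methods)
  write_corpus(w$corpus, file.path(d, "c.jsonl"))
  expect_identical(read_corpus(file.path(d, "c.jsonl")), w$corpus)
})
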