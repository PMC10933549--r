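toy_categorical <- function() {
  categorical_source("go_like", data.frame(
    gene = c("A", "B", "A", "C"),
    term = c("T1", "T1", "T2", "T2"),
    stringsAsFactors = FALSE), min_genes = 1)
}

test_that("term filtering removes rarely annotated terms", {
  ann <- rbind(
    data.frame(gene = paste0("g", 1:5), term = "rare5"),
    data.frame(gene = paste0("g", 1:10), term = "edge10"),
    data.frame(gene = paste0("g", 1:50), term = "common50"))
  src <- categorical_source("s", ann)
  f <- filter_terms(src, min_genes = 10)
  terms <- unique(unlist(f$annotations))
  expect_setequal(terms, c("edge10", "common50"))  # >= threshold survives
  # a 9-gene term is removed at the default threshold
  f9 <- filter_terms(categorical_source(
    "s", data.frame(gene = paste0("g", 1:9), term = "t9")), 10)
  expect_length(unlist(f9$annotations), 0)
  # min_genes = 1 leaves the source unchanged
  f1 <- filter_terms(src, min_genes = 1)
  expect_setequal(unique(unlist(f1$annotations)),
                  c("rare5", "edge10", "common50"))
})

test_that("loading cutoff is strict and two-sided", {
  ld <- data.frame(gene = c("A", "B", "C", "D"),
                   term = "F1",
                   loading = c(0.05, -0.2, 0.1, 0.3),
                   stringsAsFactors = FALSE)
  src <- webster_to_categorical(ld, threshold = 0.1, min_genes = 1)
  annotated <- names(src$annotations)
  expect_false("A" %in% annotated)  # |0.05| below cutoff
  expect_true("B" %in% annotated)   # -0.2 passes on the negative side
  expect_false("C" %in% annotated)  # exactly 0.1 fails the strict inequality
  expect_true("D" %in% annotated)
})

test_that("categorical triplet encoding follows the shared/prev/next rule", {
  src <- toy_categorical()
  expect_equal(unname(encode_categorical("A", "B", "T1", src)), c(1, 0, 0))
  expect_equal(unname(encode_categorical("A", "B", "T2", src)), c(0, 1, 0))
  expect_equal(unname(encode_categorical("B", "C", "T2", src)), c(0, 0, 1))
  expect_equal(unname(encode_categorical("B", "D", "T2", src)), c(0, 0, 0))
})

test_that("numerical encoding is the Pearson correlation with 0 fallbacks", {
  P <- rbind(A = c(1, 2, 3), B = c(3, 2, 1), C = c(1, 2, 4),
             D = c(2, 2, 5), E = c(7, 7, 7))
  src <- numerical_source("expr", P)
  expect_equal(encode_numerical("A", "A", src), 1)
  expect_equal(encode_numerical("A", "B", src), -1)
  # direct covariance/sd computation as the oracle
  x <- P["C", ]; y <- P["D", ]
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(encode_numerical("C", "D", src), r_oracle)
  expect_equal(encode_numerical("A", "E", src), 0)     # zero variance
  expect_equal(encode_numerical("A", "ZZ", src), 0)    # missing gene
  expect_error(numerical_source("short", rbind(A = c(1, 2))), ">= 3")
})

test_that("pairwise-complete correlation needs at least 3 shared samples", {
  P <- rbind(A = c(1, 2, 3, 4, NA), B = c(2, 4, 6, NA, 1),
             C = c(NA, NA, 1, 2, 3))
  src <- numerical_source("expr", P)
  expect_equal(encode_numerical("A", "B", src), 1)  # 3 complete points
  expect_equal(encode_numerical("A", "C", src), 0)  # only 2 complete points
})

test_that("embedding encoding is cosine similarity with 0 fallbacks", {
  E <- rbind(A = c(1, 1), B = c(1, 1), C = c(1, 0), D = c(0, 1),
             Z = c(0, 0))
  src <- embedding_source("emb", E)
  expect_equal(encode_embedding("A", "B", src), 1)
  expect_equal(encode_embedding("C", "D", src), 0)
  expect_equal(encode_embedding("A", "C", src), 1 / sqrt(2))
  expect_equal(encode_embedding("A", "Z", src), 0)   # zero norm
  expect_equal(encode_embedding("A", "QQ", src), 0)  # missing gene
})

test_that("schema dimension is 3T + N_num + N_emb with frozen column order", {
  num <- numerical_source("expr", rbind(A = 1:3, B = 3:1))
  emb <- embedding_source("emb", rbind(A = c(1, 0), B = c(0, 1)))
  sch <- build_schema(list(toy_categorical(), num, emb))
  expect_identical(sch$dimension, 3L * 2L + 1L + 1L)
  expect_identical(sch$columns$term[1:6],
                   rep(c("T1", "T2"), each = 3))
  expect_identical(sch$columns$slot[1:3],
                   c("both", "prev_only", "next_only"))
  expect_identical(tail(sch$columns$kind, 2), c("numerical", "embedding"))
  expect_warning(build_schema(list()), "dimension 0")
  expect_error(build_schema(list(toy_categorical(), toy_categorical())),
               "duplicate")
  # JSON persistence round-trips
  d <- withr::local_tempdir()
  write_schema(sch, file.path(d, "schema.json"))
  sch2 <- read_schema(file.path(d, "schema.json"))
  expect_identical(sch2$columns, sch$columns)
  expect_identical(sch2$dimension, sch$dimension)
})

test_that("featurization matches the slot-wise encoders and is deterministic", {
  set.seed(1)
  fit <- small_world_fit()
  pairs <- fit$census[1:40, c("gene_prev", "gene_next")]
  X <- featurize(pairs, fit$schema, fit$sources)
  expect_identical(dim(X), c(40L, fit$schema$dimension))
  # categorical slots boolean, at most one hot per term triple
  cat_idx <- which(fit$schema$columns$kind == "categorical")
  expect_true(all(X[, cat_idx] %in% c(0, 1)))
  trip <- matrix(cat_idx, nrow = 3)
  expect_true(all(apply(trip, 2, function(ci) rowSums(X[, ci]) <= 1)))
  # numerical and embedding slots bounded
  v_idx <- which(fit$schema$columns$kind != "categorical")
  expect_true(all(X[, v_idx] >= -1 - 1e-12 & X[, v_idx] <= 1 + 1e-12))
  # spot-check each kind against the scalar encoders
  src_by_name <- setNames(fit$sources,
                          vapply(fit$sources, function(s) s$name, ""))
  for (i in c(1, 7, 23)) {
    gp <- pairs$gene_prev[i]; gn <- pairs$gene_next[i]
    for (j in sample(cat_idx, 20)) {
      col <- fit$schema$columns[j, ]
      tri <- encode_categorical(gp, gn, col$term, src_by_name[[col$source]])
      expect_identical(unname(X[i, j]),
                       unname(tri[c("both", "prev_only", "next_only") == col$slot]))
    }
    for (j in v_idx) {
      col <- fit$schema$columns[j, ]
      v <- if (col$kind == "numerical")
        encode_numerical(gp, gn, src_by_name[[col$source]])
      else encode_embedding(gp, gn, src_by_name[[col$source]])
      expect_equal(unname(X[i, j]), v, tolerance = 1e-12)
    }
  }
  # byte-identical across runs
  expect_identical(X, featurize(pairs, fit$schema, fit$sources))
})

test_that("swapping the pair order exchanges prev/next slots only", {
  fit <- small_world_fit()
  pairs <- fit$census[1:30, c("gene_prev", "gene_next")]
  swapped <- data.frame(gene_prev = pairs$gene_next,
                        gene_next = pairs$gene_prev)
  X <- featurize(pairs, fit$schema, fit$sources)
  Y <- featurize(swapped, fit$schema, fit$sources)
  cols <- fit$schema$columns
  expect_identical(X[, cols$slot == "both"], Y[, cols$slot == "both"])
  expect_identical(unname(X[, cols$slot == "prev_only"]),
                   unname(Y[, cols$slot == "next_only"]))
  expect_identical(unname(X[, cols$slot == "next_only"]),
                   unname(Y[, cols$slot == "prev_only"]))
  expect_equal(X[, cols$kind != "categorical"],
               Y[, cols$kind != "categorical"], tolerance = 1e-12)
})

test_that("genes absent from all sources produce warned all-zero rows", {
  sch <- build_schema(list(toy_categorical()))
  expect_warning(
    X <- featurize(data.frame(gene_prev = "NOPE1", gene_next = "NOPE2"),
                   sch, list(toy_categorical())),
    "all-zero")
  expect_true(all(X == 0))
})

test_that("profile and annotation files round-trip through their readers", {
  w <- small_world()
  d <- withr::local_tempdir()
  write_profiles(w$profiles[[1]], file.path(d, "p.tsv"))
  expect_equal(read_profiles(file.path(d, "p.tsv")), w$profiles[[1]])
  write_embeddings(w$embeddings, file.path(d, "e.tsv"))
  expect_equal(read_embeddings(file.path(d, "e.tsv")), w$embeddings)
  write_annotations(w$annotations, file.path(d, "a.tsv"))
  expect_identical(read_annotations(file.path(d, "a.tsv")), w$annotations)
  write_network(w$network, file.path(d, "n.tsv"))
  n2 <- read_network(file.path(d, "n.tsv"))
  expect_equal(n2$edges, w$network$edges)
})
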