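# Ranking models over featurized gene pairs: training, whole-universe
# ranking for a query gene, the literature-frequency baseline,
# permutation-sampling Shapley attribution, and next-experiment method
# category prediction.

ranker_algorithms <- c("gradient_boosting", "logistic_regression", "svm",
                       "random_forest", "mlp", "naive_bayes", "knn")

default_hyperparams <- function(algorithm) {
  switch(algorithm,
    gradient_boosting = list(nrounds = 100, max_depth = 6, eta = 0.3),
    logistic_regression = list(alpha = 0, lambda = 1e-3),
    svm = list(kernel = "radial", cost = 1),
    random_forest = list(num.trees = 500),
    mlp = list(size = 8, decay = 0.01, maxit = 200),
    naive_bayes = list(laplace = 0),
    knn = list(k = 10))
}

#' Train a binary ranking classifier on featurized gene pairs
#'
#' Fits one of seven classifier families to observed-vs-sampled pair labels.
#' Hyperparameters default to the library defaults recorded in
#' \code{default_hyperparams}; overrides are merged in and stored in the
#' model artifact, so a fit is fully described by (algorithm, hyperparams,
#' seed, schema). Training is reproducible under a fixed seed (tree and
#' network fits are forced single-threaded).
#'
#' @param features numeric feature matrix (rows = pairs).
#' @param labels 0/1 vector, both classes present.
#' @param algorithm one of \code{"gradient_boosting"},
#'   \code{"logistic_regression"}, \code{"svm"}, \code{"random_forest"},
#'   \code{"mlp"}, \code{"naive_bayes"}, \code{"knn"}.
#' @param hyperparams named list of overrides.
#' @param seed integer seed.
#' @param schema optional \code{feature_schema} stored with the model.
#' @return Object of class \code{gene_ranker} with a
#'   \code{\link{predict.gene_ranker}} method returning probabilities.
#' @export
train_ranker <- function(features, labels,
                         algorithm = c("gradient_boosting",
                                       "logistic_regression", "svm",
                                       "random_forest", "mlp",
                                       "naive_bayes", "knn"),
                         hyperparams = list(), seed = 1, schema = NULL) {
  algorithm <- match.arg(algorithm)
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stopf("features and labels disagree in length")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stopf("both classes must be present in the labels")
  hp <- utils::modifyList(default_hyperparams(algorithm), hyperparams)
  yfac <- factor(labels, levels = c(0, 1))

  fit <- with_seed(seed, switch(algorithm,
    gradient_boosting = xgboost::xgb.train(
      params = xgboost::xgb.params(
        objective = "binary:logistic", max_depth = hp$max_depth,
        learning_rate = hp$eta, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(features, label = labels, nthread = 1),
      nrounds = hp$nrounds, verbose = 0),
    logistic_regression = glmnet::glmnet(
      features, yfac, family = "binomial", alpha = hp$alpha,
      lambda = hp$lambda),
    svm = e1071::svm(features, yfac, probability = TRUE,
                     kernel = hp$kernel, cost = hp$cost, scale = FALSE),
    random_forest = ranger::ranger(
      y = yfac, x = as.data.frame(features), probability = TRUE,
      num.trees = hp$num.trees, seed = seed, num.threads = 1),
    mlp = nnet::nnet(x = features, y = labels, size = hp$size,
                     decay = hp$decay, maxit = hp$maxit,
                     entropy = TRUE, trace = FALSE, MaxNWts = 1e5),
    naive_bayes = e1071::naiveBayes(as.data.frame(features), yfac,
                                    laplace = hp$laplace),
    knn = list(train = features, cl = yfac)))

  structure(list(algorithm = algorithm, fit = fit, hyperparams = hp,
                 seed = seed, schema = schema,
                 feature_names = colnames(features),
                 n_train = nrow(features), n_positive = sum(labels == 1)),
            class = "gene_ranker")
}

#' Predict pair probabilities from a fitted ranker
#'
#' @param object a \code{gene_ranker}.
#' @param newdata numeric feature matrix with the training columns.
#' @param ... unused.
#' @return Vector of probabilities in \[0, 1\] that each pair is an observed
#'   consecutive-experiment pair.
#' @export
predict.gene_ranker <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- switch(object$algorithm,
    gradient_boosting = as.numeric(predict(
      object$fit, xgboost::xgb.DMatrix(newdata, nthread = 1))),
    logistic_regression = as.numeric(predict(
      object$fit, newdata, type = "response",
      s = object$hyperparams$lambda)),
    svm = {
      pr <- predict(object$fit, newdata, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    random_forest = predict(object$fit, data = as.data.frame(newdata),
                            num.threads = 1)$predictions[, "1"],
    mlp = as.numeric(predict(object$fit, newdata)),
    naive_bayes = predict(object$fit, as.data.frame(newdata),
                          type = "raw")[, "1"],
    knn = with_seed(object$seed, {
      k <- min(object$hyperparams$k, nrow(object$fit$train))
      pr <- class::knn(object$fit$train, newdata, object$fit$cl,
                       k = k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    }))
  unname(pmin(1, pmax(0, as.numeric(p))))
}

#' @export
print.gene_ranker <- function(x, ...) {
  cat(sprintf("Gene pair ranker (%s), %d features, %d training pairs (%d positive), seed %d\n",
              x$algorithm, length(x$feature_names), x$n_train,
              x$n_positive, x$seed))
  invisible(x)
}

#' @export
summary.gene_ranker <- function(object, ...) {
  print(object)
  cat("Hyperparameters:\n")
  for (nm in names(object$hyperparams))
    cat(sprintf("  %s = %s\n", nm,
                paste(object$hyperparams[[nm]], collapse = ", ")))
  if (!is.null(object$schema)) print(object$schema)
  invisible(object)
}

#' Save and restore a fitted ranker
#'
#' Serializes the model artifact (algorithm, hyperparameters, seed, schema,
#' fitted parameters) so that reloaded models give bit-identical
#' predictions. Gradient-boosting fits are stored through the library's raw
#' serialization format.
#'
#' @param model a \code{gene_ranker}.
#' @param path file path.
#' @return \code{load_ranker} returns the restored \code{gene_ranker}.
#' @export
save_ranker <- function(model, path) {
  if (model$algorithm == "gradient_boosting") {
    model$fit_raw <- xgboost::xgb.save.raw(model$fit)
    model$fit <- NULL
  }
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ranker
#' @export
load_ranker <- function(path) {
  model <- readRDS(path)
  if (model$algorithm == "gradient_boosting") {
    model$fit <- xgboost::xgb.load.raw(model$fit_raw)
    model$fit_raw <- NULL
  }
  model
}

#' Construct a ranked suggestion list
#'
#' @param query_gene the query gene symbol.
#' @param genes candidate gene symbols (query excluded).
#' @param scores numeric scores, one per candidate.
#' @param extra optional data.frame of extra per-candidate columns.
#' @return Object of class \code{ranked_suggestion}: list with
#'   \code{query_gene}, \code{entries} (data.frame \code{gene},
#'   \code{score}, \code{rank}, sorted by descending score) and
#'   \code{universe_size}.
#' @export
ranked_suggestion <- function(query_gene, genes, scores, extra = NULL) {
  stopifnot(length(genes) == length(scores), !query_gene %in% genes)
  o <- order(-scores)
  entries <- data.frame(gene = genes[o], score = scores[o],
                        rank = seq_along(genes), stringsAsFactors = FALSE)
  if (!is.null(extra)) entries <- cbind(entries, extra[o, , drop = FALSE])
  rownames(entries) <- NULL
  structure(list(query_gene = query_gene, entries = entries,
                 universe_size = length(genes)),
            class = "ranked_suggestion")
}

#' @export
print.ranked_suggestion <- function(x, n = 10, ...) {
  cat(sprintf("Ranking for query gene %s over %d candidates; top %d:\n",
              x$query_gene, x$universe_size, min(n, nrow(x$entries))))
  print(utils::head(x$entries, n), row.names = FALSE)
  invisible(x)
}

#' The protein-coding candidate universe
#'
#' Candidate genes for ranking are restricted to the gene table's
#' protein-coding entries (\code{locus_group == "protein-coding gene"}),
#' mirroring the "genes with protein product" nomenclature filter.
#'
#' @param genes data.frame gene table.
#' @return Character vector of symbols.
#' @export
protein_coding_universe <- function(genes) {
  genes$symbol[genes$locus_group == "protein-coding gene"]
}

#' Rank the gene universe for a query gene
#'
#' Scores the tuple (query, candidate) for every candidate in the universe
#' with the fitted ranker and sorts descending.
#'
#' @param model a \code{gene_ranker}.
#' @param query_gene query gene symbol.
#' @param sources the feature sources used at training time.
#' @param schema the feature schema (defaults to the model's stored schema).
#' @param universe candidate symbols; defaults to the protein-coding
#'   universe of \code{gene_table} minus the query.
#' @param gene_table gene table used to derive the default universe and to
#'   validate the query symbol.
#' @param top if non-NULL, truncate the returned entries to the top
#'   \code{top} candidates (display view; \code{universe_size} is
#'   unchanged).
#' @return A \code{ranked_suggestion}.
#' @export
rank_genes <- function(model, query_gene, sources, schema = model$schema,
                       universe = NULL, gene_table = NULL, top = NULL) {
  if (!is.null(gene_table) && !query_gene %in% gene_table$symbol)
    stopf("unknown query gene: %s", query_gene)
  if (is.null(universe)) {
    if (is.null(gene_table))
      stopf("supply either a universe or a gene_table")
    universe <- protein_coding_universe(gene_table)
  }
  universe <- setdiff(universe, query_gene)
  if (!length(universe)) stopf("empty candidate universe")
  pairs <- data.frame(gene_prev = query_gene, gene_next = universe,
                      stringsAsFactors = FALSE)
  X <- featurize(pairs, schema, sources)
  rs <- ranked_suggestion(query_gene, universe, predict(model, X))
  if (!is.null(top)) rs$entries <- utils::head(rs$entries, top)
  rs
}

#' Literature-frequency baseline ranker
#'
#' Ranks genes by how many experiments mention them in the training-period
#' literature, independent of the query gene. The obvious comparator for
#' any next-gene recommender: frequently studied genes are frequently the
#' next experiment's target regardless of context.
#'
#' @param experiment_counts named integer vector (gene -> experiment count),
#'   e.g. \code{table(mentions$gene)} over the training years.
#' @return Object of class \code{frequency_baseline}.
#' @export
frequency_baseline <- function(experiment_counts) {
  counts <- unlist(experiment_counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stopf("experiment_counts must be named by gene")
  if (any(counts < 0)) stopf("counts must be >= 0")
  structure(list(counts = counts), class = "frequency_baseline")
}

#' @export
print.frequency_baseline <- function(x, ...) {
  cat(sprintf("Frequency baseline over %d genes (max count %d)\n",
              length(x$counts), max(x$counts)))
  invisible(x)
}

#' Query-independent ranking from the frequency baseline
#'
#' @param baseline a \code{frequency_baseline}.
#' @param query_gene query symbol, excluded from the candidates.
#' @param universe candidate symbols (default: all counted genes); genes
#'   without a count score 0.
#' @return A \code{ranked_suggestion}; ties in the counts are left to the
#'   downstream evaluation jitter rule.
#' @export
baseline_ranking <- function(baseline, query_gene,
                             universe = names(baseline$counts)) {
  stopifnot(inherits(baseline, "frequency_baseline"))
  universe <- setdiff(universe, query_gene)
  sc <- baseline$counts[universe]
  sc[is.na(sc)] <- 0
  ranked_suggestion(query_gene, universe, as.numeric(sc))
}

#' Shapley attribution of one pair prediction by permutation sampling
#'
#' Estimates per-feature Shapley contributions for one instance: for each
#' sampled permutation of the features, starting from a background row
#' drawn from the training features, features are switched to the
#' instance's values in permutation order and the marginal score changes
#' are accumulated; contributions are averaged over permutations. By the
#' efficiency property the contributions sum to
#' \code{score(instance) - mean score(sampled background)}.
#'
#' @param model a \code{gene_ranker}.
#' @param feature_vector named numeric vector or 1-row matrix for the pair.
#' @param background feature matrix to draw reference rows from (typically
#'   a seeded sample of ~100 training rows).
#' @param n_permutations number of sampled permutations (default 100).
#' @param seed integer seed.
#' @param top_k how many features to list by absolute contribution
#'   (default 10).
#' @return Object of class \code{attribution}: list with
#'   \code{contributions} (named), \code{top_k} (data.frame), \code{score},
#'   \code{baseline}, \code{by_source} (contributions summed per source,
#'   using the \code{source|term|slot} column naming).
#' @export
attribute <- function(model, feature_vector, background,
                      n_permutations = 100, seed = 1, top_k = 10) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  if (!nrow(background)) stopf("background must be nonempty")
  x <- as.numeric(feature_vector)
  m <- length(x)
  nms <- if (!is.null(names(feature_vector))) names(feature_vector)
         else colnames(feature_vector)
  if (is.null(nms)) nms <- colnames(background)
  if (is.null(nms)) nms <- paste0("f", seq_len(m))
  phi <- numeric(m)
  base_scores <- numeric(n_permutations)
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      b <- as.numeric(background[sample.int(nrow(background), 1), ])
      perm <- sample.int(m)
      Z <- matrix(rep(b, m + 1), nrow = m + 1, byrow = TRUE)
      for (j in seq_len(m))
        Z[(j + 1):(m + 1), perm[j]] <- x[perm[j]]
      colnames(Z) <- nms
      sc <- predict(model, Z)
      base_scores[p] <- sc[1]
      phi[perm] <- phi[perm] + diff(sc)
    }
  })
  phi <- phi / n_permutations
  names(phi) <- nms
  xi <- matrix(x, nrow = 1, dimnames = list(NULL, nms))
  score <- predict(model, xi)
  ord <- order(-abs(phi))
  top <- data.frame(column = nms[ord[seq_len(min(top_k, m))]],
                    contribution = phi[ord[seq_len(min(top_k, m))]],
                    stringsAsFactors = FALSE)
  rownames(top) <- NULL
  src <- sub("\\|.*$", "", nms)
  by_source <- tapply(phi, src, sum)
  structure(list(contributions = phi, top_k = top,
                 score = score,
                 baseline = mean(base_scores),
                 by_source = by_source, n_permutations = n_permutations,
                 seed = seed),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("Shapley attribution (%d permutations): score %.4f, baseline %.4f\n",
              x$n_permutations, x$score, x$baseline))
  print(x$top_k, row.names = FALSE)
  invisible(x)
}

#' Train a multiclass predictor of the next experiment's method category
#'
#' Multinomial (ridge-regularized) logistic regression over the closed set
#' of 20 method categories, trained on the same pair feature vectors as the
#' ranker. Predictions are probability simplexes over exactly 20
#' categories; categories unseen in training get probability 0, and
#' categories with a single training example are excluded from the fit
#' with a warning (one observation cannot constrain a class boundary).
#'
#' @param features numeric feature matrix.
#' @param categories character vector of method-category labels (must all
#'   be in \code{\link{method_categories}}).
#' @param lambda ridge penalty at which predictions are made; the fit
#'   follows the library's regularization path and interpolates
#'   (default 0.01).
#' @param seed integer seed.
#' @return Object of class \code{method_predictor}.
#' @export
train_method_predictor <- function(features, categories, lambda = 0.01,
                                   seed = 1) {
  cats <- method_categories()
  bad <- setdiff(unique(categories), cats)
  if (length(bad))
    stopf("unseen method categor%s: %s", if (length(bad) > 1) "ies" else "y",
          paste(bad, collapse = ", "))
  features <- as.matrix(features)
  if (nrow(features) != length(categories))
    stopf("features and categories disagree in length")
  counts <- table(categories)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    warnf("%d categor%s with a single training example excluded from the fit: %s",
          length(singletons),
          if (length(singletons) > 1) "ies" else "y",
          paste(singletons, collapse = ", "))
    keep <- !(categories %in% singletons)
    features <- features[keep, , drop = FALSE]
    categories <- categories[keep]
  }
  observed <- intersect(cats, unique(categories))
  fit <- NULL
  if (length(observed) > 1) {
    y <- factor(categories, levels = observed)
    fit <- with_seed(seed, glmnet::glmnet(
      features, y, family = "multinomial", alpha = 0,
      lambda.min.ratio = 1e-4))
  }
  structure(list(fit = fit, observed = observed, lambda = lambda,
                 feature_names = colnames(features), seed = seed),
            class = "method_predictor")
}

#' Predict next-experiment method category probabilities
#'
#' @param object a \code{method_predictor}.
#' @param newdata numeric feature matrix.
#' @param ... unused.
#' @return List with \code{probs} (matrix, one row per input, 20 columns in
#'   the fixed category order, rows summing to 1) and \code{category} (the
#'   argmax; ties broken by the fixed category order).
#' @export
predict.method_predictor <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  cats <- method_categories()
  probs <- matrix(0, nrow(newdata), length(cats),
                  dimnames = list(NULL, cats))
  if (is.null(object$fit)) {
    probs[, object$observed] <- 1
  } else {
    pr <- predict(object$fit, newdata, type = "response",
                  s = object$lambda)[, , 1, drop = FALSE]
    probs[, object$observed] <- pr[, object$observed, 1]
    probs <- probs / rowSums(probs)
  }
  list(probs = probs, category = cats[apply(probs, 1, which.max)])
}

#' @export
print.method_predictor <- function(x, ...) {
  cat(sprintf("Method-category predictor: %d observed of %d categories, ridge lambda %g\n",
              length(x$observed), length(method_categories()), x$lambda))
  invisible(x)
}
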