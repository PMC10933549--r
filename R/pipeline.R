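# End-to-end recovery experiment: generate (or accept) a synthetic world,
# extract its experiment list from the rendered corpus, build pairs and
# negatives, train a ranker, and evaluate whole-universe rankings against
# the frequency baseline on the held-out years.

#' Run the end-to-end next-gene recovery experiment
#'
#' Executes the full pipeline on a synthetic world: dictionary extraction
#' of the experiment list from the rendered corpus (all-positive relation
#' baseline), consecutive-pair construction, temporal split, negative
#' sampling, feature encoding, ranker training, and AUROC@k evaluation of
#' the trained ranker against the literature-frequency baseline on the
#' test-year queries. The question it answers: can the ranker recover the
#' planted functional-module structure well enough to put a query gene's
#' future partners in the top of a whole-universe ranking?
#'
#' @param config a \code{sim_config} describing the world (default: the
#'   standard study conditions, seed 0).
#' @param algorithm ranker algorithm (default \code{"gradient_boosting"}).
#' @param neg_ratio negatives per positive (default 3).
#' @param k rank cutoff for AUROC@k (default 100).
#' @param min_genes categorical term filter (default 10).
#' @param seed seed for negative sampling, training and evaluation jitter
#'   (the world has its own seed in \code{config}).
#' @param predict_methods also train/evaluate the method-category
#'   predictor (default TRUE).
#' @return List with \code{summary} (data.frame of mean AUROC and AUROC@k
#'   per model), \code{comparison} (a \code{model_comparison}),
#'   \code{eval_ranker} and \code{eval_baseline} (per-query tables),
#'   \code{method_accuracy}, \code{n_queries}, plus the fitted
#'   \code{model}, \code{schema}, \code{sources}, \code{world},
#'   \code{mentions}, \code{split} and \code{baseline}.
#' @export
run_recovery_experiment <- function(config = sim_config(),
                                    algorithm = "gradient_boosting",
                                    neg_ratio = 3, k = 100,
                                    min_genes = 10, seed = 1,
                                    predict_methods = TRUE) {
  world <- generate_world(config)
  index <- build_term_index(world$genes, world$methods)
  mentions <- extract_experiments(world$corpus, index,
                                  classifier_all_positive(), 0.5)
  pairs <- build_pairs(mentions)
  split <- temporal_split(pairs)
  universe <- protein_coding_universe(world$genes)

  negatives <- sample_negatives(split$train, universe, ratio = neg_ratio,
                                seed = seed)
  train <- rbind(split$train, negatives)
  sources <- world_sources(world, min_genes = min_genes)
  schema <- build_schema(sources)
  X <- featurize(train[, c("gene_prev", "gene_next")], schema, sources)
  model <- train_ranker(X, train$label, algorithm, seed = seed,
                        schema = schema)

  # frequency baseline: experiment counts in the training-period literature
  train_mentions <- mentions[mentions$year <= split$boundaries[1], ]
  baseline <- frequency_baseline(table(train_mentions$gene))

  eval_partners <- partner_sets(split$test)
  train_partners <- partner_sets(rbind(split$train, split$validation))
  queries <- intersect(names(eval_partners), universe)

  eval_ranker <- evaluate_rankings(
    function(q) rank_genes(model, q, sources, schema, universe = universe),
    queries, eval_partners, train_partners, k_values = k, seed = seed)
  eval_baseline <- evaluate_rankings(
    function(q) baseline_ranking(baseline, q, universe),
    queries, eval_partners, train_partners, k_values = k, seed = seed)

  common <- intersect(eval_ranker$query, eval_baseline$query)
  kcol <- paste0("auroc_at_", k)
  per_query <- list(
    ranker = stats::setNames(eval_ranker[[kcol]], eval_ranker$query)[common],
    frequency_baseline = stats::setNames(
      eval_baseline[[kcol]], eval_baseline$query)[common])
  comparison <- compare_models(per_query, n_boot = 2000, seed = seed)
  summary <- data.frame(
    model = c("ranker", "frequency_baseline"),
    mean_auroc = c(mean(eval_ranker$auroc[eval_ranker$query %in% common]),
                   mean(eval_baseline$auroc[eval_baseline$query %in% common])),
    mean_auroc_at_k = c(mean(per_query$ranker),
                        mean(per_query$frequency_baseline)),
    k = k, stringsAsFactors = FALSE)

  method_accuracy <- NA_real_
  if (predict_methods) {
    cat_of <- stats::setNames(world$methods$category, world$methods$term)
    mp_rows <- method_pairs(mentions, cat_of)
    tr <- mp_rows$year <= split$boundaries[1]
    te <- mp_rows$year >= split$boundaries[3]
    if (sum(tr) > 1 && sum(te) > 0) {
      Xm <- featurize(mp_rows[, c("gene_prev", "gene_next")], schema,
                      sources)
      mp <- train_method_predictor(Xm[tr, , drop = FALSE],
                                   mp_rows$category[tr], seed = seed)
      pred <- predict(mp, Xm[te, , drop = FALSE])
      method_accuracy <- mean(pred$category == mp_rows$category[te])
    }
  }

  list(summary = summary, comparison = comparison,
       eval_ranker = eval_ranker, eval_baseline = eval_baseline,
       method_accuracy = method_accuracy, n_queries = length(common),
       model = model, schema = schema, sources = sources, world = world,
       mentions = mentions, split = split, baseline = baseline)
}

# pair each consecutive different-gene adjacency with the category of the
# NEXT experiment's method
method_pairs <- function(mentions, category_of) {
  out <- lapply(split(mentions, mentions$article_id), function(a) {
    n <- nrow(a)
    if (n < 2) return(NULL)
    d <- data.frame(gene_prev = a$gene[-n], gene_next = a$gene[-1],
                    category = unname(category_of[a$method[-1]]),
                    year = a$year[1], stringsAsFactors = FALSE)
    d[d$gene_prev != d$gene_next, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
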