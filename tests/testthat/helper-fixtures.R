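# Shared fixtures: a tiny hand-built gene/method vocabulary around the
# centriole-biology example sentence, plus a small cached synthetic world
# so expensive generation runs once per test session.

tiny_gene_table <- function() {
  data.frame(
    symbol = c("PLK1", "HsSAS6", "TP53", "CEP63"),
    aliases = c("", "", "p53|Trp53", ""),
    locus_group = c("protein-coding gene", "protein-coding gene",
                    "protein-coding gene", "protein-coding gene"),
    location = c("16p", "1p", "17p", "3q"),
    stringsAsFactors = FALSE)
}

tiny_method_table <- function() {
  data.frame(term = c("inhibition", "immunostaining"),
             category = c("knockdown/knockout", "immunofluorescence"),
             stringsAsFactors = FALSE)
}

tiny_index <- function() {
  build_term_index(tiny_gene_table(), tiny_method_table())
}

centriole_sentence <- function() {
  "Inhibition of Plk1 suppressed loss of HsSAS6 from the centrioles."
}

# small world: fast enough to regenerate but cached for reuse
.world_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 11) {
  sim_config(n_genes = 60, n_modules = 6, n_articles = 80,
             experiments_per_article = 3:6, profile_length = 20,
             embedding_dim = 20, seed = seed)
}

small_world <- function() {
  if (is.null(.world_cache$w)) .world_cache$w <- generate_world(small_config())
  .world_cache$w
}

small_world_fit <- function() {
  if (!is.null(.world_cache$fit)) return(.world_cache$fit)
  w <- small_world()
  census <- ground_truth_pairs(w)
  sp <- temporal_split(census)
  srcs <- world_sources(w, min_genes = 5)
  schema <- build_schema(srcs)
  uni <- protein_coding_universe(w$genes)
  neg <- sample_negatives(sp$train, uni, ratio = 3, seed = 21)
  train <- rbind(sp$train, neg)
  X <- featurize(train[, c("gene_prev", "gene_next")], schema, srcs)
  model <- train_ranker(X, train$label, "gradient_boosting",
                        hyperparams = list(nrounds = 50), seed = 7,
                        schema = schema)
  .world_cache$fit <- list(world = w, census = census, split = sp,
                           sources = srcs, schema = schema,
                           universe = uni, train = train, X = X,
                           model = model)
  .world_cache$fit
}

# independent pairwise-comparison oracle for AUROC
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exact interventional Shapley values by enumeration over all 2^m subsets
exact_shapley <- function(predict_fun, x, background) {
  m <- length(x)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  v <- apply(masks, 1, function(S) {
    Z <- background
    if (any(S))
      Z[, S] <- matrix(x[S], nrow(background), sum(S), byrow = TRUE)
    mean(predict_fun(Z))
  })
  bit_id <- function(S) sum(2^(which(S) - 1)) + 1L
  stopifnot(identical(order(apply(masks, 1, bit_id)), seq_len(2^m)))
  phi <- numeric(m)
  for (i in seq_len(nrow(masks))) {
    S <- masks[i, ]
    s <- sum(S)
    for (j in which(!S)) {
      w <- factorial(s) * factorial(m - s - 1) / factorial(m)
      Sj <- S; Sj[j] <- TRUE
      phi[j] <- phi[j] + w * (v[bit_id(Sj)] - v[i])
    }
  }
  phi
}

# dense linear-solve oracle for random walk with restart
rwr_oracle <- function(network, seed_gene, restart_prob) {
  W <- matrix(0, length(network$nodes), length(network$nodes),
              dimnames = list(network$nodes, network$nodes))
  for (i in seq_len(nrow(network$edges))) {
    a <- network$edges$geneA[i]; b <- network$edges$geneB[i]
    W[a, b] <- W[a, b] + network$edges$weight[i]
    W[b, a] <- W[b, a] + network$edges$weight[i]
  }
  deg <- colSums(W)
  P <- sweep(W, 2, ifelse(deg == 0, 1, deg), "/")
  e <- as.numeric(network$nodes == seed_gene)
  r <- restart_prob * solve(diag(length(e)) - (1 - restart_prob) * P, e)
  stats::setNames(r, network$nodes)
}

random_network <- function(n, p = 0.2, seed = 1) {
  with_seed <- nextgene:::with_seed
  with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(n))
    idx <- utils::combn(n, 2)
    keep <- stats::runif(ncol(idx)) < p
    if (!any(keep)) keep[1] <- TRUE
    gene_network(data.frame(geneA = nodes[idx[1, keep]],
                            geneB = nodes[idx[2, keep]],
                            weight = stats::runif(sum(keep), 0.1, 1),
                            stringsAsFactors = FALSE),
                 nodes = nodes)
  })
}
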