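# Ranking evaluation: AUROC and AUROC@k with tie jitter and
# train-only-partner removal, random-walk-with-restart network comparators,
# raw pairwise-score comparators, and statistical model comparison.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counting one half
#' (rank-statistic form; invariant under strictly monotone transforms of
#' the scores).
#'
#' @param scores numeric score vector.
#' @param labels 0/1 vector; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stopf("AUROC needs both positive and negative labels")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUROC restricted to the top-k of a ranking
#'
#' Adds a uniform tie-breaking jitter in \code{(0, jitter_bound)} to every
#' score, re-ranks, sets the score of every candidate ranked below \code{k}
#' to 0, and computes AUROC of the modified scores against membership in
#' the positive set. Measures whether true partners appear among the top-k
#' suggestions; with \code{k >= universe} it reduces to plain AUROC.
#'
#' @param ranking a \code{ranked_suggestion}.
#' @param positive_set character vector of true partner genes.
#' @param k rank cutoff (>= 1).
#' @param jitter_bound upper bound of the tie jitter (default 1e-10).
#' @param seed seed of the dedicated jitter generator.
#' @return AUROC@k in \[0, 1\].
#' @export
auroc_at_k <- function(ranking, positive_set, k, jitter_bound = 1e-10,
                       seed = 1) {
  stopifnot(inherits(ranking, "ranked_suggestion"), k >= 1,
            jitter_bound > 0)
  e <- ranking$entries
  n <- nrow(e)
  sc <- e$score + with_seed(seed, stats::runif(n, 0, jitter_bound))
  rk <- rank(-sc, ties.method = "first")
  sc[rk > k] <- 0
  auroc(sc, as.integer(e$gene %in% positive_set))
}

#' Remove genes that can be neither positive nor negative
#'
#' Genes analyzed after the query in the training period but not in the
#' evaluation period carry stale evidence: they cannot be scored as
#' positives (no evaluation-period pair) nor fairly as negatives (they were
#' real partners once). They are deleted from the ranking before scoring
#' and the ranks recomputed.
#'
#' @param ranking a \code{ranked_suggestion}.
#' @param query the query gene (provenance of the partner sets).
#' @param train_partners genes following \code{query} in the training
#'   period.
#' @param eval_partners genes following \code{query} in the evaluation
#'   period.
#' @return The filtered \code{ranked_suggestion}.
#' @export
filter_ambiguous <- function(ranking, query, train_partners, eval_partners) {
  stopifnot(inherits(ranking, "ranked_suggestion"))
  drop <- setdiff(train_partners, eval_partners)
  e <- ranking$entries[!(ranking$entries$gene %in% drop), , drop = FALSE]
  e$rank <- seq_len(nrow(e))
  rownames(e) <- NULL
  ranking$entries <- e
  ranking$universe_size <- nrow(e)
  ranking
}

#' Construct a weighted undirected gene network
#'
#' @param edges data.frame with columns \code{geneA}, \code{geneB},
#'   \code{weight} (non-negative, finite); self-loops are rejected.
#' @param name network name.
#' @param nodes optional node set (defaults to the genes in the edges;
#'   extra nodes are kept as isolated).
#' @return Object of class \code{gene_network}.
#' @export
gene_network <- function(edges, name = "network", nodes = NULL) {
  stopifnot(all(c("geneA", "geneB", "weight") %in% names(edges)))
  if (any(edges$geneA == edges$geneB)) stopf("self-loops are not allowed")
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stopf("weights must be finite and >= 0")
  all_nodes <- union(edges$geneA, edges$geneB)
  if (!is.null(nodes)) all_nodes <- union(nodes, all_nodes)
  structure(list(nodes = all_nodes,
                 edges = edges[, c("geneA", "geneB", "weight")],
                 name = name),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene network '%s': %d nodes, %d undirected weighted edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

network_adjacency <- function(network) {
  n <- length(network$nodes)
  W <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    W[e$geneA[i], e$geneB[i]] <- W[e$geneA[i], e$geneB[i]] + e$weight[i]
    W[e$geneB[i], e$geneA[i]] <- W[e$geneB[i], e$geneA[i]] + e$weight[i]
  }
  W
}

#' Random walk with restart on a weighted gene network
#'
#' Iterates \code{r <- (1 - c) * P \%*\% r + c * e} where \code{P} is the
#' column-normalized weighted adjacency (column j holds the transition
#' probabilities out of node j), \code{e} the seed indicator and \code{c}
#' the restart probability, until the L1 change falls below \code{tol}.
#' The stationary vector is the seed-relative proximity of every node;
#' nodes unreachable from the seed get proximity 0 and are flagged.
#'
#' @param network a \code{gene_network} with at least one edge.
#' @param seed_gene seed node symbol.
#' @param restart_prob restart probability \code{c} (default 0.15).
#' @param tol L1 convergence tolerance (default 1e-9).
#' @param max_iter iteration cap (default 1000).
#' @return Object of class \code{rwr_result}: list with \code{seed_gene},
#'   \code{proximity} (named, sums to 1 within tolerance),
#'   \code{restart_prob}, \code{iterations}, \code{residual},
#'   \code{unreached} (nodes with zero proximity).
#' @export
rwr <- function(network, seed_gene, restart_prob = 0.15, tol = 1e-9,
                max_iter = 1000) {
  stopifnot(inherits(network, "gene_network"))
  if (!seed_gene %in% network$nodes)
    stopf("seed gene %s is not in the network", seed_gene)
  if (!nrow(network$edges)) stopf("network has no edges")
  W <- network_adjacency(network)
  deg <- colSums(W)
  if (deg[seed_gene] == 0) {
    warnf("seed gene %s is isolated; returning the degenerate restart vector",
          seed_gene)
    r <- stats::setNames(as.numeric(network$nodes == seed_gene),
                         network$nodes)
    return(structure(list(seed_gene = seed_gene, proximity = r,
                          restart_prob = restart_prob, iterations = 0L,
                          residual = 0,
                          unreached = setdiff(network$nodes, seed_gene)),
                     class = "rwr_result"))
  }
  P <- sweep(W, 2, ifelse(deg == 0, 1, deg), "/")
  e <- as.numeric(network$nodes == seed_gene)
  r <- e
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r_new <- (1 - restart_prob) * as.numeric(P %*% r) + restart_prob * e
    res <- sum(abs(r_new - r))
    r <- r_new
    if (res <= tol) break
  }
  if (res > tol)
    stopf("RWR did not converge in %d iterations (L1 residual %.3g)",
          max_iter, res)
  structure(list(seed_gene = seed_gene,
                 proximity = stats::setNames(r, network$nodes),
                 restart_prob = restart_prob, iterations = it,
                 residual = res,
                 unreached = network$nodes[r == 0]),
            class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat(sprintf(
    "RWR from %s (restart %.2f): converged in %d iterations (L1 residual %.2g), %d unreached node(s)\n",
    x$seed_gene, x$restart_prob, x$iterations, x$residual,
    length(x$unreached)))
  invisible(x)
}

#' Rank genes by random-walk proximity to a query
#'
#' Runs \code{\link{rwr}} from the query and ranks all other nodes by
#' proximity. The \code{feature_score} column carries the proximity with
#' values below \code{cutoff} set to 0 — the form in which RWR proximities
#' are integrated as features into an augmented ranking model.
#'
#' @param network a \code{gene_network}.
#' @param query query gene symbol.
#' @param cutoff integration cutoff applied to the exported feature
#'   (default 0: no cutoff).
#' @param ... passed to \code{\link{rwr}}.
#' @return A \code{ranked_suggestion} whose entries carry
#'   \code{feature_score}.
#' @export
rwr_ranking <- function(network, query, cutoff = 0, ...) {
  res <- rwr(network, query, ...)
  prox <- res$proximity[names(res$proximity) != query]
  ranked_suggestion(query, names(prox), as.numeric(prox),
                    extra = data.frame(
                      feature_score = ifelse(prox < cutoff, 0, prox)))
}

#' Rank genes by a stored pairwise score table
#'
#' Comparator for precomputed association scores (functional-coupling
#' confidence, link scores, semantic similarity): candidates are ranked by
#' the stored score of (query, candidate); lookups are symmetric and
#' missing pairs score 0.
#'
#' @param pair_scores data.frame with columns \code{geneA}, \code{geneB},
#'   \code{score}.
#' @param query query gene symbol.
#' @param universe candidate symbols (default: all genes in the table,
#'   minus the query).
#' @return A \code{ranked_suggestion}.
#' @export
raw_score_ranking <- function(pair_scores, query, universe = NULL) {
  stopifnot(all(c("geneA", "geneB", "score") %in% names(pair_scores)))
  if (is.null(universe))
    universe <- union(pair_scores$geneA, pair_scores$geneB)
  universe <- setdiff(universe, query)
  key <- c(paste(pair_scores$geneA, pair_scores$geneB, sep = "\r"),
           paste(pair_scores$geneB, pair_scores$geneA, sep = "\r"))
  val <- rep(pair_scores$score, 2)
  sc <- val[match(paste(query, universe, sep = "\r"), key)]
  sc[is.na(sc)] <- 0
  ranked_suggestion(query, universe, sc)
}

#' Compare per-query AUROC distributions between models
#'
#' Pairwise two-sided Mann-Whitney U tests with Bonferroni correction over
#' all reported comparisons, per-model percentile-bootstrap 95\% CIs of the
#' mean (default 10,000 resamples), and pairwise mean differences with
#' bootstrap CIs from paired query resampling.
#'
#' @param per_query_aurocs named list of numeric vectors, one per model,
#'   over the same query set (equal lengths; equal names when named).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return Object of class \code{model_comparison}: list with \code{means}
#'   (data.frame model, mean, ci_low, ci_high), \code{pairwise}
#'   (data.frame model_a, model_b, mean_diff, diff_ci_low, diff_ci_high,
#'   p_value, p_bonferroni).
#' @export
compare_models <- function(per_query_aurocs, n_boot = 10000, seed = 1,
                           conf = 0.95) {
  if (length(per_query_aurocs) < 2) stopf("need at least two models")
  if (is.null(names(per_query_aurocs)))
    names(per_query_aurocs) <- paste0("model", seq_along(per_query_aurocs))
  lens <- vapply(per_query_aurocs, length, integer(1))
  if (length(unique(lens)) != 1)
    stopf("models were evaluated on different query sets")
  nm_sets <- lapply(per_query_aurocs, names)
  if (!any(vapply(nm_sets, is.null, logical(1))) &&
      length(unique(vapply(nm_sets, paste, character(1), collapse = "\r"))) != 1)
    stopf("models were evaluated on different query sets")
  n <- lens[1]
  a <- (1 - conf) / 2
  models <- names(per_query_aurocs)

  boot_idx <- with_seed(seed, matrix(
    sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot, byrow = TRUE))
  means <- do.call(rbind, lapply(models, function(mname) {
    v <- per_query_aurocs[[mname]]
    bm <- rowMeans(matrix(v[t(boot_idx)], nrow = n_boot, byrow = TRUE))
    ci <- unname(stats::quantile(bm, c(a, 1 - a)))
    data.frame(model = mname, mean = mean(v), ci_low = ci[1],
               ci_high = ci[2], stringsAsFactors = FALSE)
  }))

  cmb <- utils::combn(models, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    va <- per_query_aurocs[[cmb[1, i]]]
    vb <- per_query_aurocs[[cmb[2, i]]]
    p <- stats::wilcox.test(va, vb, alternative = "two.sided",
                            exact = FALSE)$p.value
    bd <- rowMeans(matrix(va[t(boot_idx)], nrow = n_boot, byrow = TRUE)) -
          rowMeans(matrix(vb[t(boot_idx)], nrow = n_boot, byrow = TRUE))
    ci <- unname(stats::quantile(bd, c(a, 1 - a)))
    data.frame(model_a = cmb[1, i], model_b = cmb[2, i],
               mean_diff = mean(va) - mean(vb),
               diff_ci_low = ci[1], diff_ci_high = ci[2], p_value = p,
               stringsAsFactors = FALSE)
  }))
  pw$p_bonferroni <- stats::p.adjust(pw$p_value, method = "bonferroni")
  rownames(means) <- rownames(pw) <- NULL
  structure(list(means = means, pairwise = pw, n_queries = n,
                 n_boot = n_boot, seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison over %d queries (%d bootstrap resamples)\n",
              x$n_queries, x$n_boot))
  print(x$means, row.names = FALSE, digits = 4)
  cat("Pairwise Mann-Whitney (Bonferroni-corrected):\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate a ranking function over a set of query genes
#'
#' For each query: build the ranking, remove training-only partners
#' (\code{\link{filter_ambiguous}}), and compute AUROC@k for each requested
#' k against the evaluation-period partners. Queries with no positive left
#' after filtering are skipped and counted (AUROC is undefined for them).
#'
#' @param ranking_fun function(query_gene) returning a
#'   \code{ranked_suggestion}.
#' @param queries character vector of query genes.
#' @param eval_partners named list: query -> evaluation-period partner
#'   genes (the positives).
#' @param train_partners named list: query -> training-period partner genes
#'   (default empty; used for the removal rule).
#' @param k_values integer vector of rank cutoffs (default c(100, 1000)).
#' @param jitter_bound tie-jitter bound (default 1e-10).
#' @param seed base jitter seed (each query perturbs it deterministically).
#' @return data.frame with one row per evaluable query: \code{query},
#'   \code{n_pos}, \code{n_candidates}, \code{auroc} and one
#'   \code{auroc_at_<k>} column per k; attribute \code{n_skipped} counts
#'   queries without positives.
#' @export
evaluate_rankings <- function(ranking_fun, queries, eval_partners,
                              train_partners = list(),
                              k_values = c(100, 1000),
                              jitter_bound = 1e-10, seed = 1) {
  rows <- list()
  skipped <- 0L
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    pos <- unique(eval_partners[[q]])
    rk <- ranking_fun(q)
    tp <- if (!is.null(train_partners[[q]])) train_partners[[q]]
          else character(0)
    rk <- filter_ambiguous(rk, q, tp, pos)
    labels <- rk$entries$gene %in% pos
    if (!any(labels) || all(labels)) { skipped <- skipped + 1L; next }
    qseed <- (seed + qi) %% .Machine$integer.max
    row <- data.frame(query = q, n_pos = sum(labels),
                      n_candidates = nrow(rk$entries),
                      auroc = auroc(rk$entries$score, as.integer(labels)),
                      stringsAsFactors = FALSE)
    for (k in k_values)
      row[[paste0("auroc_at_", k)]] <-
        auroc_at_k(rk, pos, k, jitter_bound, seed = qseed)
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(query = character(0), n_pos = integer(0),
                         n_candidates = integer(0), auroc = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Partner sets of each query gene in a pair table
#'
#' @param pairs data.frame of positive pairs.
#' @return Named list: \code{gene_prev} -> unique \code{gene_next} partners.
#' @export
partner_sets <- function(pairs) {
  lapply(split(pairs$gene_next, pairs$gene_prev), unique)
}
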