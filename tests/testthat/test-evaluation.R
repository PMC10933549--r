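test_that("AUROC equals the pairwise-comparison probability", {
  expect_identical(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # enumerate the four positive-negative comparisons by hand:
  # 0.9>0.8, 0.9>0.1, 0.7<0.8, 0.7>0.1 -> 3/4
  expect_identical(auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_error(auroc(c(1, 2), c(1, 1)), "both")
})

test_that("AUROC matches the brute-force oracle and monotone invariance", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), brute_auroc(s, y), tolerance = 1e-12)
    expect_equal(auroc(exp(3 * s) + 7, y), auroc(s, y), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent library implementation", {
  set.seed(9)
  for (i in 1:5) {
    s <- runif(80)
    y <- rbinom(80, 1, 0.5)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = s, quiet = TRUE, direction = "<")))
    expect_equal(auroc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("AUROC@k zeroes below-k scores and reduces to AUROC at full k", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:12)
  scores <- seq(0.95, 0.4, length.out = 12)  # distinct, gaps >> jitter
  rk <- ranked_suggestion("q", genes, scores)
  pos <- c("g02", "g05")
  expect_equal(auroc_at_k(rk, pos, k = 12, seed = 1),
               auroc(scores, as.integer(genes %in% pos)))
  # all positives inside top-k, all negatives outside
  rk2 <- ranked_suggestion("q", c("p1", "p2", "n1", "n2", "n3"),
                           c(0.9, 0.8, 0.3, 0.2, 0.1))
  expect_identical(auroc_at_k(rk2, c("p1", "p2"), k = 2, seed = 1), 1)
})

test_that("AUROC@k matches hand-enumerated zeroed-score computations", {
  # spec-style constructed fixtures: 6-20 genes, positives at known ranks
  cases <- list(
    list(n = 6, pos_ranks = c(2, 5), k = 3),
    list(n = 10, pos_ranks = c(1, 4, 9), k = 4),
    list(n = 20, pos_ranks = c(3, 11, 17), k = 10),
    list(n = 12, pos_ranks = c(11, 12), k = 3))
  for (cs in cases) {
    genes <- sprintf("g%02d", seq_len(cs$n))
    scores <- seq(0.99, 0.5, length.out = cs$n)
    rk <- ranked_suggestion("q", genes, scores)
    pos <- genes[cs$pos_ranks]
    # independent oracle: zero scores below k, count pairs by brute force
    zeroed <- ifelse(seq_len(cs$n) <= cs$k, scores, 0)
    oracle <- brute_auroc(zeroed, as.integer(genes %in% pos))
    expect_equal(auroc_at_k(rk, pos, cs$k, seed = 3), oracle,
                 tolerance = 1e-12)
  }
})

test_that("AUROC@k is non-decreasing in k in expectation", {
  set.seed(11)
  genes <- sprintf("g%02d", 1:15)
  scores <- runif(15)
  rk <- ranked_suggestion("q", genes, scores)
  pos <- sample(genes, 4)
  means <- vapply(c(3, 8, 15), function(k)
    mean(vapply(1:20, function(s) auroc_at_k(rk, pos, k, seed = s),
                numeric(1))), numeric(1))
  expect_true(all(diff(means) >= -1e-9))
})

test_that("training-only partners are removed before scoring", {
  rk <- ranked_suggestion("Q", c("B", "C", "D"), c(0.9, 0.5, 0.1))
  f <- filter_ambiguous(rk, "Q", train_partners = "B", eval_partners = "C")
  expect_setequal(f$entries$gene, c("C", "D"))
  expect_identical(f$entries$rank, 1:2)
  expect_identical(f$universe_size, 2L)
  # train subset of eval: unchanged
  f2 <- filter_ambiguous(rk, "Q", "C", c("B", "C"))
  expect_identical(f2$entries, rk$entries)
  # removal can flip a borderline top-k verdict: B occupied rank 1
  pos <- "C"
  before <- auroc_at_k(rk, pos, k = 1, seed = 2)
  after <- auroc_at_k(f, pos, k = 1, seed = 2)
  expect_gt(after, before)
})

test_that("RWR matches the closed-form solution on a single edge", {
  net <- gene_network(data.frame(geneA = "A", geneB = "B", weight = 1))
  res <- rwr(net, "A", restart_prob = 0.15)
  # 2x2 linear system: r = c (I - (1-c) P)^-1 e with P = [[0,1],[1,0]]
  c15 <- 0.15
  oracle <- c15 * solve(diag(2) - (1 - c15) * matrix(c(0, 1, 1, 0), 2),
                        c(1, 0))
  expect_equal(unname(res$proximity[c("A", "B")]), oracle,
               tolerance = 1e-8)
  expect_equal(sum(res$proximity), 1, tolerance = 1e-8)
  # immediate restart concentrates all mass on the seed
  r1 <- rwr(net, "A", restart_prob = 1)
  expect_equal(unname(r1$proximity[c("A", "B")]), c(1, 0))
})

test_that("RWR agrees with the dense linear-solve oracle on random graphs", {
  for (seed in 1:4) {
    n <- c(15, 30, 50, 24)[seed]
    net <- random_network(n, p = 0.15, seed = seed)
    q <- net$nodes[1]
    res <- rwr(net, q, restart_prob = 0.15, tol = 1e-9)
    oracle <- rwr_oracle(net, q, 0.15)
    expect_lt(sum(abs(res$proximity - oracle[names(res$proximity)])),
              10 * 1e-9)
    expect_equal(sum(res$proximity), 1, tolerance = 1e-6)
    expect_true(all(res$proximity >= 0))
  }
})

test_that("RWR flags unreachable components and isolated seeds", {
  net <- gene_network(data.frame(geneA = c("A", "C"), geneB = c("B", "D"),
                                 weight = 1), nodes = c("A", "B", "C", "D", "E"))
  res <- rwr(net, "A")
  expect_true(all(c("C", "D", "E") %in% res$unreached))
  expect_equal(unname(res$proximity[c("C", "D", "E")]), c(0, 0, 0))
  expect_warning(res_iso <- rwr(net, "E"), "isolated")
  expect_identical(unname(res_iso$proximity["E"]), 1)
  expect_error(rwr(net, "ZZ"), "not in the network")
})

test_that("RWR ranking applies the integration cutoff to exported features", {
  net <- random_network(20, p = 0.3, seed = 3)
  rk <- rwr_ranking(net, net$nodes[1], cutoff = 0.02)
  expect_false(net$nodes[1] %in% rk$entries$gene)
  below <- rk$entries$score < 0.02
  expect_true(all(rk$entries$feature_score[below] == 0))
  expect_identical(rk$entries$feature_score[!below],
                   rk$entries$score[!below])
  # star graph: all leaves tie by symmetry
  star <- gene_network(data.frame(geneA = "HUB",
                                  geneB = paste0("L", 1:6), weight = 1))
  rs <- rwr_ranking(star, "HUB")
  expect_lt(diff(range(rs$entries$score)), 1e-9)
})

test_that("raw pairwise-score ranking is symmetric with missing pairs at 0", {
  tab <- data.frame(geneA = c("Q", "Q"), geneB = c("A", "B"),
                    score = c(0.9, 0.2), stringsAsFactors = FALSE)
  rk <- raw_score_ranking(tab, "Q", universe = c("A", "B", "C"))
  expect_identical(rk$entries$gene, c("A", "B", "C"))
  expect_identical(rk$entries$score, c(0.9, 0.2, 0))
  # symmetric lookup: table stored as (A, Q) ranks identically
  tab2 <- data.frame(geneA = c("A", "B"), geneB = c("Q", "Q"),
                     score = c(0.9, 0.2), stringsAsFactors = FALSE)
  rk2 <- raw_score_ranking(tab2, "Q", universe = c("A", "B", "C"))
  expect_identical(rk2$entries, rk$entries)
  # re-sort oracle
  expect_identical(rk$entries$score, sort(c(0.9, 0.2, 0), decreasing = TRUE))
})

test_that("model comparison: self-comparison is null, separation is significant", {
  set.seed(5)
  a <- runif(200, 0.4, 0.6)
  b <- runif(200, 0.7, 0.9)  # disjoint, well separated
  cmp <- compare_models(list(m1 = a, m2 = a, m3 = b), n_boot = 2000,
                        seed = 3)
  self_row <- cmp$pairwise[cmp$pairwise$model_a == "m1" &
                           cmp$pairwise$model_b == "m2", ]
  expect_gt(self_row$p_bonferroni, 0.99)
  expect_true(self_row$diff_ci_low <= 0 && self_row$diff_ci_high >= 0)
  sep_row <- cmp$pairwise[cmp$pairwise$model_a == "m1" &
                          cmp$pairwise$model_b == "m3", ]
  expect_lt(sep_row$p_bonferroni, 0.001)
  # p-values invariant to model labeling order
  cmp_rev <- compare_models(list(m3 = b, m2 = a, m1 = a), n_boot = 2000,
                            seed = 3)
  expect_equal(sort(cmp_rev$pairwise$p_value), sort(cmp$pairwise$p_value))
  # constant vectors give zero-width CIs
  cc <- compare_models(list(x = rep(0.7, 50), y = rep(0.7, 50)),
                       n_boot = 500, seed = 1)
  expect_identical(cc$means$ci_low, cc$means$ci_high)
  expect_error(compare_models(list(a = 1:3 / 10, b = 1:4 / 10)),
               "query sets")
})

test_that("query evaluation skips queries without scorable positives", {
  fit <- small_world_fit()
  sp <- fit$split
  te <- partner_sets(sp$test)
  tr <- partner_sets(rbind(sp$train, sp$validation))
  queries <- head(intersect(names(te), fit$universe), 25)
  ev <- evaluate_rankings(
    function(q) rank_genes(fit$model, q, fit$sources, universe = fit$universe),
    queries, te, tr, k_values = c(10, 25), seed = 2)
  expect_true(all(c("auroc", "auroc_at_10", "auroc_at_25") %in% names(ev)))
  expect_true(all(ev$n_pos >= 1))
  expect_true(all(ev$auroc >= 0 & ev$auroc <= 1))
  expect_identical(nrow(ev) + attr(ev, "n_skipped"), length(queries))
})
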