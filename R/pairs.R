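# Consecutive-experiment gene pairs: construction from ordered per-article
# experiment lists, temporal splitting, negative sampling and the
# sequentiality audit statistics.

#' Build consecutive-experiment gene pairs from an experiment list
#'
#' For each article, every adjacent pair of mentions (by \code{order_index})
#' yields an ordered tuple \code{(gene_prev, gene_next)}. Pairs never cross
#' article boundaries. Adjacent mentions of the same gene are dropped by
#' default: only different-gene pairs carry a sequential-experiment signal
#' strong enough to train on (the same-gene adjacencies are frequently
#' re-descriptions of one experiment).
#'
#' @param mentions data.frame of experiment mentions (see
#'   \code{\link{extract_experiments}}), sorted by \code{order_index} within
#'   each article.
#' @param keep_same_gene keep same-gene adjacencies (default \code{FALSE}).
#' @return data.frame with columns \code{gene_prev}, \code{gene_next},
#'   \code{article_id}, \code{year}, \code{label} (all 1).
#' @export
build_pairs <- function(mentions, keep_same_gene = FALSE) {
  if (!nrow(mentions)) return(empty_pairs())
  bad <- vapply(split(mentions$order_index, mentions$article_id),
                function(o) is.unsorted(o, strictly = TRUE), logical(1))
  if (any(bad))
    stopf("mentions not sorted by order_index within article(s): %s",
          paste(names(bad)[bad], collapse = ", "))
  out <- lapply(split(mentions, mentions$article_id), function(a) {
    n <- nrow(a)
    if (n < 2) return(NULL)
    data.frame(gene_prev = a$gene[-n], gene_next = a$gene[-1],
               article_id = a$article_id[1], year = a$year[1],
               label = 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_pairs())
  if (!keep_same_gene)
    out <- out[out$gene_prev != out$gene_next, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(gene_prev = character(0), gene_next = character(0),
             article_id = character(0), year = integer(0),
             label = integer(0), stringsAsFactors = FALSE)
}

#' Split pairs into train/validation/test by publication year
#'
#' Pairs from articles published up to \code{train_end_year} train the
#' models, pairs from \code{validation_year} validate them, and pairs from
#' \code{test_start_year} onwards are held out for testing. Because the
#' split is on the article's year, the article sets of the three splits are
#' disjoint by construction.
#'
#' @param pairs data.frame of pairs with a \code{year} column.
#' @param train_end_year last training year (default 2018).
#' @param validation_year validation year (default 2019).
#' @param test_start_year first test year (default 2020).
#' @return Object of class \code{split_dataset}: list with \code{train},
#'   \code{validation}, \code{test} data.frames and \code{boundaries}.
#' @export
temporal_split <- function(pairs, train_end_year = 2018,
                           validation_year = 2019, test_start_year = 2020) {
  if (!(train_end_year < validation_year && validation_year < test_start_year))
    stopf("split boundaries must satisfy train_end < validation < test_start")
  if (any(is.na(pairs$year))) stopf("every pair needs a year")
  sel <- function(cond) {
    d <- pairs[cond, , drop = FALSE]; rownames(d) <- NULL; d
  }
  structure(list(
    train = sel(pairs$year <= train_end_year),
    validation = sel(pairs$year == validation_year),
    test = sel(pairs$year >= test_start_year),
    boundaries = c(train_end_year = train_end_year,
                   validation_year = validation_year,
                   test_start_year = test_start_year)),
    class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf(
    "Temporal split: %d train (<= %d), %d validation (%d), %d test (>= %d)\n",
    nrow(x$train), x$boundaries[1], nrow(x$validation), x$boundaries[2],
    nrow(x$test), x$boundaries[3]))
  invisible(x)
}

#' Sample negative pairs for ranking-as-classification
#'
#' For each positive tuple, draws \code{ratio} replacement genes for
#' \code{gene_next} uniformly from the universe, rejecting the positive's
#' own \code{gene_prev}, any gene forming an observed positive tuple with
#' that \code{gene_prev} (collision scope: the global positive set), and
#' duplicate draws within one positive's samples. Equivalent to sampling
#' \code{ratio} genes without replacement from the legal set.
#'
#' @param positives data.frame of positive pairs.
#' @param universe character vector of candidate gene symbols.
#' @param ratio negatives per positive (default 3).
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return data.frame of negative pairs (label 0), \code{ratio} rows per
#'   positive, in positive order.
#' @export
sample_negatives <- function(positives, universe, ratio = 3, seed = 1) {
  if (length(universe) < 2) stopf("universe must contain more than one gene")
  if (ratio < 1) stopf("ratio must be >= 1")
  if (!nrow(positives)) return(empty_pairs())
  partners <- lapply(split(positives$gene_next, positives$gene_prev), unique)
  with_seed(seed, {
    drawn <- lapply(seq_len(nrow(positives)), function(i) {
      gp <- positives$gene_prev[i]
      legal <- setdiff(universe, c(gp, partners[[gp]]))
      if (length(legal) < ratio)
        stopf("cannot draw %d non-colliding negatives for positive (%s, %s)",
              ratio, gp, positives$gene_next[i])
      sample(legal, ratio, replace = FALSE)
    })
    idx <- rep(seq_len(nrow(positives)), each = ratio)
    data.frame(gene_prev = positives$gene_prev[idx],
               gene_next = unlist(drawn),
               article_id = positives$article_id[idx],
               year = positives$year[idx],
               label = 0L, stringsAsFactors = FALSE)
  })
}

#' Proportion estimate with percentile-bootstrap confidence interval
#'
#' Computes \code{numerator/denominator} and a percentile bootstrap CI of
#' the proportion, resampling the \code{denominator} Bernoulli outcomes with
#' replacement \code{n_boot} times (default 10,000). Used for the audit of
#' how often consecutive experiment descriptions reflect sequentially
#' performed experiments.
#'
#' @param numerator number of successes.
#' @param denominator number of trials (> 0).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return Object of class \code{proportion_estimate}: list with
#'   \code{numerator}, \code{denominator}, \code{proportion}, \code{ci_low},
#'   \code{ci_high}, \code{n_boot}, \code{seed}.
#' @export
sequentiality_stats <- function(numerator, denominator, n_boot = 10000,
                                seed = 1, conf = 0.95) {
  if (denominator <= 0) stopf("denominator must be > 0")
  if (numerator < 0 || numerator > denominator)
    stopf("need 0 <= numerator <= denominator")
  p <- numerator / denominator
  x <- c(rep(1L, numerator), rep(0L, denominator - numerator))
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    mean(x[sample.int(denominator, denominator, replace = TRUE)]),
    numeric(1)))
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a), type = 7))
  structure(list(numerator = numerator, denominator = denominator,
                 proportion = p, ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, seed = seed),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, digits = 1, ...) {
  cat(sprintf("%d/%d = %.*f%% (95%% CI: %.*f%%-%.*f%%, %d bootstrap resamples)\n",
              x$numerator, x$denominator, digits, 100 * x$proportion,
              digits, 100 * x$ci_low, digits, 100 * x$ci_high, x$n_boot))
  invisible(x)
}
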