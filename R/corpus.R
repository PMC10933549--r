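# Corpus extraction: dictionary matching of gene and experiment-method terms
# in sentences, candidate masking for relation classification, and assembly
# of per-article ordered experiment lists.

#' Build a dictionary index of gene and method surface terms
#'
#' Collects every gene symbol/alias and experiment-method term into a single
#' lookup table used for sentence matching. Terms shorter than
#' \code{min_length} characters and terms in \code{stopwords} are excluded
#' (both checks are case-insensitive, as is all downstream matching).
#' A surface string that maps to two different genes is ambiguous and is
#' dropped from the index with a warning.
#'
#' @param genes data.frame with columns \code{symbol}, \code{aliases}
#'   (pipe-separated, possibly empty), \code{locus_group}, \code{location}.
#' @param methods data.frame with columns \code{term}, \code{category}.
#' @param min_length minimum surface length kept in the index (default 3).
#' @param stopwords character vector of excluded surfaces.
#' @return An object of class \code{term_index}: a list with \code{entries}
#'   (data.frame \code{surface}, \code{kind}, \code{canonical}),
#'   \code{min_length}, \code{stopwords} and \code{n_ambiguous}.
#' @export
build_term_index <- function(genes, methods, min_length = 3,
                             stopwords = character()) {
  if (min_length < 1) stopf("min_length must be >= 1")
  validate_gene_table(genes)
  if (!all(c("term", "category") %in% names(methods)))
    stopf("methods table needs columns 'term' and 'category'")
  bad_cat <- setdiff(unique(methods$category), method_categories())
  if (length(bad_cat))
    stopf("unknown method categories: %s", paste(bad_cat, collapse = ", "))

  stop_lc <- tolower(stopwords)

  surfaces <- character(0); kinds <- character(0); canon <- character(0)
  for (i in seq_len(nrow(genes))) {
    al <- genes$aliases[i]
    al <- if (is.na(al) || !nzchar(al)) character(0)
          else strsplit(al, "|", fixed = TRUE)[[1]]
    ss <- c(genes$symbol[i], al)
    ss <- ss[nzchar(ss)]
    surfaces <- c(surfaces, ss)
    kinds <- c(kinds, rep("gene", length(ss)))
    canon <- c(canon, rep(genes$symbol[i], length(ss)))
  }
  surfaces <- c(surfaces, methods$term)
  kinds <- c(kinds, rep("method", nrow(methods)))
  canon <- c(canon, methods$term)

  ent <- data.frame(surface = surfaces, kind = kinds, canonical = canon,
                    stringsAsFactors = FALSE)
  ent$surface_lc <- tolower(ent$surface)
  ent <- ent[nchar(ent$surface) >= min_length &
             !(ent$surface_lc %in% stop_lc), , drop = FALSE]
  ent <- unique(ent)

  # one lowercase surface resolving to two different genes is ambiguous
  n_ambiguous <- 0L
  g <- ent[ent$kind == "gene", ]
  if (nrow(g)) {
    tab <- tapply(g$canonical, g$surface_lc, function(x) length(unique(x)))
    amb <- names(tab)[tab > 1]
    n_ambiguous <- length(amb)
    if (n_ambiguous) {
      warnf("%d ambiguous gene surface(s) excluded from the index",
            n_ambiguous)
      ent <- ent[!(ent$kind == "gene" & ent$surface_lc %in% amb), ,
                 drop = FALSE]
    }
  }
  rownames(ent) <- NULL
  structure(list(entries = ent, min_length = as.integer(min_length),
                 stopwords = stop_lc, n_ambiguous = n_ambiguous),
            class = "term_index")
}

#' @export
print.term_index <- function(x, ...) {
  cat("Term index:", nrow(x$entries), "surfaces (",
      sum(x$entries$kind == "gene"), "gene,",
      sum(x$entries$kind == "method"), "method ), min length",
      x$min_length, ",", length(x$stopwords), "stopwords,",
      x$n_ambiguous, "ambiguous excluded\n")
  invisible(x)
}

validate_gene_table <- function(genes) {
  need <- c("symbol", "aliases", "locus_group", "location")
  if (!all(need %in% names(genes)))
    stopf("gene table needs columns: %s", paste(need, collapse = ", "))
  if (any(!nzchar(genes$symbol))) stopf("empty gene symbol")
  arm <- genes$location
  ok <- arm == "" | is.na(arm) | grepl("^([0-9]+|[XY])[pq]$", arm)
  if (!all(ok))
    stopf("malformed chromosome arm(s): %s",
          paste(unique(arm[!ok]), collapse = ", "))
  for (i in seq_len(nrow(genes))) {
    al <- genes$aliases[i]
    if (!is.na(al) && nzchar(al)) {
      al <- strsplit(al, "|", fixed = TRUE)[[1]]
      if (genes$symbol[i] %in% al)
        stopf("gene %s lists its own symbol as an alias", genes$symbol[i])
    }
  }
  invisible(TRUE)
}

# All word-boundary matches of every index surface in a vector of sentences.
# Returns a data.frame (sent, start, end, surface, kind, canonical) with
# half-open [start, end) 1-based character spans, overlaps unresolved.
match_all_terms <- function(sentences, index) {
  ent <- index$entries
  out <- vector("list", nrow(ent))
  for (i in seq_len(nrow(ent))) {
    pat <- paste0("(?<![[:alnum:]_])",
                  gsub("([^A-Za-z0-9 ])", "\\\\\\1", ent$surface[i]),
                  "(?![[:alnum:]_])")
    m <- gregexpr(pat, sentences, ignore.case = TRUE, perl = TRUE)
    hits <- lapply(seq_along(m), function(s) {
      st <- m[[s]]
      if (st[1] == -1L) return(NULL)
      len <- attr(st, "match.length")
      data.frame(sent = s, start = as.integer(st),
                 end = as.integer(st) + len,
                 surface = ent$surface[i], kind = ent$kind[i],
                 canonical = ent$canonical[i], stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, hits)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sent = integer(0), start = integer(0),
                      end = integer(0), surface = character(0),
                      kind = character(0), canonical = character(0))
  res
}

# Longest-match-wins overlap resolution within one sentence's matches:
# candidates sorted by decreasing length then start; accepted greedily if
# they do not overlap an already accepted span.
resolve_overlaps <- function(m) {
  if (nrow(m) <= 1) return(m)
  m <- m[order(-(m$end - m$start), m$start, m$kind), , drop = FALSE]
  keep <- logical(nrow(m))
  acc_s <- integer(0); acc_e <- integer(0)
  for (i in seq_len(nrow(m))) {
    if (!any(m$start[i] < acc_e & m$end[i] > acc_s)) {
      keep[i] <- TRUE
      acc_s <- c(acc_s, m$start[i]); acc_e <- c(acc_e, m$end[i])
    }
  }
  m <- m[keep, , drop = FALSE]
  m[order(m$start), , drop = FALSE]
}

empty_candidates <- function() {
  data.frame(article_id = character(0), year = integer(0),
             sentence_index = integer(0), sentence_text = character(0),
             gene_start = integer(0), gene_end = integer(0),
             method_start = integer(0), method_end = integer(0),
             gene_symbol = character(0), gene_surface = character(0),
             method_name = character(0), method_surface = character(0),
             stringsAsFactors = FALSE)
}

# Cross product of resolved gene x method matches for one sentence.
candidates_from_matches <- function(m, sentence_text, article_id = NA_character_,
                                    year = NA_integer_, sentence_index = 0L) {
  g <- m[m$kind == "gene", , drop = FALSE]
  e <- m[m$kind == "method", , drop = FALSE]
  if (!nrow(g) || !nrow(e)) return(empty_candidates())
  idx <- expand.grid(gi = seq_len(nrow(g)), mi = seq_len(nrow(e)))
  out <- data.frame(
    article_id = article_id, year = year, sentence_index = sentence_index,
    sentence_text = sentence_text,
    gene_start = g$start[idx$gi], gene_end = g$end[idx$gi],
    method_start = e$start[idx$mi], method_end = e$end[idx$mi],
    gene_symbol = g$canonical[idx$gi], gene_surface = g$surface[idx$gi],
    method_name = e$canonical[idx$mi], method_surface = e$surface[idx$mi],
    stringsAsFactors = FALSE)
  # spans are guaranteed disjoint after overlap resolution, but keep the
  # invariant explicit for safety
  ok <- out$gene_end <= out$method_start | out$method_end <= out$gene_start
  out <- out[ok, , drop = FALSE]
  out <- out[order(out$gene_start, out$method_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find gene/method candidate pairs in a sentence
#'
#' Matches the sentence against the term index (case-insensitive, word
#' boundaries only; overlapping dictionary hits are resolved longest-first
#' with ties broken by leftmost start) and returns the cross product of all
#' gene matches with all method matches. Spans are half-open 1-based
#' character offsets \code{[start, end)}.
#'
#' @param sentence_text a single sentence.
#' @param index a \code{term_index}.
#' @return data.frame of candidate pairs ordered by
#'   \code{(gene_start, method_start)}; zero rows when either side is absent.
#' @export
find_candidates <- function(sentence_text, index) {
  stopifnot(length(sentence_text) == 1, nzchar(sentence_text))
  m <- match_all_terms(sentence_text, index)
  m <- resolve_overlaps(m)
  candidates_from_matches(m, sentence_text)
}

candidate_surface <- function(cand, what = c("gene", "method")) {
  what <- match.arg(what)
  s <- if (what == "gene") cand$gene_start else cand$method_start
  e <- if (what == "gene") cand$gene_end else cand$method_end
  substr(cand$sentence_text, s, e - 1L)
}

#' Mask a candidate's gene and method surfaces with special tokens
#'
#' Replaces the gene surface with \code{[GENE]} and the method surface with
#' \code{[EXPE]}; every other character of the sentence is untouched, so
#' \code{\link{unmask}} reproduces the original sentence exactly.
#'
#' @param candidate a one-row candidate data.frame from
#'   \code{\link{find_candidates}}.
#' @return Object of class \code{masked_sentence}: list with \code{text} and
#'   \code{provenance} (the candidate row).
#' @export
mask_candidate <- function(candidate) {
  stopifnot(nrow(candidate) == 1)
  gs <- candidate$gene_start; ge <- candidate$gene_end
  ms <- candidate$method_start; me <- candidate$method_end
  txt <- candidate$sentence_text
  n <- nchar(txt)
  if (gs >= ge || ms >= me || gs < 1 || ms < 1 || ge > n + 1 || me > n + 1)
    stopf("malformed candidate spans")
  if (gs < me && ms < ge) stopf("overlapping gene and method spans")
  spans <- list(list(s = gs, e = ge, tok = "[GENE]"),
                list(s = ms, e = me, tok = "[EXPE]"))
  spans <- spans[order(-c(gs, ms))]  # replace right-to-left to keep offsets
  for (sp in spans)
    txt <- paste0(substr(txt, 1, sp$s - 1L), sp$tok,
                  substr(txt, sp$e, nchar(txt)))
  structure(list(text = txt, provenance = candidate),
            class = "masked_sentence")
}

#' Restore the original sentence from a masked sentence
#'
#' @param masked a \code{masked_sentence}.
#' @return The original \code{sentence_text} of the provenance candidate.
#' @export
unmask <- function(masked) {
  stopifnot(inherits(masked, "masked_sentence"))
  cand <- masked$provenance
  txt <- masked$text
  gsurf <- candidate_surface(cand, "gene")
  msurf <- candidate_surface(cand, "method")
  # the earlier span was replaced first when reading left to right
  first_gene <- cand$gene_start < cand$method_start
  reps <- if (first_gene) list(c("[GENE]", gsurf), c("[EXPE]", msurf))
          else list(c("[EXPE]", msurf), c("[GENE]", gsurf))
  for (r in reps) {
    i <- regexpr(r[1], txt, fixed = TRUE)
    txt <- paste0(substr(txt, 1, i - 1L), r[2],
                  substr(txt, i + attr(i, "match.length"), nchar(txt)))
  }
  txt
}

#' @export
print.masked_sentence <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' Relation classifier baselines
#'
#' A relation classifier scores a masked sentence with the probability that
#' the masked gene and method stand in a gene-experiment relation. Two
#' deterministic baselines ship with the package: \code{classifier_all_positive}
#' always returns 1 (recall 1 by construction: every candidate is accepted),
#' and \code{classifier_nearest_method} returns 1 only when, among all gene
#' occurrences in the sentence, the masked gene is the one closest (in
#' characters between spans) to the masked method. A fine-tuned language
#' model can be plugged in through the same contract.
#'
#' @return An object of class \code{relation_classifier} with fields
#'   \code{name} and \code{score(masked, context)}.
#' @export
classifier_all_positive <- function() {
  structure(list(name = "all_positive",
                 score = function(masked, context = NULL) 1.0),
            class = "relation_classifier")
}

#' @rdname classifier_all_positive
#' @export
classifier_nearest_method <- function() {
  score <- function(masked, context = NULL) {
    cand <- masked$provenance
    if (is.null(context))
      stopf("nearest-method classifier needs the sentence's candidate set")
    ctx <- context[context$method_start == cand$method_start &
                   context$method_end == cand$method_end, , drop = FALSE]
    gap <- function(gs, ge, ms, me) ifelse(ge <= ms, ms - ge, gs - me)
    d <- gap(ctx$gene_start, ctx$gene_end, ctx$method_start, ctx$method_end)
    best <- ctx[order(d, ctx$gene_start), , drop = FALSE][1, ]
    as.numeric(best$gene_start == cand$gene_start &&
               best$gene_end == cand$gene_end)
  }
  structure(list(name = "nearest_method", score = score),
            class = "relation_classifier")
}

#' Score a masked sentence with a relation classifier
#'
#' @param masked a \code{masked_sentence}.
#' @param classifier a \code{relation_classifier}.
#' @param context optional data.frame of all candidates found in the same
#'   sentence (required by context-aware baselines such as
#'   \code{classifier_nearest_method}).
#' @return Probability in \[0, 1\].
#' @export
classify_relation <- function(masked, classifier, context = NULL) {
  stopifnot(inherits(masked, "masked_sentence"),
            inherits(classifier, "relation_classifier"))
  p <- tryCatch(classifier$score(masked, context), error = function(e) {
    cand <- masked$provenance
    stopf("relation classifier '%s' failed on article %s sentence %d (%s/%s): %s",
          classifier$name, cand$article_id, cand$sentence_index,
          cand$gene_symbol, cand$method_name, conditionMessage(e))
  })
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stopf("classifier '%s' returned an invalid probability", classifier$name)
  p
}

#' Extract an ordered experiment list from a corpus
#'
#' Runs dictionary matching over every sentence of every article, masks each
#' gene/method candidate, scores it with the relation classifier, and keeps
#' candidates with score >= \code{threshold}. Accepted mentions are ordered
#' within each article by \code{(sentence_index, gene_start, method_start)}
#' and given a 0-based \code{order_index}.
#'
#' @param articles list of article records, each a list with
#'   \code{article_id}, \code{year} and \code{sentences} (character vector in
#'   document order), as returned by \code{\link{read_corpus}}.
#' @param index a \code{term_index}.
#' @param classifier a \code{relation_classifier}.
#' @param threshold acceptance threshold on the relation score (default 0.5).
#' @return data.frame of experiment mentions with columns \code{article_id},
#'   \code{year}, \code{sentence_index}, \code{order_index}, \code{gene},
#'   \code{method}, \code{score}.
#' @export
extract_experiments <- function(articles, index, classifier,
                                threshold = 0.5) {
  sent <- unlist(lapply(articles, function(a) a$sentences))
  if (is.null(sent) || !length(sent)) return(empty_mentions())
  aid <- unlist(lapply(articles, function(a)
    rep(a$article_id, length(a$sentences))))
  yr <- unlist(lapply(articles, function(a)
    rep(as.integer(a$year), length(a$sentences))))
  sidx <- unlist(lapply(articles, function(a)
    seq_along(a$sentences) - 1L))

  m <- match_all_terms(sent, index)
  res <- vector("list", length(sent))
  for (s in unique(m$sent)) {
    ms <- resolve_overlaps(m[m$sent == s, , drop = FALSE])
    cands <- candidates_from_matches(ms, sent[s], aid[s], yr[s], sidx[s])
    if (!nrow(cands)) next
    sc <- vapply(seq_len(nrow(cands)), function(i) {
      classify_relation(mask_candidate(cands[i, , drop = FALSE]),
                        classifier, context = cands)
    }, numeric(1))
    cands$score <- sc
    res[[s]] <- cands[sc >= threshold, , drop = FALSE]
  }
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) return(empty_mentions())
  out <- out[order(out$article_id, out$sentence_index, out$gene_start,
                   out$method_start), , drop = FALSE]
  out$order_index <- stats::ave(seq_len(nrow(out)), out$article_id,
                                FUN = seq_along) - 1L
  mentions <- data.frame(article_id = out$article_id, year = out$year,
                         sentence_index = out$sentence_index,
                         order_index = out$order_index,
                         gene = out$gene_symbol, method = out$method_name,
                         score = out$score, stringsAsFactors = FALSE)
  rownames(mentions) <- NULL
  mentions
}

empty_mentions <- function() {
  data.frame(article_id = character(0), year = integer(0),
             sentence_index = integer(0), order_index = integer(0),
             gene = character(0), method = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Rule-based sentence splitter
#'
#' Splits text on sentence-final punctuation (\code{.}, \code{!}, \code{?})
#' followed by whitespace and an uppercase letter or digit. Deliberately
#' simple; segmentation is pluggable and any pre-segmented corpus bypasses
#' it entirely.
#'
#' @param text a character scalar.
#' @return Character vector of sentences.
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1)
  parts <- strsplit(text, "(?<=[.!?])\\s+(?=[A-Z0-9])", perl = TRUE)[[1]]
  parts[nzchar(trimws(parts))]
}
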