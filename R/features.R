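# Pairwise feature encoding for ordered gene pairs. Categorical annotation
# terms contribute three 0/1 slots each (shared / previous-only / next-only),
# numerical profile sources one Pearson-correlation slot, embedding sources
# one cosine-similarity slot.

#' Construct a categorical annotation source
#'
#' @param name source name (unique within a schema).
#' @param annotations either a data.frame with columns \code{gene},
#'   \code{term}, or a named list mapping gene to a character vector of
#'   term ids.
#' @param min_genes minimum number of annotated genes a term needs to be
#'   retained (default 10); applied by \code{\link{filter_terms}}.
#' @return Object of class \code{categorical_source}.
#' @export
categorical_source <- function(name, annotations, min_genes = 10) {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("gene", "term") %in% names(annotations)))
    ann <- lapply(split(annotations$term, annotations$gene), unique)
  } else {
    ann <- lapply(annotations, unique)
  }
  structure(list(name = name, annotations = ann,
                 min_genes = as.integer(min_genes)),
            class = "categorical_source")
}

#' Construct a numerical profile source
#'
#' @param name source name.
#' @param profiles numeric matrix, one row per gene (rownames), columns on a
#'   shared sample axis; at least 3 samples so pairwise correlation is
#'   nondegenerate.
#' @return Object of class \code{numerical_source}.
#' @export
numerical_source <- function(name, profiles) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  if (ncol(profiles) < 3)
    stopf("numerical source '%s' needs >= 3 samples", name)
  structure(list(name = name, profiles = profiles),
            class = "numerical_source")
}

#' Construct an embedding source
#'
#' @param name source name.
#' @param vectors numeric matrix, one row per gene (rownames), uniform
#'   dimension (e.g. 100-dimensional word embeddings of gene names).
#' @return Object of class \code{embedding_source}.
#' @export
embedding_source <- function(name, vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (all(abs(vectors) < .Machine$double.eps))
    stopf("embedding source '%s' is all zero", name)
  structure(list(name = name, vectors = vectors),
            class = "embedding_source")
}

#' Drop rarely annotated terms from a categorical source
#'
#' Removes every term annotating fewer than \code{min_genes} genes;
#' annotation-source terms carried by only a handful of genes contribute
#' noise-level features, so the default keeps terms with at least 10
#' annotated genes.
#'
#' @param source a \code{categorical_source}.
#' @param min_genes threshold (defaults to the source's own).
#' @return The filtered \code{categorical_source}.
#' @export
filter_terms <- function(source, min_genes = source$min_genes) {
  stopifnot(inherits(source, "categorical_source"))
  all_terms <- unlist(source$annotations, use.names = FALSE)
  counts <- table(all_terms)
  keep <- names(counts)[counts >= min_genes]
  ann <- lapply(source$annotations, function(ts) ts[ts %in% keep])
  ann <- ann[vapply(ann, length, integer(1)) > 0]
  categorical_source(source$name, ann, min_genes)
}

#' Convert sparse-dictionary loadings to a categorical source
#'
#' A gene is annotated with an inferred function iff the absolute loading
#' strictly exceeds \code{threshold} (default 0.1); weaker loadings are
#' treated as no association in either direction.
#'
#' @param loadings data.frame with columns \code{gene}, \code{term} (the
#'   inferred function) and \code{loading}.
#' @param threshold strict absolute-loading cutoff (default 0.1).
#' @param name source name (default \code{"essentiality_functions"}).
#' @param min_genes retained-term threshold forwarded to the source.
#' @return Object of class \code{categorical_source}.
#' @export
webster_to_categorical <- function(loadings, threshold = 0.1,
                                   name = "essentiality_functions",
                                   min_genes = 10) {
  stopifnot(all(c("gene", "term", "loading") %in% names(loadings)))
  keep <- abs(loadings$loading) > threshold
  categorical_source(name, loadings[keep, c("gene", "term")], min_genes)
}

#' Encode one categorical term for an ordered gene pair
#'
#' @param gene_prev,gene_next the ordered pair's gene symbols.
#' @param term a term id retained in \code{source}.
#' @param source a \code{categorical_source}.
#' @return Named numeric triple \code{(both, prev_only, next_only)}:
#'   \code{(1,0,0)} when both genes carry the term, \code{(0,1,0)} when only
#'   \code{gene_prev} does, \code{(0,0,1)} when only \code{gene_next} does,
#'   \code{(0,0,0)} when neither does.
#' @export
encode_categorical <- function(gene_prev, gene_next, term, source) {
  p <- term %in% source$annotations[[gene_prev]]
  n <- term %in% source$annotations[[gene_next]]
  c(both = as.numeric(p && n), prev_only = as.numeric(p && !n),
    next_only = as.numeric(!p && n))
}

#' Encode a numerical source for a gene pair as a Pearson correlation
#'
#' Pearson correlation of the two genes' profiles over pairwise-complete
#' samples; 0 when either gene is missing from the source, fewer than 3
#' complete sample pairs remain, or either profile has zero variance
#' (0 is the no-evidence point of the encoding).
#'
#' @param gene_prev,gene_next gene symbols.
#' @param source a \code{numerical_source}.
#' @return Correlation in \[-1, 1\].
#' @export
encode_numerical <- function(gene_prev, gene_next, source) {
  P <- source$profiles
  if (!(gene_prev %in% rownames(P)) || !(gene_next %in% rownames(P)))
    return(0)
  x <- P[gene_prev, ]; y <- P[gene_next, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(0)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Encode an embedding source for a gene pair as a cosine similarity
#'
#' @param gene_prev,gene_next gene symbols.
#' @param source an \code{embedding_source}.
#' @return Cosine similarity in \[-1, 1\]; 0 when either gene is missing or
#'   has a zero-norm vector.
#' @export
encode_embedding <- function(gene_prev, gene_next, source) {
  E <- source$vectors
  if (!(gene_prev %in% rownames(E)) || !(gene_next %in% rownames(E)))
    return(0)
  u <- E[gene_prev, ]; v <- E[gene_next, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Freeze the feature layout of a set of sources
#'
#' Column order is deterministic: categorical sources in declared order with
#' their retained terms in lexicographic order (3 slots per term: both,
#' prev_only, next_only), then numerical sources, then embedding sources
#' (1 slot each). The total dimension is \code{3*T + N_num + N_emb}. The
#' term vocabulary is frozen here, at training time; terms unseen at
#' inference are ignored.
#'
#' @param sources list of \code{categorical_source}, \code{numerical_source}
#'   and \code{embedding_source} objects (any mix, any order).
#' @return Object of class \code{feature_schema}: list with \code{columns}
#'   (data.frame \code{source}, \code{kind}, \code{term}, \code{slot}),
#'   \code{dimension} and \code{source_kinds}.
#' @export
build_schema <- function(sources) {
  nm <- vapply(sources, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stopf("duplicate source names: %s",
                               paste(nm[duplicated(nm)], collapse = ", "))
  kind_of <- function(s)
    if (inherits(s, "categorical_source")) "categorical"
    else if (inherits(s, "numerical_source")) "numerical"
    else if (inherits(s, "embedding_source")) "embedding"
    else stopf("unknown source class")
  kinds <- vapply(sources, kind_of, character(1))
  cols <- list()
  for (i in which(kinds == "categorical")) {
    terms <- sort(unique(unlist(sources[[i]]$annotations, use.names = FALSE)))
    if (length(terms))
      cols[[length(cols) + 1L]] <- data.frame(
        source = nm[i], kind = "categorical",
        term = rep(terms, each = 3),
        slot = rep(c("both", "prev_only", "next_only"), length(terms)),
        stringsAsFactors = FALSE)
  }
  for (i in which(kinds == "numerical"))
    cols[[length(cols) + 1L]] <- data.frame(
      source = nm[i], kind = "numerical", term = "pearson", slot = "value",
      stringsAsFactors = FALSE)
  for (i in which(kinds == "embedding"))
    cols[[length(cols) + 1L]] <- data.frame(
      source = nm[i], kind = "embedding", term = "cosine", slot = "value",
      stringsAsFactors = FALSE)
  columns <- if (length(cols)) do.call(rbind, cols)
             else data.frame(source = character(0), kind = character(0),
                             term = character(0), slot = character(0),
                             stringsAsFactors = FALSE)
  if (!nrow(columns)) warnf("feature schema has dimension 0")
  structure(list(columns = columns, dimension = nrow(columns),
                 source_kinds = stats::setNames(kinds, nm)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  ncat <- sum(x$source_kinds == "categorical")
  nterm <- sum(x$columns$kind == "categorical") / 3
  cat(sprintf(
    "Feature schema: %d columns (3 x %d categorical terms over %d sources, %d numerical, %d embedding)\n",
    x$dimension, nterm, ncat, sum(x$source_kinds == "numerical"),
    sum(x$source_kinds == "embedding")))
  invisible(x)
}

schema_colnames <- function(schema) {
  with(schema$columns, paste(source, term, slot, sep = "|"))
}

#' Persist and restore a feature schema as JSON
#'
#' @param schema a \code{feature_schema}.
#' @param path file path.
#' @return \code{read_schema} returns the restored \code{feature_schema}.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(list(columns = schema$columns,
                            source_kinds = as.list(schema$source_kinds)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(columns = obj$columns, dimension = nrow(obj$columns),
                 source_kinds = unlist(obj$source_kinds)),
            class = "feature_schema")
}

#' Encode ordered gene pairs as a feature matrix
#'
#' One row per pair, columns aligned to the schema. Categorical slots follow
#' the (both, prev_only, next_only) triplet rule; numerical slots are
#' Pearson correlations and embedding slots cosine similarities. A gene
#' absent from every source yields an all-zero row (warned once).
#'
#' @param pairs data.frame with columns \code{gene_prev}, \code{gene_next}.
#' @param schema a \code{feature_schema} built from \code{sources}.
#' @param sources the source list the schema was built from (sources may
#'   carry annotations for terms outside the schema vocabulary; those are
#'   ignored).
#' @return Numeric matrix \code{nrow(pairs) x schema$dimension} with
#'   schema-derived column names.
#' @export
featurize <- function(pairs, schema, sources) {
  stopifnot(inherits(schema, "feature_schema"))
  nm <- vapply(sources, function(s) s$name, character(1))
  missing_src <- setdiff(names(schema$source_kinds), nm)
  if (length(missing_src))
    stopf("sources missing for schema: %s", paste(missing_src, collapse = ", "))
  n <- nrow(pairs)
  X <- matrix(0, nrow = n, ncol = schema$dimension,
              dimnames = list(NULL, schema_colnames(schema)))
  if (!n || !schema$dimension) {
    check_orphans(pairs, sources)
    return(X)
  }
  cols <- schema$columns
  for (src in names(schema$source_kinds)) {
    s <- sources[[match(src, nm)]]
    kind <- schema$source_kinds[[src]]
    ci <- which(cols$source == src)
    if (!length(ci)) next
    if (kind == "categorical") {
      terms <- unique(cols$term[ci])
      genes <- union(pairs$gene_prev, pairs$gene_next)
      M <- matrix(FALSE, length(genes), length(terms),
                  dimnames = list(genes, terms))
      for (g in intersect(genes, names(s$annotations))) {
        ts <- intersect(s$annotations[[g]], terms)
        if (length(ts)) M[g, ts] <- TRUE
      }
      bp <- M[pairs$gene_prev, , drop = FALSE]
      bn <- M[pairs$gene_next, , drop = FALSE]
      vals <- cbind(both = bp & bn, prev = bp & !bn, nxt = !bp & bn)
      # interleave into (both, prev_only, next_only) per term
      Tn <- length(terms)
      ord <- as.vector(rbind(seq_len(Tn), Tn + seq_len(Tn), 2 * Tn + seq_len(Tn)))
      X[, ci] <- vals[, ord, drop = FALSE] + 0
    } else if (kind == "numerical") {
      X[, ci] <- pair_pearson(pairs, s)
    } else {
      X[, ci] <- pair_cosine(pairs, s)
    }
  }
  check_orphans(pairs, sources)
  X
}

check_orphans <- function(pairs, sources) {
  genes <- union(pairs$gene_prev, pairs$gene_next)
  known <- unique(unlist(lapply(sources, function(s) {
    if (inherits(s, "categorical_source")) names(s$annotations)
    else if (inherits(s, "numerical_source")) rownames(s$profiles)
    else rownames(s$vectors)
  })))
  orphans <- setdiff(genes, known)
  if (length(orphans))
    warnf("%d gene(s) absent from every source encode as all-zero rows",
          length(orphans))
  invisible(NULL)
}

# vectorized rowwise Pearson for all pairs against one numerical source
pair_pearson <- function(pairs, source) {
  P <- source$profiles
  n <- nrow(pairs)
  out <- numeric(n)
  has <- pairs$gene_prev %in% rownames(P) & pairs$gene_next %in% rownames(P)
  if (!any(has)) return(out)
  if (!anyNA(P)) {
    m <- ncol(P)
    Z <- P - rowMeans(P)
    sds <- sqrt(rowSums(Z^2) / (m - 1))
    Z <- Z / ifelse(sds == 0, Inf, sds)   # zero-variance rows -> all-zero
    r <- rowSums(Z[pairs$gene_prev[has], , drop = FALSE] *
                 Z[pairs$gene_next[has], , drop = FALSE]) / (m - 1)
    out[has] <- r
  } else {
    out[has] <- vapply(which(has), function(i)
      encode_numerical(pairs$gene_prev[i], pairs$gene_next[i], source),
      numeric(1))
  }
  out
}

pair_cosine <- function(pairs, source) {
  E <- source$vectors
  n <- nrow(pairs)
  out <- numeric(n)
  has <- pairs$gene_prev %in% rownames(E) & pairs$gene_next %in% rownames(E)
  if (!any(has)) return(out)
  nrm <- sqrt(rowSums(E^2))
  En <- E / ifelse(nrm == 0, Inf, nrm)
  out[has] <- rowSums(En[pairs$gene_prev[has], , drop = FALSE] *
                      En[pairs$gene_next[has], , drop = FALSE])
  out
}
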