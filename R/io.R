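# Readers and writers for the tool's plain-text exchange formats:
# TSV tables (genes, methods, annotations, profiles, embeddings, networks,
# pairs, experiment lists), JSONL corpora and JSON feature schemas.

read_tsv_base <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_base <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read and write the gene nomenclature table
#'
#' TSV with columns \code{symbol}, \code{aliases} (pipe-separated),
#' \code{locus_group}, \code{location} (chromosome arm such as \code{17p}).
#'
#' @param path file path.
#' @return data.frame gene table.
#' @export
read_gene_table <- function(path) {
  g <- read_tsv_base(path, colClasses = "character")
  g$aliases[is.na(g$aliases)] <- ""
  g$location[is.na(g$location)] <- ""
  validate_gene_table(g)
  g
}

#' @rdname read_gene_table
#' @param genes data.frame gene table.
#' @export
write_gene_table <- function(genes, path) write_tsv_base(genes, path)

#' Read and write the experiment-method term table
#'
#' TSV with columns \code{term} and \code{category} (one of the 20 closed
#' method categories, see \code{\link{method_categories}}).
#'
#' @param path file path.
#' @return data.frame with columns \code{term}, \code{category}.
#' @export
read_method_table <- function(path) read_tsv_base(path, colClasses = "character")

#' @rdname read_method_table
#' @param methods data.frame method table.
#' @export
write_method_table <- function(methods, path) write_tsv_base(methods, path)

#' Read and write a JSONL corpus
#'
#' One JSON record per line: \code{\{"article_id": ..., "year": ...,
#' "sentences": [...]\}} with sentences in document order.
#'
#' @param path file path.
#' @return List of article records (lists with \code{article_id},
#'   \code{year}, \code{sentences}).
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    list(article_id = as.character(rec$article_id),
         year = as.integer(rec$year),
         sentences = as.character(rec$sentences))
  })
}

#' @rdname read_corpus
#' @param articles list of article records.
#' @export
write_corpus <- function(articles, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (a in articles)
    writeLines(jsonlite::toJSON(
      list(article_id = a$article_id, year = a$year,
           sentences = a$sentences),
      auto_unbox = TRUE), con)
  invisible(path)
}

#' Read and write experiment lists
#'
#' TSV with columns \code{article_id}, \code{year}, \code{sentence_index},
#' \code{order_index}, \code{gene}, \code{method}, \code{score}.
#'
#' @param path file path.
#' @return data.frame of experiment mentions.
#' @export
read_experiments <- function(path) read_tsv_base(path)

#' @rdname read_experiments
#' @param mentions data.frame of experiment mentions.
#' @export
write_experiments <- function(mentions, path) write_tsv_base(mentions, path)

#' Read and write experiment-pair tables
#'
#' TSV with columns \code{gene_prev}, \code{gene_next}, \code{article_id},
#' \code{year}, \code{label} (1 = observed consecutive pair, 0 = sampled
#' negative).
#'
#' @param path file path.
#' @return data.frame of pairs.
#' @export
read_pairs <- function(path) read_tsv_base(path)

#' @rdname read_pairs
#' @param pairs data.frame of pairs.
#' @export
write_pairs <- function(pairs, path) write_tsv_base(pairs, path)

#' Read a gene annotation table
#'
#' TSV with columns \code{gene}, \code{term}, \code{source}; one row per
#' annotation.
#'
#' @param path file path.
#' @return data.frame with columns \code{gene}, \code{term}, \code{source}.
#' @export
read_annotations <- function(path) read_tsv_base(path, colClasses = "character")

#' @rdname read_annotations
#' @param annotations data.frame of annotations.
#' @export
write_annotations <- function(annotations, path)
  write_tsv_base(annotations, path)

#' Read a numerical profile matrix
#'
#' TSV whose first column is the gene symbol and whose remaining columns are
#' samples (TPM-like or essentiality-like values on a shared sample axis).
#'
#' @param path file path.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_profiles <- function(path) {
  d <- read_tsv_base(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d[[1]]
  m
}

#' @rdname read_profiles
#' @param profiles numeric matrix with gene rownames.
#' @export
write_profiles <- function(profiles, path) {
  d <- data.frame(gene = rownames(profiles), profiles, check.names = FALSE)
  write_tsv_base(d, path)
}

#' Read a gene embedding table
#'
#' TSV: gene symbol followed by the embedding coordinates (default 100
#' dimensions).
#'
#' @param path file path.
#' @return Numeric matrix, genes in rows.
#' @export
read_embeddings <- function(path) read_profiles(path)

#' @rdname read_embeddings
#' @param embeddings numeric matrix with gene rownames.
#' @export
write_embeddings <- function(embeddings, path)
  write_profiles(embeddings, path)

#' Read and write a weighted gene-network edge list
#'
#' TSV with columns \code{geneA}, \code{geneB}, \code{weight}; edges are
#' undirected, weights non-negative and finite, no self-loops.
#'
#' @param path file path.
#' @param name network name attached to the result.
#' @return Object of class \code{gene_network} (see
#'   \code{\link{gene_network}}).
#' @export
read_network <- function(path, name = basename(path)) {
  e <- read_tsv_base(path)
  gene_network(e, name = name)
}

#' @rdname read_network
#' @param network a \code{gene_network}.
#' @export
write_network <- function(network, path)
  write_tsv_base(network$edges, path)
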