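# Synthetic fixture world with planted functional modules: gene table,
# annotation/profile/embedding/network sources and a templated corpus of
# articles with ordered experiment sentences, so the full pipeline runs
# end to end with no external data.

#' Configuration of the synthetic world
#'
#' Defaults define the standard study conditions of the package's
#' end-to-end experiments: 300 genes in 15 functional modules, 400 articles
#' of 3-8 experiments whose narratives stay within the article's home
#' module with probability 0.9, two categorical annotation sources plus a
#' chromosome-arm source and a loading-derived source, two numerical
#' profile sources, one 100-dimensional embedding source and one weighted
#' network.
#'
#' @param n_genes number of genes (default 300).
#' @param n_modules number of functional modules (default 15).
#' @param n_articles number of articles (default 400).
#' @param experiments_per_article integer range, experiments per article
#'   (default 3:8).
#' @param within_module_prob probability the next experiment's gene stays
#'   in the article's home module (default 0.9).
#' @param terms_per_module terms owned by each module in each categorical
#'   source (default 5).
#' @param terms_shared_frac probability a module member carries each module
#'   term (default 0.9).
#' @param annotation_noise probability a non-member carries a module term
#'   (default 0.02).
#' @param profile_length samples per numerical profile (default 50).
#' @param module_correlation expected within-module profile correlation;
#'   sets the latent/noise variance ratio (default 0.8).
#' @param embedding_dim embedding dimension (default 100).
#' @param embedding_noise_sd isotropic noise around the module centroid
#'   (default 0.6).
#' @param within_edge_prob,between_edge_prob network edge densities inside
#'   and between modules (defaults 0.3 and 0.01).
#' @param year_range publication years (default 2015:2022).
#' @param prop_coding fraction of protein-coding genes (default 0.95).
#' @param favored_method_prob probability an experiment uses the module's
#'   favored method category (default 0.7).
#' @param seed integer seed; all randomness flows from it (default 0).
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 300, n_modules = 15, n_articles = 400,
                       experiments_per_article = 3:8,
                       within_module_prob = 0.9,
                       terms_per_module = 5, terms_shared_frac = 0.9,
                       annotation_noise = 0.02,
                       profile_length = 50, module_correlation = 0.8,
                       embedding_dim = 100, embedding_noise_sd = 0.6,
                       within_edge_prob = 0.3, between_edge_prob = 0.01,
                       year_range = 2015:2022, prop_coding = 0.95,
                       favored_method_prob = 0.7, seed = 0) {
  if (n_modules > n_genes) stopf("n_modules must be <= n_genes")
  if (!length(experiments_per_article) || min(experiments_per_article) < 1)
    stopf("experiments_per_article range is empty or invalid")
  probs <- c(within_module_prob, terms_shared_frac, annotation_noise,
             module_correlation, within_edge_prob, between_edge_prob,
             prop_coding, favored_method_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must be in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

#' Built-in experiment-method term table
#'
#' One or two surface terms per method category, chosen so that the
#' templated synthetic sentences are matched exactly by dictionary lookup.
#'
#' @return data.frame with columns \code{term}, \code{category}.
#' @export
default_method_table <- function() {
  data.frame(term = c(
    "knockdown", "knockout", "overexpression", "immunofluorescence",
    "immunostaining", "co-immunoprecipitation", "yeast two-hybrid",
    "quantitative PCR", "RT-PCR", "bioinformatic analysis",
    "immunohistochemistry", "RNA sequencing", "whole-exome sequencing",
    "rescue experiment", "crystallography",
    "fluorescence in situ hybridization", "CRISPR screening",
    "mass spectrometry", "super-resolution microscopy",
    "electron microscopy", "genome-wide association study",
    "live-cell imaging", "X-ray scattering", "circular dichroism",
    "reporter assay"),
    category = c(
      "knockdown/knockout", "knockdown/knockout", "overexpression",
      "immunofluorescence", "immunofluorescence",
      "protein-protein interaction", "protein-protein interaction",
      "RT-PCR or qPCR", "RT-PCR or qPCR", "bioinformatics",
      "immunohistochemistry", "next generation sequencing",
      "next generation sequencing", "rescue experiment",
      "protein structure", "FISH", "screening", "mass spectrometry",
      "super-resolution microscopy", "electron microscopy", "GWAS",
      "live-imaging", "Xray-flattering", "circular dichroism", "others"),
    stringsAsFactors = FALSE)
}

sentence_templates <- function() {
  c("%s of %s altered the phenotype.",
    "We performed %s of %s.",
    "%s of %s confirmed this effect.",
    "Next, %s of %s produced a comparable result.")
}

#' Generate a synthetic world with planted functional modules
#'
#' Genes are partitioned into modules; each module owns term sets in every
#' categorical source (carried by members with probability
#' \code{terms_shared_frac}, leaked to non-members at
#' \code{annotation_noise}), a latent numerical profile (members = latent +
#' Gaussian noise at the variance ratio implied by
#' \code{module_correlation}), an embedding centroid, dense within-module
#' network edges and a favored experiment-method category. Articles pick a
#' home module and emit an ordered experiment narrative that stays
#' in-module with probability \code{within_module_prob}, rendered as
#' templated sentences that the dictionary matcher resolves exactly.
#'
#' @param config a \code{sim_config}.
#' @return Object of class \code{sim_world}: list with \code{config},
#'   \code{genes} (gene table), \code{methods} (method table),
#'   \code{annotations}, \code{loadings}, \code{profiles} (named list of
#'   matrices), \code{embeddings}, \code{network}, \code{corpus} and the
#'   withheld \code{truth} (module map, per-article gene/method log,
#'   favored categories).
#' @export
generate_world <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    symbols <- sprintf("GS%03d", seq_len(cf$n_genes))
    module_of <- stats::setNames(
      sample(rep(seq_len(cf$n_modules), length.out = cf$n_genes)), symbols)
    mod_genes <- split(symbols, module_of)

    # gene table: aliases for ~30% of genes, mostly protein-coding,
    # module-biased chromosome arms
    arms_pool <- paste0(rep(1:11, each = 2), c("p", "q"))
    home_arm <- sample(arms_pool, cf$n_modules, replace = TRUE)
    has_alias <- stats::runif(cf$n_genes) < 0.3
    aliases <- ifelse(has_alias, paste0(symbols, "L"), "")
    coding <- stats::runif(cf$n_genes) < cf$prop_coding
    arm <- ifelse(stats::runif(cf$n_genes) < 0.8,
                  home_arm[module_of], sample(arms_pool, cf$n_genes,
                                              replace = TRUE))
    genes <- data.frame(
      symbol = symbols, aliases = aliases,
      locus_group = ifelse(coding, "protein-coding gene", "non-coding RNA"),
      location = arm, stringsAsFactors = FALSE)

    # categorical annotation sources
    make_annotations <- function(prefix) {
      rows <- list()
      for (m in seq_len(cf$n_modules)) {
        terms <- sprintf("%s:M%02d:T%d", prefix, m,
                         seq_len(cf$terms_per_module))
        for (tm in terms) {
          member <- symbols[module_of == m]
          other <- symbols[module_of != m]
          carriers <- c(
            member[stats::runif(length(member)) < cf$terms_shared_frac],
            other[stats::runif(length(other)) < cf$annotation_noise])
          if (length(carriers))
            rows[[length(rows) + 1L]] <- data.frame(
              gene = carriers, term = tm, source = prefix,
              stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    }
    annotations <- rbind(make_annotations("go_like"),
                         make_annotations("pheno_like"))

    # loading matrix: members load on their module's inferred function
    loadings <- do.call(rbind, lapply(seq_len(cf$n_modules), function(m) {
      member <- symbols[module_of == m]
      rbind(
        data.frame(gene = member, term = sprintf("F%02d", m),
                   loading = stats::rnorm(length(member), 0.5, 0.2),
                   stringsAsFactors = FALSE),
        data.frame(gene = symbols, term = sprintf("F%02d", m),
                   loading = stats::rnorm(cf$n_genes, 0, 0.03),
                   stringsAsFactors = FALSE))
    }))

    # numerical profiles: latent module profile + noise
    noise_sd <- sqrt((1 - cf$module_correlation) / cf$module_correlation)
    make_profiles <- function(center) {
      latent <- matrix(stats::rnorm(cf$n_modules * cf$profile_length),
                       cf$n_modules)
      P <- latent[module_of, , drop = FALSE] +
        matrix(stats::rnorm(cf$n_genes * cf$profile_length, 0, noise_sd),
               cf$n_genes)
      P <- P + center
      rownames(P) <- symbols
      colnames(P) <- sprintf("S%03d", seq_len(cf$profile_length))
      round(P, 6)
    }
    profiles <- list(expression_cancer = make_profiles(6),
                     essentiality_cancer = make_profiles(0))

    # embeddings: module centroid + isotropic noise
    centroids <- matrix(stats::rnorm(cf$n_modules * cf$embedding_dim),
                        cf$n_modules)
    embeddings <- centroids[module_of, , drop = FALSE] +
      matrix(stats::rnorm(cf$n_genes * cf$embedding_dim, 0,
                          cf$embedding_noise_sd), cf$n_genes)
    rownames(embeddings) <- symbols
    colnames(embeddings) <- sprintf("d%03d", seq_len(cf$embedding_dim))
    embeddings <- round(embeddings, 6)

    # network: dense within modules, sparse between
    idx <- utils::combn(cf$n_genes, 2)
    same <- module_of[idx[1, ]] == module_of[idx[2, ]]
    keep <- stats::runif(ncol(idx)) <
      ifelse(same, cf$within_edge_prob, cf$between_edge_prob)
    w <- ifelse(same[keep], stats::runif(sum(keep), 0.5, 1),
                stats::runif(sum(keep), 0.05, 0.3))
    network <- gene_network(
      data.frame(geneA = symbols[idx[1, keep]],
                 geneB = symbols[idx[2, keep]],
                 weight = round(w, 6), stringsAsFactors = FALSE),
      name = "synthetic_coupling", nodes = symbols)

    # corpus: per-article ordered experiment narrative
    methods <- default_method_table()
    cats <- method_categories()
    favored <- stats::setNames(sample(cats, cf$n_modules, replace = TRUE),
                               seq_len(cf$n_modules))
    templates <- sentence_templates()
    articles <- vector("list", cf$n_articles)
    log <- vector("list", cf$n_articles)
    for (i in seq_len(cf$n_articles)) {
      home <- sample.int(cf$n_modules, 1)
      n_exp <- sample(cf$experiments_per_article, 1)
      gs <- character(n_exp)
      gs[1] <- sample(mod_genes[[as.character(home)]], 1)
      for (j in seq_len(n_exp)[-1]) {
        gs[j] <- if (stats::runif(1) < cf$within_module_prob)
          sample(mod_genes[[as.character(home)]], 1) else sample(symbols, 1)
      }
      cat_j <- ifelse(stats::runif(n_exp) < cf$favored_method_prob,
                      favored[home], sample(cats, n_exp, replace = TRUE))
      term_j <- vapply(cat_j, function(cc) {
        pool <- methods$term[methods$category == cc]
        if (!length(pool)) pool <- methods$term
        sample(pool, 1)
      }, character(1))
      sent <- vapply(seq_len(n_exp), function(j)
        sprintf(sample(templates, 1), term_j[j], gs[j]), character(1))
      aid <- sprintf("A%04d", i)
      articles[[i]] <- list(article_id = aid,
                            year = sample(cf$year_range, 1),
                            sentences = sent)
      log[[i]] <- data.frame(article_id = aid,
                             year = articles[[i]]$year,
                             position = seq_len(n_exp) - 1L,
                             gene = gs, method = term_j,
                             category = unname(cat_j),
                             home_module = home,
                             stringsAsFactors = FALSE)
    }

    structure(list(
      config = cf, genes = genes, methods = methods,
      annotations = annotations, loadings = loadings,
      profiles = profiles, embeddings = embeddings, network = network,
      corpus = articles,
      truth = list(module_of = module_of,
                   favored_category = favored,
                   experiment_log = do.call(rbind, log))),
      class = "sim_world")
  })
}

#' @export
print.sim_world <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "Synthetic world: %d genes in %d modules, %d articles (%d-%d experiments each), seed %d\n",
    cf$n_genes, cf$n_modules, cf$n_articles,
    min(cf$experiments_per_article), max(cf$experiments_per_article),
    cf$seed))
  invisible(x)
}

#' Exact census of different-gene consecutive pairs
#'
#' Reads the generator's own experiment log (not the rendered corpus) and
#' returns every adjacent different-gene pair per article — the ground
#' truth that extraction plus pair building must reproduce.
#'
#' @param world a \code{sim_world}.
#' @return data.frame in the \code{\link{build_pairs}} layout (label 1).
#' @export
ground_truth_pairs <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  log <- world$truth$experiment_log
  if (is.null(log) || !nrow(log)) return(empty_pairs())
  mentions <- data.frame(article_id = log$article_id, year = log$year,
                         sentence_index = log$position,
                         order_index = log$position, gene = log$gene,
                         method = log$method, score = 1,
                         stringsAsFactors = FALSE)
  build_pairs(mentions)
}

#' Write every world file to a directory
#'
#' Emits the gene table, method table, annotations, loading table, one
#' profile matrix per numerical source, embeddings, network edge list and
#' the JSONL corpus, plus \code{truth.json} (module map and experiment
#' log — withheld from models, used only for checks).
#'
#' @param world a \code{sim_world}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "sim_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gene_table(world$genes, p("genes.tsv"))
  write_method_table(world$methods, p("methods.tsv"))
  write_annotations(world$annotations, p("annotations.tsv"))
  write_tsv_base(world$loadings, p("loadings.tsv"))
  for (nm in names(world$profiles))
    write_profiles(world$profiles[[nm]], p(paste0("profiles_", nm, ".tsv")))
  write_embeddings(world$embeddings, p("embeddings.tsv"))
  write_network(world$network, p("network.tsv"))
  write_corpus(world$corpus, p("corpus.jsonl"))
  jsonlite::write_json(
    list(module_of = as.list(world$truth$module_of),
         favored_category = as.list(world$truth$favored_category),
         experiment_log = world$truth$experiment_log),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c("genes.tsv", "methods.tsv", "annotations.tsv", "loadings.tsv",
             paste0("profiles_", names(world$profiles), ".tsv"),
             "embeddings.tsv", "network.tsv", "corpus.jsonl", "truth.json")
  invisible(stats::setNames(file.path(dir, files), files))
}

#' Chromosome-arm categorical source from a gene table
#'
#' Encodes shared chromosome location: each arm (e.g. \code{17p}) is a
#' term annotating the genes located on it.
#'
#' @param genes data.frame gene table.
#' @param min_genes retained-term threshold (default 10).
#' @return A \code{categorical_source} named \code{"chromosome_arm"}.
#' @export
arm_source <- function(genes, min_genes = 10) {
  keep <- nzchar(genes$location)
  categorical_source("chromosome_arm",
                     data.frame(gene = genes$symbol[keep],
                                term = genes$location[keep],
                                stringsAsFactors = FALSE),
                     min_genes)
}

#' Assemble the feature sources of a world
#'
#' Builds the full source list used by the end-to-end experiments: the two
#' generated categorical annotation sources, the chromosome-arm source, the
#' loading-derived source (strict |loading| > \code{webster_threshold}),
#' the two numerical profile sources and the embedding source — each
#' categorical source filtered to terms with at least \code{min_genes}
#' annotated genes.
#'
#' @param world a \code{sim_world}.
#' @param min_genes categorical term threshold (default 10).
#' @param webster_threshold loading cutoff (default 0.1).
#' @return List of source objects, ready for \code{\link{build_schema}}.
#' @export
world_sources <- function(world, min_genes = 10, webster_threshold = 0.1) {
  stopifnot(inherits(world, "sim_world"))
  ann <- world$annotations
  srcs <- list()
  for (nm in unique(ann$source))
    srcs[[length(srcs) + 1L]] <- filter_terms(categorical_source(
      nm, ann[ann$source == nm, c("gene", "term")], min_genes))
  srcs[[length(srcs) + 1L]] <- filter_terms(arm_source(world$genes,
                                                       min_genes))
  srcs[[length(srcs) + 1L]] <- filter_terms(webster_to_categorical(
    world$loadings, threshold = webster_threshold, min_genes = min_genes))
  for (nm in names(world$profiles))
    srcs[[length(srcs) + 1L]] <- numerical_source(nm, world$profiles[[nm]])
  srcs[[length(srcs) + 1L]] <- embedding_source("gene_embedding",
                                                world$embeddings)
  srcs
}
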