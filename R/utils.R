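#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' The closed set of experiment-method categories
#'
#' Twenty method-category labels used for method prediction, in the fixed
#' order that also breaks prediction ties.
#'
#' @return Character vector of length 20.
#' @export
method_categories <- function() {
  c("knockdown/knockout", "overexpression", "immunofluorescence",
    "protein-protein interaction", "RT-PCR or qPCR", "bioinformatics",
    "immunohistochemistry", "next generation sequencing",
    "rescue experiment", "protein structure", "FISH", "screening",
    "mass spectrometry", "super-resolution microscopy",
    "electron microscopy", "GWAS", "live-imaging", "Xray-flattering",
    "circular dichroism", "others")
}
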