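#' Build a bag-of-words corpus from a region-TF count matrix
#'
#' Document d contains `count(d, w)` copies of token w, ordered by factor
#' index, so the corpus is a deterministic function of the matrix.
#'
#' @param m region-TF count matrix (regions x factors) or a
#'   `cobinding_regions` object.
#' @return a `tf_corpus`: list with `documents` (integer token vectors,
#'   1-based vocabulary indices), `vocabulary`, and `ids` (region ids).
#' @export
corpus_from_matrix <- function(m) {
  if (inherits(m, "cobinding_regions")) m <- build_region_tf_matrix(m)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers")
  }
  nz <- rowSums(m) > 0
  if (any(!nz)) {
    warning(sum(!nz), " all-zero row(s) excluded from the corpus")
    m <- m[nz, , drop = FALSE]
  }
  docs <- lapply(seq_len(nrow(m)), function(d) {
    rep(seq_len(ncol(m)), times = m[d, ])
  })
  structure(list(documents = docs, vocabulary = colnames(m),
                 ids = rownames(m)),
            class = "tf_corpus")
}

#' @export
print.tf_corpus <- function(x, ...) {
  cat("corpus:", length(x$documents), "documents,",
      sum(lengths(x$documents)), "tokens,",
      length(x$vocabulary), "vocabulary terms\n")
  invisible(x)
}

#' Fit the hierarchical Dirichlet process topic model
#'
#' Direct-assignment collapsed Gibbs sampling; the number of modules
#' (topics) is inferred from the data.  The document-level and top-level
#' concentration parameters are resampled every sweep under vague
#' Gamma(1, 1) priors.  The run executes exactly `max_iter` sweeps (no
#' early stopping) and returns the final state.
#'
#' @param corpus a `tf_corpus` from [corpus_from_matrix()].
#' @param eta symmetric Dirichlet hyperparameter of the module-over-factor
#'   distributions.  Small values (default 0.1) encode the assumption that
#'   each module involves only a few factors; values between 0.01 and 1
#'   give similar module structure.
#' @param max_iter number of Gibbs sweeps (default 2000; mixing is
#'   typically reached by about half that).
#' @param seed integer seed; runs are fully reproducible given the seed.
#' @param alpha_prior,gamma_prior shape/rate of the Gamma priors on the
#'   document-level and top-level concentrations.
#' @param alpha0,gamma optionally fix the respective concentration at this
#'   value instead of resampling it (default `NA`: resample each sweep).
#' @param init_topics number of seed topics for the initialization
#'   (default 1: start compact and let the sampler grow the topic count).
#'   Values > 1 spread tokens uniformly over that many seed topics, a
#'   dispersed start that explores finely split solutions; surplus topics
#'   are pruned as they empty.  Single chains mix slowly between coarse
#'   and fine modes, which is why [fit_hdp_multistart()] runs both kinds
#'   of start and lets the likelihood arbitrate.
#' @return an `hdp_state`: list with `z` (1-based topic of every token in
#'   document order), `K`, `n_kw` (topic x word counts), `beta`, `alpha0`,
#'   `gamma`, `loglik` (per-sweep joint collapsed log-likelihood), `eta`,
#'   `seed`.
#' @export
fit_hdp <- function(corpus, eta = 0.1, max_iter = 2000L, seed = 1L,
                    alpha_prior = c(1, 1), gamma_prior = c(1, 1),
                    alpha0 = NA, gamma = NA, init_topics = 1L) {
  if (length(corpus$documents) == 0) stop("empty corpus")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (eta <= 0) stop("eta must be > 0")
  doc <- rep(seq_along(corpus$documents) - 1L, lengths(corpus$documents))
  word <- unlist(corpus$documents, use.names = FALSE) - 1L
  set.seed(as.integer(seed))
  res <- hdp_gibbs_cpp(doc, word, length(corpus$documents),
                       length(corpus$vocabulary), eta,
                       as.integer(max_iter),
                       alpha_prior[1], alpha_prior[2],
                       gamma_prior[1], gamma_prior[2],
                       as.numeric(alpha0), as.numeric(gamma),
                       as.integer(init_topics))
  res$eta <- eta
  res$seed <- as.integer(seed)
  res$max_iter <- as.integer(max_iter)
  colnames(res$n_kw) <- corpus$vocabulary
  class(res) <- "hdp_state"
  res
}

#' @export
print.hdp_state <- function(x, ...) {
  cat("HDP state: K =", x$K, "modules,",
      length(x$z), "tokens, final log-likelihood",
      format(x$loglik[length(x$loglik)], digits = 8),
      "(seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Fit the HDP from several seeds and keep the best run
#'
#' Each seed is run once per initialization scheme (by default a compact
#' single-topic start and a dispersed 20-topic start, which bracket the
#' coarse and fine posterior modes a single Gibbs chain mixes between
#' only very slowly); the state with the highest final joint collapsed
#' log-likelihood is returned.  All runs' likelihood traces are attached.
#'
#' @inheritParams fit_hdp
#' @param seeds integer vector of seeds (default `c(1, 2, 3)`).
#' @param init_topics initializations to pair with every seed (default
#'   `c(1, 20)`).
#' @return the winning `hdp_state`, with a `runs` element: data frame of
#'   seed, init, K, and final log-likelihood per run, plus a `traces`
#'   list.
#' @export
fit_hdp_multistart <- function(corpus, seeds = c(1L, 2L, 3L), eta = 0.1,
                               max_iter = 2000L,
                               init_topics = c(1L, 20L), ...) {
  if (length(seeds) < 1) stop("need at least one seed")
  grid <- expand.grid(seed = as.integer(seeds),
                      init = as.integer(init_topics))
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    fit_hdp(corpus, eta = eta, max_iter = max_iter, seed = grid$seed[i],
            init_topics = grid$init[i], ...)
  })
  final_ll <- vapply(fits, function(f) f$loglik[length(f$loglik)], 0)
  best <- which.max(final_ll)
  out <- fits[[best]]
  out$runs <- data.frame(
    seed = grid$seed,
    init = grid$init,
    K = vapply(fits, function(f) f$K, 0L),
    final_loglik = final_ll,
    selected = seq_len(nrow(grid)) == best)
  out$traces <- lapply(fits, function(f) f$loglik)
  out
}

#' Extract the module-TF matrix and the site assignment table
#'
#' Empty topics are dropped (the sampler already prunes them) and module
#' ids are relabeled densely by descending total site count, so module 1 is
#' always the largest.
#'
#' @param state a fitted `hdp_state`.
#' @param corpus the corpus the state was fitted on.
#' @return list with
#'   \describe{
#'     \item{module_tf}{K x V matrix of site counts contributed by each
#'       factor to each module (rows `M01`, `M02`, ...);}
#'     \item{assignments}{data frame `region_id`, `site_index`, `factor`,
#'       `module` with one row per token.  `site_index` follows the
#'       deterministic token order of the corpus documents (factor-sorted
#'       within region).}
#'   }
#' @export
extract_outputs <- function(state, corpus) {
  keep <- which(rowSums(state$n_kw) > 0)
  ord <- keep[order(rowSums(state$n_kw)[keep], decreasing = TRUE)]
  module_tf <- state$n_kw[ord, , drop = FALSE]
  rownames(module_tf) <- sprintf("M%02d", seq_along(ord))
  relab <- integer(state$K)
  relab[ord] <- seq_along(ord)

  doc_of <- rep(seq_along(corpus$documents), lengths(corpus$documents))
  site_index <- sequence(lengths(corpus$documents))
  word <- unlist(corpus$documents, use.names = FALSE)
  assignments <- data.frame(
    region_id = corpus$ids[doc_of],
    site_index = site_index,
    factor = corpus$vocabulary[word],
    module = relab[state$z],
    stringsAsFactors = FALSE)

  list(module_tf = module_tf, assignments = assignments)
}
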