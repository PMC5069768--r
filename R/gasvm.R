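# Discriminative-feature selection: a genetic algorithm searches fixed-size
# feature subsets, each scored by the leave-one-out accuracy of a linear
# soft-margin SVM distinguishing the strains. This reduces the most intense
# features (default 500) to a compact discriminating set (default 50).

#' GA/SVM parameters
#'
#' Defaults mirror the published wrapper settings: population 25, 10
#' generations, mutation rate 1 (one random gene replacement per offspring
#' per generation), linear SVM with cost 100 and balanced class weighting
#' (ratio 1), subsets of 50 drawn from the 500 most intense features.
#'
#' @param population_size number of chromosomes (>= 2).
#' @param generations GA iterations.
#' @param mutation_rate random gene replacements per offspring per
#'   generation.
#' @param svm_cost soft-margin cost parameter C.
#' @param class_weight_ratio 1 = equal class weights.
#' @param subset_size k, features per chromosome.
#' @param n_input_features size of the candidate pool.
#' @param seed RNG seed for the search.
#' @return object of class `gasvm_params`.
#' @export
gasvm_params <- function(population_size = 25L, generations = 10L,
                         mutation_rate = 1L, svm_cost = 100,
                         class_weight_ratio = 1, subset_size = 50L,
                         n_input_features = 500L, seed = 1L) {
  stopifnot(population_size >= 2, generations >= 1, subset_size >= 1,
            subset_size <= n_input_features)
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         mutation_rate = as.integer(mutation_rate),
         svm_cost = svm_cost, class_weight_ratio = class_weight_ratio,
         subset_size = as.integer(subset_size),
         n_input_features = as.integer(n_input_features),
         seed = as.integer(seed)),
    class = "gasvm_params"
  )
}

# Standardise train columns; apply the same centring/scaling to test rows.
# Zero-variance columns are centred only.
scale_fold <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(
    train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
    test = sweep(sweep(test, 2, mu, "-"), 2, sdv, "/")
  )
}

#' Leave-one-out SVM accuracy of a feature subset
#'
#' For each sample, a multiclass (one-vs-one voting, linear kernel,
#' soft-margin cost `svm_cost`) SVM is trained on the remaining samples
#' restricted to the subset columns, standardised on the training fold, and
#' the held-out sample is classified.
#'
#' @param X samples x features numeric matrix.
#' @param y class labels (strains), length nrow(X).
#' @param subset column indices (or names) of the candidate feature subset.
#' @param params a [gasvm_params()] object.
#' @return LOO accuracy in \[0, 1\].
#' @export
loo_fitness <- function(X, y, subset, params = gasvm_params()) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples for leave-one-out")
  stopifnot(length(y) == nrow(X), length(subset) >= 1)
  y <- factor(y)
  Xs <- X[, subset, drop = FALSE]
  weights <- NULL
  if (!is.null(params$class_weight_ratio) && params$class_weight_ratio == 1) {
    tab <- table(y)
    weights <- stats::setNames(as.numeric(sum(tab) / (length(tab) * tab)), names(tab))
  }
  correct <- 0L
  for (i in seq_len(nrow(Xs))) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2) next  # held-out class was a singleton and unlearnable
    sc <- scale_fold(Xs[-i, , drop = FALSE], Xs[i, , drop = FALSE])
    fit <- e1071::svm(sc$train, ytr, kernel = "linear", cost = params$svm_cost,
                      scale = FALSE,
                      class.weights = if (!is.null(weights)) weights[levels(ytr)])
    pred <- stats::predict(fit, sc$test)
    if (as.character(pred) == as.character(y[i])) correct <- correct + 1L
  }
  correct / nrow(Xs)
}

#' GA search for a discriminative feature subset
#'
#' Initialises `population_size` random subsets of size `subset_size`; each
#' generation keeps the better half (elitism), refills by uniform crossover
#' of random elite pairs (shared genes are inherited, the remainder drawn
#' from the parents' symmetric difference), and applies `mutation_rate`
#' random gene replacements to each offspring. The best-ever chromosome is
#' returned; the search is deterministic given `params$seed`.
#'
#' @param X samples x features matrix (columns = candidate pool).
#' @param y class labels.
#' @param params a [gasvm_params()] object.
#' @return list of class `gasvm_result`: subset (column indices), fitness,
#'   history (data frame generation / best_fitness / mean_fitness),
#'   selection_freq (per-feature frequency in the final elite).
#' @export
ga_select <- function(X, y, params = gasvm_params()) {
  X <- as.matrix(X)
  n_feat <- ncol(X)
  k <- params$subset_size
  stopifnot(k <= n_feat)
  if (k == n_feat) {
    fit <- loo_fitness(X, y, seq_len(n_feat), params)
    return(structure(
      list(subset = seq_len(n_feat), fitness = fit,
           history = data.frame(generation = 0L, best_fitness = fit,
                                mean_fitness = fit),
           selection_freq = stats::setNames(rep(1, n_feat), colnames(X))),
      class = "gasvm_result"
    ))
  }
  with_seed(params$seed, {
    pop <- lapply(seq_len(params$population_size),
                  function(i) sort(sample.int(n_feat, k)))
    best_ever <- NULL
    best_fit <- -Inf
    history <- NULL
    for (gen in seq_len(params$generations)) {
      fits <- vapply(pop, function(s) loo_fitness(X, y, s, params), 0)
      if (max(fits) > best_fit) {
        best_fit <- max(fits)
        best_ever <- pop[[which.max(fits)]]
      }
      history <- rbind(history, data.frame(
        generation = gen, best_fitness = best_fit, mean_fitness = mean(fits)
      ))
      n_elite <- max(2L, ceiling(params$population_size / 2))
      elite_idx <- order(-fits, seq_along(fits))[seq_len(n_elite)]
      elite <- pop[elite_idx]
      # rank-weighted parent choice keeps pressure on the best chromosomes
      parent_w <- rev(seq_len(n_elite))
      offspring <- list()
      while (length(offspring) < params$population_size - n_elite) {
        par <- sample.int(n_elite, 2, prob = parent_w)
        a <- elite[[par[1]]]; b <- elite[[par[2]]]
        shared <- intersect(a, b)
        restpool <- setdiff(union(a, b), shared)
        need <- k - length(shared)
        child <- c(shared, restpool[sample.int(length(restpool), need)])
        for (m in seq_len(params$mutation_rate)) {
          out_pool <- setdiff(seq_len(n_feat), child)
          pos <- sample.int(k, 1)
          child[pos] <- out_pool[sample.int(length(out_pool), 1)]
        }
        offspring[[length(offspring) + 1L]] <- sort(child)
      }
      pop <- c(elite, offspring)
    }
    freq_tab <- table(unlist(pop))
    selection_freq <- stats::setNames(numeric(n_feat), colnames(X))
    selection_freq[as.integer(names(freq_tab))] <-
      as.numeric(freq_tab) / length(pop)
    structure(
      list(subset = best_ever, fitness = best_fit, history = history,
           selection_freq = selection_freq),
      class = "gasvm_result"
    )
  })
}

#' @export
print.gasvm_result <- function(x, ...) {
  cat(sprintf("gasvm_result: %d features selected, LOO accuracy %.3f\n",
              length(x$subset), x$fitness))
  invisible(x)
}

#' Sample matrix for strain classification from a feature table
#'
#' Rows are strain x replicate extracts, columns features; intensities are
#' log-transformed (`log1p`).
#'
#' @param table a `feature_table`.
#' @return list: X (samples x features), y (strain labels).
#' @export
classification_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  X <- log1p(table$intensity)
  y <- table$samples$strain_id[match(rownames(X), table$samples$sample_id)]
  list(X = X, y = y)
}
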