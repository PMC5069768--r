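# Shared fixtures: a small planted world keeps per-test runtime low while
# exercising every stage; worlds are cached per (seed, dropout) within a
# test run.

small_config <- function(seed = 1L, dropout_rate = 0.05, ...) {
  world_config(
    n_strains = 5L,
    clade_split = list(1:2, 3:5),
    clonal_pairs = list(),
    n_core_families = 12L,
    n_accessory_families = 8L,
    n_singletons_per_strain = 1L,
    genes_per_contig = 12L,
    planted_clusters = list(
      planted_cluster("PCA", n_genes = 5L, strains = 3:5, n_features = 4L,
                      halogenated = TRUE)
    ),
    features_per_strain = 60L,
    n_halogenated_features = 8L,
    blank_features = 8L,
    protein_length_range = c(80L, 160L),
    dropout_rate = dropout_rate,
    seed = seed,
    ...
  )
}

.world_cache <- new.env(parent = emptyenv())

small_world <- function(seed = 1L, dropout_rate = 0.05) {
  key <- sprintf("w_%d_%g", seed, dropout_rate)
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(small_config(seed, dropout_rate))
  }
  .world_cache[[key]]
}

small_hits <- function(seed = 1L, dropout_rate = 0.05) {
  key <- sprintf("h_%d_%g", seed, dropout_rate)
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- pairwise_hits(small_world(seed, dropout_rate)$proteomes)
  }
  .world_cache[[key]]
}

# random presence matrix for property tests
random_presence <- function(n_strains, n_entities, p = 0.4) {
  presence_matrix(matrix(stats::runif(n_strains * n_entities) < p,
                         n_strains, n_entities))
}

# random fragment spectrum with <= max_peaks peaks
random_spectrum <- function(id, max_peaks = 8L) {
  np <- sample(2:max_peaks, 1)
  fragment_spectrum(
    id, precursor_mz = stats::runif(1, 150, 800),
    peaks = cbind(sort(stats::runif(np, 50, 700)), stats::runif(np, 1, 100))
  )
}

# separable toy data: each class has its own marker feature plus noise
separable_data <- function(n_classes = 4, reps = 3, n_noise = 10, seed = 1) {
  set.seed(seed)
  n <- n_classes * reps
  X <- matrix(stats::rnorm(n * (n_classes + n_noise), sd = 0.3),
              n, n_classes + n_noise)
  y <- rep(sprintf("C%d", seq_len(n_classes)), each = reps)
  for (k in seq_len(n_classes)) {
    X[y == sprintf("C%d", k), k] <- X[y == sprintf("C%d", k), k] + 5
  }
  colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  list(X = X, y = y, markers = seq_len(n_classes))
}

# planted-marker data with a fitness gradient: n_markers + 1 classes whose
# profiles over the markers are increasing step vectors, so marker i is the
# only feature separating class i from class i+1 — dropping any one marker
# makes a specific class pair indistinguishable. The remaining features are
# inert (constant background), like chemistry shared by every extract.
staircase_data <- function(n_markers = 5, reps = 2, n_noise = 10, seed = 1) {
  set.seed(seed)
  n_classes <- n_markers + 1
  n <- n_classes * reps
  X <- matrix(0, n, n_markers + n_noise)
  X[, seq_len(n_markers)] <- stats::rnorm(n * n_markers, sd = 0.3)
  y <- rep(sprintf("C%d", seq_len(n_classes)), each = reps)
  for (j in seq_len(n_classes)) {
    rows <- y == sprintf("C%d", j)
    for (i in seq_len(n_markers)) {
      if (j > i) X[rows, i] <- X[rows, i] + 4
    }
  }
  colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  list(X = X, y = y, markers = seq_len(n_markers))
}

# trivially separable data: replicate rows are exact duplicates, so every
# held-out sample has an identical twin in the training fold
duplicated_data <- function(n_classes = 4, reps = 3, n_features = 12, seed = 1) {
  set.seed(seed)
  base <- matrix(stats::rnorm(n_classes * n_features, sd = 2),
                 n_classes, n_features)
  X <- base[rep(seq_len(n_classes), each = reps), , drop = FALSE]
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  list(X = X, y = rep(sprintf("C%d", seq_len(n_classes)), each = reps))
}

# raw long feature-table row builder
raw_rows <- function(masses, rts, strain = "ST01", replicate = 1L,
                     mode = "positive", intensity = 1000) {
  data.frame(
    sample_id = sprintf("%s_R%d", strain, replicate), strain_id = strain,
    replicate = replicate, mode = mode, neutral_mass = masses, rt = rts,
    intensity = rep_len(intensity, length(masses)), stringsAsFactors = FALSE
  )
}
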