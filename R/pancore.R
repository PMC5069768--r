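# Pan/core accumulation analysis for any strains x entities presence matrix.
# The same machinery serves gene families (pan-/core-genome) and molecular
# features (pan-/core-metabolome): strains are added in a chosen order, the
# pan curve tracks the cumulative union and the core curve the running
# intersection.

#' Build a presence matrix
#'
#' @param bits logical (or 0/1) matrix, rows = strains, columns = entities
#'   (gene families or molecular features).
#' @param strain_ids,entity_ids optional dimnames; taken from `bits` if absent.
#' @return logical matrix with unique dimnames, class `presence_matrix`.
#' @export
presence_matrix <- function(bits, strain_ids = rownames(bits),
                            entity_ids = colnames(bits)) {
  bits <- as.matrix(bits)
  mode(bits) <- "logical"
  if (is.null(strain_ids)) strain_ids <- sprintf("S%02d", seq_len(nrow(bits)))
  if (is.null(entity_ids)) entity_ids <- sprintf("E%05d", seq_len(ncol(bits)))
  if (anyDuplicated(strain_ids)) stop("duplicate strain ids")
  if (anyDuplicated(entity_ids)) stop("duplicate entity ids")
  stopifnot(length(strain_ids) == nrow(bits), length(entity_ids) == ncol(bits))
  dimnames(bits) <- list(strain_ids, entity_ids)
  class(bits) <- c("presence_matrix", class(bits))
  bits
}

as_presence <- function(mat) {
  if (inherits(mat, "presence_matrix")) return(mat)
  presence_matrix(mat)
}

#' Pan and core accumulation curves
#'
#' Adds strains one at a time in `order`; position i reports the size of the
#' union (pan), of the intersection (core), and of the increment of new
#' entities contributed by strain i.
#'
#' @param mat presence matrix (strains x entities).
#' @param order character vector of strain ids (a permutation of the rows) or
#'   `NULL` to use [cluster_order()].
#' @return list of class `pan_core_result`: order, pan_curve, core_curve,
#'   new_counts, unique_per_strain.
#' @export
pan_core <- function(mat, order = NULL) {
  mat <- as_presence(mat)
  if (is.null(order)) {
    order <- if (nrow(mat) >= 2) cluster_order(mat) else rownames(mat)
  }
  if (!identical(sort(order), sort(rownames(mat)))) {
    stop("order must be a permutation of the strain ids")
  }
  n <- length(order)
  pan <- core <- new_counts <- integer(n)
  cum_union <- cum_inter <- mat[order[1], ]
  pan[1] <- core[1] <- new_counts[1] <- sum(cum_union)
  if (n > 1) {
    for (i in 2:n) {
      row <- mat[order[i], ]
      prev_pan <- pan[i - 1]
      cum_union <- cum_union | row
      cum_inter <- cum_inter & row
      pan[i] <- sum(cum_union)
      core[i] <- sum(cum_inter)
      new_counts[i] <- pan[i] - prev_pan
    }
  }
  one_hit <- colSums(mat) == 1
  uniq <- rowSums(mat[, one_hit, drop = FALSE])
  structure(
    list(order = order, pan_curve = pan, core_curve = core,
         new_counts = new_counts, unique_per_strain = uniq[order]),
    class = "pan_core_result"
  )
}

#' @export
print.pan_core_result <- function(x, ...) {
  n <- length(x$order)
  cat(sprintf("pan/core curves over %d strains: pan %d -> %d, core %d -> %d\n",
              n, x$pan_curve[1], x$pan_curve[n], x$core_curve[1], x$core_curve[n]))
  invisible(x)
}

#' Strain input order from hierarchical clustering
#'
#' Clusters strain presence profiles and returns the dendrogram leaf order,
#' the conventional input ordering for pan/core plots. Rows are pre-sorted
#' lexicographically by strain id so the result does not depend on input
#' order, and ties in the dendrogram are broken by strain id.
#'
#' @param mat presence matrix.
#' @param distance `"jaccard"` (on presence profiles) or `"manhattan"`.
#' @param linkage `"average"` or `"complete"`.
#' @return character vector: permutation of the strain ids.
#' @export
cluster_order <- function(mat, distance = c("jaccard", "manhattan"),
                          linkage = c("average", "complete")) {
  mat <- as_presence(mat)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (nrow(mat) < 2) stop("need at least 2 strains to cluster")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  d <- switch(distance,
    jaccard = stats::dist(mat, method = "binary"),
    manhattan = stats::dist(mat * 1L, method = "manhattan")
  )
  hc <- stats::hclust(d, method = linkage)
  rownames(mat)[hc$order]
}

#' Core and unique fractions of a presence matrix
#'
#' @param mat presence matrix.
#' @return list: core_fraction (entities present in every strain / all
#'   entities), unique_fraction (entities present in exactly one strain /
#'   all entities), per_strain_unique (named count of singleton entities
#'   per strain).
#' @export
unique_and_shared_fractions <- function(mat) {
  mat <- as_presence(mat)
  if (ncol(mat) == 0) stop("empty presence matrix")
  hits <- colSums(mat)
  core <- sum(hits == nrow(mat))
  uniq_cols <- hits == 1
  per_strain <- rowSums(mat[, uniq_cols, drop = FALSE])
  list(
    core_fraction = core / ncol(mat),
    unique_fraction = sum(uniq_cols) / ncol(mat),
    per_strain_unique = per_strain
  )
}

#' Coverage of a reference entity set by a strain subset
#'
#' Fraction of the reference entities detected in at least one strain of the
#' subset — the quantity behind "how much of the chemical diversity do k
#' selected strains cover".
#'
#' @param mat presence matrix.
#' @param subset character vector of strain ids (may be empty).
#' @param reference entity ids to cover; defaults to all entities.
#' @return proportion in \[0, 1\].
#' @seealso [best_pair_coverage()] for the exhaustive argmax over strain pairs.
#' @export
subset_coverage <- function(mat, subset, reference = colnames(mat)) {
  mat <- as_presence(mat)
  if (length(reference) == 0) stop("empty reference entity set")
  stopifnot(all(subset %in% rownames(mat)), all(reference %in% colnames(mat)))
  if (length(subset) == 0) return(0)
  sub <- mat[subset, reference, drop = FALSE]
  sum(colSums(sub) > 0) / length(reference)
}

#' Best strain pair by coverage (exhaustive search)
#'
#' @inheritParams subset_coverage
#' @return list: pair (two strain ids), coverage, all (data frame of every
#'   pair and its coverage).
#' @export
best_pair_coverage <- function(mat, reference = colnames(mat)) {
  mat <- as_presence(mat)
  ids <- rownames(mat)
  if (length(ids) < 2) stop("need at least 2 strains")
  pairs <- utils::combn(ids, 2)
  cov <- apply(pairs, 2, function(p) subset_coverage(mat, p, reference))
  best <- which.max(cov)
  list(
    pair = pairs[, best],
    coverage = cov[best],
    all = data.frame(strain_a = pairs[1, ], strain_b = pairs[2, ],
                     coverage = cov, stringsAsFactors = FALSE)
  )
}
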