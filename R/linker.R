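# The discovery core: cross-examining genotype and chemotype presence
# patterns. A metabolite family restricted to a set of strains implies its
# biosynthetic genes should show the same presence/absence barcode; genes
# matching the pattern that additionally sit adjacent on one contig are
# candidate biosynthetic gene clusters. The reverse direction pulls out the
# molecular features matching a gene cluster's conservation pattern.

#' A barcode link query
#'
#' @param pattern presence pattern (bit string or logical vector) over the
#'   strain universe.
#' @param max_hamming allowed Hamming distance between a barcode and the
#'   pattern (default 0: exact match).
#' @param min_cluster_genes minimum genes for a candidate cluster.
#' @param max_gap maximum number of intervening non-matching genes inside a
#'   cluster run.
#' @return object of class `link_query`.
#' @export
link_query <- function(pattern, max_hamming = 0L, min_cluster_genes = 3L,
                       max_gap = 2L) {
  bits <- parse_pattern(pattern)
  stopifnot(max_hamming >= 0, max_hamming < length(bits),
            min_cluster_genes >= 1, max_gap >= 0)
  structure(
    list(pattern = bits, max_hamming = as.integer(max_hamming),
         min_cluster_genes = as.integer(min_cluster_genes),
         max_gap = as.integer(max_gap)),
    class = "link_query"
  )
}

#' Genes whose barcode matches a pattern
#'
#' @param barcodes logical matrix proteins x strains (from
#'   [bbh_orthologs()]).
#' @param query a [link_query()] (or a pattern coercible to one).
#' @return character vector of protein ids within `max_hamming` of the
#'   pattern.
#' @export
genes_matching_pattern <- function(barcodes, query) {
  if (!inherits(query, "link_query")) query <- link_query(query)
  bits <- parse_pattern(query$pattern, width = ncol(barcodes))
  d <- hamming_to_pattern(barcodes, bits)
  rownames(barcodes)[d <= query$max_hamming]
}

#' Molecular features whose presence matches a pattern
#'
#' @param presence strains x features [presence_matrix()].
#' @param pattern presence pattern over the strains.
#' @param max_hamming allowed Hamming distance.
#' @return character vector of feature ids.
#' @export
features_matching_pattern <- function(presence, pattern, max_hamming = 0L) {
  bits <- parse_pattern(pattern, width = nrow(presence))
  d <- hamming_to_pattern(t(presence), bits)
  colnames(presence)[d <= max_hamming]
}

#' Call candidate gene clusters from pattern-matching genes
#'
#' Within each strain and contig, matching genes are joined into maximal
#' runs allowing at most `max_gap` intervening non-matching genes; runs with
#' at least `min_cluster_genes` members are reported, ranked by member count
#' (ties: strain id, then contig id).
#'
#' @param matching_genes protein ids from [genes_matching_pattern()].
#' @param records records data frame of a [proteome_set()] (gene_index
#'   required).
#' @param query a [link_query()].
#' @return data frame of class `candidate_clusters`: strain_id, contig_id,
#'   start_index, end_index, n_genes (score), protein_ids
#'   (semicolon-joined, ordered by gene index).
#' @export
call_clusters <- function(matching_genes, records, query) {
  if (!inherits(query, "link_query")) stop("query must be a link_query")
  empty <- data.frame(
    strain_id = character(0), contig_id = character(0),
    start_index = integer(0), end_index = integer(0), n_genes = integer(0),
    protein_ids = character(0), stringsAsFactors = FALSE
  )
  if (length(matching_genes) == 0) {
    class(empty) <- c("candidate_clusters", class(empty))
    return(empty)
  }
  rec <- records[records$protein_id %in% matching_genes, , drop = FALSE]
  out <- empty
  for (key in unique(paste(rec$strain_id, rec$contig_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- rec[rec$strain_id == parts[1] & rec$contig_id == parts[2], , drop = FALSE]
    sub <- sub[order(sub$gene_index), , drop = FALSE]
    idx <- sub$gene_index
    run_start <- 1L
    flush <- function(from, to) {
      members <- sub$protein_id[from:to]
      if (length(members) >= query$min_cluster_genes) {
        out <<- rbind(out, data.frame(
          strain_id = parts[1], contig_id = parts[2],
          start_index = idx[from], end_index = idx[to],
          n_genes = length(members),
          protein_ids = paste(members, collapse = ";"),
          stringsAsFactors = FALSE
        ))
      }
    }
    if (length(idx) >= 1) {
      for (i in seq_along(idx)[-1]) {
        gap <- idx[i] - idx[i - 1] - 1L
        if (gap > query$max_gap) {
          flush(run_start, i - 1L)
          run_start <- i
        }
      }
      flush(run_start, length(idx))
    }
  }
  out <- out[order(-out$n_genes, out$strain_id, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_clusters", class(out))
  out
}

#' Permutation significance of an observed cluster run
#'
#' Null model: gene barcodes are fixed but gene positions are shuffled
#' within each contig, preserving contig sizes. The p-value is the
#' probability, under that null, of seeing a run of pattern-matching genes
#' at least as long as observed:
#' `p = (1 + #permutations with max run >= observed) / (1 + n_permutations)`.
#'
#' @param pattern presence pattern over the strains.
#' @param barcodes logical matrix proteins x strains.
#' @param records records data frame (strain_id, contig_id, gene_index).
#' @param query a [link_query()]; its gap/size rules define a "run".
#' @param n_permutations at least 100.
#' @param seed RNG seed.
#' @return list: p_value, observed_max_run, null_max_runs.
#' @export
match_significance <- function(pattern, barcodes, records,
                               query = link_query(pattern),
                               n_permutations = 999L, seed = 1L) {
  stopifnot(n_permutations >= 100)
  bits <- parse_pattern(pattern, width = ncol(barcodes))
  query$pattern <- bits
  matching <- genes_matching_pattern(barcodes, query)
  max_run <- function(rec) {
    cl <- call_clusters(matching, rec, modify_query_min1(query))
    if (nrow(cl) == 0) 0L else max(cl$n_genes)
  }
  observed <- max_run(records)
  # shuffling all positions within a contig and keeping the matching genes
  # is equivalent to drawing the matching genes' positions uniformly from
  # the contig's index pool
  key_all <- paste(records$strain_id, records$contig_id, sep = "\r")
  rec_m <- records[records$protein_id %in% matching, , drop = FALSE]
  key_m <- paste(rec_m$strain_id, rec_m$contig_id, sep = "\r")
  pools <- split(records$gene_index, key_all)
  rows_by_key <- split(seq_len(nrow(rec_m)), key_m)
  null_runs <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      rec <- rec_m
      for (key in names(rows_by_key)) {
        rows <- rows_by_key[[key]]
        pool <- pools[[key]]
        rec$gene_index[rows] <- pool[sample.int(length(pool), length(rows))]
      }
      max_run(rec)
    }, 0L)
  })
  list(
    p_value = (1 + sum(null_runs >= observed)) / (1 + n_permutations),
    observed_max_run = observed,
    null_max_runs = null_runs
  )
}

# runs of any size count when measuring the null distribution
modify_query_min1 <- function(query) {
  query$min_cluster_genes <- 1L
  query
}
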