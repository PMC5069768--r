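# MS/MS molecular networking. Spectral similarity is the modified cosine:
# fragment peaks may match either directly or offset by the difference of the
# two precursor masses, so structural analogues (same scaffold, one
# substituent changed) still score highly. Edges above the cosine threshold
# define the network; connected components are molecular families.

#' Networking parameters
#'
#' @param cosine_threshold retain an edge when score is strictly greater
#'   (default 0.7).
#' @param fragment_tol Da tolerance for matching fragment peaks.
#' @param min_matched_peaks minimum number of matched peak pairs for an edge.
#' @param intensity_transform `"sqrt"` (default, damps base-peak dominance)
#'   or `"none"`.
#' @return object of class `network_params`.
#' @export
network_params <- function(cosine_threshold = 0.7, fragment_tol = 0.3,
                           min_matched_peaks = 6L,
                           intensity_transform = c("sqrt", "none")) {
  stopifnot(cosine_threshold >= 0, cosine_threshold <= 1, fragment_tol > 0,
            min_matched_peaks >= 1)
  structure(
    list(cosine_threshold = cosine_threshold, fragment_tol = fragment_tol,
         min_matched_peaks = as.integer(min_matched_peaks),
         intensity_transform = match.arg(intensity_transform)),
    class = "network_params"
  )
}

#' Construct a fragment spectrum
#'
#' @param spectrum_id identifier.
#' @param precursor_mz precursor m/z (Th).
#' @param peaks two-column matrix or data frame (mz, intensity); resorted by
#'   m/z.
#' @param charge precursor charge.
#' @param rt retention time (min), optional.
#' @param strain_id producing strain, optional.
#' @param feature_id linked molecular feature, optional.
#' @return object of class `fragment_spectrum`.
#' @export
fragment_spectrum <- function(spectrum_id, precursor_mz, peaks, charge = 1L,
                              rt = NA_real_, strain_id = NA_character_,
                              feature_id = NA_character_) {
  peaks <- as.matrix(peaks)
  stopifnot(ncol(peaks) == 2, nrow(peaks) >= 1, all(peaks[, 2] > 0))
  peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  colnames(peaks) <- c("mz", "intensity")
  structure(
    list(spectrum_id = spectrum_id, precursor_mz = precursor_mz,
         charge = as.integer(charge), rt = rt, peaks = peaks,
         strain_id = strain_id, feature_id = feature_id),
    class = "fragment_spectrum"
  )
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  cat(sprintf("fragment_spectrum %s: precursor %.4f, %d peaks\n",
              x$spectrum_id, x$precursor_mz, nrow(x$peaks)))
  invisible(x)
}

transform_intensity <- function(x, transform) {
  if (transform == "sqrt") sqrt(x) else x
}

# Candidate peak pairs between two spectra: direct matches and matches under
# the precursor-difference offset. Returns a data frame i, j, product.
candidate_pairs <- function(s1, s2, params) {
  mz1 <- s1$peaks[, 1]; mz2 <- s2$peaks[, 1]
  t1 <- transform_intensity(s1$peaks[, 2], params$intensity_transform)
  t2 <- transform_intensity(s2$peaks[, 2], params$intensity_transform)
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- t2 / sqrt(sum(t2^2))
  delta <- s1$precursor_mz - s2$precursor_mz
  d_direct <- abs(outer(mz1, mz2, "-"))
  d_shift <- abs(outer(mz1, mz2 + delta, "-"))
  ok <- d_direct <= params$fragment_tol | d_shift <= params$fragment_tol
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  data.frame(i = idx[, 1], j = idx[, 2],
             product = t1[idx[, 1]] * t2[idx[, 2]])
}

#' Modified cosine similarity of two fragment spectra
#'
#' Peaks are pairable when their m/z values agree within `fragment_tol`
#' either directly or after shifting one spectrum by the precursor-mass
#' difference. A one-to-one pairing is chosen to (approximately, for
#' `method = "greedy"`; exactly, for `method = "optimal"`) maximise the sum
#' of products of unit-normalised transformed intensities; that sum is the
#' score.
#'
#' @param s1,s2 [fragment_spectrum()] objects.
#' @param params a [network_params()] object.
#' @param method `"greedy"` (descending-product, the classic networking
#'   behaviour) or `"optimal"` (exhaustive assignment, for small spectra /
#'   oracle checks).
#' @return list: score in \[0, 1\], n_matched.
#' @export
modified_cosine <- function(s1, s2, params = network_params(),
                            method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(inherits(s1, "fragment_spectrum"), inherits(s2, "fragment_spectrum"))
  cand <- candidate_pairs(s1, s2, params)
  if (is.null(cand)) return(list(score = 0, n_matched = 0L))
  if (method == "greedy") {
    cand <- cand[order(-cand$product, cand$i, cand$j), , drop = FALSE]
    used_i <- logical(nrow(s1$peaks)); used_j <- logical(nrow(s2$peaks))
    score <- 0; n <- 0L
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE; used_j[j] <- TRUE
        score <- score + cand$product[k]
        n <- n + 1L
      }
    }
  } else {
    res <- best_assignment(cand)
    score <- res$score; n <- res$n
  }
  # unit-normalised vectors bound the sum by 1; guard float overshoot
  list(score = min(score, 1), n_matched = n)
}

# Exact maximum-weight one-to-one assignment over the candidate pair list by
# depth-first search with an upper-bound cut; intended for small spectra.
best_assignment <- function(cand) {
  cand <- cand[order(cand$i, -cand$product), , drop = FALSE]
  by_i <- split(seq_len(nrow(cand)), cand$i)
  # optimistic bound: best product available at each remaining level
  best_at <- vapply(by_i, function(r) max(cand$product[r]), 0)
  suffix <- rev(cumsum(rev(best_at)))
  best <- list(score = 0, n = 0L)
  used_j <- new.env(parent = emptyenv())
  recurse <- function(level, score, n) {
    if (level > length(by_i)) {
      if (score > best$score) best <<- list(score = score, n = n)
      return()
    }
    if (score + suffix[level] <= best$score) return()
    for (r in by_i[[level]]) {
      jkey <- as.character(cand$j[r])
      if (!is.null(used_j[[jkey]])) next
      used_j[[jkey]] <- TRUE
      recurse(level + 1L, score + cand$product[r], n + 1L)
      rm(list = jkey, envir = used_j)
    }
    recurse(level + 1L, score, n) # leave this peak unmatched
  }
  recurse(1L, 0, 0L)
  best
}

#' Build a molecular network
#'
#' Scores all spectrum pairs with [modified_cosine()]; an edge is retained
#' when the score strictly exceeds `cosine_threshold` and at least
#' `min_matched_peaks` peak pairs matched. Connected components with two or
#' more nodes are molecular families.
#'
#' @param spectra list of [fragment_spectrum()] objects.
#' @param params a [network_params()] object.
#' @return list of class `molecular_network`: edges (data frame source,
#'   target, cosine, n_matched, delta_mz), families (named list of
#'   spectrum-id vectors), singletons, nodes.
#' @export
build_network <- function(spectra, params = network_params()) {
  stopifnot(length(spectra) >= 2)
  ids <- vapply(spectra, `[[`, "", "spectrum_id")
  if (anyDuplicated(ids)) stop("duplicate spectrum ids")
  ord <- order(ids)
  spectra <- spectra[ord]; ids <- ids[ord]
  n <- length(spectra)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mc <- modified_cosine(spectra[[i]], spectra[[j]], params)
      if (mc$score > params$cosine_threshold &&
          mc$n_matched >= params$min_matched_peaks) {
        rows[[length(rows) + 1L]] <- data.frame(
          source = ids[i], target = ids[j],
          cosine = mc$score, n_matched = mc$n_matched,
          delta_mz = spectra[[i]]$precursor_mz - spectra[[j]]$precursor_mz,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), target = character(0),
               cosine = numeric(0), n_matched = integer(0),
               delta_mz = numeric(0), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  fam_sets <- split(names(comp), comp)
  fam_sets <- fam_sets[order(vapply(fam_sets, min, ""))]
  families <- fam_sets[lengths(fam_sets) >= 2]
  names(families) <- sprintf("MF%03d", seq_along(families))
  singletons <- unlist(fam_sets[lengths(fam_sets) == 1], use.names = FALSE)
  structure(
    list(edges = edges, families = families,
         singletons = singletons %||% character(0),
         nodes = data.frame(spectrum_id = ids, stringsAsFactors = FALSE),
         params = params, spectra = spectra),
    class = "molecular_network"
  )
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("molecular_network: %d nodes, %d edges, %d families, %d singletons\n",
              nrow(x$nodes), nrow(x$edges), length(x$families),
              length(x$singletons)))
  invisible(x)
}

#' Annotate network nodes with strain presence
#'
#' Each node is matched to a molecular feature — by its spectrum's
#' `feature_id` when set, otherwise by precursor neutral mass (precursor m/z
#' minus a proton for singly charged positive ions) within `mass_tol_ppm` —
#' and labelled `core` (feature in all strains), `unique` (one strain),
#' `shared` (in between), or `unknown` (no match; warned).
#'
#' @param network a `molecular_network`.
#' @param feature_table a [align_features()] / [merge_modes()] result.
#' @param mass_tol_ppm mass tolerance for precursor-to-feature matching.
#' @return the network with a `nodes` data frame gaining feature_id, label
#'   and presence-pattern columns.
#' @export
annotate_nodes <- function(network, feature_table, mass_tol_ppm = 20) {
  stopifnot(inherits(network, "molecular_network"),
            inherits(feature_table, "feature_table"))
  feats <- feature_table$features
  pres <- feature_table$presence
  n_strains <- nrow(pres)
  nodes <- network$nodes
  nodes$feature_id <- NA_character_
  nodes$label <- "unknown"
  nodes$pattern <- NA_character_
  for (k in seq_len(nrow(nodes))) {
    sp <- network$spectra[[k]]
    fid <- sp$feature_id
    if (is.na(fid) || !fid %in% feats$feature_id) {
      neutral <- sp$precursor_mz * max(sp$charge, 1L) - adducts[["[M+H]+"]] * max(sp$charge, 1L)
      tol <- mass_tol_ppm * 1e-6 * pmax(neutral, feats$neutral_mass)
      hit <- which(abs(feats$neutral_mass - neutral) <= tol)
      fid <- if (length(hit)) feats$feature_id[hit[which.min(abs(feats$neutral_mass[hit] - neutral))]] else NA_character_
    }
    if (is.na(fid)) {
      warning("no feature match for spectrum ", sp$spectrum_id)
      next
    }
    bits <- pres[, fid]
    nodes$feature_id[k] <- fid
    nodes$pattern[k] <- pattern_string(bits)
    nodes$label[k] <- if (all(bits)) "core" else if (sum(bits) == 1) "unique" else "shared"
  }
  network$nodes <- nodes
  network
}

#' Write network edges as a Cytoscape-importable TSV
#' @param network a `molecular_network`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' Honours PEPMASS, CHARGE, RTINSECONDS, TITLE and the optional STRAIN and
#' FEATURE fields written by [write_mgf()].
#'
#' @param path MGF file.
#' @return list of [fragment_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  in_block <- FALSE
  hdr <- list(); pk <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      in_block <- TRUE; hdr <- list(); pk <- NULL
    } else if (ln == "END IONS") {
      if (is.null(pk)) stop("spectrum without peaks in ", path)
      ch <- hdr$CHARGE %||% "1+"
      spectra[[length(spectra) + 1L]] <- fragment_spectrum(
        spectrum_id = hdr$TITLE %||% sprintf("spec_%03d", length(spectra) + 1L),
        precursor_mz = as.numeric(strsplit(hdr$PEPMASS, " ")[[1]][1]),
        peaks = do.call(rbind, pk),
        charge = as.integer(sub("[+-]$", "", ch)),
        rt = if (!is.null(hdr$RTINSECONDS)) as.numeric(hdr$RTINSECONDS) / 60 else NA_real_,
        strain_id = hdr$STRAIN %||% NA_character_,
        feature_id = hdr$FEATURE %||% NA_character_
      )
      in_block <- FALSE
    } else if (in_block && grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      hdr[[kv[1]]] <- paste(kv[-1], collapse = "=")
    } else if (in_block) {
      vals <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
      if (length(vals) < 2 || any(is.na(vals[1:2]))) {
        stop("unparseable peak line in ", path, ": ", ln)
      }
      pk[[length(pk) + 1L]] <- vals[1:2]
    }
  }
  spectra
}

#' Write spectra to an MGF file
#' @param spectra list of [fragment_spectrum()] objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", sp$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    if (!is.na(sp$rt)) writeLines(sprintf("RTINSECONDS=%.2f", sp$rt * 60), con)
    if (!is.na(sp$strain_id)) writeLines(sprintf("STRAIN=%s", sp$strain_id), con)
    if (!is.na(sp$feature_id)) writeLines(sprintf("FEATURE=%s", sp$feature_id), con)
    writeLines(sprintf("%.6f %.2f", sp$peaks[, 1], sp$peaks[, 2]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
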