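# Untargeted-metabolomics feature handling: blank (medium) subtraction,
# cross-sample alignment into consensus features, ESI+/ESI- merging and
# intensity filtering. The end product is a strains x features presence
# matrix, the common currency shared with the genomic side.
#
# Raw per-sample tables are long data frames with columns
#   sample_id, strain_id, replicate, mode, neutral_mass, rt, intensity
# (neutral mass in Da as produced by molecular-feature extraction, RT in
# minutes, intensity in ion counts).

#' Alignment and presence-calling parameters
#'
#' @param mass_tol_ppm mass tolerance in ppm (applied to the larger mass of a
#'   compared pair).
#' @param rt_tol retention-time tolerance in minutes.
#' @param presence_rule a strain is called positive for a feature if
#'   `"any_replicate"` (default) or only if `"all_replicates"` of that strain
#'   contain it.
#' @return object of class `alignment_params`.
#' @export
alignment_params <- function(mass_tol_ppm = 20, rt_tol = 0.2,
                             presence_rule = c("any_replicate", "all_replicates")) {
  stopifnot(mass_tol_ppm > 0, rt_tol > 0)
  structure(
    list(mass_tol_ppm = mass_tol_ppm, rt_tol = rt_tol,
         presence_rule = match.arg(presence_rule)),
    class = "alignment_params"
  )
}

.raw_cols <- c("sample_id", "strain_id", "replicate", "mode",
               "neutral_mass", "rt", "intensity")

check_raw_features <- function(df) {
  missing <- setdiff(.raw_cols, names(df))
  if (length(missing)) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df
}

# TRUE for each row of `df` that matches any row of `ref` within tolerance.
matches_any <- function(mass, rt, ref_mass, ref_rt, params) {
  if (length(ref_mass) == 0) return(rep(FALSE, length(mass)))
  out <- logical(length(mass))
  ord <- order(ref_mass)
  ref_mass <- ref_mass[ord]
  ref_rt <- ref_rt[ord]
  for (i in seq_along(mass)) {
    tol <- params$mass_tol_ppm * 1e-6 * pmax(mass[i], ref_mass)
    hit <- abs(ref_mass - mass[i]) <= tol & abs(ref_rt - rt[i]) <= params$rt_tol
    out[i] <- any(hit)
  }
  out
}

#' Remove features that match blank (medium) features
#'
#' Any feature whose mass and retention time both fall within tolerance of a
#' blank feature is discarded; the operation is idempotent.
#'
#' @param features raw long feature table (see module header for columns).
#' @param blank_features table with at least `neutral_mass` and `rt` columns.
#' @param params an [alignment_params()] object.
#' @return the filtered table, with attribute `n_removed`.
#' @export
subtract_blanks <- function(features, blank_features, params = alignment_params()) {
  check_raw_features(features)
  if (is.null(blank_features) || nrow(blank_features) == 0) {
    attr(features, "n_removed") <- 0L
    return(features)
  }
  hit <- matches_any(features$neutral_mass, features$rt,
                     blank_features$neutral_mass, blank_features$rt, params)
  out <- features[!hit, , drop = FALSE]
  message(sprintf("subtract_blanks: removed %d of %d feature rows",
                  sum(hit), nrow(features)))
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Align per-sample feature lists into consensus features
#'
#' Groups raw feature rows by single-linkage within the mass and RT
#' tolerances (an edge joins two rows when both differences are inside
#' tolerance; groups are the connected components, so tolerant to small RT
#' drift chains). Each group becomes one consensus feature whose mass and RT
#' are intensity-weighted means of its members. Per-strain presence is called
#' from the strain's replicates by `params$presence_rule`.
#'
#' @param samples one long raw table, or a list of per-sample tables which
#'   are row-bound.
#' @param params an [alignment_params()] object.
#' @param strain_ids optional full strain universe (so strains whose every
#'   feature dropped out still occupy a presence row).
#' @return object of class `feature_table`: list with
#'   * `features`: data frame feature_id, neutral_mass, rt, mode, n_members
#'   * `intensity`: samples x features matrix (0 = absent)
#'   * `presence`: strains x features [presence_matrix()]
#'   * `samples`: sample_id/strain_id/replicate/mode bookkeeping
#' @export
align_features <- function(samples, params = alignment_params(), strain_ids = NULL) {
  if (is.data.frame(samples)) df <- samples else df <- do.call(rbind, samples)
  check_raw_features(df)
  if (nrow(df) == 0) stop("no feature rows to align")
  df <- df[order(df$neutral_mass), , drop = FALSE]
  n <- nrow(df)

  # single-linkage grouping: union-find over tolerance edges, scanning a
  # sliding mass window (masses are sorted)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  m <- df$neutral_mass
  rt <- df$rt
  max_tol <- params$mass_tol_ppm * 1e-6 * max(m)
  j_start <- 1L
  for (i in seq_len(n)) {
    while (m[i] - m[j_start] > max_tol) j_start <- j_start + 1L
    if (j_start < i) {
      js <- j_start:(i - 1L)
      tol <- params$mass_tol_ppm * 1e-6 * pmax(m[i], m[js])
      ok <- abs(m[i] - m[js]) <= tol & abs(rt[i] - rt[js]) <= params$rt_tol
      for (j in js[ok]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  grp <- vapply(seq_len(n), find, 1L)
  grp <- match(grp, unique(grp))

  w <- df$intensity
  gmass <- tapply(m * w, grp, sum) / tapply(w, grp, sum)
  grt <- tapply(rt * w, grp, sum) / tapply(w, grp, sum)
  gmode <- tapply(df$mode, grp, function(x) {
    u <- unique(x); if (length(u) == 1) u else "merged"
  })
  ord <- order(gmass)
  feature_id <- sprintf("F%05d", seq_along(ord))
  remap <- match(grp, ord)  # group -> ordered feature index

  sample_key <- unique(df[, c("sample_id", "strain_id", "replicate", "mode")])
  sample_key <- sample_key[order(sample_key$sample_id), , drop = FALSE]
  intensity <- matrix(0, nrow(sample_key), length(ord),
                      dimnames = list(sample_key$sample_id, feature_id))
  srow <- match(df$sample_id, sample_key$sample_id)
  for (k in seq_len(n)) {
    intensity[srow[k], remap[k]] <- max(intensity[srow[k], remap[k]], w[k])
  }

  strains <- strain_ids %||% sort(unique(sample_key$strain_id))
  pres <- matrix(FALSE, length(strains), length(ord),
                 dimnames = list(strains, feature_id))
  for (s in strains) {
    rows <- which(sample_key$strain_id == s)
    if (length(rows) == 0) next
    det <- intensity[rows, , drop = FALSE] > 0
    pres[s, ] <- if (params$presence_rule == "any_replicate")
      colSums(det) > 0 else colSums(det) == length(rows)
  }

  structure(
    list(
      features = data.frame(
        feature_id = feature_id,
        neutral_mass = as.numeric(gmass[ord]),
        rt = as.numeric(grt[ord]),
        mode = as.character(gmode[ord]),
        n_members = as.integer(table(grp)[ord]),
        stringsAsFactors = FALSE
      ),
      intensity = intensity,
      presence = presence_matrix(pres),
      samples = sample_key,
      params = params
    ),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d strains (%d samples)\n",
              nrow(x$features), nrow(x$presence), nrow(x$intensity)))
  invisible(x)
}

#' Merge positive- and negative-mode feature tables
#'
#' Features from the two ionisation modes whose neutral masses and retention
#' times agree within tolerance are collapsed to a single merged feature
#' (presence = OR of the two patterns, intensity = per-sample maximum), so
#' `|merged| = |P| + |N| - |matched pairs|`. Matching is one-to-one, closest
#' mass first.
#'
#' @param pos_table,neg_table `feature_table` objects (blank-subtracted,
#'   aligned).
#' @param params an [alignment_params()] object.
#' @return a merged `feature_table`, with attribute `n_matched`.
#' @export
merge_modes <- function(pos_table, neg_table, params = alignment_params()) {
  stopifnot(inherits(pos_table, "feature_table"), inherits(neg_table, "feature_table"))
  fp <- pos_table$features
  fn <- neg_table$features
  # candidate cross-mode pairs within tolerance, greedily matched by |dmass|
  cand <- NULL
  for (i in seq_len(nrow(fp))) {
    tol <- params$mass_tol_ppm * 1e-6 * pmax(fp$neutral_mass[i], fn$neutral_mass)
    ok <- which(abs(fp$neutral_mass[i] - fn$neutral_mass) <= tol &
                abs(fp$rt[i] - fn$rt) <= params$rt_tol)
    if (length(ok)) {
      cand <- rbind(cand, data.frame(
        p = i, n = ok,
        d = abs(fp$neutral_mass[i] - fn$neutral_mass[ok])
      ))
    }
  }
  p_match <- integer(0)
  n_match <- integer(0)
  if (!is.null(cand)) {
    cand <- cand[order(cand$d), , drop = FALSE]
    used_p <- logical(nrow(fp)); used_n <- logical(nrow(fn))
    for (k in seq_len(nrow(cand))) {
      i <- cand$p[k]; j <- cand$n[k]
      if (!used_p[i] && !used_n[j]) {
        used_p[i] <- TRUE; used_n[j] <- TRUE
        p_match <- c(p_match, i); n_match <- c(n_match, j)
      }
    }
  }
  strains <- sort(union(rownames(pos_table$presence), rownames(neg_table$presence)))
  samples <- rbind(pos_table$samples, neg_table$samples)
  samples <- samples[!duplicated(samples$sample_id), , drop = FALSE]
  expand_pres <- function(tab) {
    out <- matrix(FALSE, length(strains), ncol(tab$presence),
                  dimnames = list(strains, colnames(tab$presence)))
    out[rownames(tab$presence), ] <- tab$presence
    out
  }
  pp <- expand_pres(pos_table); pn <- expand_pres(neg_table)
  expand_int <- function(tab) {
    out <- matrix(0, nrow(samples), ncol(tab$intensity),
                  dimnames = list(samples$sample_id, colnames(tab$intensity)))
    out[rownames(tab$intensity), ] <- tab$intensity
    out
  }
  ip <- expand_int(pos_table); inn <- expand_int(neg_table)

  n_merged <- nrow(fp) + nrow(fn) - length(p_match)
  keep_p_only <- setdiff(seq_len(nrow(fp)), p_match)
  keep_n_only <- setdiff(seq_len(nrow(fn)), n_match)

  mass <- c((fp$neutral_mass[p_match] + fn$neutral_mass[n_match]) / 2,
            fp$neutral_mass[keep_p_only], fn$neutral_mass[keep_n_only])
  rt <- c((fp$rt[p_match] + fn$rt[n_match]) / 2,
          fp$rt[keep_p_only], fn$rt[keep_n_only])
  mode <- c(rep("merged", length(p_match)),
            fp$mode[keep_p_only], fn$mode[keep_n_only])
  pres <- cbind(
    if (length(p_match)) pp[, p_match, drop = FALSE] | pn[, n_match, drop = FALSE],
    pp[, keep_p_only, drop = FALSE],
    pn[, keep_n_only, drop = FALSE]
  )
  intens <- cbind(
    if (length(p_match)) pmax(ip[, p_match, drop = FALSE], inn[, n_match, drop = FALSE]),
    ip[, keep_p_only, drop = FALSE],
    inn[, keep_n_only, drop = FALSE]
  )
  ord <- order(mass)
  feature_id <- sprintf("F%05d", seq_len(n_merged))
  features <- data.frame(
    feature_id = feature_id,
    neutral_mass = mass[ord], rt = rt[ord], mode = mode[ord],
    n_members = 1L, stringsAsFactors = FALSE
  )
  pres <- pres[, ord, drop = FALSE]; colnames(pres) <- feature_id
  intens <- intens[, ord, drop = FALSE]; colnames(intens) <- feature_id
  out <- structure(
    list(features = features, intensity = intens,
         presence = presence_matrix(pres), samples = samples, params = params),
    class = "feature_table"
  )
  attr(out, "n_matched") <- length(p_match)
  out
}

#' Keep the n most intense features
#'
#' Intensity of a feature is its maximum across samples; ties are broken in
#' favour of the smaller feature id.
#'
#' @param table a `feature_table`.
#' @param n number of features to keep.
#' @return a `feature_table` restricted to the selected features.
#' @export
top_n_by_intensity <- function(table, n) {
  stopifnot(inherits(table, "feature_table"), n >= 1)
  total <- nrow(table$features)
  if (n > total) {
    warning(sprintf("n = %d exceeds the %d available features; returning all", n, total))
    n <- total
  }
  maxint <- apply(table$intensity, 2, max)
  ord <- order(-maxint, table$features$feature_id)
  keep <- sort(ord[seq_len(n)])
  structure(
    list(
      features = table$features[keep, , drop = FALSE],
      intensity = table$intensity[, keep, drop = FALSE],
      presence = presence_matrix(table$presence[, keep, drop = FALSE]),
      samples = table$samples,
      params = table$params
    ),
    class = "feature_table"
  )
}

#' Presence matrix of a feature table
#' @param table a `feature_table`.
#' @return strains x features [presence_matrix()].
#' @export
feature_presence_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  table$presence
}

#' Read a raw long feature table from CSV/TSV
#'
#' @param path file with columns sample_id, strain_id, replicate, mode,
#'   neutral_mass, rt, intensity.
#' @param sep field separator; `","` default, use `"\t"` for TSV.
#' @return data frame in the raw long format.
#' @export
read_feature_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  check_raw_features(df)
}
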