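# Comparative proteome analysis: pairwise protein similarity, gene families
# by the 50/50 rule (identity > 50% over >= 50% of the longest gene),
# bidirectional best hits (BBH), per-protein presence/absence barcodes across
# all strains, and counts of ortholog groups shared exactly by strain groups.

#' Assemble a proteome set from records and sequences
#'
#' @param records data frame: protein_id, strain_id, contig_id, gene_index
#'   (0-based position on the contig).
#' @param seqs `Biostrings::AAStringSet` named by protein_id (optional when
#'   only precomputed hit tables will be used).
#' @return object of class `proteome_set`.
#' @export
proteome_set <- function(records, seqs = NULL) {
  need <- c("protein_id", "strain_id", "contig_id", "gene_index")
  stopifnot(all(need %in% names(records)))
  if (anyDuplicated(records$protein_id)) stop("duplicate protein ids")
  if (!is.null(seqs)) {
    stopifnot(methods::is(seqs, "AAStringSet"))
    if (!all(records$protein_id %in% names(seqs))) {
      stop("sequences missing for some records")
    }
    seqs <- seqs[records$protein_id]
    records$length <- Biostrings::width(seqs)
  }
  structure(list(records = records, seqs = seqs), class = "proteome_set")
}

#' @export
print.proteome_set <- function(x, ...) {
  cat(sprintf("proteome_set: %d proteins from %d strains\n",
              nrow(x$records), length(unique(x$records$strain_id))))
  invisible(x)
}

#' Read per-strain protein FASTA files
#'
#' FASTA headers carry `strain|contig|gene_index|protein_id`.
#'
#' @param paths character vector of FASTA files.
#' @return a [proteome_set()].
#' @export
read_proteomes <- function(paths) {
  seqs <- do.call(c, lapply(paths, Biostrings::readAAStringSet))
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad)) {
    stop("malformed FASTA header (want strain|contig|gene_index|protein_id): ",
         names(seqs)[bad[1]])
  }
  records <- data.frame(
    strain_id = vapply(parts, `[`, "", 1),
    contig_id = vapply(parts, `[`, "", 2),
    gene_index = as.integer(vapply(parts, `[`, "", 3)),
    protein_id = vapply(parts, `[`, "", 4),
    stringsAsFactors = FALSE
  )
  names(seqs) <- records$protein_id
  proteome_set(records, seqs)
}

#' Write a proteome set as per-strain FASTA files
#' @param proteomes a [proteome_set()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_proteomes <- function(proteomes, dir) {
  stopifnot(inherits(proteomes, "proteome_set"), !is.null(proteomes$seqs))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- proteomes$records
  paths <- character(0)
  for (s in unique(rec$strain_id)) {
    idx <- rec$strain_id == s
    ss <- proteomes$seqs[rec$protein_id[idx]]
    names(ss) <- sprintf("%s|%s|%d|%s", rec$strain_id[idx], rec$contig_id[idx],
                         rec$gene_index[idx], rec$protein_id[idx])
    path <- file.path(dir, paste0(s, ".faa"))
    Biostrings::writeXStringSet(ss, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' All-vs-all pairwise protein hits
#'
#' The builtin engine shortlists candidate pairs by shared k-mers and scores
#' them with local alignment (BLOSUM62, affine gaps) via
#' `Biostrings::pairwiseAlignment`; identity is identical positions over the
#' alignment length. Hits are reported symmetrically (both query/subject
#' orientations) so downstream best-hit logic can treat them directionally.
#' Use [read_blast_table()] to import hits from an external aligner instead.
#'
#' @param proteomes a [proteome_set()] with sequences.
#' @param k k-mer length of the candidate prefilter.
#' @param min_kmer_hits shared k-mers required before a pair is aligned
#'   (2 suppresses chance single-word matches between unrelated proteins).
#' @param min_score discard alignments scoring below this; the default (100
#'   BLOSUM62 units) keeps homologue-range hits and drops the weak
#'   random-alignment scores that would otherwise create spurious
#'   reciprocal best hits.
#' @param include_self include within-strain (paralog) comparisons; needed
#'   for family building, ignored by BBH.
#' @return data frame of class `pairwise_hits`: query_id, subject_id,
#'   query_strain, subject_strain, identity (%), length (aligned columns),
#'   score.
#' @export
pairwise_hits <- function(proteomes, k = 5L, min_kmer_hits = 2L,
                          min_score = 100, include_self = TRUE) {
  stopifnot(inherits(proteomes, "proteome_set"), !is.null(proteomes$seqs))
  rec <- proteomes$records
  seqs <- proteomes$seqs
  n <- nrow(rec)

  # k-mer prefilter: candidate unordered pairs sharing at least one k-mer
  seq_chr <- as.character(seqs)
  km_list <- lapply(seq_chr, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  kmer <- unlist(km_list, use.names = FALSE)
  prot <- rep.int(seq_len(n), lengths(km_list))
  shared <- kmer %in% kmer[duplicated(kmer)]
  kmer <- kmer[shared]; prot <- prot[shared]
  if (length(kmer) == 0) return(empty_hits())
  by_kmer <- split(prot, kmer)
  pair_mat <- do.call(cbind, lapply(by_kmer, function(idx) {
    if (length(idx) < 2) NULL else utils::combn(sort(idx), 2L)
  }))
  if (is.null(pair_mat) || ncol(pair_mat) == 0) return(empty_hits())
  key <- pair_mat[1, ] * (n + 1) + pair_mat[2, ]
  shared_counts <- table(key)
  keep_keys <- as.numeric(names(shared_counts)[shared_counts >= min_kmer_hits])
  keep <- !duplicated(key) & key %in% keep_keys
  i <- pair_mat[1, keep]; j <- pair_mat[2, keep]
  if (length(i) == 0) return(empty_hits())
  if (!include_self) {
    keep <- rec$strain_id[i] != rec$strain_id[j]
    i <- i[keep]; j <- j[keep]
  }
  if (length(i) == 0) return(empty_hits())

  al <- Biostrings::pairwiseAlignment(
    seqs[i], seqs[j], type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5
  )
  sc <- Biostrings::score(al)
  keep <- sc >= min_score
  if (!any(keep)) return(empty_hits())
  ident <- Biostrings::pid(al, type = "PID1")[keep]
  len <- Biostrings::nchar(al)[keep]
  i <- i[keep]; j <- j[keep]; sc <- sc[keep]
  hits <- data.frame(
    query_id = c(rec$protein_id[i], rec$protein_id[j]),
    subject_id = c(rec$protein_id[j], rec$protein_id[i]),
    query_strain = c(rec$strain_id[i], rec$strain_id[j]),
    subject_strain = c(rec$strain_id[j], rec$strain_id[i]),
    identity = c(ident, ident),
    length = c(len, len),
    score = c(sc, sc),
    stringsAsFactors = FALSE
  )
  class(hits) <- c("pairwise_hits", class(hits))
  hits
}

empty_hits <- function() {
  h <- data.frame(query_id = character(0), subject_id = character(0),
                  query_strain = character(0), subject_strain = character(0),
                  identity = numeric(0), length = integer(0), score = numeric(0),
                  stringsAsFactors = FALSE)
  class(h) <- c("pairwise_hits", class(h))
  h
}

#' Import hits from a 12-column tabular alignment report
#'
#' Parses the standard tab-separated 12-column report (query, subject,
#' percent identity, alignment length, mismatches, gap opens, q.start, q.end,
#' s.start, s.end, e-value, bit score).
#'
#' @param path report file.
#' @param records optional records data frame to fill in strain columns.
#' @return `pairwise_hits` data frame.
#' @export
read_blast_table <- function(path, records = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12)
  if (length(bad)) {
    stop(sprintf("cannot parse 12-column hit report %s at line %d", path, bad[1]))
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(cbind(as.numeric(m[, 3]), as.numeric(m[, 4]),
                                as.numeric(m[, 12])))
  bad <- which(apply(num, 1, function(r) any(is.na(r))))
  if (length(bad)) {
    stop(sprintf("non-numeric identity/length/score in %s at line %d", path, bad[1]))
  }
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    query_strain = NA_character_, subject_strain = NA_character_,
    identity = num[, 1], length = as.integer(num[, 2]), score = num[, 3],
    stringsAsFactors = FALSE
  )
  if (!is.null(records)) {
    hits$query_strain <- records$strain_id[match(hits$query_id, records$protein_id)]
    hits$subject_strain <- records$strain_id[match(hits$subject_id, records$protein_id)]
  }
  class(hits) <- c("pairwise_hits", class(hits))
  hits
}

#' Gene-family clustering parameters (the 50/50 rule)
#'
#' Two genes belong to the same family when pairwise identity is strictly
#' greater than `min_identity` over an alignment covering at least
#' `min_coverage_of_longest` of the longer of the two genes; families are the
#' transitive closure (single linkage) of this relation.
#'
#' @param min_identity percent, strict lower bound (default 50).
#' @param min_coverage_of_longest proportion, inclusive (default 0.5).
#' @return object of class `family_params`.
#' @export
family_params <- function(min_identity = 50, min_coverage_of_longest = 0.5) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_coverage_of_longest > 0, min_coverage_of_longest <= 1)
  structure(list(min_identity = min_identity,
                 min_coverage_of_longest = min_coverage_of_longest),
            class = "family_params")
}

#' Build gene families by the 50/50 rule
#'
#' @param hits `pairwise_hits` table (builtin or imported).
#' @param proteomes a [proteome_set()] (provides the full protein universe
#'   and lengths; lengths may also come with `lengths`).
#' @param params a [family_params()] object.
#' @param lengths optional named vector of protein lengths overriding the
#'   proteome's.
#' @return list of class `gene_families`: membership (protein_id ->
#'   family_id), families summary (family_id, n_genes, n_strains), presence
#'   (strains x families [presence_matrix()]), and the counts pan (families),
#'   core and singleton.
#' @export
build_families <- function(hits, proteomes, params = family_params(),
                           lengths = NULL) {
  rec <- proteomes$records
  if (is.null(lengths)) {
    if (is.null(rec$length)) stop("protein lengths unavailable; pass `lengths`")
    lengths <- stats::setNames(rec$length, rec$protein_id)
  }
  len_q <- lengths[hits$query_id]
  len_s <- lengths[hits$subject_id]
  edge <- hits$identity > params$min_identity &
    hits$length >= params$min_coverage_of_longest * pmax(len_q, len_s)
  g <- igraph::graph_from_data_frame(
    hits[edge, c("query_id", "subject_id"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = rec$protein_id)
  )
  comp <- igraph::components(g)$membership
  fam_id <- sprintf("FAM%05d", match(comp, unique(comp[rec$protein_id])))
  names(fam_id) <- rec$protein_id

  strains <- sort(unique(rec$strain_id))
  fams <- sort(unique(fam_id))
  pres <- matrix(FALSE, length(strains), length(fams),
                 dimnames = list(strains, fams))
  pres[cbind(rec$strain_id, fam_id[rec$protein_id])] <- TRUE
  hitcount <- colSums(pres)
  structure(
    list(
      membership = data.frame(protein_id = rec$protein_id,
                              family_id = unname(fam_id[rec$protein_id]),
                              stringsAsFactors = FALSE),
      families = data.frame(
        family_id = fams,
        n_genes = as.integer(table(fam_id)[fams]),
        n_strains = as.integer(hitcount[fams]),
        stringsAsFactors = FALSE
      ),
      presence = presence_matrix(pres),
      pan = length(fams),
      core = sum(hitcount == length(strains)),
      singleton = sum(hitcount == 1)
    ),
    class = "gene_families"
  )
}

#' @export
print.gene_families <- function(x, ...) {
  cat(sprintf("gene_families: pan %d, core %d, singleton %d\n",
              x$pan, x$core, x$singleton))
  invisible(x)
}

#' Bidirectional best hits, ortholog barcodes and 1:1 groups
#'
#' For proteins p in strain A and q in strain B, (p, q) is a BBH when q is
#' p's unique best-scoring hit in B and p is q's unique best in A; score ties
#' produce no BBH (nongreedy). Every protein receives a presence/absence
#' barcode across strains: its own strain's bit is always set, and strain B's
#' bit is set iff the protein has a BBH in B. 1:1 ortholog groups are sets of
#' one protein per strain forming a full pairwise BBH clique.
#'
#' @param hits `pairwise_hits` with strain columns filled.
#' @param proteomes a [proteome_set()].
#' @return list of class `bbh_result`: barcodes (proteins x strains logical
#'   matrix), pairs (data frame of BBH pairs), groups (list of protein-id
#'   vectors), n_groups.
#' @export
bbh_orthologs <- function(hits, proteomes) {
  rec <- proteomes$records
  strains <- sort(unique(rec$strain_id))
  cross <- hits[hits$query_strain != hits$subject_strain, , drop = FALSE]

  # unique best hit of each protein in each foreign strain (ties -> none)
  key <- paste(cross$query_id, cross$subject_strain)
  ord <- order(key, -cross$score)
  cross <- cross[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  best <- cross[first, , drop = FALSE]
  # tie detection: a second row with the same key and the same score
  nxt <- which(first) + 1L
  tied <- nxt <= nrow(cross) &
    paste(cross$query_id[pmin(nxt, nrow(cross))],
          cross$subject_strain[pmin(nxt, nrow(cross))]) == key[first] &
    cross$score[pmin(nxt, nrow(cross))] == best$score
  best <- best[!tied, , drop = FALSE]

  bmap <- stats::setNames(best$subject_id, paste(best$query_id, best$subject_strain))
  # reciprocity
  back <- bmap[paste(best$subject_id, best$query_strain)]
  recip <- !is.na(back) & back == best$query_id
  pairs <- best[recip, c("query_id", "subject_id", "query_strain",
                         "subject_strain", "score"), drop = FALSE]
  rownames(pairs) <- NULL

  barcodes <- matrix(FALSE, nrow(rec), length(strains),
                     dimnames = list(rec$protein_id, strains))
  barcodes[cbind(rec$protein_id, rec$strain_id)] <- TRUE
  if (nrow(pairs)) {
    barcodes[cbind(pairs$query_id, pairs$subject_strain)] <- TRUE
  }

  # 1:1 groups: start from full-barcode proteins of the first strain and
  # verify the full BBH clique
  bbh_key <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      bbh_key[[paste(pairs$query_id[k], pairs$subject_id[k])]] <- TRUE
    }
  }
  is_bbh <- function(a, b) {
    isTRUE(bbh_key[[paste(a, b)]]) || isTRUE(bbh_key[[paste(b, a)]])
  }
  partner <- stats::setNames(pairs$subject_id,
                             paste(pairs$query_id, pairs$subject_strain))
  groups <- list()
  seed_strain <- strains[1]
  full <- rownames(barcodes)[rowSums(barcodes) == length(strains)]
  seeds <- intersect(rec$protein_id[rec$strain_id == seed_strain], full)
  for (p in seeds) {
    members <- stats::setNames(character(length(strains)), strains)
    members[seed_strain] <- p
    ok <- TRUE
    for (s in setdiff(strains, seed_strain)) {
      q <- partner[paste(p, s)]
      if (is.na(q)) { ok <- FALSE; break }
      members[s] <- q
    }
    if (!ok) next
    for (a in seq_along(strains)) {
      for (b in seq_along(strains)) {
        if (a < b && !is_bbh(members[a], members[b])) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) groups[[length(groups) + 1L]] <- unname(members)
  }

  structure(
    list(barcodes = barcodes, pairs = pairs, groups = groups,
         n_groups = length(groups), strains = strains),
    class = "bbh_result"
  )
}

#' @export
print.bbh_result <- function(x, ...) {
  cat(sprintf("bbh_result: %d BBH pairs, %d 1:1 ortholog groups over %d strains\n",
              nrow(x$pairs), x$n_groups, length(x$strains)))
  invisible(x)
}

#' Count ortholog groups shared exactly by strain groups
#'
#' For each node of a strain hierarchy (a named list of strain-id vectors),
#' counts the barcode rows whose TRUE set equals exactly that node's strain
#' set — the per-box numbers of an icicle plot of shared genes. Pass
#' per-group barcodes to count groups, or per-protein barcodes to count
#' genes.
#'
#' @param barcodes logical matrix (rows = proteins or groups, columns =
#'   strains).
#' @param hierarchy named list; each element a character vector of strain ids.
#' @return named integer vector of counts per node.
#' @export
clade_shared_counts <- function(barcodes, hierarchy) {
  stopifnot(is.list(hierarchy))
  strains <- colnames(barcodes)
  vapply(hierarchy, function(node) {
    stopifnot(all(node %in% strains))
    target <- strains %in% node
    sum(apply(barcodes, 1, function(r) identical(unname(r), target)))
  }, 0L)
}

#' Barcode table as bit strings
#'
#' @param barcodes logical matrix proteins x strains.
#' @return data frame: protein_id, barcode (bit string).
#' @export
barcode_strings <- function(barcodes) {
  data.frame(
    protein_id = rownames(barcodes),
    barcode = apply(barcodes, 1, pattern_string),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
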