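# Operational biosynthetic units (OBUs): predicted biosynthetic pathways
# from different strains are grouped into one unit when most of their genes
# are shared at high identity, and partial (contig-truncated) pathways with
# the same conservation pattern are merged so diversity is not overcounted.

#' OBU grouping parameters
#'
#' Two pathways fall in the same OBU when at least `min_gene_fraction` of the
#' genes of the smaller pathway have a homologue in the other pathway at
#' `min_identity` percent amino-acid identity or better. Both thresholds are
#' inclusive. Defaults: 80% of genes at >= 60% identity.
#'
#' @param min_gene_fraction proportion in (0, 1].
#' @param min_identity percent in (0, 100].
#' @return object of class `obu_params`.
#' @export
obu_params <- function(min_gene_fraction = 0.80, min_identity = 60) {
  stopifnot(min_gene_fraction > 0, min_gene_fraction <= 1,
            min_identity > 0, min_identity <= 100)
  structure(list(min_gene_fraction = min_gene_fraction,
                 min_identity = min_identity),
            class = "obu_params")
}

#' Construct a pathway prediction record
#'
#' @param pathway_id identifier.
#' @param strain_id,contig_id location of the predicted cluster.
#' @param genes character vector of member protein ids (>= 1).
#' @param type_label free-text pathway type (e.g. NRPS, PKS, RiPP).
#' @param partial is the pathway truncated at a contig edge?
#' @return object of class `pathway_prediction`.
#' @export
pathway_prediction <- function(pathway_id, strain_id, contig_id, genes,
                               type_label = "", partial = FALSE) {
  stopifnot(length(genes) >= 1)
  structure(
    list(pathway_id = pathway_id, strain_id = strain_id, contig_id = contig_id,
         genes = genes, type_label = type_label, partial = isTRUE(partial)),
    class = "pathway_prediction"
  )
}

#' Read pathway predictions from TSV
#'
#' Columns: pathway_id, strain_id, contig_id, type_label, partial (0/1),
#' genes (semicolon-separated protein ids).
#'
#' @param path TSV file.
#' @return list of [pathway_prediction()] objects.
#' @export
read_pathways <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("pathway_id", "strain_id", "contig_id", "type_label", "partial", "genes")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("pathway TSV lacks: ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    pathway_prediction(df$pathway_id[i], df$strain_id[i], df$contig_id[i],
                       strsplit(df$genes[i], ";", fixed = TRUE)[[1]],
                       df$type_label[i], df$partial[i] %in% c(1, TRUE, "TRUE"))
  })
}

#' Write pathway predictions to TSV
#' @param pathways list of [pathway_prediction()] objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_pathways <- function(pathways, path) {
  df <- data.frame(
    pathway_id = vapply(pathways, `[[`, "", "pathway_id"),
    strain_id = vapply(pathways, `[[`, "", "strain_id"),
    contig_id = vapply(pathways, `[[`, "", "contig_id"),
    type_label = vapply(pathways, `[[`, "", "type_label"),
    partial = vapply(pathways, function(p) as.integer(p$partial), 0L),
    genes = vapply(pathways, function(p) paste(p$genes, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Do two pathways belong to the same OBU?
#'
#' A gene of the smaller pathway counts as covered when it has at least one
#' hit to a gene of the other pathway at `min_identity` or better (in either
#' hit orientation); one subject gene may cover several queries.
#'
#' @param p1,p2 [pathway_prediction()] objects.
#' @param hits `pairwise_hits` table covering the two gene sets.
#' @param params an [obu_params()] object.
#' @return logical.
#' @export
pathway_pair_same_obu <- function(p1, p2, hits, params = obu_params()) {
  if (length(p1$genes) <= length(p2$genes)) {
    small <- p1$genes; other <- p2$genes
  } else {
    small <- p2$genes; other <- p1$genes
  }
  good <- hits$identity >= params$min_identity &
    ((hits$query_id %in% small & hits$subject_id %in% other) |
     (hits$subject_id %in% small & hits$query_id %in% other))
  covered <- union(
    intersect(hits$query_id[good], small),
    intersect(hits$subject_id[good], small)
  )
  length(covered) >= params$min_gene_fraction * length(small)
}

#' Group pathways into OBUs
#'
#' OBUs are the connected components of the pairwise same-OBU relation
#' (transitive closure: dissimilar pathways can be chained through an
#' intermediate, which mirrors the recursive grouping practice).
#'
#' @param pathways list of [pathway_prediction()] objects.
#' @param hits `pairwise_hits` table.
#' @param params an [obu_params()] object.
#' @param strain_ids full strain universe for the barcodes; defaults to the
#'   strains seen among the pathways.
#' @return list of class `obu_set`; each OBU has obu_id, pathway_ids,
#'   strains, barcode (logical over `strain_ids`), all_partial.
#' @export
group_obus <- function(pathways, hits, params = obu_params(), strain_ids = NULL) {
  stopifnot(length(pathways) >= 1)
  ids <- vapply(pathways, `[[`, "", "pathway_id")
  if (anyDuplicated(ids)) stop("duplicate pathway ids")
  ord <- order(ids)
  pathways <- pathways[ord]; ids <- ids[ord]
  strain_ids <- strain_ids %||% sort(unique(vapply(pathways, `[[`, "", "strain_id")))
  n <- length(pathways)
  edges <- NULL
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (pathway_pair_same_obu(pathways[[i]], pathways[[j]], hits, params)) {
          edges <- rbind(edges, data.frame(a = ids[i], b = ids[j]))
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    edges %||% data.frame(a = character(0), b = character(0)),
    directed = FALSE, vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- groups[order(vapply(groups, min, ""))]
  obus <- lapply(seq_along(groups), function(k) {
    members <- pathways[match(groups[[k]], ids)]
    strains <- unique(vapply(members, `[[`, "", "strain_id"))
    list(
      obu_id = sprintf("OBU%03d", k),
      pathway_ids = groups[[k]],
      strains = strains,
      barcode = strain_ids %in% strains,
      all_partial = all(vapply(members, `[[`, TRUE, "partial"))
    )
  })
  structure(list(obus = obus, strain_ids = strain_ids, params = params),
            class = "obu_set")
}

#' @export
print.obu_set <- function(x, ...) {
  cat(sprintf("obu_set: %d OBUs over %d strains\n",
              length(x$obus), length(x$strain_ids)))
  invisible(x)
}

#' Merge all-partial OBUs into OBUs with the same conservation pattern
#'
#' An OBU consisting solely of partial pathways whose strain barcode is
#' identical to another OBU's barcode is absorbed into that OBU (the first
#' such OBU by id), so split contigs do not inflate the unit count.
#'
#' @param obu_set result of [group_obus()].
#' @return an `obu_set` with merged units.
#' @export
merge_partials <- function(obu_set) {
  stopifnot(inherits(obu_set, "obu_set"))
  obus <- obu_set$obus
  if (length(obus) < 2) return(obu_set)
  codes <- vapply(obus, function(o) pattern_string(o$barcode), "")
  absorbed <- logical(length(obus))
  for (k in seq_along(obus)) {
    if (!obus[[k]]$all_partial) next
    target <- which(codes == codes[k] & seq_along(obus) != k & !absorbed)
    if (length(target)) {
      # prefer a unit that still contains a complete pathway
      np <- target[!vapply(obus[target], `[[`, TRUE, "all_partial")]
      t1 <- if (length(np)) np[1] else target[1]
      obus[[t1]]$pathway_ids <- sort(c(obus[[t1]]$pathway_ids, obus[[k]]$pathway_ids))
      obus[[t1]]$all_partial <- obus[[t1]]$all_partial && obus[[k]]$all_partial
      absorbed[k] <- TRUE
    }
  }
  obus <- obus[!absorbed]
  for (k in seq_along(obus)) obus[[k]]$obu_id <- sprintf("OBU%03d", k)
  obu_set$obus <- obus
  obu_set
}

#' OBU table with barcode strings
#' @param obu_set result of [group_obus()] / [merge_partials()].
#' @return data frame: obu_id, n_pathways, barcode, all_partial, pathway_ids.
#' @export
obu_table <- function(obu_set) {
  data.frame(
    obu_id = vapply(obu_set$obus, `[[`, "", "obu_id"),
    n_pathways = vapply(obu_set$obus, function(o) length(o$pathway_ids), 0L),
    barcode = vapply(obu_set$obus, function(o) pattern_string(o$barcode), ""),
    all_partial = vapply(obu_set$obus, `[[`, TRUE, "all_partial"),
    pathway_ids = vapply(obu_set$obus, function(o) paste(o$pathway_ids, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
}
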