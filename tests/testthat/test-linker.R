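# Barcode pattern matching, adjacency-based cluster calling and the
# permutation null for coincidental matches.

toy_barcodes <- function() {
  strains <- c("S1", "S2", "S3", "S4")
  codes <- rbind(
    g1 = c(TRUE, TRUE, FALSE, FALSE),
    g2 = c(TRUE, TRUE, FALSE, FALSE),
    g3 = c(TRUE, TRUE, TRUE, FALSE),
    g4 = c(TRUE, TRUE, TRUE, TRUE),
    g5 = c(FALSE, TRUE, FALSE, FALSE)
  )
  colnames(codes) <- strains
  codes
}

test_that("pattern matching respects Hamming slack and is monotone", {
  codes <- toy_barcodes()
  expect_setequal(genes_matching_pattern(codes, link_query("1100")),
                  c("g1", "g2"))
  m0 <- genes_matching_pattern(codes, link_query("1100", max_hamming = 0))
  m1 <- genes_matching_pattern(codes, link_query("1100", max_hamming = 1))
  m3 <- genes_matching_pattern(codes, link_query("1100", max_hamming = 3))
  expect_true(all(m0 %in% m1))
  expect_true(all(m1 %in% m3))
  expect_setequal(m3, rownames(codes))  # width-1 slack matches everything
  # all-ones pattern selects the full-barcode genes
  expect_setequal(genes_matching_pattern(codes, link_query("1111")), "g4")
})

test_that("feature pattern matching mirrors the gene direction", {
  pres <- presence_matrix(t(toy_barcodes()))
  expect_setequal(features_matching_pattern(pres, "1100"), c("g1", "g2"))
  expect_setequal(features_matching_pattern(pres, "0100"), "g5")
  f0 <- features_matching_pattern(pres, "1100", 0)
  f1 <- features_matching_pattern(pres, "1100", 1)
  expect_true(all(f0 %in% f1))
})

test_that("cluster calling joins runs across small gaps and ranks by size", {
  rec <- data.frame(
    protein_id = sprintf("p%02d", 1:30),
    strain_id = "S1",
    contig_id = "S1_C1",
    gene_index = 0:29,
    stringsAsFactors = FALSE
  )
  q <- link_query("1100", min_cluster_genes = 3, max_gap = 2)
  # contiguous genes at indices 4..14: one 11-gene cluster
  eleven <- sprintf("p%02d", 5:15)
  cl <- call_clusters(eleven, rec, q)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_genes, 11)
  expect_equal(cl$start_index, 4)
  expect_equal(cl$end_index, 14)
  expect_equal(strsplit(cl$protein_ids, ";")[[1]], eleven)
  # two trios separated by 5 non-matching genes stay separate
  split_runs <- sprintf("p%02d", c(1:3, 9:11))
  cl2 <- call_clusters(split_runs, rec, q)
  expect_equal(nrow(cl2), 2)
  expect_true(all(cl2$n_genes == 3))
  # a gap of 2 is bridged
  bridged <- sprintf("p%02d", c(1:3, 6:8))
  cl3 <- call_clusters(bridged, rec, q)
  expect_equal(nrow(cl3), 1)
  expect_equal(cl3$n_genes, 6)
  # below min size nothing is called; empty input gives an empty frame
  expect_equal(nrow(call_clusters(sprintf("p%02d", 1:2), rec, q)), 0)
  expect_equal(nrow(call_clusters(character(0), rec, q)), 0)
})

test_that("runs never span contigs", {
  rec <- data.frame(
    protein_id = sprintf("p%02d", 1:10),
    strain_id = "S1",
    contig_id = rep(c("S1_C1", "S1_C2"), each = 5),
    gene_index = c(0:4, 0:4),
    stringsAsFactors = FALSE
  )
  cl <- call_clusters(sprintf("p%02d", 1:10), rec,
                      link_query("1100", min_cluster_genes = 3))
  expect_equal(nrow(cl), 2)
  expect_true(all(cl$n_genes == 5))
})

test_that("planted patterns recover the planted genes and features", {
  w <- small_world()
  hits <- small_hits()
  bbh <- bbh_orthologs(hits, w$proteomes)
  cl <- w$ledger$clusters[[1]]
  q <- link_query(cl$strain_pattern)
  genes <- genes_matching_pattern(bbh$barcodes, q)
  planted <- unlist(cl$genes_by_strain, use.names = FALSE)
  expect_true(all(planted %in% genes))
  called <- call_clusters(genes, w$proteomes$records, q)
  top <- called[1, ]
  expect_equal(strsplit(top$protein_ids, ";")[[1]],
               cl$genes_by_strain[[top$strain_id]])
  # reverse direction: planted features match the intact pattern
  feats <- features_matching_pattern(w$ledger$feature_presence,
                                     cl$intact_pattern)
  expect_true(all(cl$linked_features %in% feats))
})

test_that("a broken cluster keeps its genes but loses its features", {
  cfg <- small_config(seed = 8L)
  cfg$planted_clusters[[1]] <- planted_cluster(
    "PCA", n_genes = 5L, strains = 3:5, n_features = 4L,
    halogenated = TRUE, broken_in = 4L
  )
  w <- generate_world(cfg)
  cl <- w$ledger$clusters[[1]]
  expect_equal(cl$strain_pattern, "00111")
  expect_equal(cl$intact_pattern, "00101")
  # genes present in the broken strain, features absent: the two probe
  # directions disagree, which is the diagnostic for a disrupted cluster
  fam_ids <- w$ledger$families$family_id[
    w$ledger$families$cluster_id == "PCA" &
      !is.na(w$ledger$families$cluster_id)]
  pat <- unique(w$ledger$families$pattern[
    w$ledger$families$family_id %in% fam_ids])
  expect_equal(pat, "00111")
  feats <- features_matching_pattern(w$ledger$feature_presence, "00111")
  expect_false(any(cl$linked_features %in% feats))
  feats_intact <- features_matching_pattern(w$ledger$feature_presence, "00101")
  expect_true(all(cl$linked_features %in% feats_intact))
  # the disrupted copy is split across two contigs
  rec <- w$proteomes$records
  broken_genes <- cl$genes_by_strain[["ST04"]]
  expect_equal(length(unique(rec$contig_id[rec$protein_id %in% broken_genes])), 2)
})

test_that("permutation null is calibrated and reproducible", {
  w <- small_world()
  hits <- small_hits()
  bbh <- bbh_orthologs(hits, w$proteomes)
  cl <- w$ledger$clusters[[1]]
  # strict adjacency: on the short synthetic contigs a gap-tolerant run of
  # five is not rare under the null, a strictly contiguous one is
  strict <- link_query(cl$strain_pattern, max_gap = 0)
  res <- match_significance(cl$strain_pattern, bbh$barcodes,
                            w$proteomes$records, query = strict,
                            n_permutations = 499L, seed = 5L)
  expect_equal(res$observed_max_run, 5)
  expect_lte(res$p_value, 0.05)
  res2 <- match_significance(cl$strain_pattern, bbh$barcodes,
                             w$proteomes$records, query = strict,
                             n_permutations = 499L, seed = 5L)
  expect_identical(res$null_max_runs, res2$null_max_runs)
  # a single matching gene is never significant
  lone_pattern <- w$ledger$families$pattern[w$ledger$families$type == "singleton"][1]
  res3 <- match_significance(lone_pattern, bbh$barcodes,
                             w$proteomes$records, n_permutations = 199L,
                             seed = 2L)
  expect_gt(res3$p_value, 0.5)
})
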