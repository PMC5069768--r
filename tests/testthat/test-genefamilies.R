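# Pairwise alignment engine, the 50/50 family rule, bidirectional best
# hits, barcodes and clade-shared counts.

aa_set <- function(...) {
  x <- c(...)
  Biostrings::AAStringSet(x)
}

toy_proteomes <- function(seqs, strains, contigs = NULL, indices = NULL) {
  n <- length(seqs)
  rec <- data.frame(
    protein_id = names(seqs),
    strain_id = strains,
    contig_id = contigs %||% paste0(strains, "_C1"),
    gene_index = indices %||% (seq_len(n) - 1L),
    stringsAsFactors = FALSE
  )
  proteome_set(rec, Biostrings::AAStringSet(seqs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("builtin engine reports exact identity for crafted pairs", {
  set.seed(2)
  base <- paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                         "L","K","M","F","P","S","T","W","Y","V"),
                       100, replace = TRUE), collapse = "")
  x <- strsplit(base, "")[[1]]
  # mismatch 40 interleaved positions (2 of every 5), ends conserved
  flip <- which(seq_len(100) %% 5 %in% c(2, 3))
  y <- x
  y[flip] <- vapply(x[flip], function(a) setdiff(c("A","G","V","L","S"), a)[1], "")
  pr <- toy_proteomes(c(p1 = base, p2 = paste(y, collapse = "")),
                      c("S1", "S2"))
  # mutations every 5 residues leave no shared 5-mers, so shorten the word
  hits <- pairwise_hits(pr, k = 3L, min_score = 10)
  h <- hits[hits$query_id == "p1" & hits$subject_id == "p2", ]
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 60, tolerance = 1e-9)
  expect_equal(h$length, 100)
  # identical sequences: identity 100 over the full length
  pr2 <- toy_proteomes(c(q1 = base, q2 = base), c("S1", "S2"))
  h2 <- pairwise_hits(pr2, min_score = 10)
  h2 <- h2[h2$query_id == "q1", ]
  expect_equal(h2$identity, 100)
  expect_equal(h2$length, 100)
})

test_that("proteins sharing no k-mers produce no hit", {
  pr <- toy_proteomes(
    c(a = strrep("ADADADADAD", 10), b = strrep("VKVKVKVKVK", 10)),
    c("S1", "S2")
  )
  expect_equal(nrow(pairwise_hits(pr, min_score = 10)), 0)
})

test_that("the 50/50 rule is evaluated with a strict identity bound", {
  rec <- data.frame(
    protein_id = c("g1", "g2", "g3", "g4"),
    strain_id = c("S1", "S2", "S1", "S2"),
    contig_id = "c", gene_index = 0:3, stringsAsFactors = FALSE
  )
  pr <- proteome_set(rec)
  lens <- c(g1 = 100, g2 = 100, g3 = 200, g4 = 100)
  mkhits <- function(identity, length, a = "g1", b = "g2") {
    data.frame(query_id = a, subject_id = b, query_strain = "S1",
               subject_strain = "S2", identity = identity,
               length = length, score = 500, stringsAsFactors = FALSE)
  }
  # identity 60 over 80% of the longest -> same family
  fam <- build_families(mkhits(60, 80), pr, lengths = lens)
  expect_equal(fam$membership$family_id[1], fam$membership$family_id[2])
  # identity 60 over only 40% of the longest -> separate
  fam <- build_families(mkhits(60, 40), pr, lengths = lens)
  expect_false(fam$membership$family_id[1] == fam$membership$family_id[2])
  # coverage is measured against the longer sequence
  fam <- build_families(mkhits(60, 90, a = "g3", b = "g4"), pr, lengths = lens)
  expect_false(fam$membership$family_id[3] == fam$membership$family_id[4])
  # identity exactly 50.0 fails the strict bound
  fam <- build_families(mkhits(50, 100), pr, lengths = lens)
  expect_false(fam$membership$family_id[1] == fam$membership$family_id[2])
  expect_equal(fam$pan, 4)
  expect_equal(fam$singleton, 4)
})

test_that("BBH gives all-ones barcodes and full groups on identical proteomes", {
  set.seed(4)
  genes <- vapply(1:3, function(i)
    paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 60, TRUE),
          collapse = ""), "")
  seqs <- character(0)
  strains <- character(0)
  for (s in c("S1", "S2", "S3")) {
    for (g in 1:3) {
      seqs[sprintf("%s_g%d", s, g)] <- genes[g]
      strains <- c(strains, s)
    }
  }
  pr <- toy_proteomes(seqs, strains)
  hits <- pairwise_hits(pr, min_score = 50)
  bbh <- bbh_orthologs(hits, pr)
  expect_equal(bbh$n_groups, 3)
  expect_true(all(rowSums(bbh$barcodes) == 3))
})

test_that("a gene missing from one strain loses that barcode bit and its group", {
  set.seed(9)
  genes <- vapply(1:3, function(i)
    paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 60, TRUE),
          collapse = ""), "")
  seqs <- character(0); strains <- character(0)
  for (s in c("S1", "S2", "S3")) {
    for (g in 1:3) {
      if (s == "S3" && g == 2) next  # S3 lacks gene 2
      seqs[sprintf("%s_g%d", s, g)] <- genes[g]
      strains <- c(strains, s)
    }
  }
  pr <- toy_proteomes(seqs, strains)
  bbh <- bbh_orthologs(pairwise_hits(pr, min_score = 50), pr)
  expect_equal(bbh$n_groups, 2)
  expect_equal(unname(rowSums(bbh$barcodes[c("S1_g2", "S2_g2"), ])), c(2, 2))
  expect_false(bbh$barcodes["S1_g2", "S3"])
})

test_that("exact score ties produce no best hit (nongreedy pairing)", {
  rec <- data.frame(
    protein_id = c("a1", "b1", "b2"),
    strain_id = c("S1", "S2", "S2"),
    contig_id = "c", gene_index = c(0L, 0L, 1L), stringsAsFactors = FALSE
  )
  pr <- proteome_set(rec)
  hits <- data.frame(
    query_id = c("a1", "a1", "b1", "b2"),
    subject_id = c("b1", "b2", "a1", "a1"),
    query_strain = c("S1", "S1", "S2", "S2"),
    subject_strain = c("S2", "S2", "S1", "S1"),
    identity = 90, length = 100, score = c(500, 500, 500, 500),
    stringsAsFactors = FALSE
  )
  bbh <- bbh_orthologs(hits, pr)
  expect_equal(nrow(bbh$pairs), 0)
  expect_false(bbh$barcodes["a1", "S2"])
  expect_true(bbh$barcodes["a1", "S1"])  # own-strain bit always set
})

test_that("BBH pairs are symmetric", {
  hits <- small_hits()
  w <- small_world()
  bbh <- bbh_orthologs(hits, w$proteomes)
  key <- paste(bbh$pairs$query_id, bbh$pairs$subject_id)
  rev <- paste(bbh$pairs$subject_id, bbh$pairs$query_id)
  expect_true(all(rev %in% key))
})

test_that("clade-shared counts match hand enumeration on a toy hierarchy", {
  strains <- c("S1", "S2", "S3", "S4")
  codes <- rbind(
    g1 = c(TRUE, TRUE, TRUE, TRUE),
    g2 = c(TRUE, TRUE, TRUE, TRUE),
    g3 = c(TRUE, TRUE, FALSE, FALSE),
    g4 = c(FALSE, FALSE, TRUE, TRUE),
    g5 = c(TRUE, FALSE, FALSE, FALSE)
  )
  colnames(codes) <- strains
  hier <- list(root = strains, left = c("S1", "S2"), right = c("S3", "S4"),
               s1 = "S1", s4 = "S4")
  counts <- clade_shared_counts(codes, hier)
  expect_equal(unname(counts), c(2L, 1L, 1L, 1L, 0L))
  # all-ones rows count only at the root; singleton rows only at leaves
  expect_equal(unname(clade_shared_counts(codes[1:2, , drop = FALSE], hier)),
               c(2L, 0L, 0L, 0L, 0L))
  expect_equal(unname(clade_shared_counts(codes[5, , drop = FALSE], hier)),
               c(0L, 0L, 0L, 1L, 0L))
})

test_that("external 12-column reports parse and malformed lines are located", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c(
    "p1\tp2\t75.5\t120\t29\t1\t1\t120\t5\t124\t1e-40\t230",
    "p2\tp1\t75.5\t120\t29\t1\t5\t124\t1\t120\t1e-40\t230"
  ), tmp)
  hits <- read_blast_table(tmp)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$identity[1], 75.5)
  expect_equal(hits$score[2], 230)
  writeLines(c("p1\tp2\t75.5\t120", "short\tline"), tmp)
  expect_error(read_blast_table(tmp), "line 1")
})

test_that("planted families and barcodes are recovered exactly", {
  w <- small_world()
  hits <- small_hits()
  fams <- build_families(hits, w$proteomes)
  truth <- split(w$ledger$gene_membership$protein_id,
                 w$ledger$gene_membership$family_id)
  called <- split(fams$membership$protein_id, fams$membership$family_id)
  canon <- function(part) unname(sort(vapply(part, function(g)
    paste(sort(g), collapse = ","), "")))
  expect_identical(canon(called), canon(truth))
  # every barcode equals its family's planted presence pattern
  bbh <- bbh_orthologs(hits, w$proteomes)
  gm <- w$ledger$gene_membership
  fam_pat <- stats::setNames(w$ledger$families$pattern,
                             w$ledger$families$family_id)
  got <- apply(bbh$barcodes[gm$protein_id, ], 1, pattern_string)
  expect_identical(unname(got), unname(fam_pat[gm$family_id]))
  # 1:1 group count equals the number of families intact in every strain
  expect_equal(bbh$n_groups,
               sum(w$ledger$families$pattern ==
                     strrep("1", length(w$strain_ids))))
  # every 1:1 group lies inside a single 50/50 family
  fam_of <- stats::setNames(fams$membership$family_id,
                            fams$membership$protein_id)
  expect_true(all(vapply(bbh$groups, function(g)
    length(unique(fam_of[g])) == 1, TRUE)))
})
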