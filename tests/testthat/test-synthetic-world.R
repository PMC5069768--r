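# The planted-world generator: determinism, ledger consistency, identity
# control and the statistical targets of the emulated collection.

test_that("configuration invariants are enforced", {
  expect_error(world_config(n_strains = 1), "n_strains")
  expect_error(world_config(clade_split = list(1:6, 8:13)), "partition")
  expect_error(world_config(dropout_rate = 1.4), "proportions")
  expect_error(world_config(core_feature_fraction = 0.6,
                            unique_feature_fraction = 0.6), "sum")
  expect_error(
    world_config(planted_clusters = list(
      planted_cluster("X", n_genes = 40, strains = 1:3)
    )),
    "contigs hold only"
  )
  expect_error(world_config(mutation_rate = 0.5), "mutation_rate")
  expect_error(planted_cluster("X", 5, strains = 1:3, broken_in = 9),
               "broken_in")
})

test_that("a fixed seed reproduces the world exactly", {
  w1 <- generate_world(small_config(seed = 17L))
  w2 <- generate_world(small_config(seed = 17L))
  expect_identical(as.character(w1$proteomes$seqs), as.character(w2$proteomes$seqs))
  expect_identical(w1$proteomes$records, w2$proteomes$records)
  expect_identical(w1$features, w2$features)
  expect_identical(w1$ledger$features, w2$ledger$features)
  w3 <- generate_world(small_config(seed = 18L))
  expect_false(identical(w1$features$neutral_mass, w3$features$neutral_mass))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_world(small_config(seed = 5L)))
  expect_identical(runif(1), before)
})

test_that("the ledger is internally consistent", {
  w <- small_world()
  rec <- w$proteomes$records
  gm <- w$ledger$gene_membership
  pres <- w$ledger$family_presence
  # family presence patterns agree with the genes actually emitted
  for (f in colnames(pres)) {
    strains_with <- sort(unique(gm$strain_id[gm$family_id == f]))
    expect_identical(strains_with, rownames(pres)[pres[, f]])
  }
  # for every planted cluster the strains containing all its genes equal
  # the strain pattern, and linked features sit exactly in intact strains
  for (cl in w$ledger$clusters) {
    fam_ids <- w$ledger$families$family_id[
      !is.na(w$ledger$families$cluster_id) &
        w$ledger$families$cluster_id == cl$cluster_id]
    has_all <- apply(pres[, fam_ids, drop = FALSE], 1, all)
    expect_equal(pattern_string(has_all), cl$strain_pattern)
    for (fid in cl$linked_features) {
      expect_equal(pattern_string(w$ledger$feature_presence[, fid]),
                   cl$intact_pattern)
    }
    # cluster genes are adjacent on one contig in intact strains
    intact <- rownames(pres)[parse_pattern(cl$intact_pattern)]
    for (s in intact) {
      genes <- cl$genes_by_strain[[s]]
      sub <- rec[rec$protein_id %in% genes, ]
      expect_equal(length(unique(sub$contig_id)), 1)
      expect_equal(sort(sub$gene_index), seq(min(sub$gene_index),
                                             max(sub$gene_index)))
    }
  }
})

test_that("identity control satisfies the 50/50 rule within, fails across", {
  w <- small_world()
  hits <- small_hits()
  gm <- w$ledger$gene_membership
  fam_of <- stats::setNames(gm$family_id, gm$protein_id)
  lens <- stats::setNames(w$proteomes$records$length,
                          w$proteomes$records$protein_id)
  same_fam <- fam_of[hits$query_id] == fam_of[hits$subject_id]
  rule <- hits$identity > 50 &
    hits$length >= 0.5 * pmax(lens[hits$query_id], lens[hits$subject_id])
  # every within-family pair passes the rule...
  expect_true(all(rule[same_fam]))
  expect_gt(min(hits$identity[same_fam]), 50)
  # ...and no cross-family hit passes it
  expect_false(any(rule[!same_fam]))
  # every within-family pair is actually present in the hit table
  fams <- split(gm$protein_id, gm$family_id)
  n_pairs <- sum(vapply(fams, function(g) choose(length(g), 2), 0))
  expect_equal(sum(same_fam) / 2, n_pairs)
})

test_that("feature composition hits the configured targets over seeds", {
  core_frac <- vapply(1:20, function(s) {
    w <- generate_world(small_config(seed = 300L + s))
    unique_and_shared_fractions(w$ledger$feature_presence)$core_fraction
  }, 0)
  expect_lt(abs(mean(core_frac) - 0.02), 0.015)
})

test_that("default-scale world matches the emulated composition", {
  w <- .world_cache$default_world
  if (is.null(w)) {
    w <- generate_world(world_config(seed = 1L))
    .world_cache$default_world <- w
  }
  fr_gene <- unique_and_shared_fractions(w$ledger$family_presence)
  expect_lt(abs(fr_gene$core_fraction - 0.33), 0.05)
  expect_lt(abs(fr_gene$unique_fraction - 0.25), 0.07)
  fr_feat <- unique_and_shared_fractions(w$ledger$feature_presence)
  expect_lt(abs(fr_feat$core_fraction - 0.02), 0.015)
  expect_lt(abs(fr_feat$unique_fraction - 0.30), 0.05)
  # 40 halogenated features in total (cluster-linked family plus extras)
  expect_equal(sum(w$ledger$features$halogenated), 40)
})

test_that("spectra for identical strain pairs give pan equal to core", {
  # a clonal pair sharing every family: over the pair, pan = core
  cfg <- small_config(seed = 23L)
  w <- generate_world(cfg)
  m <- w$ledger$family_presence
  # construct the duplicated-strain case directly
  dup <- presence_matrix(rbind(A = m[1, ], B = m[1, ]))
  res <- pan_core(dup, c("A", "B"))
  expect_identical(res$pan_curve, res$core_curve)
})

test_that("generate_spectrum honours its contract", {
  scaffold <- cbind(c(100, 150, 220), c(10, 40, 20))
  expect_error(generate_spectrum(200, scaffold), "below the precursor")
  sp <- generate_spectrum(400, scaffold, analogue_shift = 0, n_noise_peaks = 0)
  expect_equal(unname(sp$peaks[, 1]), scaffold[, 1])
  # seeded noise is reproducible
  a <- generate_spectrum(400, scaffold, 0, 4, seed = 11)
  b <- generate_spectrum(400, scaffold, 0, 4, seed = 11)
  expect_identical(a$peaks, b$peaks)
})

test_that("worlds serialise to plain-text artifacts and read back", {
  w <- small_world()
  dir <- file.path(tempdir(), "world_out")
  write_world(w, dir)
  expect_true(file.exists(file.path(dir, "features.csv")))
  expect_true(file.exists(file.path(dir, "ledger.json")))
  expect_true(file.exists(file.path(dir, "config.json")))
  pr <- read_proteomes(list.files(file.path(dir, "proteomes"),
                                  full.names = TRUE))
  expect_equal(nrow(pr$records), nrow(w$proteomes$records))
  ord <- match(w$proteomes$records$protein_id, pr$records$protein_id)
  expect_false(any(is.na(ord)))
  expect_identical(pr$records$contig_id[ord], w$proteomes$records$contig_id)
  sp <- read_mgf(file.path(dir, "spectra.mgf"))
  expect_equal(length(sp), length(w$spectra))
  ftab <- read_feature_table(file.path(dir, "features.csv"))
  expect_equal(nrow(ftab), nrow(w$features))
})
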