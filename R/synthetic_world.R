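# Seeded "planted world" generator. Emulates the statistical structure of a
# 13-strain collection of closely related marine bacteria: two clades (six
# and seven strains), a near-clonal pair sharing almost all gene families,
# a pan-genome that is ~1/3 core and ~1/4 singleton families, a
# pan-metabolome with ~2% core and ~30% unique features, planted
# biosynthetic gene clusters whose strain pattern matches planted metabolite
# families, halogenated masses sitting inside the mass-defect screen window,
# and fragment spectra that form molecular families under the modified
# cosine. Every planted fact is recorded in a ground-truth ledger so each
# downstream stage can be scored.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Describe a planted biosynthetic gene cluster
#'
#' @param cluster_id identifier.
#' @param n_genes genes in the cluster (adjacent on one contig).
#' @param strains strain indices carrying all cluster genes.
#' @param n_features size of the linked molecular family produced by the
#'   cluster (present exactly in the intact strains).
#' @param halogenated do the linked features carry halogen-like mass
#'   defects?
#' @param broken_in subset of `strains` in which the cluster is present but
#'   disrupted (split across two contigs, no linked features).
#' @return object of class `planted_cluster`.
#' @export
planted_cluster <- function(cluster_id, n_genes, strains, n_features = 5L,
                            halogenated = FALSE, broken_in = integer(0)) {
  stopifnot(n_genes >= 1, length(strains) >= 1, n_features >= 0,
            all(broken_in %in% strains))
  structure(
    list(cluster_id = cluster_id, n_genes = as.integer(n_genes),
         strains = sort(unique(as.integer(strains))),
         n_features = as.integer(n_features),
         halogenated = isTRUE(halogenated),
         broken_in = sort(unique(as.integer(broken_in)))),
    class = "planted_cluster"
  )
}

#' Configuration of a synthetic planted world
#'
#' Defaults encode the emulated study conditions at desk scale: 13 strains
#' split 6 + 7 into two clades with one near-clonal pair; a pan-genome whose
#' family composition is about one third core and one quarter singletons;
#' about 300 consensus features per strain of which 2% are core and 30%
#' unique; one 11-gene halogen cluster planted in the 7-strain clade with a
#' 6-member linked molecular family, one 13-gene cluster in three strains;
#' 40 features in total carrying halogen-like mass defects.
#'
#' @param n_strains number of strains (>= 2).
#' @param clade_split list of two integer vectors partitioning the strains.
#' @param clonal_pairs list of strain index pairs forced to share almost all
#'   accessory families.
#' @param n_core_families,n_accessory_families,n_singletons_per_strain
#'   gene-family composition.
#' @param genes_per_contig nominal contig size in genes.
#' @param planted_clusters list of [planted_cluster()] objects.
#' @param features_per_strain target detected features per strain.
#' @param core_feature_fraction,unique_feature_fraction pan-metabolome
#'   composition targets.
#' @param n_halogenated_features total features given halogen-like mass
#'   defects (includes halogenated clusters' linked families).
#' @param blank_features medium-derived features injected into every sample.
#' @param mass_range,rt_range Da / minute intervals for feature generation.
#' @param intensity_lognormal c(mu, sigma) of log intensity.
#' @param dropout_rate probability that a truly produced feature is missed
#'   in one replicate injection.
#' @param n_replicates replicate extracts per strain.
#' @param mutation_rate per-site substitution probability per branch from
#'   the family ancestor (keeps within-family identity near 70%).
#' @param protein_length_range ancestor length interval (residues).
#' @param seed RNG seed; fixed seed gives a byte-identical world.
#' @return object of class `world_config`.
#' @export
world_config <- function(n_strains = 13L,
                         clade_split = list(1:6, 7:13),
                         clonal_pairs = list(c(1L, 2L)),
                         n_core_families = 50L,
                         n_accessory_families = 38L,
                         n_singletons_per_strain = 3L,
                         genes_per_contig = 25L,
                         planted_clusters = list(
                           planted_cluster("CLUSTER_A", n_genes = 11L,
                                           strains = 7:13, n_features = 6L,
                                           halogenated = TRUE),
                           planted_cluster("CLUSTER_B", n_genes = 13L,
                                           strains = 3:5, n_features = 7L)
                         ),
                         features_per_strain = 300L,
                         core_feature_fraction = 0.02,
                         unique_feature_fraction = 0.30,
                         n_halogenated_features = 40L,
                         blank_features = 30L,
                         mass_range = c(150, 900),
                         rt_range = c(0.5, 20),
                         intensity_lognormal = c(mu = 10, sigma = 1.5),
                         dropout_rate = 0.05,
                         n_replicates = 2L,
                         mutation_rate = 0.15,
                         protein_length_range = c(150L, 600L),
                         seed = 1L) {
  cfg <- structure(
    list(n_strains = as.integer(n_strains), clade_split = clade_split,
         clonal_pairs = clonal_pairs,
         n_core_families = as.integer(n_core_families),
         n_accessory_families = as.integer(n_accessory_families),
         n_singletons_per_strain = as.integer(n_singletons_per_strain),
         genes_per_contig = as.integer(genes_per_contig),
         planted_clusters = planted_clusters,
         features_per_strain = as.integer(features_per_strain),
         core_feature_fraction = core_feature_fraction,
         unique_feature_fraction = unique_feature_fraction,
         n_halogenated_features = as.integer(n_halogenated_features),
         blank_features = as.integer(blank_features),
         mass_range = mass_range, rt_range = rt_range,
         intensity_lognormal = intensity_lognormal,
         dropout_rate = dropout_rate, n_replicates = as.integer(n_replicates),
         mutation_rate = mutation_rate,
         protein_length_range = protein_length_range,
         seed = as.integer(seed)),
    class = "world_config"
  )
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  n <- cfg$n_strains
  if (n < 2) stop("n_strains must be >= 2")
  split_all <- sort(unlist(cfg$clade_split))
  if (!identical(as.integer(split_all), seq_len(n))) {
    stop("clade_split must partition strains 1..n_strains exactly once")
  }
  props <- c(cfg$core_feature_fraction, cfg$unique_feature_fraction,
             cfg$dropout_rate)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (cfg$core_feature_fraction + cfg$unique_feature_fraction > 1) {
    stop("core and unique feature fractions must sum to at most 1")
  }
  for (pc in cfg$planted_clusters) {
    if (!inherits(pc, "planted_cluster")) stop("planted_clusters entries must be planted_cluster objects")
    if (any(pc$strains > n)) stop("planted cluster strain index out of range")
    if (pc$n_genes > cfg$genes_per_contig) {
      stop(sprintf("cluster %s has %d genes but contigs hold only %d",
                   pc$cluster_id, pc$n_genes, cfg$genes_per_contig))
    }
  }
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 0.35) {
    stop("mutation_rate must keep within-family identity above the 50% rule; use [0, 0.35]")
  }
  if (cfg$protein_length_range[1] < 30) stop("proteins shorter than 30 aa are not supported")
  if (diff(cfg$mass_range) < 50) stop("mass_range too narrow to place distinguishable features")
  # crude sequence-space feasibility guard
  n_fam <- cfg$n_core_families + cfg$n_accessory_families +
    n * cfg$n_singletons_per_strain + sum(vapply(cfg$planted_clusters, `[[`, 0L, "n_genes"))
  if (n_fam > 20^4) stop("more families requested than distinguishable sequence space")
  invisible(cfg)
}

strain_names <- function(n) sprintf("ST%02d", seq_len(n))

random_protein <- function(len) paste(sample(.AA20, len, replace = TRUE), collapse = "")

mutate_protein <- function(seq, rate) {
  x <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(x)) < rate)
  if (length(hit)) {
    x[hit] <- vapply(x[hit], function(a) sample(setdiff(.AA20, a), 1), "")
  }
  paste(x, collapse = "")
}

# draw a mass whose nearest-integer defect is either inside (halogen-like)
# or safely outside the screening window
draw_mass <- function(halogenated, mass_range, params = mass_defect_params()) {
  nominal <- sample(seq(ceiling(mass_range[1]), floor(mass_range[2]) - 1L), 1)
  if (halogenated) {
    expected <- params$intercept + params$slope * nominal / 100
    defect <- expected + stats::runif(1, -0.8, 0.8) * params$tolerance
  } else {
    defect <- nominal * stats::runif(1, 0.00055, 0.00095)
  }
  nominal + defect
}

#' Generate a planted world
#'
#' Deterministic for a fixed `config$seed`. See [world_config()] for the
#' emulated structure. The returned ledger records every family's strain
#' pattern, every planted cluster's gene and feature identities, and every
#' feature's origin, so downstream recovery can be scored exactly.
#'
#' @param config a [world_config()].
#' @return object of class `planted_world`: list with `config`,
#'   `strain_ids`, `proteomes` (a [proteome_set()]), `pathways` (list of
#'   [pathway_prediction()], emulating external cluster predictions),
#'   `features` (long per-sample table), `blank_features` (long table of
#'   blank samples), `spectra` (list of [fragment_spectrum()]), `ledger`.
#' @export
generate_world <- function(config = world_config()) {
  validate_world_config(config)
  with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  n <- cfg$n_strains
  strains <- strain_names(n)
  clades <- cfg$clade_split

  ## ---- gene-family presence patterns -------------------------------------
  cluster_sizes <- vapply(cfg$planted_clusters, `[[`, 0L, "n_genes")
  cluster_patterns <- lapply(cfg$planted_clusters, function(pc) {
    seq_len(n) %in% pc$strains
  })
  forbidden <- vapply(cluster_patterns, pattern_string, "")

  acc_pattern <- function() {
    for (try in 1:50) {
      clade <- clades[[sample.int(length(clades), 1)]]
      size <- if (length(clade) > 2) sample(2:length(clade), 1) else length(clade)
      members <- sample(clade, size)
      if (stats::runif(1) < 0.3) {
        other <- setdiff(seq_len(n), clade)
        members <- c(members, sample(other, min(length(other), sample(1:2, 1))))
      }
      pat <- seq_len(n) %in% members
      for (cp in cfg$clonal_pairs) {
        if (xor(pat[cp[1]], pat[cp[2]]) && stats::runif(1) < 0.98) {
          pat[cp] <- TRUE
        }
      }
      if (!(pattern_string(pat) %in% forbidden)) return(pat)
    }
    stop("could not draw an accessory pattern distinct from planted clusters")
  }

  fam_rows <- list()
  add_family <- function(type, pattern, cluster_id = NA_character_) {
    fam_rows[[length(fam_rows) + 1L]] <<- list(type = type, pattern = pattern,
                                               cluster_id = cluster_id)
  }
  for (i in seq_len(cfg$n_core_families)) add_family("core", rep(TRUE, n))
  for (i in seq_len(cfg$n_accessory_families)) add_family("accessory", acc_pattern())
  for (s in seq_len(n)) {
    for (i in seq_len(cfg$n_singletons_per_strain)) {
      add_family("singleton", seq_len(n) == s)
    }
  }
  for (ci in seq_along(cfg$planted_clusters)) {
    pc <- cfg$planted_clusters[[ci]]
    for (g in seq_len(pc$n_genes)) {
      add_family("cluster", cluster_patterns[[ci]], pc$cluster_id)
    }
  }
  n_fam <- length(fam_rows)
  fam_ids <- sprintf("TF%04d", seq_len(n_fam))
  fam_presence <- do.call(rbind, lapply(fam_rows, `[[`, "pattern"))
  fam_presence <- t(fam_presence)  # strains x families
  dimnames(fam_presence) <- list(strains, fam_ids)
  fam_df <- data.frame(
    family_id = fam_ids,
    type = vapply(fam_rows, `[[`, "", "type"),
    cluster_id = vapply(fam_rows, `[[`, "", "cluster_id"),
    pattern = apply(fam_presence, 2, pattern_string),
    stringsAsFactors = FALSE, row.names = NULL
  )

  ## ---- protein sequences --------------------------------------------------
  lens <- sample(cfg$protein_length_range[1]:cfg$protein_length_range[2],
                 n_fam, replace = TRUE)
  ancestors <- vapply(lens, random_protein, "")
  # member sequences: per-strain branch from the ancestor
  seq_list <- character(0)
  rec_list <- list()
  counter <- stats::setNames(integer(n), strains)
  for (f in seq_len(n_fam)) {
    for (s in which(fam_presence[, f])) {
      counter[s] <- counter[s] + 1L
      pid <- sprintf("%s_G%04d", strains[s], counter[s])
      seq_list[pid] <- mutate_protein(ancestors[f], cfg$mutation_rate)
      rec_list[[length(rec_list) + 1L]] <- list(
        protein_id = pid, strain_id = strains[s], family_id = fam_ids[f]
      )
    }
  }
  rec <- data.frame(
    protein_id = vapply(rec_list, `[[`, "", "protein_id"),
    strain_id = vapply(rec_list, `[[`, "", "strain_id"),
    family_id = vapply(rec_list, `[[`, "", "family_id"),
    stringsAsFactors = FALSE
  )

  ## ---- genome layout: contigs and gene order ------------------------------
  fam_type <- stats::setNames(fam_df$type, fam_df$family_id)
  fam_cluster <- stats::setNames(fam_df$cluster_id, fam_df$family_id)
  rec$contig_id <- NA_character_
  rec$gene_index <- NA_integer_
  pathway_list <- list()
  cluster_members <- list()  # cluster_id -> list(strain -> protein ids)
  for (s in strains) {
    rows <- which(rec$strain_id == s)
    is_cluster <- fam_type[rec$family_id[rows]] == "cluster"
    free_rows <- rows[!is_cluster]
    order_free <- sample(free_rows)
    contigs <- split(order_free,
                     ceiling(seq_along(order_free) / cfg$genes_per_contig))
    # insert each planted cluster carried by this strain as one block;
    # a contig hosts at most one cluster so blocks never interleave
    used_hosts <- integer(0)
    s_idx <- match(s, strains)
    for (ci in seq_along(cfg$planted_clusters)) {
      pc <- cfg$planted_clusters[[ci]]
      if (!(s_idx %in% pc$strains)) next
      crows <- rows[is_cluster & fam_cluster[rec$family_id[rows]] == pc$cluster_id]
      crows <- crows[order(rec$family_id[crows])]  # stable gene order
      cluster_members[[pc$cluster_id]][[s]] <- rec$protein_id[crows]
      if (s_idx %in% pc$broken_in) {
        # disrupted copy: the block is split across two contigs
        cut <- sample(2:(length(crows) - 1), 1)
        contigs[[length(contigs) + 1L]] <- crows[1:(cut - 1)]
        contigs[[length(contigs) + 1L]] <- crows[cut:length(crows)]
        pathway_list[[length(pathway_list) + 1L]] <- pathway_prediction(
          sprintf("%s_%s_p1", pc$cluster_id, s), s,
          sprintf("%s_C%02d", s, length(contigs) - 1L),
          rec$protein_id[crows[1:(cut - 1)]], type_label = pc$cluster_id,
          partial = TRUE)
        pathway_list[[length(pathway_list) + 1L]] <- pathway_prediction(
          sprintf("%s_%s_p2", pc$cluster_id, s), s,
          sprintf("%s_C%02d", s, length(contigs)),
          rec$protein_id[crows[cut:length(crows)]], type_label = pc$cluster_id,
          partial = TRUE)
      } else {
        # host the block on the largest cluster-free contig, as real
        # biosynthetic clusters sit inside full-size contigs
        free_hosts <- setdiff(seq_along(contigs), used_hosts)
        sizes <- lengths(contigs[free_hosts])
        best <- free_hosts[sizes == max(sizes)]
        host <- best[sample.int(length(best), 1)]
        used_hosts <- c(used_hosts, host)
        at <- sample.int(length(contigs[[host]]) + 1L, 1)
        contigs[[host]] <- append(contigs[[host]], crows, after = at - 1L)
        pathway_list[[length(pathway_list) + 1L]] <- pathway_prediction(
          sprintf("%s_%s", pc$cluster_id, s), s, sprintf("%s_C%02d", s, host),
          rec$protein_id[crows], type_label = pc$cluster_id, partial = FALSE)
      }
    }
    for (k in seq_along(contigs)) {
      rws <- contigs[[k]]
      rec$contig_id[rws] <- sprintf("%s_C%02d", s, k)
      rec$gene_index[rws] <- seq_along(rws) - 1L
    }
  }
  seqs <- Biostrings::AAStringSet(seq_list)
  proteomes <- proteome_set(
    rec[, c("protein_id", "strain_id", "contig_id", "gene_index")], seqs
  )

  ## ---- molecular features -------------------------------------------------
  core_f <- cfg$core_feature_fraction
  uniq_f <- cfg$unique_feature_fraction
  acc_f <- 1 - core_f - uniq_f
  mean_acc_presence <- mean(2:(n - 1)) / n
  per_strain_rate <- core_f + acc_f * mean_acc_presence + uniq_f / n
  pool <- max(10L, round(cfg$features_per_strain / per_strain_rate))
  n_core_feat <- round(core_f * pool)
  n_uniq_feat <- round(uniq_f * pool)
  n_acc_feat <- pool - n_core_feat - n_uniq_feat

  feat_rows <- list()
  used_mass <- numeric(0)
  used_rt <- numeric(0)
  draw_position <- function(halogenated) {
    # enforce separation so feature alignment is unambiguous
    for (try in 1:200) {
      m <- draw_mass(halogenated, cfg$mass_range)
      rt <- stats::runif(1, cfg$rt_range[1], cfg$rt_range[2])
      clash <- abs(used_mass - m) < 0.05 & abs(used_rt - rt) < 0.5
      if (!any(clash)) {
        used_mass <<- c(used_mass, m)
        used_rt <<- c(used_rt, rt)
        return(c(m, rt))
      }
    }
    stop("could not place a feature with the required mass/RT separation")
  }
  add_feature <- function(origin, pattern, halogenated = FALSE,
                          cluster_id = NA_character_) {
    pos <- draw_position(halogenated)
    feat_rows[[length(feat_rows) + 1L]] <<- list(
      origin = origin, pattern = pattern, halogenated = halogenated,
      cluster_id = cluster_id, mass = pos[1], rt = pos[2]
    )
  }

  intact_patterns <- lapply(cfg$planted_clusters, function(pc) {
    seq_len(n) %in% setdiff(pc$strains, pc$broken_in)
  })
  n_cluster_halo <- 0L
  for (ci in seq_along(cfg$planted_clusters)) {
    pc <- cfg$planted_clusters[[ci]]
    if (!any(intact_patterns[[ci]])) next
    for (k in seq_len(pc$n_features)) {
      add_feature("cluster", intact_patterns[[ci]], pc$halogenated, pc$cluster_id)
      if (pc$halogenated) n_cluster_halo <- n_cluster_halo + 1L
    }
  }
  # extra halogenated features confined to the strains of the first
  # halogenated cluster (or arbitrary subsets when none is planted)
  halo_host <- NULL
  for (ci in seq_along(cfg$planted_clusters)) {
    if (cfg$planted_clusters[[ci]]$halogenated && any(intact_patterns[[ci]])) {
      halo_host <- which(intact_patterns[[ci]]); break
    }
  }
  n_extra_halo <- max(0L, cfg$n_halogenated_features - n_cluster_halo)
  for (k in seq_len(n_extra_halo)) {
    host <- halo_host %||% seq_len(n)
    size <- sample.int(length(host), 1)
    add_feature("halogenated", seq_len(n) %in% sample(host, size), TRUE)
  }
  for (k in seq_len(n_core_feat)) add_feature("core", rep(TRUE, n))
  for (k in seq_len(n_acc_feat)) {
    size <- sample(2:(n - 1), 1)
    add_feature("accessory", seq_len(n) %in% sample.int(n, size))
  }
  for (k in seq_len(n_uniq_feat)) {
    add_feature("unique", seq_len(n) == (((k - 1L) %% n) + 1L))
  }
  blank_rows <- list()
  for (k in seq_len(cfg$blank_features)) {
    pos <- draw_position(FALSE)
    blank_rows[[length(blank_rows) + 1L]] <- list(mass = pos[1], rt = pos[2])
  }

  n_feat <- length(feat_rows)
  feat_ids <- sprintf("TM%04d", seq_len(n_feat))
  feat_presence <- t(vapply(feat_rows, `[[`, logical(n), "pattern"))
  feat_presence <- t(feat_presence)  # strains x features
  dimnames(feat_presence) <- list(strains, feat_ids)
  mode_class <- sample(c("both", "positive", "negative"), n_feat,
                       replace = TRUE, prob = c(0.236, 0.701, 0.063))
  base_int <- stats::rlnorm(n_feat, cfg$intensity_lognormal[1],
                            cfg$intensity_lognormal[2])
  feat_df <- data.frame(
    feature_id = feat_ids,
    neutral_mass = vapply(feat_rows, `[[`, 0, "mass"),
    rt = vapply(feat_rows, `[[`, 0, "rt"),
    origin = vapply(feat_rows, `[[`, "", "origin"),
    halogenated = vapply(feat_rows, `[[`, TRUE, "halogenated"),
    cluster_id = vapply(feat_rows, `[[`, "", "cluster_id"),
    mode_class = mode_class,
    base_intensity = base_int,
    pattern = apply(feat_presence, 2, pattern_string),
    stringsAsFactors = FALSE, row.names = NULL
  )

  ## ---- per-sample long tables (with replicate dropout) --------------------
  sample_rows <- list()
  emit <- function(sample_id, strain, repl, mode, ids, masses, rts, ints) {
    if (length(ids) == 0) return()
    sample_rows[[length(sample_rows) + 1L]] <<- data.frame(
      sample_id = sample_id, strain_id = strain, replicate = repl,
      mode = mode, neutral_mass = masses, rt = rts, intensity = ints,
      true_feature = ids, stringsAsFactors = FALSE
    )
  }
  blank_mass <- vapply(blank_rows, `[[`, 0, "mass")
  blank_rt <- vapply(blank_rows, `[[`, 0, "rt")
  blank_ids <- sprintf("BLK%03d", seq_along(blank_rows))
  blank_mode <- sample(c("both", "positive", "negative"),
                       length(blank_rows), replace = TRUE,
                       prob = c(0.5, 0.4, 0.1))
  blank_int <- stats::rlnorm(length(blank_rows), cfg$intensity_lognormal[1],
                             cfg$intensity_lognormal[2] / 2)
  for (s in seq_len(n)) {
    for (r in seq_len(cfg$n_replicates)) {
      sid <- sprintf("%s_R%d", strains[s], r)
      present <- which(feat_presence[s, ])
      kept <- present[stats::runif(length(present)) >= cfg$dropout_rate]
      ints <- feat_df$base_intensity[kept] * exp(stats::rnorm(length(kept), 0, 0.2))
      for (mode in c("positive", "negative")) {
        in_mode <- feat_df$mode_class[kept] %in% c(mode, "both")
        bk_in_mode <- blank_mode %in% c(mode, "both")
        emit(sid, strains[s], r, mode,
             c(feat_ids[kept[in_mode]], blank_ids[bk_in_mode]),
             c(feat_df$neutral_mass[kept[in_mode]], blank_mass[bk_in_mode]),
             c(feat_df$rt[kept[in_mode]], blank_rt[bk_in_mode]),
             c(ints[in_mode],
               blank_int[bk_in_mode] * exp(stats::rnorm(sum(bk_in_mode), 0, 0.2))))
      }
    }
  }
  features_long <- do.call(rbind, sample_rows)
  blank_long <- do.call(rbind, lapply(seq_len(cfg$n_replicates), function(r) {
    do.call(rbind, lapply(c("positive", "negative"), function(mode) {
      bk <- blank_mode %in% c(mode, "both")
      if (!any(bk)) return(NULL)
      data.frame(
        sample_id = sprintf("BLANK_R%d", r), strain_id = "BLANK",
        replicate = r, mode = mode, neutral_mass = blank_mass[bk],
        rt = blank_rt[bk],
        intensity = blank_int[bk] * exp(stats::rnorm(sum(bk), 0, 0.2)),
        true_feature = blank_ids[bk], stringsAsFactors = FALSE
      )
    }))
  }))

  ## ---- fragment spectra ---------------------------------------------------
  spectra <- list()
  for (ci in seq_along(cfg$planted_clusters)) {
    pc <- cfg$planted_clusters[[ci]]
    members <- which(feat_df$cluster_id == pc$cluster_id)
    if (length(members) < 1) next
    base_mass <- min(feat_df$neutral_mass[members])
    n_scaf <- 8L
    scaffold <- cbind(
      mz = sort(stats::runif(n_scaf, 50, base_mass * 0.85)),
      intensity = stats::runif(n_scaf, 30, 100)
    )
    first_strain <- strains[which(intact_patterns[[ci]])[1] %||% pc$strains[1]]
    for (m in members) {
      shift <- feat_df$neutral_mass[m] - base_mass
      spectra[[length(spectra) + 1L]] <- generate_spectrum(
        feat_df$neutral_mass[m], scaffold, analogue_shift = shift,
        n_noise_peaks = 3L, seed = NULL,
        spectrum_id = sprintf("MSMS_%s", feat_df$feature_id[m]),
        strain_id = first_strain, rt = feat_df$rt[m],
        feature_id = feat_df$feature_id[m]
      )
    }
  }
  # unrelated singleton spectra from non-cluster features
  lone <- which(feat_df$origin %in% c("core", "accessory", "unique"))
  lone <- utils::head(lone, 10L)
  for (m in lone) {
    mass <- feat_df$neutral_mass[m]
    scaf <- cbind(mz = sort(stats::runif(7, 50, mass * 0.85)),
                  intensity = stats::runif(7, 30, 100))
    spectra[[length(spectra) + 1L]] <- generate_spectrum(
      mass, scaf, analogue_shift = 0, n_noise_peaks = 3L, seed = NULL,
      spectrum_id = sprintf("MSMS_%s", feat_df$feature_id[m]),
      strain_id = strains[which(feat_presence[, m])[1]], rt = feat_df$rt[m],
      feature_id = feat_df$feature_id[m]
    )
  }

  ## ---- ground-truth ledger ------------------------------------------------
  ledger <- list(
    strain_ids = strains,
    families = fam_df,
    family_presence = presence_matrix(fam_presence),
    gene_membership = rec[, c("protein_id", "strain_id", "family_id")],
    clusters = lapply(seq_along(cfg$planted_clusters), function(ci) {
      pc <- cfg$planted_clusters[[ci]]
      list(cluster_id = pc$cluster_id,
           strain_pattern = pattern_string(cluster_patterns[[ci]]),
           intact_pattern = pattern_string(intact_patterns[[ci]]),
           broken_in = strains[pc$broken_in],
           genes_by_strain = cluster_members[[pc$cluster_id]],
           linked_features = feat_ids[!is.na(feat_df$cluster_id) &
                                        feat_df$cluster_id == pc$cluster_id])
    }),
    features = feat_df,
    feature_presence = presence_matrix(feat_presence),
    blank_ids = blank_ids
  )

  structure(
    list(config = cfg, strain_ids = strains, proteomes = proteomes,
         pathways = pathway_list, features = features_long,
         blank_features = blank_long, spectra = spectra, ledger = ledger),
    class = "planted_world"
  )
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf(paste0(
    "planted_world: %d strains, %d gene families (%d proteins), ",
    "%d features, %d spectra, %d planted clusters\n"),
    length(x$strain_ids), nrow(x$ledger$families),
    nrow(x$proteomes$records), nrow(x$ledger$features), length(x$spectra),
    length(x$ledger$clusters)))
  invisible(x)
}

#' Generate an analogue fragment spectrum from a shared scaffold
#'
#' Members of one molecular family share scaffold fragment peaks; in each
#' analogue the high-mass scaffold peaks (those above 60% of the scaffold's
#' maximum m/z) are shifted by `analogue_shift`, emulating a substituent
#' change that propagates into part of the fragmentation. Modified cosine
#' therefore links analogues: unshifted peaks match directly and shifted
#' peaks match under the precursor-difference offset.
#'
#' @param formula_mass neutral monoisotopic mass of the analogue (Da); the
#'   recorded precursor is its `[M+H]+` ion.
#' @param scaffold_peaks two-column matrix (mz, intensity); all m/z must lie
#'   below `formula_mass`.
#' @param analogue_shift Da added to the high-mass scaffold peaks.
#' @param n_noise_peaks uniform low-intensity noise peaks added.
#' @param seed RNG seed, or `NULL` to draw from the current stream.
#' @param spectrum_id,strain_id,rt,feature_id passed to
#'   [fragment_spectrum()].
#' @return a [fragment_spectrum()].
#' @export
generate_spectrum <- function(formula_mass, scaffold_peaks, analogue_shift = 0,
                              n_noise_peaks = 0L, seed = NULL,
                              spectrum_id = "spec", strain_id = NA_character_,
                              rt = NA_real_, feature_id = NA_character_) {
  scaffold_peaks <- as.matrix(scaffold_peaks)
  if (any(scaffold_peaks[, 1] >= formula_mass)) {
    stop("scaffold peaks must lie below the precursor mass")
  }
  build <- function() {
    mz <- scaffold_peaks[, 1]
    int <- scaffold_peaks[, 2]
    hi <- mz > 0.6 * max(mz)
    mz[hi] <- mz[hi] + analogue_shift
    if (n_noise_peaks > 0) {
      mz <- c(mz, stats::runif(n_noise_peaks, 50, formula_mass))
      int <- c(int, stats::runif(n_noise_peaks, 0.02, 0.08) * max(int))
    }
    fragment_spectrum(spectrum_id, formula_mass + adducts[["[M+H]+"]],
                      cbind(mz, int), charge = 1L, rt = rt,
                      strain_id = strain_id, feature_id = feature_id)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Write a planted world to disk
#'
#' Emits per-strain protein FASTA (headers `strain|contig|gene_index|id`),
#' the long feature and blank tables as CSV, spectra as MGF, pathway
#' predictions as TSV, the ground-truth ledger and the configuration as
#' JSON.
#'
#' @param world a `planted_world`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "planted_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_proteomes(world$proteomes, file.path(dir, "proteomes"))
  utils::write.csv(world$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(world$blank_features, file.path(dir, "blanks.csv"),
                   row.names = FALSE)
  write_mgf(world$spectra, file.path(dir, "spectra.mgf"))
  write_pathways(world$pathways, file.path(dir, "pathways.tsv"))
  ledger <- world$ledger
  ledger$family_presence <- apply(ledger$family_presence, 1, pattern_string)
  ledger$feature_presence <- apply(ledger$feature_presence, 1, pattern_string)
  jsonlite::write_json(ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- world$config
  cfg$planted_clusters <- lapply(cfg$planted_clusters, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
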