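#' Configuration for the synthetic holo-omics cohort
#'
#' Bundles every tunable of the synthetic-cohort generator. The defaults
#' describe the study design the package targets: a genotyped cohort of 298
#' animals at 20,571 variants carrying a moderately heritable rumen taxon
#' (h2 = 0.5) with an oligogenic architecture, a causal chain
#' taxon -> mediator -> phenotype, and three 18-sample (9 efficient vs 9
#' inefficient) omics feature layers with planted differential features.
#'
#' @param n_animals Number of genotyped animals in the causal-chain cohort.
#' @param n_variants Number of simulated biallelic variants.
#' @param maf_range Length-2 numeric, the uniform range minor-allele
#'   frequencies are drawn from; both ends in (0, 0.5].
#' @param n_causal_variants Number of variants with a true effect on the
#'   taxon. Kept deliberately small (oligogenic) so that genome-wide
#'   instrument selection at stringent thresholds has non-trivial power at
#'   cohort scale.
#' @param taxon_h2 Narrow-sense heritability of the (log-scale) taxon
#'   abundance, in [0, 1).
#' @param theta_taxon_to_mediator True effect of the taxon on the mediator.
#' @param delta_mediator_to_phenotype True effect of the mediator on the
#'   phenotype.
#' @param gamma_direct True direct taxon -> phenotype effect that bypasses
#'   the mediator.
#' @param pleiotropy_frac Fraction of causal variants given a direct effect
#'   on the mediator (horizontal pleiotropy); 0 disables it.
#' @param pleiotropy_mean Mean of the pleiotropic direct effects; a nonzero
#'   mean produces directional pleiotropy (a nonzero Egger intercept).
#' @param n_samples_per_group Animals per feed-efficiency group in the
#'   feature-table layers (9 vs 9 by default).
#' @param n_features_per_layer Named integer vector (MTT, MTP, MTB) of
#'   feature counts per omics layer.
#' @param n_differential Planted differentially abundant features per layer
#'   (half shifted up in the efficient group, half down).
#' @param planted_log2fc Absolute log2 fold change of planted features.
#' @param noise_sd Residual SD used throughout: log-scale within-group SD of
#'   feature abundances and noise SD of the mediator/phenotype equations.
#' @param dropout_prob Fraction of the layer's lowest-intensity cells
#'   censored to zero (a detection-limit model of missingness, which
#'   concentrates absences in low-abundance features and gives the
#'   prevalence filter something to act on).
#' @param seed Integer seed; every generator call is deterministic given the
#'   seed and config.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_animals = 298L,
                          n_variants = 20571L,
                          maf_range = c(0.05, 0.5),
                          n_causal_variants = 5L,
                          taxon_h2 = 0.5,
                          theta_taxon_to_mediator = 0.5,
                          delta_mediator_to_phenotype = 0.4,
                          gamma_direct = 0.2,
                          pleiotropy_frac = 0,
                          pleiotropy_mean = 0,
                          n_samples_per_group = 9L,
                          n_features_per_layer = c(MTT = 300L, MTP = 400L, MTB = 150L),
                          n_differential = c(MTT = 20L, MTP = 24L, MTB = 12L),
                          planted_log2fc = 2,
                          noise_sd = 0.5,
                          dropout_prob = 0.05,
                          seed = 1L) {
  cfg <- list(
    n_animals = assert_count(n_animals, "n_animals", min = 2L),
    n_variants = assert_count(n_variants, "n_variants"),
    maf_range = maf_range,
    n_causal_variants = assert_count(n_causal_variants, "n_causal_variants"),
    taxon_h2 = taxon_h2,
    theta_taxon_to_mediator = theta_taxon_to_mediator,
    delta_mediator_to_phenotype = delta_mediator_to_phenotype,
    gamma_direct = gamma_direct,
    pleiotropy_frac = pleiotropy_frac,
    pleiotropy_mean = pleiotropy_mean,
    n_samples_per_group = assert_count(n_samples_per_group,
                                       "n_samples_per_group", min = 2L),
    n_features_per_layer = n_features_per_layer,
    n_differential = n_differential,
    planted_log2fc = planted_log2fc,
    noise_sd = noise_sd,
    dropout_prob = dropout_prob,
    seed = assert_count(seed, "seed", min = 0L)
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (!(is.numeric(cfg$maf_range) && length(cfg$maf_range) == 2L &&
        all(is.finite(cfg$maf_range)) && all(cfg$maf_range > 0) &&
        all(cfg$maf_range <= 0.5) && cfg$maf_range[1] <= cfg$maf_range[2])) {
    hg_abort("`maf_range` must be an increasing pair within (0, 0.5]",
             "invalid_config")
  }
  assert_scalar_number(cfg$taxon_h2, "taxon_h2", 0, 1, strict_upper = TRUE)
  if (cfg$n_causal_variants > cfg$n_variants) {
    hg_abort("`n_causal_variants` cannot exceed `n_variants`", "invalid_config")
  }
  assert_scalar_number(cfg$pleiotropy_frac, "pleiotropy_frac", 0, 1)
  assert_scalar_number(cfg$dropout_prob, "dropout_prob", 0, 1,
                       strict_upper = TRUE)
  assert_scalar_number(cfg$noise_sd, "noise_sd", 0, Inf)
  layers <- c("MTT", "MTP", "MTB")
  for (fld in c("n_features_per_layer", "n_differential")) {
    v <- cfg[[fld]]
    if (!(is.numeric(v) && length(v) == 3L && all(v >= 0) &&
          all(v == floor(v)))) {
      hg_abort(sprintf("`%s` must be three non-negative integers (MTT, MTP, MTB)",
                       fld), "invalid_config")
    }
    if (is.null(names(v)) || !setequal(names(v), layers)) names(v) <- layers
    cfg[[fld]] <- as.integer(v[layers])
    names(cfg[[fld]]) <- layers
  }
  if (any(cfg$n_differential > cfg$n_features_per_layer)) {
    hg_abort("`n_differential` cannot exceed `n_features_per_layer`",
             "invalid_config")
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  cohort: %d animals x %d variants (%d causal, h2 = %.2f)\n",
              x$n_animals, x$n_variants, x$n_causal_variants, x$taxon_h2))
  cat(sprintf("  chain: theta = %.2f, delta = %.2f, gamma = %.2f (ACME = %.3f)\n",
              x$theta_taxon_to_mediator, x$delta_mediator_to_phenotype,
              x$gamma_direct,
              x$theta_taxon_to_mediator * x$delta_mediator_to_phenotype))
  cat(sprintf("  layers: %s features (%s planted), %d v %d samples, seed %d\n",
              paste(x$n_features_per_layer, collapse = "/"),
              paste(x$n_differential, collapse = "/"),
              x$n_samples_per_group, x$n_samples_per_group, x$seed))
  invisible(x)
}

#' Simulate a biallelic genotype panel
#'
#' Draws one minor-allele frequency per variant uniformly from
#' `config$maf_range`, then per-animal allele counts Binomial(2, maf),
#' centred to the -1/0/1 coding used by the association scan (AA = -1,
#' AB = 0, BB = 1, with B the minor allele).
#'
#' @param config A [cohort_config()].
#' @return A list of class `geno_matrix` with elements `geno` (animals x
#'   variants integer matrix in -1/0/1), and `variants` (tibble: variant_id,
#'   chrom, pos, a1, a2, maf_target, maf the realized frequency).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_animals
  m <- config$n_variants
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  geno <- matrix(rbinom(n * m, 2L, rep(maf, each = n)) - 1L, nrow = n, ncol = m)
  ids <- sprintf("var%05d", seq_len(m))
  rownames(geno) <- sprintf("animal%03d", seq_len(n))
  colnames(geno) <- ids
  variants <- tibble::tibble(
    variant_id = ids,
    chrom = ((seq_len(m) - 1L) %% 29L) + 1L,  # 29 bovine autosomes
    pos = seq_len(m) * 1000L,
    a1 = "A", a2 = "B",
    maf_target = maf,
    maf = colMeans(geno + 1L) / 2
  )
  structure(list(geno = geno, variants = variants), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d animals x %d variants (MAF %.3f-%.3f)\n",
              nrow(x$geno), ncol(x$geno), min(x$variants$maf),
              max(x$variants$maf)))
  invisible(x)
}

#' Simulate the causal chain SNPs -> taxon -> mediator -> phenotype
#'
#' The taxon's (log-scale) abundance is a sum of causal-variant effects plus
#' Gaussian noise; effects are drawn N(0,1) and rescaled against the realized
#' genetic-score variance so the in-sample heritability equals
#' `config$taxon_h2`. The mediator is `theta * taxon` plus optional direct
#' (pleiotropic) variant effects on a flagged subset of causal variants, plus
#' noise; the phenotype is `delta * mediator + gamma * taxon` plus noise.
#'
#' @param genos A `geno_matrix` from [simulate_genotypes()].
#' @param config The same [cohort_config()].
#' @return A list of class `causal_chain`: `cohort` (tibble: animal_id,
#'   taxon, mediator, phenotype), `truth` (ground-truth ledger: causal
#'   variant ids and effects, pleiotropic ids and effects, theta, delta,
#'   gamma, acme = theta * delta).
#' @export
simulate_causal_chain <- function(genos, config) {
  stopifnot(inherits(genos, "geno_matrix"), inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  G <- genos$geno
  n <- nrow(G)
  h2 <- config$taxon_h2
  causal_idx <- sort(sample.int(ncol(G), config$n_causal_variants))
  alpha <- rnorm(config$n_causal_variants)
  score <- as.numeric(G[, causal_idx, drop = FALSE] %*% alpha)
  if (h2 > 0 && sd(score) > 0) {
    scl <- sqrt(h2) / sd(score)
    alpha <- alpha * scl
    score <- score * scl
  } else {
    alpha <- alpha * 0
    score <- score * 0
  }
  taxon <- score + rnorm(n, sd = sqrt(1 - h2))

  n_pleio <- round(config$pleiotropy_frac * config$n_causal_variants)
  pleio_idx <- if (n_pleio > 0) causal_idx[seq_len(n_pleio)] else integer(0)
  pleio_eff <- if (n_pleio > 0) {
    rnorm(n_pleio, mean = config$pleiotropy_mean,
          sd = max(abs(config$pleiotropy_mean) / 2, 1e-8))
  } else numeric(0)
  pleio_term <- if (n_pleio > 0) {
    as.numeric(G[, pleio_idx, drop = FALSE] %*% pleio_eff)
  } else 0

  mediator <- config$theta_taxon_to_mediator * taxon + pleio_term +
    rnorm(n, sd = config$noise_sd)
  phenotype <- config$delta_mediator_to_phenotype * mediator +
    config$gamma_direct * taxon + rnorm(n, sd = config$noise_sd)

  truth <- list(
    causal_variant_ids = colnames(G)[causal_idx],
    alpha = setNames(alpha, colnames(G)[causal_idx]),
    pleiotropic_variant_ids = colnames(G)[pleio_idx],
    pleiotropy_effects = setNames(pleio_eff, colnames(G)[pleio_idx]),
    theta = config$theta_taxon_to_mediator,
    delta = config$delta_mediator_to_phenotype,
    gamma = config$gamma_direct,
    acme = config$theta_taxon_to_mediator * config$delta_mediator_to_phenotype
  )
  structure(list(
    cohort = tibble::tibble(animal_id = rownames(G), taxon = taxon,
                            mediator = mediator, phenotype = phenotype),
    truth = truth
  ), class = "causal_chain")
}

# fixed synthetic ontology: plausible rumen taxa and functional vocabularies
synthetic_taxonomy <- function() {
  tibble::tribble(
    ~species, ~family,
    "Selenomonas bovis",            "Selenomonadaceae",
    "Selenomonas ruminantium",      "Selenomonadaceae",
    "Prevotella bryantii",          "Prevotellaceae",
    "Prevotella ruminicola",        "Prevotellaceae",
    "Prevotella brevis",            "Prevotellaceae",
    "Butyrivibrio fibrisolvens",    "Lachnospiraceae",
    "Butyrivibrio proteoclasticus", "Lachnospiraceae",
    "Blautia schinkii",             "Lachnospiraceae",
    "Ruminococcus albus",           "Ruminococcaceae",
    "Ruminococcus flavefaciens",    "Ruminococcaceae",
    "Faecalibacterium prausnitzii", "Ruminococcaceae",
    "Clostridium saccharobutylicum", "Clostridiaceae",
    "Clostridium beijerinckii",     "Clostridiaceae",
    "Ruminobacter amylophilus",     "Succinivibrionaceae",
    "Succinivibrio dextrinosolvens", "Succinivibrionaceae",
    "Fibrobacter succinogenes",     "Fibrobacteraceae",
    "Megasphaera elsdenii",         "Veillonellaceae",
    "Lactobacillus ruminis",        "Lactobacillaceae",
    "Streptococcus equinus",        "Streptococcaceae",
    "Treponema bryantii",           "Treponemataceae"
  )
}

synthetic_categories <- function() {
  list(
    COG = c("G", "E", "C", "F", "H", "I", "K", "N", "T", "P"),
    KEGG = sprintf("ko%05d", c(10, 20, 30, 51, 52, 500, 620, 630, 650, 2030)),
    GO = sprintf("GO:%07d", c(5975, 6096, 6099, 6520, 8152, 9401, 6935,
                              16052, 19682, 46356)),
    domain = sprintf("PF%05d", c(128, 121, 342, 1011, 2666, 515, 1547,
                                 13802, 573, 205))
  )
}

#' Simulate the three 18-sample omics feature layers
#'
#' Generates log-normal abundance tables for the MTT (transcript), MTP
#' (protein), and MTB (metabolite) layers over `2 * n_samples_per_group`
#' samples. A feed-conversion-ratio (FCR) phenotype is drawn per sample and
#' the efficient/inefficient labels are assigned by median split (efficient =
#' lower FCR). Half the planted differential features of each layer are
#' shifted up in the efficient group by `planted_log2fc`, half down. Every
#' feature carries species/family and functional-category annotations from a
#' fixed synthetic ontology; metabolites additionally carry an origin label
#' (microbiota / host / co-metabolism / others) and a spectral-match
#' similarity score straddling 200. Planted metabolites are given qualifying
#' origins and similarity scores so the ground-truth MTB group is well
#' defined.
#'
#' @param config A [cohort_config()].
#' @return A list of class `feature_layers`: `tables` (named list of wide
#'   feature tibbles), `annotations` (named list of annotation tibbles),
#'   `samples` (tibble: sample_id, group, fcr), and `truth` (planted
#'   differential ids and directions per layer plus the expected
#'   functional-group species sets).
#' @export
simulate_feature_tables <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 2L)
  n_per <- config$n_samples_per_group
  n_samp <- 2L * n_per
  sample_ids <- sprintf("cow%02d", seq_len(n_samp))
  fcr <- rnorm(n_samp, mean = 6, sd = 1)
  group <- ifelse(rank(fcr, ties.method = "first") <= n_per,
                  "efficient", "inefficient")
  samples <- tibble::tibble(sample_id = sample_ids, group = group, fcr = fcr)

  taxa <- synthetic_taxonomy()
  cats <- synthetic_categories()
  layers <- c("MTT", "MTP", "MTB")
  tables <- list()
  annotations <- list()
  truth_diff <- list()
  truth_species <- list()

  for (layer in layers) {
    p <- config$n_features_per_layer[[layer]]
    n_de <- config$n_differential[[layer]]
    ids <- sprintf("%s_%04d", tolower(layer), seq_len(p))
    base <- rnorm(p, mean = 8, sd = 1.5)          # log-scale baseline
    logab <- matrix(rnorm(p * n_samp, mean = base, sd = config$noise_sd),
                    nrow = p, ncol = n_samp)
    de_idx <- if (n_de > 0) sample.int(p, n_de) else integer(0)
    up_idx <- de_idx[seq_len(floor(n_de / 2))]
    dn_idx <- setdiff(de_idx, up_idx)
    eff <- group == "efficient"
    shift <- config$planted_log2fc * log(2)
    if (length(up_idx)) logab[up_idx, eff] <- logab[up_idx, eff] + shift
    if (length(dn_idx)) logab[dn_idx, eff] <- logab[dn_idx, eff] - shift
    ab <- exp(logab)
    if (config$dropout_prob > 0) {
      # detection-limit censoring: the lowest-intensity cells of the layer
      # fall below the limit of detection and are recorded as absent, as in
      # MS-based quantification (missingness concentrates in low-abundance
      # features rather than striking uniformly)
      lod <- quantile(ab, config$dropout_prob)
      ab[ab < lod] <- 0
    }
    dimnames(ab) <- list(ids, sample_ids)
    tables[[layer]] <- matrix_ft(ab)

    sp_idx <- sample.int(nrow(taxa), p, replace = TRUE)
    if (n_de > 0) {
      # planted features concentrate in a small guild of species with at
      # least two supporting features each: phenotype-linked functions
      # cluster in a handful of taxa, and functional redundancy means every
      # guild member carries the signal in several features
      n_up <- length(up_idx)
      guild <- sample.int(nrow(taxa), max(2L, floor(max(n_up, 1) / 2)))
      if (length(up_idx)) sp_idx[up_idx] <- rep_len(guild, length(up_idx))
      if (length(dn_idx)) sp_idx[dn_idx] <- rep_len(guild, length(dn_idx))
    }
    categories <- vapply(seq_len(p), function(i) {
      paste(c(sample(cats$COG, 1L), sample(cats$KEGG, 1L),
              sample(cats$GO, 1L), sample(cats$domain, 1L)),
            collapse = ";")
    }, character(1))
    ann <- tibble::tibble(
      feature_id = ids,
      species = taxa$species[sp_idx],
      family = taxa$family[sp_idx],
      categories = categories
    )
    if (layer == "MTB") {
      origin_pool <- c("microbiota", "host", "co-metabolism", "others")
      # class proportions mirroring a typical rumen metabolome origin split
      origin <- sample(origin_pool, p, replace = TRUE,
                       prob = c(0.18, 0.02, 0.40, 0.40))
      similarity <- runif(p, 50, 800)
      # planted metabolites must be recoverable by the full filter chain
      origin[de_idx] <- sample(c("microbiota", "co-metabolism"),
                               length(de_idx), replace = TRUE)
      similarity[de_idx] <- runif(length(de_idx), 250, 800)
      ann$origin <- origin
      ann$similarity <- similarity
    }
    annotations[[layer]] <- ann

    truth_diff[[layer]] <- tibble::tibble(
      feature_id = ids[de_idx],
      direction = ifelse(ids[de_idx] %in% ids[up_idx], "up", "down")
    )
    truth_species[[layer]] <- sort(unique(ann$species[up_idx]))
  }

  truth <- list(
    differential = truth_diff,
    group_species = truth_species,
    planted_log2fc = config$planted_log2fc
  )
  structure(list(tables = tables, annotations = annotations,
                 samples = samples, truth = truth),
            class = "feature_layers")
}

#' Simulate the full synthetic cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_causal_chain()], and [simulate_feature_tables()] under one
#' config, merging the truth ledgers.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with `genotypes`, `cohort`,
#'   `tables`, `annotations`, `samples`, `truth`, and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  genos <- simulate_genotypes(config)
  chain <- simulate_causal_chain(genos, config)
  layers <- simulate_feature_tables(config)
  truth <- c(chain$truth, layers$truth)
  structure(list(genotypes = genos, cohort = chain$cohort,
                 tables = layers$tables, annotations = layers$annotations,
                 samples = layers$samples, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  print(x$config)
  invisible(x)
}

#' Write genotypes as PLINK .ped/.map text files
#'
#' Whitespace-delimited PLINK pedigree dialect with alleles coded A/B
#' (A = major, B = minor); `-1/0/1` map to `A A`, `A B`, `B B`.
#'
#' @param genos A `geno_matrix`.
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return The two file paths, invisibly.
#' @export
write_plink <- function(genos, prefix) {
  stopifnot(inherits(genos, "geno_matrix"))
  map <- genos$variants
  map_lines <- sprintf("%d %s 0 %d", map$chrom, map$variant_id, map$pos)
  writeLines(map_lines, paste0(prefix, ".map"))
  allele_pair <- c("A A", "A B", "B B")  # index by geno + 2
  G <- genos$geno
  ped_lines <- vapply(seq_len(nrow(G)), function(i) {
    paste(c(rownames(G)[i], rownames(G)[i], "0", "0", "0", "-9",
            allele_pair[G[i, ] + 2L]), collapse = " ")
  }, character(1))
  writeLines(ped_lines, paste0(prefix, ".ped"))
  invisible(paste0(prefix, c(".ped", ".map")))
}

#' Read genotypes from PLINK .ped/.map text files
#'
#' Inverse of [write_plink()]: alleles A/B are translated back to the
#' -1/0/1 coding (B = minor/effect allele). `0 0` becomes `NA`.
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @return A `geno_matrix`.
#' @export
read_plink <- function(prefix) {
  map_lines <- strsplit(readLines(paste0(prefix, ".map")), "[ \t]+")
  variants <- tibble::tibble(
    variant_id = vapply(map_lines, `[[`, character(1), 2L),
    chrom = as.integer(vapply(map_lines, `[[`, character(1), 1L)),
    pos = as.integer(vapply(map_lines, `[[`, character(1), 4L)),
    a1 = "A", a2 = "B"
  )
  ped <- strsplit(readLines(paste0(prefix, ".ped")), "[ \t]+")
  m <- nrow(variants)
  geno <- matrix(NA_integer_, nrow = length(ped), ncol = m)
  ids <- character(length(ped))
  for (i in seq_along(ped)) {
    f <- ped[[i]]
    if (length(f) != 6L + 2L * m) {
      hg_abort(sprintf(".ped row %d has %d fields, expected %d", i,
                       length(f), 6L + 2L * m), "format_error")
    }
    ids[i] <- f[2L]
    a <- f[seq(7L, length(f), by = 2L)]
    b <- f[seq(8L, length(f), by = 2L)]
    g <- (a == "B") + (b == "B") - 1L
    g[a == "0" | b == "0"] <- NA_integer_
    geno[i, ] <- g
  }
  rownames(geno) <- ids
  colnames(geno) <- variants$variant_id
  variants$maf <- colMeans(geno + 1L, na.rm = TRUE) / 2
  structure(list(geno = geno, variants = variants), class = "geno_matrix")
}

#' Write genotypes as a minimal VCF (v4.2, GT only)
#'
#' @param genos A `geno_matrix`.
#' @param path Output path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genos, path) {
  stopifnot(inherits(genos, "geno_matrix"))
  G <- genos$geno
  v <- genos$variants
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(G)), function(j) {
    gt <- gt_codes[G[, j] + 2L]
    gt[is.na(gt)] <- "./."
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], "A", "T", ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses GT fields with \pkg{vcfR}; alternate-allele dosage 0/1/2 is centred
#' to -1/0/1.
#'
#' @param path Path to a VCF file.
#' @return A `geno_matrix`.
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean == "0/1" | clean == "1/0"] <- 1L
  dose[clean == "1/1"] <- 2L
  geno <- t(dose) - 1L
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  variants <- tibble::tibble(
    variant_id = fix$ID,
    chrom = suppressWarnings(as.integer(fix$CHROM)),
    pos = as.integer(fix$POS),
    a1 = fix$REF, a2 = fix$ALT,
    maf = colMeans(geno + 1L, na.rm = TRUE) / 2
  )
  colnames(geno) <- variants$variant_id
  structure(list(geno = geno, variants = variants), class = "geno_matrix")
}

#' Export a full synthetic cohort to plain-text files
#'
#' Writes the PLINK pair, feature-table and annotation TSVs, the phenotype
#' TSV (sample, FCR, group), the cohort trait TSV, and the JSON truth ledger
#' into a directory. Output bytes are deterministic given the cohort.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  write_plink(cohort$genotypes, file.path(dir, "genotypes"))
  paths["ped"] <- file.path(dir, "genotypes.ped")
  paths["map"] <- file.path(dir, "genotypes.map")
  for (layer in names(cohort$tables)) {
    p <- file.path(dir, sprintf("%s_abundance.tsv", tolower(layer)))
    write_feature_table(cohort$tables[[layer]], p)
    paths[paste0(layer, "_table")] <- p
    pa <- file.path(dir, sprintf("%s_annotations.tsv", tolower(layer)))
    readr::write_tsv(cohort$annotations[[layer]], pa)
    paths[paste0(layer, "_annotations")] <- pa
  }
  pheno <- file.path(dir, "phenotype.tsv")
  readr::write_tsv(cohort$samples, pheno)
  paths["phenotype"] <- pheno
  traits <- file.path(dir, "cohort_traits.tsv")
  readr::write_tsv(cohort$cohort, traits)
  paths["traits"] <- traits
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["truth"] <- truth
  invisible(paths)
}
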