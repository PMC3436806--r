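## Synthetic exome-capture cohorts: Hardy-Weinberg CNV genotypes, a
## logistic disease model, and per-base depths with latent-factor batch
## structure, GC sensitivity and overdispersed counting noise -- so every
## pipeline stage is testable without external data.
##
## The technical-noise model is hierarchical, mirroring how capture
## experiments actually misbehave:
##   * a few cohort-wide latent factors (reagent lots, hybridization
##     chemistry, processing waves) with decaying strengths -- the low-rank
##     structure global PCs can find and remove;
##   * iid per-(capture-array, region) effects -- arrays hold two samples,
##     so this is a high-dimensional noise floor no small number of PCs can
##     absorb, and it is what keeps any single region's own depth pattern
##     from surfacing as a global PC;
##   * iid per-(sample, region) capture-efficiency noise -- the unclustered
##     residual that dominates once factors are projected out;
##   * a per-base capture profile shared across samples within each region
##     -- the covariance-of-shape signal the local first PC feeds on;
##   * negative-binomial counting noise per base.
## Case-control confounding enters through processing waves: with
## probability `batch_phenotype_confounding` a sample is processed in its
## phenotype's wave, arrays are filled within wave, and wave shifts the
## loadings of the leading factors.

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline targets: a psoriasis-
#' scale case-control cohort (700 cases, 800 controls) sequenced to
#' ~15-fold exome coverage on two-sample capture arrays, with a common
#' deletion of allele frequency 0.6 and odds ratio 1.38 as the positive
#' control.
#'
#' @param n_case,n_control cohort sizes.
#' @param n_regions number of capture regions.
#' @param region_length_bp capture-region length in bp (default 200).
#' @param causal_region_ids region ids carrying the deletion (possibly
#'   empty). The first causal region's genotypes drive the phenotype.
#' @param deletion_allele_freq deletion allele frequency q; genotypes are
#'   Hardy-Weinberg draws with P(CN=0) = q^2, P(CN=1) = 2q(1-q),
#'   P(CN=2) = (1-q)^2.
#' @param odds_ratio disease odds ratio per deletion allele.
#' @param mean_depth_range fold-coverage range samples are drawn from
#'   uniformly (default 12-18, centred on 15x).
#' @param batch_count number of capture arrays; `NULL` (default) gives
#'   two samples per array.
#' @param n_factors number of latent technical factors (default 10).
#' @param batch_effect_sd log-scale strength of the latent factors; factor
#'   f has strength `batch_effect_sd / sqrt(f)` (default 0.1, ~10% depth
#'   swings on the leading factor).
#' @param array_noise_sd sd of the iid per-(array, region) log-depth
#'   effect (default 0.03).
#' @param sample_region_sd sd of the iid per-(sample, probe) log-depth
#'   capture-efficiency noise (default 0.15); probes are
#'   `region_length_bp` wide, so a one-probe capture region carries the
#'   full sd while a multi-kb locus averages it across its probes.
#' @param batch_phenotype_confounding probability in `[0, 1]` that a
#'   sample is processed in its phenotype's wave (cases wave 1, controls
#'   wave 2) rather than a random wave. Wave shifts the loadings of the
#'   three leading factors, so confounding is low-rank and removable.
#' @param gc_effect_strength per-sample GC sensitivity scale; sample k's
#'   depth is multiplied by `exp(gamma_k g(gc))` with `g` a quadratic
#'   peaking at mid GC and `gamma_k` centred on the sample's wave sign, so
#'   a confounded cohort shows GC-localized spurious association.
#' @param profile_sd sd of the per-base log-normal capture-efficiency
#'   profile within each region (default 0.3); shared across samples, it
#'   is what lets a region's first PC recover per-sample relative depth
#'   from the covariance of shape.
#' @param overdispersion negative-binomial overdispersion phi
#'   (variance = mu + phi mu^2); 0 gives Poisson counts.
#' @param seed integer seed; identical config + seed reproduce the cohort
#'   exactly.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_case = 700L, n_control = 800L, n_regions = 2000L,
                       region_length_bp = 200L,
                       causal_region_ids = character(0),
                       deletion_allele_freq = 0.6, odds_ratio = 1.38,
                       mean_depth_range = c(12, 18), batch_count = NULL,
                       n_factors = 10L, batch_effect_sd = 0.1,
                       array_noise_sd = 0.03, sample_region_sd = 0.15,
                       batch_phenotype_confounding = 0,
                       gc_effect_strength = 0, profile_sd = 0.3,
                       overdispersion = 0.15, seed = 1L) {
  n <- n_case + n_control
  if (is.null(batch_count)) batch_count <- as.integer(ceiling(n / 2))
  stopifnot(n >= 2, n_regions >= 1, region_length_bp >= 1,
            deletion_allele_freq >= 0, deletion_allele_freq <= 1,
            odds_ratio > 0, length(mean_depth_range) == 2,
            all(mean_depth_range > 0), batch_count >= 1, batch_count <= n,
            n_factors >= 1, batch_effect_sd >= 0, array_noise_sd >= 0,
            sample_region_sd >= 0, batch_phenotype_confounding >= 0,
            batch_phenotype_confounding <= 1, gc_effect_strength >= 0,
            profile_sd >= 0, overdispersion >= 0)
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_regions = as.integer(n_regions),
                 region_length_bp = as.integer(region_length_bp),
                 causal_region_ids = as.character(causal_region_ids),
                 deletion_allele_freq = deletion_allele_freq,
                 odds_ratio = odds_ratio,
                 mean_depth_range = as.numeric(mean_depth_range),
                 batch_count = as.integer(batch_count),
                 n_factors = as.integer(n_factors),
                 batch_effect_sd = batch_effect_sd,
                 array_noise_sd = array_noise_sd,
                 sample_region_sd = sample_region_sd,
                 batch_phenotype_confounding = batch_phenotype_confounding,
                 gc_effect_strength = gc_effect_strength,
                 profile_sd = profile_sd,
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Hardy-Weinberg copy-number genotypes for a biallelic deletion
#'
#' @param freq deletion allele frequency q.
#' @param n number of samples.
#' @return integer copy numbers in `{0, 1, 2}` (0 = homozygous deletion).
#' @export
simulate_genotypes <- function(freq, n) {
  stopifnot(freq >= 0, freq <= 1)
  sample(c(0L, 1L, 2L), n, replace = TRUE,
         prob = c(freq^2, 2 * freq * (1 - freq), (1 - freq)^2))
}

#' Case-control phenotypes under a per-allele logistic disease model
#'
#' Case probability follows `logit p = alpha + log(OR) * a` with `a` the
#' deletion allele count (2 - CN). The intercept is tuned by root finding
#' so the expected case count matches the target, then whole phenotype
#' vectors are drawn until the case count matches exactly (the
#' conditional case-control distribution).
#'
#' @param genotypes copy numbers in `{0, 1, 2}`.
#' @param odds_ratio per-allele disease odds ratio.
#' @param n_case required number of cases.
#' @param max_tries rejection cap.
#' @return 0/1 phenotype vector with exactly `n_case` ones.
#' @export
simulate_phenotypes <- function(genotypes, odds_ratio, n_case,
                                max_tries = 10000L) {
  n <- length(genotypes)
  if (n_case < 0 || n_case > n) stop("unattainable case count ", n_case)
  if (n_case == 0L) return(rep(0L, n))
  if (n_case == n) return(rep(1L, n))
  a <- 2L - genotypes
  alpha <- uniroot(function(al)
    sum(plogis(al + log(odds_ratio) * a)) - n_case,
    interval = c(-40, 40))$root
  p <- plogis(alpha + log(odds_ratio) * a)
  for (i in seq_len(max_tries)) {
    y <- rbinom(n, 1L, p)
    if (sum(y) == n_case) return(y)
  }
  stop("could not reach exact case count in ", max_tries, " draws")
}

## Quadratic GC response peaking at mid GC content: +1 at gc = 0.5,
## 0 at gc = 0.25 and 0.75, negative at the extremes.
gc_response <- function(gc) 1 - ((gc - 0.5) / 0.25)^2

## Wave shift applied to the loadings of the leading factors of a
## confounded cohort (log-depth scale, before the per-factor strength).
CONFOUND_SHIFT <- 0.2
N_CONFOUNDED_FACTORS <- 3L

## Draw the persistent sample-level technical state: waves, capture
## arrays (filled within wave), factor loadings with wave shift, and
## per-sample GC sensitivity.
sim_factor_model <- function(phenotype, config) {
  n <- length(phenotype)
  wave <- ifelse(runif(n) < config$batch_phenotype_confounding,
                 ifelse(phenotype == 1L, 1L, 2L),
                 sample(1:2, n, replace = TRUE))
  ## fill arrays within wave so confounded arrays are wave-pure
  per_array <- ceiling(n / config$batch_count)
  ord <- order(wave, runif(n))
  batch <- integer(n)
  batch[ord] <- rep(seq_len(config$batch_count), each = per_array,
                    length.out = n)
  array_wave <- vapply(seq_len(config$batch_count), function(b)
    as.integer(round(mean(wave[batch == b]))), integer(1))
  wave_sign <- ifelse(array_wave == 1L, 1, -1)
  loadings <- matrix(rnorm(config$batch_count * config$n_factors),
                     config$batch_count, config$n_factors)
  shift_f <- seq_len(config$n_factors) <= N_CONFOUNDED_FACTORS
  has_confounding <- config$batch_phenotype_confounding > 0
  if (has_confounding && any(shift_f)) {
    loadings[, shift_f] <- loadings[, shift_f] +
      CONFOUND_SHIFT * wave_sign /
        sqrt(seq_len(config$n_factors))[col(loadings[, shift_f, drop = FALSE])]
  }
  gamma <- config$gc_effect_strength *
    (ifelse(wave == 1L, 1, -1) * as.numeric(has_confounding) +
       0.5 * rnorm(n))
  list(wave = wave, batch = batch, loadings = loadings, gamma = gamma)
}

## Per-(sample, region) log-scale technical effects for a set of regions:
## factor part + per-array noise + per-sample noise + GC response.
sim_log_effects <- function(regions, batch, fm, config) {
  r <- nrow(regions)
  n <- length(batch)
  strengths <- config$batch_effect_sd / sqrt(seq_len(config$n_factors))
  profiles <- matrix(rnorm(config$n_factors * r), config$n_factors, r)
  eff <- fm$loadings[batch, , drop = FALSE] %*% (strengths * profiles)
  eff <- eff + matrix(rnorm(config$batch_count * r,
                            sd = config$array_noise_sd),
                      config$batch_count, r)[batch, , drop = FALSE]
  eff <- eff + matrix(rnorm(n * r, sd = config$sample_region_sd), n, r)
  eff + outer(fm$gamma, gc_response(regions$gc_fraction))
}

#' Per-base depth matrices for a set of regions
#'
#' Each region is tiled into capture probes of `region_length_bp` (a scan
#' region is a single probe; a multi-kb locus spans many). All log-scale
#' technical effects -- latent factors, per-array noise, per-(sample,
#' probe) capture noise, GC response -- are drawn at probe resolution, so
#' wide loci average them across probes exactly as real capture data do.
#' Expected depth of sample k at base j is
#' `mean_depth_k * (CN_k / 2) * exp(effects[k, probe_j]) * profile_j`
#' with CN/2 = 1 at non-causal regions and `profile` the per-base capture
#' profile (mean 1, shared across samples). Counts are negative-binomial
#' with the configured overdispersion (Poisson when 0).
#'
#' @param regions region data.frame with `region_id`, `start`, `end`,
#'   `gc_fraction`.
#' @param manifest data.frame with `sample_id`, `batch`, `mean_depth`.
#' @param truth_cn named-by-region list of per-sample copy numbers at
#'   causal regions (others assumed CN = 2).
#' @param config a [sim_config()].
#' @param factor_model persistent technical state of the cohort (waves,
#'   arrays, factor loadings, GC sensitivities); a fresh unconfounded one
#'   is drawn when omitted.
#' @return named list (by region_id) of M x N integer matrices.
#' @export
simulate_depth <- function(regions, manifest, truth_cn, config,
                           factor_model = NULL) {
  n <- nrow(manifest)
  r <- nrow(regions)
  if (is.null(factor_model)) {
    factor_model <- sim_factor_model(rep(0L, n), config)
  }
  depth <- vector("list", r)
  names(depth) <- regions$region_id
  for (i in seq_len(r)) {
    m <- regions$end[i] - regions$start[i]
    probe_len <- config$region_length_bp
    n_probe <- as.integer(ceiling(m / probe_len))
    probes <- data.frame(gc_fraction = rep(regions$gc_fraction[i], n_probe))
    eff <- sim_log_effects(probes, factor_model$batch, factor_model, config)
    cn_factor <- rep(1, n)
    if (regions$region_id[i] %in% names(truth_cn)) {
      cn_factor <- truth_cn[[regions$region_id[i]]] / 2
    }
    ## per-base capture-efficiency profile, shared across samples
    profile <- exp(rnorm(m, sd = config$profile_sd))
    profile <- profile / mean(profile)
    seg <- rep(seq_len(n_probe), each = probe_len, length.out = m)
    mu <- profile * t(exp(eff))[seg, , drop = FALSE]
    mu <- sweep(mu, 2L, manifest$mean_depth * cn_factor, "*")
    mu <- as.vector(mu)
    counts <- if (config$overdispersion > 0) {
      rnbinom(m * n, mu = mu, size = 1 / config$overdispersion)
    } else {
      rpois(m * n, lambda = mu)
    }
    mat <- matrix(as.integer(counts), m, n)
    colnames(mat) <- manifest$sample_id
    depth[[i]] <- mat
  }
  depth
}

#' Simulate a full exome-capture case-control cohort
#'
#' Draws genotypes, phenotypes, processing waves, capture arrays, latent
#' technical factors and per-base depths under one seed; identical config
#' + seed give an identical cohort.
#'
#' @param config a [sim_config()].
#' @return an `rdcnv_cohort` list: `regions`, `manifest` (sample_id,
#'   phenotype, wave, batch, mean_depth), `depth` (named list of M x N
#'   integer matrices), `truth` (long data.frame of causal-region copy
#'   numbers), `truth_cn` (list form), `factor_model`, `config`.
#' @export
simulate_cohort <- function(config) {
  withr::with_seed(config$seed, {
    n <- config$n_case + config$n_control
    regions <- data.frame(
      chrom = "chr1",
      start = (seq_len(config$n_regions) - 1L) *
        (2L * config$region_length_bp),
      end = (seq_len(config$n_regions) - 1L) *
        (2L * config$region_length_bp) + config$region_length_bp,
      region_id = sprintf("R%05d", seq_len(config$n_regions)),
      gc_fraction = rbeta(config$n_regions, 5, 5),
      stringsAsFactors = FALSE)
    if (!all(config$causal_region_ids %in% regions$region_id)) {
      stop("causal_region_ids not among simulated regions")
    }
    truth_cn <- lapply(config$causal_region_ids, function(id)
      simulate_genotypes(config$deletion_allele_freq, n))
    names(truth_cn) <- config$causal_region_ids

    geno_for_pheno <- if (length(truth_cn)) truth_cn[[1L]] else rep(2L, n)
    phenotype <- simulate_phenotypes(geno_for_pheno, config$odds_ratio,
                                     config$n_case)
    fm <- sim_factor_model(phenotype, config)
    manifest <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      phenotype = phenotype,
      wave = fm$wave,
      batch = fm$batch,
      mean_depth = runif(n, config$mean_depth_range[1L],
                         config$mean_depth_range[2L]),
      stringsAsFactors = FALSE)
    depth <- simulate_depth(regions, manifest, truth_cn, config,
                            factor_model = fm)
    truth <- if (length(truth_cn)) {
      do.call(rbind, lapply(names(truth_cn), function(id)
        data.frame(sample_id = manifest$sample_id, region_id = id,
                   copy_number = truth_cn[[id]], stringsAsFactors = FALSE)))
    } else {
      data.frame(sample_id = character(0), region_id = character(0),
                 copy_number = integer(0))
    }
    structure(list(regions = regions, manifest = manifest, depth = depth,
                   truth = truth, truth_cn = truth_cn, factor_model = fm,
                   config = config),
              class = "rdcnv_cohort")
  })
}

#' @export
print.rdcnv_cohort <- function(x, ...) {
  cat("rdcnv cohort:", nrow(x$manifest), "samples (",
      sum(x$manifest$phenotype), "cases ),", nrow(x$regions), "regions,",
      length(x$truth_cn), "causal; seed", x$config$seed %||% NA, "\n")
  invisible(x)
}

#' Empirical per-sample mean depth of a simulated cohort
#'
#' Computed exactly as for real data: total depth over the capture
#' footprint divided by footprint length.
#'
#' @param cohort an `rdcnv_cohort`.
#' @return named numeric vector of per-sample mean depths.
#' @export
cohort_mean_depths <- function(cohort) {
  tot <- Reduce(`+`, lapply(cohort$depth, colSums))
  len <- sum(cohort$regions$end - cohort$regions$start)
  if (any(tot <= 0)) {
    stop("sample(s) with zero total depth: ",
         paste(cohort$manifest$sample_id[tot <= 0], collapse = ", "))
  }
  tot / len
}

#' Simulate per-base depth at a wide genotyping locus
#'
#' Generates a contiguous multi-kb locus (default 32,200 bp, a common-
#' deletion scale) whose per-sample copy number is the cohort's first
#' causal genotype vector (or a fresh Hardy-Weinberg draw when the cohort
#' has no causal region). The locus shares the cohort's persistent
#' technical state (factor loadings, GC sensitivity) but draws fresh
#' factor profiles and noise, and lies outside the capture footprint so
#' it does not enter mean-depth estimation.
#'
#' @param cohort an `rdcnv_cohort`.
#' @param locus_length_bp locus length (default 32200).
#' @param gc_fraction GC content of the locus (default 0.5).
#' @return list with `depth` (M x N integer matrix), `truth` (per-sample
#'   copy numbers), `interval` (single-row region data.frame).
#' @export
simulate_locus_depth <- function(cohort, locus_length_bp = 32200L,
                                 gc_fraction = 0.5) {
  config <- cohort$config
  withr::with_seed(derive_seed(config$seed, "genotyping-locus"), {
    n <- nrow(cohort$manifest)
    truth <- if (length(cohort$truth_cn)) {
      cohort$truth_cn[[1L]]
    } else {
      simulate_genotypes(config$deletion_allele_freq, n)
    }
    interval <- data.frame(chrom = "chr2", start = 0L,
                           end = as.integer(locus_length_bp),
                           region_id = "locus",
                           gc_fraction = gc_fraction,
                           stringsAsFactors = FALSE)
    depth <- simulate_depth(interval, cohort$manifest,
                            setNames(list(truth), "locus"), config,
                            factor_model = cohort$factor_model)
    list(depth = depth[["locus"]], truth = truth, interval = interval)
  })
}

#' Write a cohort fixture to disk / read it back
#'
#' Emits the regions BED (id in column 4, GC fraction in column 5), the
#' sample manifest TSV, one multi-sample per-base depth table, and the
#' truth TSV; [read_cohort()] reproduces the depth values exactly.
#'
#' @param cohort an `rdcnv_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- cohort$regions
  writeLines(paste(reg$chrom, reg$start, reg$end, reg$region_id,
                   format_full(reg$gc_fraction), sep = "\t"),
             file.path(dir, "regions.bed"))
  write_tsv_full(cohort$manifest, file.path(dir, "manifest.tsv"),
                 header_comment = run_header(paste0("seed=",
                                                    cohort$config$seed)))
  pos <- unlist(lapply(seq_len(nrow(reg)), function(i)
    reg$start[i]:(reg$end[i] - 1L)))
  chrom <- rep(reg$chrom, reg$end - reg$start)
  depth_df <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  big <- do.call(rbind, cohort$depth)
  depth_df <- cbind(depth_df, as.data.frame(big))
  write_tsv_full(depth_df, file.path(dir, "depth.tsv"))
  write_tsv_full(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  regions <- load_regions(file.path(dir, "regions.bed"), gc_col = 5L)
  manifest <- read_tsv_full(file.path(dir, "manifest.tsv"))
  tab <- read_depth_table(file.path(dir, "depth.tsv"))
  depth <- lapply(seq_len(nrow(regions)), function(i)
    depth_from_table(tab, regions[i, ]))
  names(depth) <- regions$region_id
  truth <- read_tsv_full(file.path(dir, "truth.tsv"))
  truth_cn <- if (nrow(truth)) {
    lapply(split(truth, truth$region_id), function(d)
      d$copy_number[match(manifest$sample_id, d$sample_id)])
  } else {
    list()
  }
  structure(list(regions = regions, manifest = manifest, depth = depth,
                 truth = truth, truth_cn = truth_cn, config = NULL),
            class = "rdcnv_cohort")
}
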