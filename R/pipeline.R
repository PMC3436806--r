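## End-to-end orchestration: local PCs once, global PCs once, then a
## per-H association scan and locus genotyping.

#' Local PCs for every region of a cohort
#'
#' Normalizes each region's per-base depths by the empirical sample mean
#' depths, then computes the region's first PC by power iteration. Each
#' region draws its random start from a stream derived from the run seed
#' and the region id, so results do not depend on processing order.
#' Regions whose centered matrix has no variance are dropped with a
#' warning.
#'
#' @param cohort an `rdcnv_cohort` (or any list with `regions`, `depth`,
#'   `manifest`).
#' @param tol,max_iter power-iteration controls; genome-scale scans can
#'   lower `max_iter` since regions dominated by structure converge fast
#'   and noise-only regions have no preferred direction to resolve.
#' @param seed run seed (defaults to the cohort's simulation seed).
#' @return list with `fpc` (regions x samples matrix, rownames = region
#'   ids), `converged`, `n_iterations`, `mean_depths`.
#' @export
compute_local_pcs <- function(cohort, tol = 1e-8, max_iter = 1000L,
                              seed = NULL) {
  if (is.null(seed)) seed <- cohort$config$seed %||% 1L
  mean_depths <- cohort_mean_depths(cohort)
  ids <- cohort$regions$region_id
  n <- nrow(cohort$manifest)
  fpc <- matrix(NA_real_, length(ids), n,
                dimnames = list(ids, cohort$manifest$sample_id))
  converged <- setNames(logical(length(ids)), ids)
  iters <- setNames(integer(length(ids)), ids)
  keep <- rep(TRUE, length(ids))
  for (i in seq_along(ids)) {
    values <- sweep(cohort$depth[[ids[i]]], 2L, mean_depths, "/")
    centered_zero <- all(values == values[1L, 1L]) ||
      all(abs(center_columns(values)) == 0)
    if (centered_zero) {
      warning("region ", ids[i], " has no depth variance; dropped from scan")
      keep[i] <- FALSE
      next
    }
    pc <- region_local_pc(values, tol = tol, max_iter = max_iter,
                          seed = derive_seed(seed, ids[i]))
    fpc[i, ] <- pc$vector
    converged[i] <- pc$converged
    iters[i] <- pc$n_iterations
  }
  list(fpc = fpc[keep, , drop = FALSE], converged = converged[keep],
       n_iterations = iters[keep], mean_depths = mean_depths)
}

#' Association scan across an adjustment grid
#'
#' Computes local PCs once and global PCs once, then for every `H` in the
#' grid projects the first `H` global PCs out of each region's local PC
#' and runs the logistic scan with inflation, QQ and GC diagnostics.
#'
#' @param cohort an `rdcnv_cohort`.
#' @param H_grid adjustment levels (default 0, 5, 20, 40, 50).
#' @param K number of global PCs (default 50; needs at least K samples and
#'   K retained regions).
#' @param tol,max_iter,seed passed to [compute_local_pcs()].
#' @param gc_p_threshold significance threshold for the GC enrichment bins.
#' @return an `rdcnv_scan` list: `local`, `gpcs`, and `by_H` (one entry
#'   per H with `results`, `inflation`, `qq`, `gc`).
#' @export
run_scan <- function(cohort, H_grid = c(0L, 5L, 20L, 40L, 50L), K = 50L,
                     tol = 1e-8, max_iter = 1000L, seed = NULL,
                     gc_p_threshold = 1e-4) {
  local <- compute_local_pcs(cohort, tol = tol, max_iter = max_iter,
                             seed = seed)
  if (nrow(local$fpc) < K || ncol(local$fpc) < K) {
    stop("K = ", K, " exceeds available regions/samples; lower K")
  }
  if (any(H_grid > K)) stop("H_grid values must not exceed K")
  gpcs <- compute_global_pcs(local$fpc, K = K, scale_rows = TRUE)
  gc_fraction <- setNames(cohort$regions$gc_fraction,
                          cohort$regions$region_id)
  phenotypes <- cohort$manifest$phenotype
  by_H <- lapply(H_grid, function(H) {
    adj <- project_out_rows(local$fpc, gpcs, H)
    scan <- assoc_scan(adj, phenotypes, H = H, gc_fraction = gc_fraction)
    est <- is.finite(scan$results$p_value)
    scan$qq <- qq_table(scan$results$p_value[est])
    scan$gc <- gc_significance_table(scan$results,
                                     p_threshold = gc_p_threshold)
    scan
  })
  names(by_H) <- paste0("H", H_grid)
  structure(list(local = local, gpcs = gpcs, by_H = by_H,
                 H_grid = as.integer(H_grid)),
            class = "rdcnv_scan")
}

#' @export
print.rdcnv_scan <- function(x, ...) {
  cat("rdcnv scan:", nrow(x$local$fpc), "regions x", ncol(x$local$fpc),
      "samples; K =", x$gpcs$K, "\n")
  for (h in names(x$by_H)) {
    inf <- x$by_H[[h]]$inflation
    cat(sprintf("  %-4s lambda = %.3f over %d regions\n",
                h, inf$lambda, inf$n_regions))
  }
  invisible(x)
}

#' Genotype a locus from window depths
#'
#' Builds the 100-bp-window normalized depth matrix, projects out the
#' first H global PCs, fits the population HMM by EM, and calls per-sample
#' copy numbers with certainties. When truth is supplied, concordance
#' metrics are attached.
#'
#' @param locus_depth M x N matrix of raw per-base depths at the locus.
#' @param interval single-row region the depths cover.
#' @param mean_depths per-sample mean depths (from the scan cohort).
#' @param gpcs global PC set from [run_scan()] (or `NULL` with `H = 0`).
#' @param H number of global PCs to project out.
#' @param window_size window width in bp (default 100).
#' @param model initial [cn_model()].
#' @param threshold certainty cutoff for missing calls (default 0.9).
#' @param truth optional per-sample true copy numbers.
#' @param sample_ids optional sample names.
#' @return list with `calls`, `fit` (model, posteriors, logliks, trace),
#'   `window_matrix`, and `metrics` when truth was supplied.
#' @export
run_genotype <- function(locus_depth, interval, mean_depths, gpcs = NULL,
                         H = 0L, window_size = 100L, model = cn_model(),
                         threshold = 0.9, truth = NULL, sample_ids = NULL) {
  wm <- build_window_matrix(locus_depth, interval, mean_depths,
                            window_size = window_size)
  if (H > 0L) {
    if (is.null(gpcs)) stop("H > 0 requires a global PC set")
    wm <- adjust_window_matrix(wm, gpcs, H)
  }
  fit <- fit_population_hmm(wm, model)
  calls <- call_genotypes(fit$posteriors, threshold = threshold,
                          states = model$states,
                          sample_ids = sample_ids %||% wm$sample_order)
  out <- list(calls = calls, fit = fit, window_matrix = wm, H = as.integer(H))
  if (!is.null(truth)) out$metrics <- concordance(calls, truth)
  out
}

#' Write scan outputs as TSV files
#'
#' One association table per H plus a combined inflation table, each with
#' a header comment carrying the tool version and the resolved settings.
#'
#' @param scan an `rdcnv_scan`.
#' @param dir output directory.
#' @param regions optional region data.frame to merge coordinates from.
#' @return the directory, invisibly.
#' @export
write_scan <- function(scan, dir, regions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- run_header(paste0("K=", scan$gpcs$K, "; H_grid=",
                           paste(scan$H_grid, collapse = ",")))
  infl <- data.frame(
    H = scan$H_grid,
    lambda = vapply(scan$by_H, function(x) x$inflation$lambda, numeric(1)),
    n_regions = vapply(scan$by_H, function(x) x$inflation$n_regions,
                       numeric(1)))
  write_tsv_full(infl, file.path(dir, "inflation.tsv"), header_comment = hdr)
  for (h in names(scan$by_H)) {
    res <- scan$by_H[[h]]$results
    if (!is.null(regions)) {
      res <- merge(regions[, c("region_id", "chrom", "start", "end")], res,
                   by = "region_id", sort = FALSE)
    }
    write_tsv_full(res, file.path(dir, paste0("assoc_", h, ".tsv")),
                   header_comment = hdr)
    write_tsv_full(scan$by_H[[h]]$qq, file.path(dir, paste0("qq_", h, ".tsv")),
                   header_comment = hdr)
    write_tsv_full(scan$by_H[[h]]$gc$bins,
                   file.path(dir, paste0("gc_bins_", h, ".tsv")),
                   header_comment = hdr)
  }
  invisible(dir)
}

#' Write genotyping outputs as TSV (and optional VCF)
#'
#' @param geno result of [run_genotype()].
#' @param dir output directory.
#' @param vcf also write a single symbolic-allele VCF record with a
#'   per-sample integer CN field (default FALSE).
#' @return the directory, invisibly.
#' @export
write_genotypes <- function(geno, dir, vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- run_header(paste0("H=", geno$H))
  calls <- geno$calls
  calls$H <- geno$H
  calls$locus <- paste0(geno$window_matrix$interval$chrom, ":",
                        geno$window_matrix$interval$start, "-",
                        geno$window_matrix$interval$end)
  write_tsv_full(calls, file.path(dir, "genotypes.tsv"), header_comment = hdr)
  write_tsv_full(geno$fit$trace, file.path(dir, "cluster_fit.tsv"),
                 header_comment = hdr)
  if (!is.null(geno$metrics)) {
    write_tsv_full(data.frame(accuracy = geno$metrics$accuracy,
                              missing_rate = geno$metrics$missing_rate,
                              n_called = geno$metrics$n_called),
                   file.path(dir, "metrics.tsv"), header_comment = hdr)
  }
  if (vcf) write_genotype_vcf(geno, file.path(dir, "genotypes.vcf"))
  invisible(dir)
}

## Minimal VCF with one symbolic <CNx> record and per-sample CN FORMAT key.
write_genotype_vcf <- function(geno, path) {
  iv <- geno$window_matrix$interval
  calls <- geno$calls
  cns <- sort(unique(calls$copy_number[!is.na(calls$copy_number)]))
  alts <- setdiff(cns, 2L)
  alt_str <- if (length(alts)) paste0("<CN", alts, ">", collapse = ",") else "."
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", run_header()),
    "##ALT=<ID=CN0,Description=\"Copy number 0\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of variant\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Copy number genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$sample_id), collapse = "\t"))
  cn_field <- ifelse(is.na(calls$copy_number), ".",
                     as.character(calls$copy_number))
  rec <- paste(c(iv$chrom, iv$start + 1L, iv$region_id, "N", alt_str, ".",
                 "PASS", paste0("END=", iv$end, ";SVTYPE=CNV"), "CN",
                 cn_field), collapse = "\t")
  writeLines(c(lines, rec), path)
  invisible(path)
}
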