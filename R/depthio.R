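## Capture regions, per-base depth, and sample-mean normalization.
##
## Coordinates follow BED semantics throughout: 0-based, half-open
## [start, end). Depth is counted per base whenever the aligned span of a
## read covers the base; strand is ignored and duplicates are counted.

#' Read capture regions from a BED source
#'
#' Parses a 3+ column tab-separated BED file (or literal text). Column 4,
#' when present, supplies the region id; otherwise ids are
#' `"chrom:start-end"`. An optional numeric column can be interpreted as a
#' per-region GC fraction.
#'
#' @param bed_source path to a BED file, or a character vector of BED lines.
#' @param gc_col optional 1-based column index holding a GC fraction in
#'   `[0, 1]`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `region_id`
#'   and `gc_fraction` (NA when not supplied), one row per BED line in file
#'   order.
#' @export
load_regions <- function(bed_source, gc_col = NULL) {
  lines <- if (length(bed_source) == 1L && file.exists(bed_source)) {
    readLines(bed_source)
  } else {
    as.character(bed_source)
  }
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0L) stop("BED source contains no region lines")

  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1L]],
         ": non-integer coordinates")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1L]],
         ": start >= end")
  }
  region_id <- ifelse(nf >= 4L,
                      vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "",
                             character(1)),
                      paste0(chrom, ":", start, "-", end))
  if (anyDuplicated(region_id)) {
    stop("duplicate region_id: ", region_id[duplicated(region_id)][1L])
  }
  gc_fraction <- rep(NA_real_, length(chrom))
  if (!is.null(gc_col)) {
    has <- nf >= gc_col
    gc_fraction[has] <- suppressWarnings(
      as.numeric(vapply(fields[has], `[[`, character(1), gc_col)))
    bad <- which(has & (is.na(gc_fraction) | gc_fraction < 0 | gc_fraction > 1))
    if (length(bad)) {
      stop("BED parse error at line ", lineno[bad[1L]],
           ": GC fraction not in [0,1]")
    }
  }
  data.frame(chrom = chrom, start = start, end = end,
             region_id = region_id, gc_fraction = gc_fraction,
             stringsAsFactors = FALSE)
}

region_length <- function(region) region$end - region$start

## Convert a SAM to an indexed BAM in tempdir (cached per path per session).
.sam_cache <- new.env(parent = emptyenv())
resolve_alignment <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    key <- normalizePath(path)
    if (is.null(.sam_cache[[key]])) {
      .sam_cache[[key]] <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                            indexDestination = TRUE)
    }
    .sam_cache[[key]]
  } else {
    path
  }
}

#' Per-base read depth over a region from an alignment file
#'
#' Counts, for every base of the region, the aligned reads whose span covers
#' it. Bases with no coverage are 0, never missing.
#'
#' @param path SAM or BAM file (BAM must be indexed; SAM is converted and
#'   indexed in a temporary directory).
#' @param region a single-row region as from [load_regions()].
#' @param min_mapq minimum mapping quality; 0 (default) keeps every read.
#' @return integer vector of length `end - start`.
#' @export
depth_from_alignments <- function(path, region, min_mapq = 0) {
  path <- resolve_alignment(path)
  bf <- Rsamtools::BamFile(path)
  hdr <- Rsamtools::scanBamHeader(bf)
  if (!(region$chrom %in% names(hdr$targets))) {
    stop("chromosome '", region$chrom, "' absent from alignment file ", path)
  }
  gr <- GenomicRanges::GRanges(region$chrom,
                               IRanges::IRanges(region$start + 1L, region$end))
  param <- Rsamtools::ScanBamParam(
    which = gr,
    mapqFilter = if (min_mapq > 0) as.integer(min_mapq) else NA_integer_)
  ga <- GenomicAlignments::readGAlignments(bf, param = param)
  m <- region_length(region)
  out <- integer(m)
  if (length(ga) == 0L) return(out)
  ## clip read spans to the region and pile up
  st <- pmax(GenomicAlignments::start(ga), region$start + 1L)
  en <- pmin(GenomicAlignments::end(ga), region$end)
  ok <- st <= en
  if (!any(ok)) return(out)
  cov <- IRanges::coverage(IRanges::IRanges(st[ok], en[ok]),
                           width = region$end)
  as.integer(cov)[(region$start + 1L):region$end]
}

#' Read a multi-sample per-base depth table
#'
#' The dialect is tab-separated with header `chrom pos sample_1 ...
#' sample_N`, one row per base, raw integer depths, 0-based positions.
#'
#' @param source path to a TSV file or a data.frame already in the dialect.
#' @return a data.frame with `chrom`, `pos` and one integer column per sample.
#' @export
read_depth_table <- function(source) {
  tab <- if (is.data.frame(source)) source else read_tsv_full(source)
  if (!all(c("chrom", "pos") %in% colnames(tab)[1:2])) {
    stop("depth table must start with columns 'chrom' and 'pos'")
  }
  tab
}

#' Per-base depth matrix for one region from a depth table
#'
#' @param table depth table (see [read_depth_table()]).
#' @param region a single-row region.
#' @return M x N integer matrix (rows = bases, columns = samples); positions
#'   absent from the table are 0.
#' @export
depth_from_table <- function(table, region) {
  tab <- read_depth_table(table)
  if (!any(tab$chrom == region$chrom)) {
    stop("chromosome '", region$chrom, "' absent from depth table")
  }
  m <- region_length(region)
  samples <- colnames(tab)[-(1:2)]
  out <- matrix(0L, nrow = m, ncol = length(samples),
                dimnames = list(NULL, samples))
  sel <- tab$chrom == region$chrom & tab$pos >= region$start &
    tab$pos < region$end
  if (any(sel)) {
    rows <- tab$pos[sel] - region$start + 1L
    out[rows, ] <- as.matrix(tab[sel, -(1:2), drop = FALSE])
  }
  out
}

#' Per-base depth for a region, dispatching on the source type
#'
#' @param depth_source SAM/BAM path, depth-table path, or depth-table
#'   data.frame.
#' @inheritParams depth_from_alignments
#' @return integer vector (alignment source) or M x N matrix (table source).
#' @export
per_base_depth <- function(depth_source, region, min_mapq = 0) {
  if (is.character(depth_source) &&
      grepl("\\.(sam|bam)$", depth_source, ignore.case = TRUE)) {
    depth_from_alignments(depth_source, region, min_mapq = min_mapq)
  } else {
    depth_from_table(depth_source, region)
  }
}

#' Mean depth of a sample over the capture footprint
#'
#' Total aligned-base count across all capture regions divided by the total
#' region length. The capture footprint stands in for the genome-wide
#' average: only captured bases are consistently observed.
#'
#' @param depth_source per-sample alignment path, or a depth table covering
#'   all regions (then a named vector over samples is returned).
#' @param regions region data.frame from [load_regions()].
#' @param min_mapq minimum mapping quality for alignment sources.
#' @return positive mean depth (scalar for an alignment source, named vector
#'   for a table source).
#' @export
sample_mean_depth <- function(depth_source, regions, min_mapq = 0) {
  total_len <- sum(region_length(regions))
  if (total_len <= 0) stop("capture footprint has zero length")
  if (is.character(depth_source) &&
      grepl("\\.(sam|bam)$", depth_source, ignore.case = TRUE)) {
    tot <- 0
    for (i in seq_len(nrow(regions))) {
      tot <- tot + sum(depth_from_alignments(depth_source, regions[i, ],
                                             min_mapq = min_mapq))
    }
    if (tot <= 0) stop("sample has zero total depth over the capture footprint")
    tot / total_len
  } else {
    tab <- read_depth_table(depth_source)
    samples <- colnames(tab)[-(1:2)]
    tot <- setNames(numeric(length(samples)), samples)
    for (i in seq_len(nrow(regions))) {
      d <- depth_from_table(tab, regions[i, ])
      tot <- tot + colSums(d)
    }
    if (any(tot <= 0)) {
      stop("sample(s) with zero total depth: ",
           paste(samples[tot <= 0], collapse = ", "))
    }
    tot / total_len
  }
}

#' Sample-mean-normalized region depth matrix
#'
#' Entry (j, k) is the raw depth of sample k at base j divided by sample k's
#' mean depth over the capture footprint.
#'
#' @param region single-row region.
#' @param depth M x N matrix of raw per-base depths for the region.
#' @param mean_depths positive numeric vector of per-sample mean depths, in
#'   column order of `depth`.
#' @return list with `region`, `values` (M x N numeric) and `sample_order`.
#' @export
build_normalized_matrix <- function(region, depth, mean_depths) {
  if (region_length(region) <= 0) stop("region of length 0")
  stopifnot(nrow(depth) == region_length(region),
            ncol(depth) == length(mean_depths))
  if (any(!is.finite(mean_depths)) || any(mean_depths <= 0)) {
    stop("mean_depths must be finite and > 0")
  }
  values <- sweep(depth, 2L, mean_depths, "/")
  list(region = region, values = values,
       sample_order = colnames(depth) %||% names(mean_depths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GC fraction of a region from a reference FASTA
#'
#' G+C over A+C+G+T (case-insensitive); ambiguous bases are excluded from
#' the denominator. A region with no unambiguous bases gives `NA`.
#'
#' @param region single-row region.
#' @param reference path to a FASTA file or a [Biostrings::DNAStringSet].
#' @return GC fraction in `[0, 1]`, or `NA_real_`.
#' @export
region_gc <- function(region, reference) {
  seqs <- if (inherits(reference, "DNAStringSet")) {
    reference
  } else {
    Biostrings::readDNAStringSet(reference)
  }
  ## FASTA headers may carry descriptions; match on the first word
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!(region$chrom %in% names(seqs))) {
    stop("chromosome '", region$chrom, "' absent from reference")
  }
  sq <- Biostrings::subseq(seqs[[region$chrom]], region$start + 1L, region$end)
  counts <- Biostrings::letterFrequency(sq, letters = c("A", "C", "G", "T"))
  counts <- setNames(as.numeric(counts), c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0) return(NA_real_)
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' Write / read a normalized region matrix as TSV
#'
#' Header row of sample ids, one row per base, full-precision floats;
#' values round-trip exactly.
#'
#' @param mat list as returned by [build_normalized_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_normalized_matrix <- function(mat, path) {
  df <- as.data.frame(mat$values)
  colnames(df) <- mat$sample_order
  write_tsv_full(df, path)
}

#' @rdname write_normalized_matrix
#' @export
read_normalized_matrix <- function(path) {
  df <- read_tsv_full(path)
  list(values = as.matrix(df), sample_order = colnames(df))
}
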