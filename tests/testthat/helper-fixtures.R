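# Shared fixture builders: everything is generated in code at test time.

# Write a minimal SAM file; reads is a data.frame with qname, rname,
# pos (1-based), and len (aligned length, cigar <len>M).
write_test_sam <- function(reads, chroms = c(chr1 = 1000L),
                           path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(chroms), "\tLN:", chroms))
  body <- if (nrow(reads)) {
    vapply(seq_len(nrow(reads)), function(i) {
      paste(reads$qname[i], 0L, reads$rname[i], reads$pos[i], 60L,
            paste0(reads$len[i], "M"), "*", 0L, 0L,
            strrep("A", reads$len[i]), strrep("I", reads$len[i]),
            sep = "\t")
    }, character(1))
  } else {
    character(0)
  }
  writeLines(c(hdr, body), path)
  path
}

region_row <- function(chrom, start, end, id = paste0(chrom, ":", start, "-", end),
                       gc = NA_real_) {
  data.frame(chrom = chrom, start = start, end = end, region_id = id,
             gc_fraction = gc, stringsAsFactors = FALSE)
}

# Depth table in the package dialect for one chromosome.
make_depth_table <- function(chrom, pos, depth_matrix) {
  stopifnot(length(pos) == nrow(depth_matrix))
  cbind(data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE),
        as.data.frame(depth_matrix))
}

# A small cohort for pipeline-level tests.
small_cohort <- function(seed = 11L, n_regions = 80L, n_case = 30L,
                         n_control = 30L, ...) {
  simulate_cohort(sim_config(n_case = n_case, n_control = n_control,
                             n_regions = n_regions, seed = seed, ...))
}
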