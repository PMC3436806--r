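#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm median pnorm rbeta rbinom rnbinom rnorm rpois runif
#'   setNames uniroot glm.fit binomial glm.control ks.test chisq.test var
#'   plogis
#' @importFrom utils packageVersion
NULL

## Deterministic 31-bit hash of a string, used to derive per-region RNG
## streams so results do not depend on region processing order.
hash_id <- function(x) {
  v <- utf8ToInt(x)
  s <- 0
  for (ch in v) s <- (s * 31 + ch) %% 2147483647
  as.integer(s)
}

#' Derive a per-stream seed from a run seed and a string label
#'
#' XORs the run seed with a hash of the label, keeping the result a valid
#' 32-bit R integer. Identical (seed, label) pairs always give the same
#' stream, independently of processing order.
#'
#' @param seed integer run seed.
#' @param label character scalar naming the stream (e.g. a region id).
#' @return a non-negative integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  s <- bitwXor(as.integer(seed %% 2147483647), hash_id(label))
  if (s < 0L) s <- -s
  s
}

## Full-precision TSV helpers: numeric values survive a round trip exactly.
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

write_tsv_full <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    cols <- lapply(df, format_full)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

read_tsv_full <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  as.data.frame(data.table::fread(text = paste(lines, collapse = "\n"),
                                  sep = "\t", header = TRUE,
                                  data.table = FALSE))
}

run_header <- function(extra = "") {
  paste0("rdcnv ", as.character(utils::packageVersion("rdcnv")),
         if (nzchar(extra)) paste0("; ", extra) else "")
}
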