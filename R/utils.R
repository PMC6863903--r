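NUCS <- c("A", "C", "G", "T")

# Derive a substream seed from a user seed; keeps results for the k-th
# stochastic stage independent of draws made by earlier stages while staying
# inside the 32-bit integer range R requires.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% .Machine$integer.max)
}

#' @keywords internal
stop_strainpop <- function(...) stop(..., call. = FALSE)

# Write a data.frame as TSV preceded by '#'-prefixed header lines that record
# the statistic, its parameters and the seed (run provenance travels with the
# file).
write_tsv_header <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_header <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
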