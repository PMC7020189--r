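## Shared TSV writer for report tables: optional "# ..." comment header,
## then a tab-separated table. Kept timestamp-free so outputs are diffable.
writeReportTable <- function(df, path, headerLines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(headerLines))
    writeLines(paste0("# ", sub("^# ?", "", headerLines)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

provenanceHeader <- function(seed = NULL) {
  h <- paste0("PapaverSSR ", as.character(packageVersion("PapaverSSR")))
  if (!is.null(seed)) h <- c(h, paste0("seed: ", seed))
  h
}
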