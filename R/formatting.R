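# Display conventions used by the report writers: folds to 2 decimals,
# family-wise thresholds to 4 decimals, p-values to 3 significant figures in
# scientific notation. Full precision is always available via precision = "full".

format_fold <- function(x) formatC(x, format = "f", digits = 2)

format_threshold <- function(x) formatC(x, format = "f", digits = 4)

format_pvalue <- function(x) {
  out <- formatC(x, format = "g", digits = 3)
  out[x == 0] <- "0"
  out
}

apply_display_precision <- function(df, precision = c("display", "full")) {
  precision <- match.arg(precision)
  if (precision == "full") return(df)
  for (nm in names(df)) {
    if (nm == "fold") df[[nm]] <- format_fold(df[[nm]])
    else if (nm == "expected") df[[nm]] <- format_fold(df[[nm]])
    else if (grepl("^p_", nm) || nm == "p_hyper") df[[nm]] <- format_pvalue(df[[nm]])
  }
  df
}

write_report_tsv <- function(df, path, footer = NULL) {
  con <- file(path, open = "wb")   # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0L) {
    body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  if (!is.null(footer)) writeLines(paste0("# ", footer), con, sep = "\n")
  invisible(path)
}
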