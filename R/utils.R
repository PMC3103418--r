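`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gd <- function(...) stop(..., call. = FALSE)

# complement map for strand flips
REV_COMP <- c(A = "T", C = "G", G = "C", T = "A")

rev_comp_base <- function(x) {
  out <- unname(REV_COMP[toupper(x)])
  out[is.na(out)] <- NA_character_
  out
}

is_base <- function(x) toupper(x) %in% c("A", "C", "G", "T")

#' @keywords internal
check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_gd("'", name, "' must be a single number")
  if (x < lower || x > upper)
    stop_gd("'", name, "' must be in [", lower, ", ", upper, "]")
  invisible(x)
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

# Write a TSV with an optional '# key=value' provenance header line.
write_tsv_gd <- function(df, path, header = NULL, digits = 6) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) fmt_num(x, digits))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_gd <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}
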