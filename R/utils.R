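#' @keywords internal
"_PACKAGE"

# Allowed experimental essentiality labels in strain gene tables.
.eg_labels <- c("essential_experimental", "nonessential", "unknown")

`%||%` <- function(x, y) if (is.null(x)) y else x

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Read a strict TSV: all columns character, no quoting, header required.
.read_tsv <- function(path, required) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(), fill = TRUE,
                          strip.white = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    .stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.is_ko_id <- function(x) grepl("^K[0-9]{5}$", x)

# Strip a KEGG-style "db:" prefix ("cpd:C00001" -> "C00001").
.strip_prefix <- function(x) sub("^[A-Za-z0-9_.]+:", "", x)
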