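#' Read a sample metadata table
#'
#' Four-column tab-delimited file: `sample_id`, `population`, `behavior`
#' (social / solitary / unknown), `is_outgroup` (TRUE/FALSE or 0/1).
#' Outgroup samples are forced to behavior `"unknown"`.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with the four canonical columns.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "population", "behavior", "is_outgroup")
  if (!all(req %in% names(md)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  md <- md[, req]
  md$sample_id <- as.character(md$sample_id)
  md$population <- as.character(md$population)
  md$behavior <- as.character(md$behavior)
  md$is_outgroup <- as.logical(md$is_outgroup)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  bad <- !md$behavior %in% c("social", "solitary", "unknown")
  if (any(bad))
    stop("invalid behavior label(s): ",
         paste(unique(md$behavior[bad]), collapse = ", "))
  if (any(md$is_outgroup & md$behavior != "unknown")) {
    warning("outgroup samples coerced to behavior 'unknown'")
    md$behavior[md$is_outgroup] <- "unknown"
  }
  md
}

#' Write a sample metadata table
#'
#' @param md Metadata `data.frame` (see [read_sample_metadata()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(md, path) {
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value run configuration file
#'
#' One `key = value` (or `key: value`) pair per line; `#` starts a comment.
#' Values are parsed as numeric where possible, `TRUE`/`FALSE` as logical.
#'
#' @param path Path to the config file.
#' @return Named list of values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (val %in% c("TRUE", "FALSE")) as.logical(val)
                  else val
  }
  out
}
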