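# Minimal YAML-subset reader/writer for run configs, dataset-split manifests
# and checkpoint metadata.  Supported: top-level `key: value` pairs, one level
# of nesting via two-space indentation, inline lists `[a, b, c]`, numbers,
# logicals, and bare strings.  Comments (#) and blank lines are ignored.

yaml_parse_scalar <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[.*\\]$", s)) {
    inner <- trimws(sub("^\\[(.*)\\]$", "\\1", s))
    if (nchar(inner) == 0L) return(list())
    parts <- trimws(strsplit(inner, ",")[[1]])
    return(unlist(lapply(parts, yaml_parse_scalar)))
  }
  if (s %in% c("true", "True", "yes")) return(TRUE)
  if (s %in% c("false", "False", "no")) return(FALSE)
  if (s %in% c("null", "~", "")) return(NULL)
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  gsub("^['\"]|['\"]$", "", s)
}

#' Read a simple YAML file
#'
#' Parses the YAML subset used by this package's run configs and manifests
#' (flat maps, one nesting level, inline lists).
#'
#' @param path file path.
#' @return named list.
#' @export
read_simple_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    indented <- grepl("^\\s+", ln)
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.-]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 0L) stop("cannot parse yaml line: ", ln)
    key <- m[2]; rest <- m[3]
    if (!indented && !nzchar(trimws(rest))) {
      section <- key
      out[[section]] <- list()
    } else if (indented) {
      if (is.null(section)) stop("indented key outside a section: ", ln)
      out[[section]][[key]] <- yaml_parse_scalar(rest)
    } else {
      section <- NULL
      out[[key]] <- yaml_parse_scalar(rest)
    }
  }
  out
}

yaml_format_scalar <- function(v) {
  if (is.logical(v) && length(v) == 1L) return(tolower(as.character(v)))
  if (is.numeric(v) && length(v) == 1L) return(format(v, digits = 17))
  if (length(v) > 1L || is.list(v)) {
    return(sprintf("[%s]", paste(vapply(v, yaml_format_scalar, ""),
                                 collapse = ", ")))
  }
  as.character(v)
}

#' Write a simple YAML file
#' @param x named list (values: scalars, vectors, or one level of named lists).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_simple_yaml <- function(x, path) {
  lines <- character(0)
  for (key in names(x)) {
    v <- x[[key]]
    if (is.list(v) && !is.null(names(v)) && length(v)) {
      lines <- c(lines, paste0(key, ":"))
      for (k2 in names(v)) {
        lines <- c(lines, sprintf("  %s: %s", k2, yaml_format_scalar(v[[k2]])))
      }
    } else {
      lines <- c(lines, sprintf("%s: %s", key, yaml_format_scalar(v)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
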