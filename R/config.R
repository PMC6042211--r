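# Flat key = value configuration files (TOML-like, no sections).
#
# Grammar, one setting per line:
#   key = value           value: number, "string", true/false
#   key = a, b, c         numeric vector
#   key = a,b,c; d,e,f    list of numeric vectors (patches rows)
#   key = 1:100; 2:50     patch:dwell pairs (simulation schedules)
# '#' starts a comment.

.parse_scalar <- function(v) {
  v <- trimws(v)
  if (grepl('^".*"$', v)) return(substr(v, 2, nchar(v) - 1))
  if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

#' Read a flat key = value configuration file
#'
#' @param path Path to the config file.
#' @return Named list. Semicolon-separated values become lists of numeric
#'   vectors; `patch:dwell` pairs become two-column data.frames; plain
#'   comma lists become numeric vectors; scalars are auto-typed.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ";", fixed = TRUE)[[1]])
    if (length(parts) > 0 && all(grepl(":", parts, fixed = TRUE))) {
      kv <- do.call(rbind, lapply(strsplit(parts, ":", fixed = TRUE),
                                  as.numeric))
      out[[key]] <- data.frame(patch = kv[, 1], dwell = kv[, 2])
    } else if (length(parts) > 1) {
      out[[key]] <- lapply(strsplit(parts, ",", fixed = TRUE),
                           function(p) as.numeric(trimws(p)))
    } else if (grepl(",", val, fixed = TRUE)) {
      out[[key]] <- as.numeric(trimws(strsplit(val, ",", fixed = TRUE)[[1]]))
    } else {
      out[[key]] <- .parse_scalar(val)
    }
  }
  out
}
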