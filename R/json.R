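# Canonical JSON emitter: sorted object keys, 2-space indent, shortest
# round-trip number rendering. Canonical bytes let tests (and archives)
# compare serialized states byte-for-byte; jsonlite does all *parsing*.

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  # remaining C0 control characters -> \u00XX
  if (grepl("[\x01-\x1f]", s, useBytes = TRUE)) {
    chars <- strsplit(s, "")[[1]]
    codes <- utf8ToInt(s)
    chars[codes < 32] <- sprintf("\\u%04x", codes[codes < 32])
    s <- paste(chars, collapse = "")
  }
  s
}

# Shortest decimal string that parses back to exactly x — through both
# strtod (as.numeric) and the JSON parser used on read. The double check
# matters: jsonlite's number conversion can land one ulp away from strtod
# on some shortest-form inputs, which would break exact round trips.
json_number <- function(x) {
  if (!is.finite(x)) stop("non-finite number cannot be serialized to JSON",
                          call. = FALSE)
  if (x == floor(x) && abs(x) < 1e15) {
    return(sprintf("%.0f", x + 0))  # +0 normalizes -0
  }
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g")
    if (as.numeric(s) == x && jsonlite::fromJSON(s) == x) return(s)
  }
  formatC(x, digits = 17, format = "g")
}

json_emit <- function(x, indent = 0L) {
  pad <- strrep("  ", indent)
  pad1 <- strrep("  ", indent + 1L)
  if (is.null(x)) return("null")
  if (is.atomic(x)) {
    scal <- function(v) {
      if (is.logical(v)) return(if (v) "true" else "false")
      if (is.numeric(v)) return(json_number(v))
      paste0("\"", json_escape(v), "\"")
    }
    if (length(x) == 1L) return(scal(x))
    return(paste0("[", paste(vapply(x, scal, character(1)),
                             collapse = ", "), "]"))
  }
  if (is.list(x)) {
    nms <- names(x)
    named <- !is.null(nms) && length(x) > 0L && all(nzchar(nms))
    if (named) {
      keys <- sort(nms, method = "radix")
      body <- vapply(keys, function(k) {
        paste0(pad1, "\"", json_escape(k), "\": ",
               json_emit(x[[k]], indent + 1L))
      }, character(1))
      return(paste0("{\n", paste(body, collapse = ",\n"), "\n", pad, "}"))
    }
    if (length(x) == 0L) return("[]")
    body <- vapply(x, function(e) {
      paste0(pad1, json_emit(e, indent + 1L))
    }, character(1))
    return(paste0("[\n", paste(body, collapse = ",\n"), "\n", pad, "]"))
  }
  stop("unsupported JSON value of class ", class(x)[1], call. = FALSE)
}
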