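# Color handling. Named colors come from R's built-in X11 table
# (grDevices::colors()); normalization to "#rrggbb" happens only at
# serialization time, never during validation.

#' Check a color specification string
#'
#' Accepts "#RRGGBB", "#RGB", or a lowercase X11 color name from the table
#' shipped with R (`grDevices::colors()`).
#'
#' @param value Color string.
#' @return `TRUE` if the string is a legal color spec.
#' @export
#' @examples
#' is_valid_color("#ff0000")
#' is_valid_color("skyblue")
#' is_valid_color("#ggg")
is_valid_color <- function(value) {
  if (!is.character(value) || length(value) != 1L || is.na(value)) return(FALSE)
  if (grepl("^#[0-9a-fA-F]{6}$", value)) return(TRUE)
  if (grepl("^#[0-9a-fA-F]{3}$", value)) return(TRUE)
  value %in% grDevices::colors()
}

#' Normalize a color specification to "#rrggbb"
#'
#' "#RGB" shorthand expands digit-doubling (CSS convention); names resolve
#' through the packaged X11 table.
#'
#' @param value Color string (see [is_valid_color()]).
#' @return Lowercase "#rrggbb" string.
#' @export
#' @examples
#' normalize_color("skyblue")
#' normalize_color("#F00")
normalize_color <- function(value) {
  if (!is_valid_color(value)) {
    stop("invalid color '", value,
         "' (expected #RRGGBB, #RGB, or an X11 color name)", call. = FALSE)
  }
  if (grepl("^#[0-9a-fA-F]{3}$", value)) {
    d <- strsplit(substring(value, 2), "")[[1]]
    return(tolower(paste0("#", d[1], d[1], d[2], d[2], d[3], d[3])))
  }
  if (grepl("^#", value)) return(tolower(value))
  rgb <- grDevices::col2rgb(value)
  sprintf("#%02x%02x%02x", rgb[1], rgb[2], rgb[3])
}
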