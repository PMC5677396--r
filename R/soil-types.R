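#' Soil-type categories
#'
#' The three soil types handled by the pipeline and their numeric category
#' codes. Category values 1, 2 and 3 are used directly as the regression
#' target when effective wavelengths are selected for classification, so the
#' code <-> name mapping is fixed.
#'
#' @return A tibble with columns `code` (integer 1..3) and `name`
#'   (`"paddy"`, `"red"`, `"seashore_saline"`).
#' @examples
#' soil_types()
#' @export
soil_types <- function() {
  tibble(
    code = 1:3,
    name = c("paddy", "red", "seashore_saline")
  )
}

#' Convert between soil-type names and category codes
#'
#' @param name Character vector of soil-type names.
#' @param code Integer vector of category codes in `{1, 2, 3}`.
#' @return `soil_type_code()` returns integer codes; `soil_type_name()`
#'   returns names.
#' @examples
#' soil_type_code(c("paddy", "seashore_saline"))
#' soil_type_name(c(3L, 1L))
#' @export
soil_type_code <- function(name) {
  types <- soil_types()
  idx <- match(name, types$name)
  if (anyNA(idx)) {
    abort(paste0(
      "Unknown soil type(s): ",
      paste(unique(name[is.na(idx)]), collapse = ", "),
      ". Expected one of: ", paste(types$name, collapse = ", ")
    ))
  }
  types$code[idx]
}

#' @rdname soil_type_code
#' @export
soil_type_name <- function(code) {
  types <- soil_types()
  idx <- match(as.integer(code), types$code)
  if (anyNA(idx)) {
    abort("Soil-type codes must be 1, 2 or 3.")
  }
  types$name[idx]
}

# soil-type factor with fixed level order (category code order)
as_soil_type <- function(x) {
  factor(as.character(x), levels = soil_types()$name)
}
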