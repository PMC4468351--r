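#' Serialize parameter sets to structured config files
#'
#' Transduction and turn-GLM parameter sets are written as YAML or JSON
#' (chosen from the file extension) with the same field names as the
#' constructors, so a fitted result can be reloaded as a drop-in parameter
#' set.
#'
#' @param params a [transduction_params()] or [turn_glm_params()].
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @rdname params_io
#' @export
write_params <- function(params, path) {
  kind <- if (inherits(params, "transduction_params")) "transduction"
  else if (inherits(params, "turn_glm_params")) "turn_glm"
  else stop("unsupported parameter object")
  lst <- c(list(kind = kind), unclass(params))
  lst <- lst[!vapply(lst, is.null, TRUE)]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname params_io
#' @export
read_params <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  kind <- lst$kind
  lst$kind <- NULL
  if (identical(kind, "transduction")) {
    do.call(transduction_params, c(list(preset = NULL), lst))
  } else if (identical(kind, "turn_glm")) {
    do.call(turn_glm_params, c(list(preset = NULL), lst))
  } else {
    stop("unrecognized parameter file")
  }
}
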