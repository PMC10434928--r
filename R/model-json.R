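# JSON (de)serialization of model specifications. A packaged default config
# ships at inst/extdata/default_model.json; build_reduced_model() accepts
# either the in-memory spec or a path read through here.

#' Write / read a model specification as JSON
#'
#' @param spec an \code{exo_model_spec}.
#' @param path JSON file path.
#' @export
write_model_config <- function(spec, path) {
  out <- unclass(spec)
  # named numeric vectors serialize as bare arrays; keep the names
  out$passive$lumbar_k <- as.list(spec$passive$lumbar_k)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' @rdname write_model_config
#' @return an \code{exo_model_spec}.
#' @export
read_model_config <- function(path = system.file("extdata",
                                                 "default_model.json",
                                                 package = "exowalk")) {
  if (!nzchar(path) || !file.exists(path)) stop("model config not found")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  spec <- raw
  spec$joints <- lapply(raw$joints, function(j) {
    j$parent <- if (length(j$parent) == 0 || is.na(j$parent[1])) NA_character_ else j$parent
    if (length(j$body) == 0) j$body <- NULL
    j
  })
  spec$muscles <- lapply(raw$muscles, function(m) {
    m$eps0 <- if (length(m$eps0) == 0 || is.na(m$eps0)) NA_real_ else m$eps0
    m
  })
  # named lumbar stiffness vector survives as a list; restore
  spec$passive$lumbar_k <- unlist(spec$passive$lumbar_k)
  class(spec) <- "exo_model_spec"
  spec
}
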