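# entry <-> config encoding: free parameters are the string "free",
# fixed parameters are their numeric value
.encode_entry <- function(v) if (is.na(v)) "free" else v
.decode_entry <- function(v) {
  if (identical(v, "free")) NA_real_
  else if (is.numeric(v)) as.numeric(v)
  else stop("config entries must be numbers or the string \"free\", got: ",
            v, call. = FALSE)
}

.spec_to_list <- function(spec) {
  enc_mat <- function(M) apply(M, 1, function(row)
    lapply(row, .encode_entry), simplify = FALSE)
  list(manifest = as.list(spec$manifest),
       latents = as.list(spec$latents),
       lambda = enc_mat(spec$lambda),
       psi = enc_mat(spec$psi),
       beta = enc_mat(spec$beta),
       theta = lapply(spec$theta, .encode_entry))
}

.spec_from_list <- function(x) {
  manifest <- unlist(x$manifest); latents <- unlist(x$latents)
  dec_mat <- function(rows, rn, cn) {
    M <- t(vapply(rows, function(row)
      vapply(row, .decode_entry, numeric(1)), numeric(length(cn))))
    if (length(cn) == 1L) M <- matrix(M, ncol = 1L)
    dimnames(M) <- list(rn, cn)
    M
  }
  model_spec(lambda = dec_mat(x$lambda, manifest, latents),
             psi = dec_mat(x$psi, latents, latents),
             beta = dec_mat(x$beta, latents, latents),
             theta = vapply(x$theta, .decode_entry, numeric(1)))
}

#' Write a model specification to a declarative config file
#'
#' Serializes an `fl_spec` to YAML or JSON: lists of manifest and latent
#' names plus the four pattern matrices, with fixed entries written as their
#' value and free entries as the string `"free"`. [read_spec()] restores the
#' specification exactly.
#'
#' @param spec An `fl_spec`.
#' @param file Output path; format from the extension (`.yaml`/`.yml` or
#'   `.json`) unless `format` is given.
#' @param format `"yaml"` or `"json"`; overrides the extension.
#' @return Invisibly, `file`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_spec(build_wmc_model(5), f)
#' identical_spec <- read_spec(f)
#' @export
write_spec <- function(spec, file, format = NULL) {
  stopifnot(inherits(spec, "fl_spec"))
  if (is.null(format))
    format <- if (grepl("\\.json$", file)) "json" else "yaml"
  x <- .spec_to_list(spec)
  if (format == "json")
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(x, file)
  invisible(file)
}

#' Read a model specification from a declarative config file
#'
#' @param file Path to a YAML or JSON file written by [write_spec()] (or
#'   hand-authored in the same dialect).
#' @return An `fl_spec`.
#' @export
read_spec <- function(file) {
  x <- if (grepl("\\.json$", file))
    jsonlite::read_json(file)
  else yaml::read_yaml(file)
  .spec_from_list(x)
}
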