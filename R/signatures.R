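#' Built-in gene signatures
#'
#' `mpasSignature()` returns the 10-gene MAPK pathway activity signature
#' (PHLDA1, SPRY2, SPRY4, DUSP4, DUSP6, CCND1, EPHA2, EPHA4, ETV4, ETV5):
#' canonical transcriptional targets of RAS-RAF-MEK-ERK signalling whose
#' aggregate z-scored expression tracks pathway output.
#' `ctrlSignature()` returns the 4-gene housekeeping negative-control
#' signature (MLH1, SMARCA4, U2AF, CLTC), aggregated identically so it
#' carries the score's noise floor but no pathway signal.
#'
#' @return A [GeneSignature-class].
#' @examples
#' mpasSignature()
#' @export
mpasSignature <- function() {
  geneSignature("MPAS", c("PHLDA1", "SPRY2", "SPRY4", "DUSP4", "DUSP6",
                          "CCND1", "EPHA2", "EPHA4", "ETV4", "ETV5"))
}

#' @rdname mpasSignature
#' @export
ctrlSignature <- function() {
  geneSignature("CTRL", c("MLH1", "SMARCA4", "U2AF", "CLTC"))
}

#' Read a signature configuration file
#'
#' The config (YAML or JSON, by extension) carries the keys
#' \code{signature_genes}, \code{housekeeping_genes} and
#' \code{negative_control_genes}.
#'
#' @param path file path to a \code{.yaml}/\code{.yml} or \code{.json}
#'   config.
#' @return A list with elements \code{signature}, \code{housekeeping}
#'   (both [GeneSignature-class]) and \code{negativeControls} (character,
#'   possibly empty).
#' @export
readSignature <- function(path) {
  if (!file.exists(path)) stop("signature config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported signature config format: .", ext))
  if (is.null(cfg$signature_genes))
    stop("signature config missing 'signature_genes'")
  list(
    signature = geneSignature("signature",
                              unlist(cfg$signature_genes)),
    housekeeping = if (!is.null(cfg$housekeeping_genes))
      geneSignature("housekeeping", unlist(cfg$housekeeping_genes))
    else ctrlSignature(),
    negativeControls = toupper(unlist(cfg$negative_control_genes %||%
                                        character())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
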