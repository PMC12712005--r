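#' Serialize an mfd result to the shared decomposition JSON schema
#'
#' Schema: `{"instance": str, "variant": "fdpc|fdt|fdw", "status":
#' "feasible|infeasible|timeout", "k": int, "elements": [{"nodes": [...],
#' "weight": int}], "iterations": int|null, "search":
#' "linear|doubling|fixed"}`.
#'
#' @param x An `mfd_result`.
#' @param file Optional path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when `file` is given.
#' @export
write_decomposition_json <- function(x, file = NULL) {
  stopifnot(inherits(x, "mfd_result"))
  elements <- if (is.null(x$decomposition)) list() else
    purrr::map(seq_len(nrow(x$decomposition)), function(i) {
      list(nodes = x$decomposition$nodes[[i]],
           weight = x$decomposition$weight[i])
    })
  obj <- list(
    instance = x$instance,
    variant = x$variant,
    status = x$status,
    k = x$k,
    elements = elements,
    iterations = x$iterations,
    search = x$search
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(json))
  }
  json
}

#' Read a decomposition JSON file back into a result-like object
#'
#' @param file Path to a JSON file written by [write_decomposition_json()].
#' @param net The [flow_network()] the decomposition refers to (used to
#'   classify elements).
#' @return An `mfd_result`.
#' @export
read_decomposition_json <- function(file, net) {
  obj <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  dec <- NULL
  if (length(obj$elements) > 0) {
    dec <- decomposition(
      net,
      purrr::map(obj$elements, function(el) unlist(el$nodes)),
      purrr::map_dbl(obj$elements, "weight")
    )
  }
  structure(
    list(instance = obj$instance, variant = obj$variant,
         method = NA_character_, search = obj$search %||% NA_character_,
         status = obj$status, k = obj$k, decomposition = dec,
         iterations = obj$iterations, probes = NULL, wallclock = NA_real_),
    class = "mfd_result"
  )
}
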