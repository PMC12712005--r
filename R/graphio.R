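#' Read flow networks from the '.graph' benchmark dialect
#'
#' The dialect is the Catfish/Toboggan family format: a line starting with
#' `#` opens a new instance (the rest of the line is its name), the next
#' non-comment line is the declared node count, and every following line
#' `u v f` is an edge from `u` to `v` carrying integer flow `f >= 1`. Node
#' identifiers are arbitrary whitespace-free tokens. Several instances may
#' be concatenated in one file.
#'
#' @param file Path to a `.graph` file (UTF-8, `\n` line endings).
#' @param text Alternatively, the file content as a character string.
#' @param strict If `TRUE` (default) a network failing validation (or a
#'   node-count mismatch) is an error; if `FALSE` networks are returned
#'   as-is with validation reports attached (see [flow_network()]).
#' @return A list of [flow_network()] objects, in file order.
#' @examples
#' nets <- read_flow_graphs(text = "# fig2\n5\ns a 1\na b 2\nb c 2\nc a 2\na t 1\n")
#' nets[[1]]
#' @export
read_flow_graphs <- function(file = NULL, text = NULL, strict = TRUE) {
  if (is.null(text)) {
    if (is.null(file)) rlang::abort("supply `file` or `text`")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  nets <- list()
  cur_name <- NULL
  cur_count <- NA_integer_
  cur_edges <- list()
  flush <- function() {
    if (is.null(cur_name)) return(invisible(NULL))
    edges <- if (length(cur_edges)) dplyr::bind_rows(cur_edges) else
      tibble::tibble(from = character(), to = character(), flow = numeric())
    net <- flow_network(edges, name = cur_name, strict = strict)
    n_seen <- length(unique(c(edges$from, edges$to)))
    if (!is.na(cur_count) && n_seen != cur_count) {
      msg <- paste0("instance '", cur_name, "': declared ", cur_count,
                    " nodes but observed ", n_seen)
      if (strict) rlang::abort(msg)
      attr(net, "validation")$violations <- dplyr::bind_rows(
        attr(net, "validation")$violations,
        tibble::tibble(kind = "node_count", where = cur_name, detail = msg)
      )
      attr(net, "validation")$ok <- FALSE
    }
    nets[[length(nets) + 1L]] <<- net
    invisible(NULL)
  }
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      flush()
      cur_name <- trimws(sub("^#+", "", ln))
      if (!nzchar(cur_name)) cur_name <- paste0("instance", length(nets) + 1L)
      cur_count <- NA_integer_
      cur_edges <- list()
      next
    }
    if (is.null(cur_name)) rlang::abort("edge data before any '#' instance header")
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (is.na(cur_count)) {
      if (length(tok) != 1 || is.na(suppressWarnings(as.integer(tok)))) {
        rlang::abort(paste0("expected node count line, got: '", ln, "'"))
      }
      cur_count <- as.integer(tok)
      next
    }
    if (length(tok) != 3) {
      rlang::abort(paste0("malformed edge line: '", ln, "'"))
    }
    fval <- suppressWarnings(as.numeric(tok[3]))
    if (is.na(fval) || fval != round(fval)) {
      rlang::abort(paste0("non-integer flow in line: '", ln, "'"))
    }
    if (fval <= 0 && strict) {
      rlang::abort(paste0("flow must be >= 1 in line: '", ln, "'"))
    }
    cur_edges[[length(cur_edges) + 1L]] <-
      tibble::tibble(from = tok[1], to = tok[2], flow = fval)
  }
  flush()
  nets
}

#' Write flow networks in the '.graph' dialect
#'
#' Round-trip property: `read_flow_graphs(text = write_flow_graphs(nets))`
#' reproduces node sets, edge order and flows exactly.
#'
#' @param nets A `flow_network` or list of them.
#' @param file Optional path; when `NULL` the text is returned only.
#' @return The serialized text, invisibly when `file` is given.
#' @export
write_flow_graphs <- function(nets, file = NULL) {
  if (inherits(nets, "flow_network")) nets <- list(nets)
  blocks <- vapply(nets, function(net) {
    rep <- validate_flow_network(net)
    if (!rep$ok) {
      rlang::abort(paste0("refusing to write invalid network '", net$name, "'"))
    }
    paste0(
      "# ", net$name, "\n", net$n, "\n",
      paste0(net$edges$from, " ", net$edges$to, " ",
             format(net$edges$flow, scientific = FALSE, trim = TRUE),
             collapse = "\n"),
      "\n"
    )
  }, character(1))
  out <- paste0(blocks, collapse = "")
  if (!is.null(file)) {
    writeLines(out, file, sep = "")
    return(invisible(out))
  }
  out
}
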