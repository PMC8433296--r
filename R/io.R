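# JSON serialization of the store-plan manifest. The plan is the
# traditional-storage side of the hybrid design: primer assignments, the
# file-to-tool map, the pool's address width and the exact container bit
# length of every stream -- everything retrieval needs besides the pool.

#' Write / read a store plan manifest as JSON
#'
#' @param store a \code{dna_store} (its plan and parameters are written), or
#'   for \code{read_store_plan} the path of a manifest written by
#'   \code{write_store_plan}.
#' @param path JSON file path.
#' @return \code{write_store_plan} returns \code{path} invisibly;
#'   \code{read_store_plan} returns a list with \code{plan} and
#'   \code{params} ready to rebuild a \code{dna_store} around a pool read
#'   from FASTA (see \code{\link{rebuild_store}}).
#' @export
write_store_plan <- function(store, path) {
  stopifnot(inherits(store, "dna_store"))
  plan <- store$plan
  payload <- list(
    method = plan$method,
    L_addr = plan$L_addr,
    params = unclass(store$params),
    file_primer_map = plan$file_primer_map,
    tool_primer_map = plan$tool_primer_map,
    file_tool = as.list(plan$file_tool),
    shared_clients = plan$shared_clients,
    registry_map = as.list(plan$registry_map),
    stream_bits = as.list(plan$stream_bits),
    pointer_nt = as.list(plan$pointer_nt)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_store_plan
#' @param path path to a plan manifest JSON file.
#' @export
read_store_plan <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  num_map <- function(l) {
    out <- vapply(l, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                  numeric(1))
    names(out) <- names(l)
    out
  }
  chr_map <- function(l) {
    out <- vapply(l, as.character, character(1))
    names(out) <- names(l)
    out
  }
  params <- structure(list(L_s = as.integer(x$params$L_s),
                           L_p = as.integer(x$params$L_p),
                           codec = x$params$codec,
                           rs_len = as.integer(x$params$rs_len)),
                      class = "storage_params")
  plan <- structure(list(
    method = x$method,
    file_primer_map = x$file_primer_map,
    tool_primer_map = x$tool_primer_map,
    file_tool = num_map(x$file_tool),
    shared_clients = lapply(x$shared_clients, function(v) as.numeric(unlist(v))),
    shared_counts = vapply(x$shared_clients, length, integer(1)),
    registry_map = chr_map(x$registry_map),
    params = params,
    L_addr = as.integer(x$L_addr),
    stream_bits = num_map(x$stream_bits),
    pointer_nt = num_map(x$pointer_nt)
  ), class = "store_plan")
  list(plan = plan, params = params)
}

#' Rebuild a store object from a pool FASTA and a plan manifest
#'
#' @param pool_path FASTA file written by \code{\link{write_pool_fasta}}.
#' @param plan_path JSON manifest written by \code{\link{write_store_plan}}.
#' @return a \code{dna_store} ready for \code{\link{retrieve}}.
#' @export
rebuild_store <- function(pool_path, plan_path) {
  pp <- read_store_plan(plan_path)
  structure(list(pool = read_pool_fasta(pool_path), plan = pp$plan,
                 params = pp$params),
            class = "dna_store")
}
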