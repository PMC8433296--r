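# Binary container formats and the self-extraction read procedure.
#
# Two record types are laid out at fixed byte offsets (big-endian integers):
#   data record:  FT(1B, =0) | FID(4B) | SM(1B) | DL-or-TFID(4B) | D | TD
#   tool record:  FT(1B, =1) | FID(4B) | TD
# SM codes: OF = 0 (unprocessed), CPF = 1 (tool embedded in the record),
# SPF = 2 (tool referenced by FID and stored separately).

FT_DATA <- 0L
FT_TOOL <- 1L
SM_CODES <- c(OF = 0L, CPF = 1L, SPF = 2L)
U32_MAX <- 2^32 - 1

u32_to_raw <- function(x) {
  x <- as.numeric(x)
  if (is.na(x) || x < 0 || x > U32_MAX || x != floor(x)) {
    stop("value out of 4-byte unsigned range: ", x)
  }
  as.raw(c(x %/% 2^24 %% 256, x %/% 2^16 %% 256, x %/% 2^8 %% 256, x %% 256))
}

raw_to_u32 <- function(b) {
  sum(as.numeric(b) * c(2^24, 2^16, 2^8, 1))
}

#' Construct a data-file container record
#'
#' @param fid file identifier (0 .. 2^32-1).
#' @param sm storage method: \code{"OF"} (unprocessed), \code{"CPF"}
#'   (compressed data with the tool embedded), or \code{"SPF"} (compressed
#'   data with the tool stored separately and referenced by \code{tfid}).
#' @param data raw vector: the (possibly compressed) file bytes.
#' @param tool raw vector of tool bytes; only allowed for CPF.
#' @param tfid tool file identifier; required for SPF.
#' @return object of class \code{data_record}.
#' @export
data_record <- function(fid, sm = c("OF", "CPF", "SPF"), data = raw(),
                        tool = raw(), tfid = NULL) {
  sm <- match.arg(sm)
  stopifnot(is.raw(data), is.raw(tool))
  if (sm == "SPF") {
    if (is.null(tfid)) stop("SPF records require a tool FID")
    if (length(tool)) stop("SPF records carry no tool bytes")
  } else if (!is.null(tfid)) {
    stop("tfid is only meaningful for SPF records")
  }
  if (sm == "OF" && length(tool)) stop("OF records carry no tool bytes")
  check_u32 <- function(x, what) {
    if (is.na(x) || x < 0 || x > U32_MAX || x != floor(x)) {
      stop(what, " out of 4-byte unsigned range: ", x)
    }
  }
  check_u32(as.numeric(fid), "FID")
  if (sm == "SPF") check_u32(as.numeric(tfid), "TFID") else check_u32(length(data), "DL")
  structure(list(ft = FT_DATA, fid = as.numeric(fid), sm = sm,
                 dl_or_tfid = if (sm == "SPF") as.numeric(tfid) else length(data),
                 data = data, tool = tool),
            class = "data_record")
}

#' Construct a tool-file container record
#' @param fid tool file identifier.
#' @param tool raw vector: the opaque tool bytes.
#' @return object of class \code{tool_record}.
#' @export
tool_record <- function(fid, tool = raw()) {
  stopifnot(is.raw(tool))
  if (is.na(as.numeric(fid)) || fid < 0 || fid > U32_MAX || fid != floor(fid)) {
    stop("FID out of 4-byte unsigned range: ", fid)
  }
  structure(list(ft = FT_TOOL, fid = as.numeric(fid), tool = tool),
            class = "tool_record")
}

#' Serialize / parse container records
#'
#' \code{serialize_data_record} lays a \code{\link{data_record}} out at its
#' fixed offsets (FT at 0, FID at 1, SM at 5, DL/TFID at 6, D at 10, TD
#' following D); \code{parse_data_record} is its exact inverse. The tool
#' mirror pair uses offsets FT 0, FID 1, TD 5.
#'
#' @param record a \code{data_record} or \code{tool_record}.
#' @param bytes raw vector holding exactly one serialized record.
#' @return a raw vector, or the reconstructed record.
#' @export
serialize_data_record <- function(record) {
  stopifnot(inherits(record, "data_record"))
  c(as.raw(FT_DATA), u32_to_raw(record$fid), as.raw(SM_CODES[[record$sm]]),
    u32_to_raw(record$dl_or_tfid), record$data, record$tool)
}

#' @rdname serialize_data_record
#' @export
parse_data_record <- function(bytes) {
  stopifnot(is.raw(bytes))
  if (length(bytes) < 10L) {
    stop(sprintf("record underflow: %d bytes, header needs 10", length(bytes)))
  }
  ft <- as.integer(bytes[1L])
  if (ft != FT_DATA) stop("format error: FT byte is ", ft, ", expected 0 (data)")
  sm_code <- as.integer(bytes[6L])
  sm <- names(SM_CODES)[match(sm_code, SM_CODES)]
  if (is.na(sm)) stop("format error: unknown SM code ", sm_code)
  fid <- raw_to_u32(bytes[2:5])
  field6 <- raw_to_u32(bytes[7:10])
  body <- if (length(bytes) > 10L) bytes[11:length(bytes)] else raw(0)
  if (sm == "SPF") {
    data_record(fid, "SPF", data = body, tfid = field6)
  } else {
    dl <- field6
    if (length(body) < dl) {
      stop(sprintf("record underflow: D field needs %d bytes, %d available",
                   dl, length(body)))
    }
    d <- body[seq_len(dl)]
    td <- if (length(body) > dl) body[(dl + 1L):length(body)] else raw(0)
    if (sm == "OF" && length(td)) {
      stop("format error: OF record has trailing bytes after D")
    }
    data_record(fid, sm, data = d, tool = td)
  }
}

#' @rdname serialize_data_record
#' @export
serialize_tool_record <- function(record) {
  stopifnot(inherits(record, "tool_record"))
  c(as.raw(FT_TOOL), u32_to_raw(record$fid), record$tool)
}

#' @rdname serialize_data_record
#' @export
parse_tool_record <- function(bytes) {
  stopifnot(is.raw(bytes))
  if (length(bytes) < 5L) {
    stop(sprintf("record underflow: %d bytes, header needs 5", length(bytes)))
  }
  ft <- as.integer(bytes[1L])
  if (ft != FT_TOOL) stop("format error: FT byte is ", ft, ", expected 1 (tool)")
  tool_record(raw_to_u32(bytes[2:5]),
              if (length(bytes) > 5L) bytes[6:length(bytes)] else raw(0))
}

#' Split serialized records into data and tool arrays
#'
#' Dispatches on the leading FT byte, preserving input order within each
#' array.
#'
#' @param records list of raw vectors, each exactly one serialized record.
#' @return object of class \code{container_set} with \code{datafiles} and
#'   \code{toolfiles} lists.
#' @export
split_by_file_type <- function(records) {
  datafiles <- list()
  toolfiles <- list()
  for (i in seq_along(records)) {
    b <- records[[i]]
    parsed <- tryCatch({
      if (!is.raw(b) || length(b) == 0L) stop("empty or non-raw element")
      switch(as.character(as.integer(b[1L])),
             "0" = parse_data_record(b),
             "1" = parse_tool_record(b),
             stop("unknown FT byte ", as.integer(b[1L])))
    }, error = function(e) {
      stop(sprintf("format error at index %d: %s", i, conditionMessage(e)),
           call. = FALSE)
    })
    if (inherits(parsed, "data_record")) {
      datafiles[[length(datafiles) + 1L]] <- parsed
    } else {
      toolfiles[[length(toolfiles) + 1L]] <- parsed
    }
  }
  structure(list(datafiles = datafiles, toolfiles = toolfiles),
            class = "container_set")
}

#' Decompressor registry for stand-in tools
#'
#' Stored tools are opaque byte blobs; actual decompression is dispatched
#' through a registry of built-in codecs keyed by tool FID. Supported codec
#' names: \code{"gzip"}, \code{"bzip2"}, \code{"xz"} (via
#' \code{memCompress}/\code{memDecompress}) and \code{"none"} (identity).
#'
#' @param map named character vector, names = tool FIDs, values = codec names.
#' @return object of class \code{tool_registry}: per-FID lists with
#'   \code{compress} and \code{decompress} functions.
#' @examples
#' reg <- tool_registry(c("9" = "gzip"))
#' reg[["9"]]$decompress(reg[["9"]]$compress(as.raw(1:10)))
#' @export
tool_registry <- function(map) {
  stopifnot(is.character(map), !is.null(names(map)), all(nzchar(names(map))))
  entries <- lapply(map, function(type) {
    if (!type %in% c("gzip", "bzip2", "xz", "none")) {
      stop("unknown registry codec: ", type)
    }
    if (type == "none") {
      list(name = type, compress = identity, decompress = identity)
    } else {
      list(name = type,
           compress = function(x) memCompress(x, type = type),
           decompress = function(x) memDecompress(x, type = type))
    }
  })
  structure(entries, class = "tool_registry")
}

#' Read one file out of a container set (the self-extraction procedure)
#'
#' Locates the record for \code{fid} in the data-file array, then follows the
#' storage-method branch: OF returns D verbatim; CPF decompresses D using the
#' registered codec of the embedded tool; SPF resolves TFID against the
#' tool-file array and decompresses D with that tool's registered codec.
#'
#' @param fid file identifier to read.
#' @param set a \code{\link{split_by_file_type}} result.
#' @param registry a \code{\link{tool_registry}}.
#' @param cpf_tools optional named numeric vector mapping data FIDs to the
#'   tool FID whose codec interprets their embedded TD bytes (CPF records do
#'   not carry a tool FID themselves; this map lives in the manifest).
#' @return raw vector: the original file bytes.
#' @export
read_file <- function(fid, set, registry, cpf_tools = NULL) {
  stopifnot(inherits(set, "container_set"), inherits(registry, "tool_registry"))
  rec <- NULL
  for (r in set$datafiles) if (r$fid == fid) { rec <- r; break }
  if (is.null(rec)) stop("file not found: FID ", fid)
  lookup <- function(tfid) {
    entry <- registry[[as.character(tfid)]]
    if (is.null(entry)) stop("unknown tool: no registry codec for FID ", tfid)
    entry
  }
  switch(rec$sm,
    OF = rec$data,
    CPF = {
      tfid <- cpf_tools[[as.character(fid)]]
      if (is.null(tfid)) stop("CPF record for FID ", fid,
                              " has no tool mapping in cpf_tools")
      lookup(tfid)$decompress(rec$data)
    },
    SPF = {
      tfid <- rec$dl_or_tfid
      tool <- NULL
      for (t in set$toolfiles) if (t$fid == tfid) { tool <- t; break }
      if (is.null(tool)) stop("dangling tool: TFID ", tfid,
                              " not present in the tool-file array")
      lookup(tfid)$decompress(rec$data)
    })
}
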