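# Seeded synthetic corpus generator and the end-to-end pipeline driver.
#
# The generator emulates the study conditions of the package's experiments:
# several data files of differing sizes and redundancy levels, plus two
# opaque tool blobs standing in for a 7z-like (~194 KB, xz registry codec)
# and a zip-like (~87 KB, gzip registry codec) decompressor.

#' Describe a synthetic corpus
#'
#' @param file_sizes_bits numeric vector of original file sizes in bits.
#' @param redundancy numeric vector in [0,1], one per file: the fraction of
#'   repeated content. Higher redundancy means lower measured compression
#'   ratio under the stand-in compressors.
#' @param file_tools integer vector, one per file: index into the tool list
#'   (NA for an unprocessed file stored as-is).
#' @param tool_sizes_bits tool blob sizes in bits.
#' @param tool_codecs registry codec per tool (\code{"gzip"}, \code{"xz"},
#'   \code{"bzip2"}, \code{"none"}).
#' @param seed integer seed; the whole corpus is deterministic under it.
#' @return object of class \code{corpus_spec}.
#' @export
corpus_spec <- function(file_sizes_bits, redundancy, file_tools,
                        tool_sizes_bits, tool_codecs, seed = 1L) {
  stopifnot(length(file_sizes_bits) == length(redundancy),
            length(file_sizes_bits) == length(file_tools),
            length(tool_sizes_bits) == length(tool_codecs),
            all(file_sizes_bits > 0), all(tool_sizes_bits > 0),
            all(redundancy >= 0 & redundancy <= 1),
            all(is.na(file_tools) | (file_tools >= 1 &
                                       file_tools <= length(tool_sizes_bits))))
  structure(list(file_sizes_bits = file_sizes_bits, redundancy = redundancy,
                 file_tools = file_tools, tool_sizes_bits = tool_sizes_bits,
                 tool_codecs = tool_codecs, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Default corpus: five files, two tools
#'
#' Five data files of differing sizes (40, 28, 20, 12 and 8 KB) and
#' redundancy levels; a 194 KB xz-backed tool shared by the first three
#' files and an 87 KB gzip-backed tool shared by the last two.
#'
#' @param seed integer seed.
#' @return a \code{\link{corpus_spec}}.
#' @export
default_corpus_spec <- function(seed = 1L) {
  corpus_spec(
    file_sizes_bits = c(40, 28, 20, 12, 8) * 1024 * 8,
    redundancy = c(0.9, 0.8, 0.6, 0.3, 0.0),
    file_tools = c(1L, 1L, 1L, 2L, 2L),
    tool_sizes_bits = c(194, 87) * 1024 * 8,
    tool_codecs = c("xz", "gzip"),
    seed = seed
  )
}

random_bytes <- function(n) as.raw(sample.int(256L, n, replace = TRUE) - 1L)

# Redundant content: draw a pool of distinct blocks sized so that a fraction
# `redundancy` of the file is repetition, then tile blocks at random.
redundant_bytes <- function(n_bytes, redundancy) {
  block <- max(16L, min(1024L, n_bytes %/% 4L + 1L))
  n_blocks <- ceiling(n_bytes / block)
  n_distinct <- max(1L, round(n_blocks * (1 - redundancy)))
  pool <- lapply(seq_len(n_distinct), function(i) random_bytes(block))
  picks <- sample.int(n_distinct, n_blocks, replace = TRUE)
  out <- do.call(c, pool[picks])
  out[seq_len(n_bytes)]
}

#' Generate a synthetic corpus
#'
#' Files with redundancy are built from seeded repeated blocks, files
#' without from seeded uniform bytes; tool blobs are seeded uniform bytes of
#' the requested size. FIDs number files first, then tools.
#'
#' @param spec a \code{\link{corpus_spec}}.
#' @return object of class \code{dna_corpus}: \code{files} (each
#'   \code{list(name, fid, data, tool_fid)}), \code{tools} (each
#'   \code{list(name, fid, data, codec)}), \code{registry_map} (tool FID ->
#'   registry codec name) and the originating \code{spec}.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  nf <- length(spec$file_sizes_bits)
  nt <- length(spec$tool_sizes_bits)
  withr::with_seed(spec$seed, {
    tools <- lapply(seq_len(nt), function(j) {
      list(name = sprintf("tool%d", j), fid = nf + j,
           data = random_bytes(ceiling(spec$tool_sizes_bits[j] / 8)),
           codec = spec$tool_codecs[j])
    })
    files <- lapply(seq_len(nf), function(i) {
      n_bytes <- ceiling(spec$file_sizes_bits[i] / 8)
      bytes <- if (spec$redundancy[i] > 0) {
        redundant_bytes(n_bytes, spec$redundancy[i])
      } else {
        random_bytes(n_bytes)
      }
      list(name = sprintf("file%d", i), fid = i, data = bytes,
           tool_fid = if (is.na(spec$file_tools[i])) NA_real_ else nf + spec$file_tools[i])
    })
    registry_map <- setNames(vapply(tools, `[[`, character(1), "codec"),
                             vapply(tools, function(t) as.character(t$fid), character(1)))
    structure(list(files = files, tools = tools, registry_map = registry_map,
                   spec = spec),
              class = "dna_corpus")
  })
}

#' @export
print.dna_corpus <- function(x, ...) {
  cat(sprintf("<dna_corpus: %d files (%.0f KB), %d tools (%.0f KB)>\n",
              length(x$files),
              sum(vapply(x$files, function(f) length(f$data), numeric(1))) / 1024,
              length(x$tools),
              sum(vapply(x$tools, function(t) length(t$data), numeric(1))) / 1024))
  invisible(x)
}

#' Measured compression ratio of a file under its assigned tool
#' @param corpus a \code{dna_corpus}.
#' @param fid data file identifier.
#' @param registry a \code{\link{tool_registry}} (default: the corpus's own).
#' @return \code{S_c / S_o} for that file (1 for unprocessed files).
#' @export
measured_compression_ratio <- function(corpus, fid, registry = corpus_registry(corpus)) {
  f <- NULL
  for (cand in corpus$files) if (cand$fid == fid) { f <- cand; break }
  if (is.null(f)) stop("file not found: FID ", fid)
  if (is.na(f$tool_fid)) return(1)
  length(compress_for_tool(f$data, f$tool_fid, registry)) / length(f$data)
}

#' Registry implied by a corpus
#' @param corpus a \code{dna_corpus}.
#' @return a \code{\link{tool_registry}} keyed by the corpus's tool FIDs.
#' @export
corpus_registry <- function(corpus) tool_registry(corpus$registry_map)

#' Run the whole pipeline and verify it end to end
#'
#' Generates primers, stores the corpus under one method, retrieves every
#' file, verifies byte equality against the originals (a mismatch is a hard
#' failure with a diff summary), and reports per-file sequencing rounds,
#' pool totals, densities, and the model-vs-pool payload-bit delta.
#'
#' @param corpus a \code{\link{generate_corpus}} result.
#' @param method storage method name.
#' @param params a \code{\link{storage_params}}.
#' @param seed integer seed for primer design and sequencing order.
#' @return report list of class \code{e2e_report}.
#' @export
run_end_to_end <- function(corpus, method = c("1-1CS", "M-1CI", "1-MCI"),
                           params = storage_params(), seed = 1L) {
  method <- match.arg(method)
  registry <- corpus_registry(corpus)
  primers <- generate_primer_library(length(corpus$files) + length(corpus$tools),
                                     L_p = params$L_p, seed = seed)
  plan <- make_store_plan(corpus, method, primers)
  store <- store_corpus(corpus, plan, params, registry)
  files <- lapply(corpus$files, function(f) {
    res <- retrieve(store, f$fid, registry, seed = seed + f$fid)
    if (!identical(res$data, f$data)) {
      n <- min(length(res$data), length(f$data))
      first_diff <- if (n > 0) which(res$data[seq_len(n)] != f$data[seq_len(n)])[1L] else NA
      stop(sprintf(paste0("retrieval mismatch for FID %.0f: got %d bytes, ",
                          "expected %d, first differing byte at %s"),
                   f$fid, length(res$data), length(f$data),
                   ifelse(is.na(first_diff), "length", first_diff)))
    }
    list(fid = f$fid, name = f$name, bytes = length(f$data),
         sequencing_rounds = res$sequencing_rounds,
         fragments_sequenced = res$fragments_sequenced)
  })
  codec <- dna_codec(params$codec)
  S_o_bits <- 8 * sum(vapply(corpus$files, function(f) length(f$data), numeric(1)))
  pool_bases <- sum(nchar(store$pool))
  payload_bits <- pool_payload_bits(store)
  model_bits <- model_stored_bits(corpus, method, registry, params)
  structure(list(
    method = method,
    n_files = length(corpus$files),
    n_tools = length(corpus$tools),
    files = files,
    pool_fragments = length(store$pool),
    pool_bases = pool_bases,
    payload_bits = payload_bits,
    model_bits = model_bits,
    model_vs_pool_delta = payload_bits - model_bits,
    density = storage_density(payload_bits, pool_bases),
    density_original = storage_density(S_o_bits, pool_bases),
    density_codec = codec$block_bits / codec$bases_per_block,
    store = store
  ), class = "e2e_report")
}

#' @export
print.e2e_report <- function(x, ...) {
  cat(sprintf("<e2e_report %s: %d files ok, %d fragments, %.0f bases, d = %.3f bits/base>\n",
              x$method, x$n_files, x$pool_fragments, x$pool_bases, x$density))
  invisible(x)
}

# Closed-form stored bits evaluated on a real corpus: one model term per
# tool-sharing group (plus unprocessed files), with per-file compressed
# sizes standing in for r_c * S_Di and S_h = the 10-byte data-record header.
model_stored_bits <- function(corpus, method, registry, params) {
  S_h <- 80 # bits: 10-byte data-record header
  total <- 0
  for (t in corpus$tools) {
    clients <- Filter(function(f) !is.na(f$tool_fid) && f$tool_fid == t$fid,
                      corpus$files)
    n <- length(clients)
    if (n == 0L) next
    compressed_bits <- vapply(clients, function(f) {
      8 * length(compress_for_tool(f$data, f$tool_fid, registry))
    }, numeric(1))
    p <- system_parameters(n = n, S_D = compressed_bits, S_h = S_h,
                           S_T = 8 * length(t$data), L_s = params$L_s,
                           L_p = params$L_p, a = 1, r_c = 1)
    total <- total + stored_bits(method, p)
  }
  plain <- Filter(function(f) is.na(f$tool_fid), corpus$files)
  total + sum(vapply(plain, function(f) 8 * length(f$data) + S_h, numeric(1)))
}
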