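# In-silico oligo pool: an unordered multiset of fragment sequences, PCR
# modelled as exact substring co-occurrence of the two primer sites, and
# sequencing as a seeded shuffle of the amplified sub-pool. Retrieval never
# uses insertion order or FASTA record ids.

#' Construct an oligo pool
#'
#' @param fragments character vector of fragment sequences (a multiset:
#'   duplicates are meaningful).
#' @param ids optional record ids, kept for human inspection in FASTA output
#'   only; no pool operation reads them.
#' @return object of class \code{dna_pool}.
#' @export
dna_pool <- function(fragments = character(0), ids = NULL) {
  fragments <- as.character(fragments)
  if (!is.null(ids)) names(fragments) <- ids
  structure(fragments, class = "dna_pool")
}

#' @export
print.dna_pool <- function(x, ...) {
  cat(sprintf("<dna_pool: %d fragments, %d total bases>\n",
              length(x), if (length(x)) sum(nchar(x)) else 0L))
  invisible(x)
}

#' @export
`[.dna_pool` <- function(x, i) {
  dna_pool(unclass(x)[i], ids = names(unclass(x)[i]))
}

#' PCR-style selective amplification
#'
#' Returns the sub-pool of fragments containing both primer sites as exact
#' substrings; the input pool is unchanged. Strand chemistry, amplification
#' bias and copy numbers are not modelled.
#'
#' @param pool a \code{\link{dna_pool}}.
#' @param forward_site,reverse_site non-empty primer sequences.
#' @return a \code{dna_pool} (possibly empty).
#' @export
pcr_select <- function(pool, forward_site, reverse_site) {
  stopifnot(inherits(pool, "dna_pool"), nzchar(forward_site), nzchar(reverse_site))
  pool[pcr_select_idx(pool, forward_site, reverse_site)]
}

pcr_select_idx <- function(pool, forward_site, reverse_site) {
  grepl(forward_site, pool, fixed = TRUE) & grepl(reverse_site, pool, fixed = TRUE)
}

#' One sequencing pass over a pool
#'
#' Returns every fragment exactly once (duplicates included) in
#' seeded-random order, modelling one round of reading out an amplified
#' sub-pool.
#'
#' @param pool a \code{\link{dna_pool}}.
#' @param seed integer seed; the same seed gives the same read order.
#' @return unnamed character vector of reads.
#' @export
sequence_pool <- function(pool, seed = 1L) {
  reads <- unname(as.character(pool))
  if (length(reads) < 2L) return(reads)
  withr::with_seed(seed, reads[sample.int(length(reads))])
}

#' Random-access retrieval of one stored file
#'
#' Implements the read path of each storage method and counts sequencing
#' rounds:
#' \describe{
#'   \item{1-1CS}{select by the file's primers, sequence once, decode the
#'     CPF container; 1 round.}
#'   \item{M-1CI}{round 1 sequences the file's fragments and extracts the
#'     tool-primer pointer from the tail of the assembled stream; round 2
#'     selects and sequences the tool under those primers; 2 rounds for
#'     tool-using files.}
#'   \item{1-MCI}{one amplification with the file primers plus the universal
#'     primer yields both classes at once; the C flag separates them;
#'     1 round.}
#' }
#'
#' @param store a \code{dna_store} from one of the \code{store_*} write
#'   paths (bundles the pool with its plan manifest).
#' @param fid file identifier to retrieve.
#' @param registry a \code{\link{tool_registry}}.
#' @param seed seed forwarded to \code{\link{sequence_pool}}.
#' @return list of class \code{retrieval_result}: \code{data} (raw vector,
#'   byte-exact original), \code{sequencing_rounds}, \code{fragments_sequenced}.
#' @export
retrieve <- function(store, fid, registry, seed = 1L) {
  stopifnot(inherits(store, "dna_store"))
  plan <- store$plan
  params <- store$params
  codec <- dna_codec(params$codec)
  key <- as.character(fid)
  pair <- plan$file_primer_map[[key]]
  if (is.null(pair)) stop("file not found: FID ", fid, " is not stored in this pool")
  file_bits <- plan$stream_bits[[paste0("file:", key)]]
  rounds <- 0L
  reads_total <- 0L

  data_layout <- function(n_shared = 1L) {
    fragment_layout(params$L_s, params$L_p, L_addr = plan$L_addr,
                    n_shared = n_shared, rs_len = params$rs_len)
  }
  decode_record <- function(stream_nt, nbits) {
    parse_data_record(bits_to_bytes(decode_bits(stream_nt, codec, nbits = nbits)))
  }
  decompress <- function(rec, tfid) {
    entry <- registry[[as.character(tfid)]]
    if (is.null(entry)) stop("unknown tool: no registry codec for FID ", tfid)
    entry$decompress(rec$data)
  }

  if (plan$method == "1-1CS") {
    sel <- pcr_select(store$pool, pair$forward, pair$reverse)
    reads <- sequence_pool(sel, seed)
    rounds <- rounds + 1L
    reads_total <- reads_total + length(reads)
    rec <- decode_record(assemble(reads, data_layout())$data, file_bits)
    out <- switch(rec$sm,
                  OF = rec$data,
                  CPF = decompress(rec, plan$file_tool[[key]]),
                  stop("unexpected SPF record in a continuous-storage pool"))
  } else if (plan$method == "M-1CI") {
    sel <- pcr_select(store$pool, pair$forward, pair$reverse)
    reads <- sequence_pool(sel, seed)
    rounds <- rounds + 1L
    reads_total <- reads_total + length(reads)
    stream <- assemble(reads, data_layout())$data
    ptr_nt <- plan$pointer_nt[[paste0("file:", key)]] %||% 0
    if (ptr_nt > 0) {
      ptr <- substr(stream, nchar(stream) - ptr_nt + 1L, nchar(stream))
      stream <- substr(stream, 1L, nchar(stream) - ptr_nt)
    }
    rec <- decode_record(stream, file_bits)
    if (rec$sm == "OF") {
      out <- rec$data
    } else {
      tfid <- rec$dl_or_tfid
      tool_f <- substr(ptr, 1L, params$L_p)
      tool_r <- substr(ptr, params$L_p + 1L, 2L * params$L_p)
      sel2 <- pcr_select(store$pool, tool_f, tool_r)
      reads2 <- sequence_pool(sel2, seed + 1L)
      rounds <- rounds + 1L
      reads_total <- reads_total + length(reads2)
      tool_bits <- plan$stream_bits[[paste0("tool:", format(tfid, scientific = FALSE))]]
      tool_reads <- filter_fragment_class(reads2, data_layout(), "tool")
      trec <- parse_tool_record(bits_to_bytes(decode_bits(
        assemble(tool_reads, data_layout())$tool, codec, nbits = tool_bits)))
      if (trec$fid != tfid) stop("dangling tool: retrieved tool FID mismatch")
      out <- decompress(rec, tfid)
    }
  } else { # 1-MCI
    tfid <- plan$file_tool[[key]]
    idx <- pcr_select_idx(store$pool, pair$forward, pair$reverse)
    if (!is.na(tfid)) {
      upair <- plan$tool_primer_map[[as.character(tfid)]]
      idx <- idx | pcr_select_idx(store$pool, upair$forward, pair$reverse)
    }
    reads <- sequence_pool(store$pool[idx], seed)
    rounds <- rounds + 1L
    reads_total <- reads_total + length(reads)
    n_shared <- if (!is.na(tfid)) {
      max(1L, length(plan$shared_clients[[as.character(tfid)]]))
    } else 1L
    parts <- assemble(reads, data_layout(n_shared))
    rec <- decode_record(parts$data, file_bits)
    if (rec$sm == "OF") {
      out <- rec$data
    } else {
      tool_bits <- plan$stream_bits[[paste0("tool:", format(rec$dl_or_tfid,
                                                            scientific = FALSE))]]
      if (is.null(parts$tool)) stop("dangling tool: no tool-class fragments amplified")
      trec <- parse_tool_record(bits_to_bytes(decode_bits(parts$tool, codec,
                                                          nbits = tool_bits)))
      if (trec$fid != rec$dl_or_tfid) stop("dangling tool: retrieved tool FID mismatch")
      out <- decompress(rec, rec$dl_or_tfid)
    }
  }
  structure(list(data = out, sequencing_rounds = rounds,
                 fragments_sequenced = reads_total),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<retrieval_result: %d bytes, %d sequencing round(s), %d reads>\n",
              length(x$data), x$sequencing_rounds, x$fragments_sequenced))
  invisible(x)
}

#' Write / read an oligo pool as FASTA
#'
#' Record ids (\code{fid|class|address}) are informational only; reading a
#' pool back discards nothing but retrieval never relies on them.
#'
#' @param pool a \code{\link{dna_pool}}.
#' @param path FASTA file path.
#' @return \code{write_pool_fasta} returns \code{path} invisibly;
#'   \code{read_pool_fasta} returns a \code{dna_pool}.
#' @export
write_pool_fasta <- function(pool, path) {
  ids <- names(pool)
  if (is.null(ids)) ids <- sprintf("frag%d", seq_along(pool))
  ids <- make.unique(ids, sep = "#")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(as.character(pool), ids)), filepath = path)
  invisible(path)
}

#' @rdname write_pool_fasta
#' @export
read_pool_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  dna_pool(as.character(ss), ids = names(ss))
}
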