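# Write-path planners for the three self-containment strategies.
#
#  1-1CS : one-to-one continuous storage. Each data file becomes one CPF
#          container embedding a full copy of its tool; k files sharing a
#          tool store k tool copies.
#  M-1CI : many-to-one chain indexing. Each data file becomes an SPF
#          container followed by a pointer block (the tool's forward and
#          reverse primer sequences, 2*L_p nt, appended to the encoded DNA
#          stream); each tool is stored once under its own primer pair.
#          Reading costs two sequencing rounds.
#  1-MCI : one-to-many chain indexing. Data files are SPF containers with no
#          pointer; every tool fragment carries the universal forward primer
#          at its head and the reverse primers of all n client files at its
#          tail, so one amplification retrieves file and tool together.

#' Write-path parameters
#'
#' @param L_s maximal fragment length in nt (default 220).
#' @param L_p primer length in nt (default 20).
#' @param codec codec name passed to \code{\link{dna_codec}}.
#' @param rs_len reserved error-correction field length in nt (default 0).
#' @return object of class \code{storage_params}.
#' @export
storage_params <- function(L_s = 220L, L_p = 20L, codec = "rotating", rs_len = 0L) {
  structure(list(L_s = as.integer(L_s), L_p = as.integer(L_p),
                 codec = codec, rs_len = as.integer(rs_len)),
            class = "storage_params")
}

#' Tool-sharing limit of one-to-many indexing
#'
#' A one-to-many tool fragment must hold the universal primer plus the
#' reverse primers of all n client files, so n is limited to
#' \code{0 < n < floor(L_s / L_p)}.
#'
#' @param n number of data files sharing one tool.
#' @param L_s,L_p fragment and primer lengths in nt.
#' @return TRUE iff n is within the sharing limit.
#' @examples
#' check_sharing_limit(10, 220, 20)  # TRUE
#' check_sharing_limit(11, 220, 20)  # FALSE
#' @export
check_sharing_limit <- function(n, L_s, L_p) {
  stopifnot(L_s > 0L, L_p > 0L)
  n > 0 & n < floor(L_s / L_p)
}

#' Bind a corpus to primers under one storage method
#'
#' Assigns primer pairs to files (and to tools where the method needs them)
#' and records the tool-sharing structure. File i takes the library's i-th
#' pair; under many-to-one indexing tool j takes pair \code{nfiles + j};
#' under one-to-many indexing every tool takes the universal pair.
#'
#' @param corpus a \code{\link{generate_corpus}} result (or any list with
#'   \code{files} and \code{tools} in the same shape).
#' @param method \code{"1-1CS"}, \code{"M-1CI"} or \code{"1-MCI"}.
#' @param primers a \code{\link{generate_primer_library}} result.
#' @return object of class \code{store_plan}.
#' @export
make_store_plan <- function(corpus, method = c("1-1CS", "M-1CI", "1-MCI"), primers) {
  method <- match.arg(method)
  nfiles <- length(corpus$files)
  ntools <- length(corpus$tools)
  if (length(primers) < nfiles + if (method == "M-1CI") ntools else 0L) {
    stop("primer library too small for this corpus/method")
  }
  if (method == "1-MCI" && is.null(primers$universal)) {
    stop("one-to-many indexing requires a universal primer pair")
  }
  file_primer_map <- list()
  file_tool <- numeric(0)
  for (i in seq_len(nfiles)) {
    f <- corpus$files[[i]]
    file_primer_map[[as.character(f$fid)]] <- primers$pairs[[i]]
    file_tool[[as.character(f$fid)]] <- if (is.na(f$tool_fid)) NA_real_ else f$tool_fid
  }
  tool_primer_map <- list()
  shared_clients <- list()
  for (j in seq_len(ntools)) {
    t <- corpus$tools[[j]]
    key <- as.character(t$fid)
    tool_primer_map[[key]] <- switch(method,
      "1-1CS" = NULL,
      "M-1CI" = primers$pairs[[nfiles + j]],
      "1-MCI" = primers$universal)
    clients <- sort(vapply(Filter(function(f) !is.na(f$tool_fid) && f$tool_fid == t$fid,
                                  corpus$files), `[[`, numeric(1), "fid"))
    shared_clients[[key]] <- clients
  }
  structure(list(method = method,
                 file_primer_map = file_primer_map,
                 tool_primer_map = tool_primer_map,
                 file_tool = file_tool,
                 shared_clients = shared_clients,
                 shared_counts = vapply(shared_clients, length, integer(1)),
                 registry_map = corpus$registry_map),
            class = "store_plan")
}

# Compress file bytes through the registry codec of its assigned tool.
compress_for_tool <- function(bytes, tfid, registry) {
  if (is.na(tfid)) return(bytes)
  entry <- registry[[as.character(tfid)]]
  if (is.null(entry)) stop("unknown tool: no registry codec for FID ", tfid)
  entry$compress(bytes)
}

# Shared stream bookkeeping: encode container bits, remember exact bit
# length per stream key ("file:<fid>" / "tool:<fid>").
encode_stream <- function(bits, codec) {
  list(dna = encode_bits(bits, codec), nbits = length(bits))
}

finish_store <- function(streams, plan, params, tool_tails) {
  # streams: named list(key -> list(dna, nbits, head, tails, class))
  codec <- dna_codec(params$codec)
  lens <- vapply(streams, function(s) nchar(s$dna), numeric(1))
  caps <- vapply(streams, function(s) {
    params$L_s - (1L + length(s$tails)) * params$L_p
  }, numeric(1))
  if (any(caps <= 0)) stop("capacity error: primers exceed the fragment length")
  L_addr <- choose_address_width(lens, caps, rs_len = params$rs_len)
  frags <- character(0)
  ids <- character(0)
  stream_bits <- numeric(0)
  pointer_nt <- numeric(0)
  for (key in names(streams)) {
    s <- streams[[key]]
    layout <- fragment_layout(params$L_s, params$L_p, L_addr = L_addr,
                              n_shared = max(1L, length(s$tails)),
                              rs_len = params$rs_len)
    fr <- segment(s$dna, layout, head = s$head, tails = s$tails, class = s$class)
    frags <- c(frags, fr)
    ids <- c(ids, sprintf("%s|%s|%d", sub("^(file|tool):", "", key),
                          s$class, seq_along(fr) - 1L))
    stream_bits[[key]] <- s$nbits
    pointer_nt[[key]] <- s$pointer_nt %||% 0
  }
  plan$params <- params
  plan$L_addr <- L_addr
  plan$stream_bits <- stream_bits
  plan$pointer_nt <- pointer_nt
  structure(list(pool = dna_pool(frags, ids = ids), plan = plan, params = params),
            class = "dna_store")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dna_store <- function(x, ...) {
  cat(sprintf("<dna_store: %s, %d fragments, %d total bases, L_addr = %d>\n",
              x$plan$method, length(x$pool), sum(nchar(x$pool)), x$plan$L_addr))
  invisible(x)
}

#' Store a corpus in an in-silico oligo pool
#'
#' The three write paths share their front end (compress, containerize,
#' transcode, fragment) and differ in how tool bytes and primers are bound;
#' see the method descriptions in the package vignette. Each returns a
#' \code{dna_store} bundling the fragment pool with the store plan manifest
#' (address width and exact per-stream container bit lengths) needed for
#' retrieval.
#'
#' @param corpus a \code{\link{generate_corpus}} result.
#' @param plan a \code{\link{make_store_plan}} for the matching method.
#' @param params a \code{\link{storage_params}}.
#' @param registry a \code{\link{tool_registry}} covering the corpus tools.
#' @return object of class \code{dna_store} with fields \code{pool},
#'   \code{plan} and \code{params}.
#' @export
store_1_1cs <- function(corpus, plan, params = storage_params(), registry) {
  stopifnot(plan$method == "1-1CS")
  codec <- dna_codec(params$codec)
  streams <- list()
  tool_bytes <- tool_bytes_map(corpus)
  for (f in corpus$files) {
    pair <- plan$file_primer_map[[as.character(f$fid)]]
    rec <- if (is.na(f$tool_fid)) {
      data_record(f$fid, "OF", data = f$data)
    } else {
      data_record(f$fid, "CPF",
                  data = compress_for_tool(f$data, f$tool_fid, registry),
                  tool = tool_bytes[[as.character(f$tool_fid)]])
    }
    es <- encode_stream(bytes_to_bits(serialize_data_record(rec)), codec)
    streams[[sprintf("file:%s", format(f$fid, scientific = FALSE))]] <-
      c(es, list(head = pair$forward, tails = pair$reverse, class = "data"))
  }
  finish_store(streams, plan, params)
}

#' @rdname store_1_1cs
#' @export
store_m_1ci <- function(corpus, plan, params = storage_params(), registry) {
  stopifnot(plan$method == "M-1CI")
  codec <- dna_codec(params$codec)
  streams <- list()
  for (f in corpus$files) {
    pair <- plan$file_primer_map[[as.character(f$fid)]]
    if (is.na(f$tool_fid)) {
      rec <- data_record(f$fid, "OF", data = f$data)
      es <- encode_stream(bytes_to_bits(serialize_data_record(rec)), codec)
    } else {
      rec <- data_record(f$fid, "SPF",
                         data = compress_for_tool(f$data, f$tool_fid, registry),
                         tfid = f$tool_fid)
      es <- encode_stream(bytes_to_bits(serialize_data_record(rec)), codec)
      tp <- plan$tool_primer_map[[as.character(f$tool_fid)]]
      es$dna <- paste0(es$dna, tp$forward, tp$reverse)
      es$pointer_nt <- 2 * params$L_p
    }
    streams[[sprintf("file:%s", format(f$fid, scientific = FALSE))]] <-
      c(es, list(head = pair$forward, tails = pair$reverse, class = "data"))
  }
  for (t in corpus$tools) {
    tp <- plan$tool_primer_map[[as.character(t$fid)]]
    es <- encode_stream(bytes_to_bits(serialize_tool_record(
      tool_record(t$fid, t$data))), codec)
    streams[[sprintf("tool:%s", format(t$fid, scientific = FALSE))]] <-
      c(es, list(head = tp$forward, tails = tp$reverse, class = "tool"))
  }
  finish_store(streams, plan, params)
}

#' @rdname store_1_1cs
#' @export
store_1_mci <- function(corpus, plan, params = storage_params(), registry) {
  stopifnot(plan$method == "1-MCI")
  codec <- dna_codec(params$codec)
  streams <- list()
  for (f in corpus$files) {
    pair <- plan$file_primer_map[[as.character(f$fid)]]
    rec <- if (is.na(f$tool_fid)) {
      data_record(f$fid, "OF", data = f$data)
    } else {
      data_record(f$fid, "SPF",
                  data = compress_for_tool(f$data, f$tool_fid, registry),
                  tfid = f$tool_fid)
    }
    es <- encode_stream(bytes_to_bits(serialize_data_record(rec)), codec)
    streams[[sprintf("file:%s", format(f$fid, scientific = FALSE))]] <-
      c(es, list(head = pair$forward, tails = pair$reverse, class = "data"))
  }
  for (t in corpus$tools) {
    key <- as.character(t$fid)
    clients <- plan$shared_clients[[key]]
    n <- length(clients)
    if (n > 0L) {
      if (!check_sharing_limit(n, params$L_s, params$L_p)) {
        stop(sprintf("limit error: %d client files exceed the sharing bound 0 < n < %d",
                     n, floor(params$L_s / params$L_p)))
      }
      payload_capacity(params$L_s, params$L_p, "mci-tool", n = n) # capacity error check
    }
    tails <- if (n > 0L) {
      vapply(clients, function(fid) plan$file_primer_map[[as.character(fid)]]$reverse,
             character(1))
    } else {
      plan$tool_primer_map[[key]]$reverse
    }
    es <- encode_stream(bytes_to_bits(serialize_tool_record(
      tool_record(t$fid, t$data))), codec)
    streams[[sprintf("tool:%s", format(t$fid, scientific = FALSE))]] <-
      c(es, list(head = plan$tool_primer_map[[key]]$forward,
                 tails = unname(tails), class = "tool"))
  }
  finish_store(streams, plan, params)
}

#' Dispatch to the write path of a plan's method
#' @inheritParams store_1_1cs
#' @return a \code{dna_store}.
#' @export
store_corpus <- function(corpus, plan, params = storage_params(), registry) {
  switch(plan$method,
         "1-1CS" = store_1_1cs(corpus, plan, params, registry),
         "M-1CI" = store_m_1ci(corpus, plan, params, registry),
         "1-MCI" = store_1_mci(corpus, plan, params, registry))
}

tool_bytes_map <- function(corpus) {
  setNames(lapply(corpus$tools, `[[`, "data"),
           vapply(corpus$tools, function(t) as.character(t$fid), character(1)))
}

#' Count the payload bits a pool stores
#'
#' Measures, from the pool itself, the binary payload the fragments carry:
#' each stream is selected by its primers, assembled, and its nucleotide
#' length converted back through the codec block size (so the count includes
#' at most one block of codec padding per stream). Pointer nucleotides in
#' many-to-one pools are counted one unit per nt, matching the closed-form
#' model's accounting of the 2*L_p pointer term.
#'
#' @param store a \code{dna_store}.
#' @return total payload bits represented in the pool.
#' @export
pool_payload_bits <- function(store) {
  plan <- store$plan
  codec <- dna_codec(store$params$codec)
  total <- 0
  for (key in names(plan$stream_bits)) {
    fid <- sub("^(file|tool):", "", key)
    is_tool <- startsWith(key, "tool:")
    if (is_tool) {
      pair <- plan$tool_primer_map[[fid]]
      clients <- plan$shared_clients[[fid]]
      reverse_site <- if (plan$method == "1-MCI" && length(clients)) {
        plan$file_primer_map[[as.character(clients[1L])]]$reverse
      } else {
        pair$reverse
      }
      sel <- pcr_select(store$pool, pair$forward, reverse_site)
      n_shared <- if (plan$method == "1-MCI") max(1L, length(clients)) else 1L
    } else {
      pair <- plan$file_primer_map[[fid]]
      sel <- pcr_select(store$pool, pair$forward, pair$reverse)
      tfid <- plan$file_tool[[fid]]
      n_shared <- if (plan$method == "1-MCI" && !is.na(tfid)) {
        max(1L, length(plan$shared_clients[[as.character(tfid)]]))
      } else 1L
    }
    layout <- fragment_layout(store$params$L_s, store$params$L_p,
                              L_addr = plan$L_addr, n_shared = n_shared,
                              rs_len = store$params$rs_len)
    frags <- filter_fragment_class(as.character(sel), layout,
                                   if (is_tool) "tool" else "data")
    parts <- assemble(frags, layout)
    stream <- if (is_tool) parts$tool else parts$data
    ptr <- plan$pointer_nt[[key]] %||% 0
    total <- total + codec_bits_for_bases(nchar(stream) - ptr, codec) + ptr
  }
  total
}
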