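# Shared fixture: 3 files over 2 tools (tool1 serves files 1-2, tool2 file 3).
make_fixture <- function(seed = 42) {
  spec <- corpus_spec(file_sizes_bits = c(4000, 3000, 2500),
                      redundancy = c(0.8, 0, 0.5),
                      file_tools = c(1, 1, 2),
                      tool_sizes_bits = c(2016, 1504),
                      tool_codecs = c("xz", "gzip"), seed = seed)
  generate_corpus(spec)
}

store_fixture <- function(method, seed = 42, params = storage_params()) {
  corpus <- make_fixture(seed)
  primers <- generate_primer_library(length(corpus$files) + length(corpus$tools),
                                     L_p = params$L_p, seed = seed)
  plan <- make_store_plan(corpus, method, primers)
  list(corpus = corpus, primers = primers,
       store = store_corpus(corpus, plan, params, corpus_registry(corpus)))
}

test_that("the sharing limit follows 0 < n < floor(L_s / L_p)", {
  expect_true(check_sharing_limit(10, 220, 20))
  expect_false(check_sharing_limit(11, 220, 20))
  expect_false(check_sharing_limit(0, 220, 20))
  # a corpus at the bound is refused by the one-to-many write path
  nf <- 11
  spec <- corpus_spec(file_sizes_bits = rep(800, nf), redundancy = rep(0, nf),
                      file_tools = rep(1L, nf), tool_sizes_bits = 800,
                      tool_codecs = "gzip", seed = 1)
  corpus <- generate_corpus(spec)
  primers <- generate_primer_library(nf + 1, seed = 2)
  plan <- make_store_plan(corpus, "1-MCI", primers)
  expect_error(store_1_mci(corpus, plan, storage_params(), corpus_registry(corpus)),
               "limit error")
})

test_that("continuous storage embeds one tool copy per client file", {
  fx <- store_fixture("1-1CS")
  store <- fx$store
  registry <- corpus_registry(fx$corpus)
  tool_bytes <- lapply(fx$corpus$tools, `[[`, "data")
  copies <- c(0, 0)
  for (f in fx$corpus$files) {
    res <- retrieve(store, f$fid, registry)
    expect_identical(res$data, f$data)
    # decode the file's own stream and inspect the embedded TD field
    pair <- store$plan$file_primer_map[[as.character(f$fid)]]
    sel <- pcr_select(store$pool, pair$forward, pair$reverse)
    stream <- assemble(as.character(sel),
                       fragment_layout(220, 20, store$plan$L_addr))$data
    rec <- parse_data_record(bits_to_bytes(decode_bits(
      stream, dna_codec(store$params$codec),
      nbits = store$plan$stream_bits[[paste0("file:", f$fid)]])))
    expect_identical(rec$sm, "CPF")
    for (j in 1:2) if (identical(rec$tool, tool_bytes[[j]])) copies[j] <- copies[j] + 1
  }
  expect_equal(copies, c(2, 1)) # one embedded copy per client file
})

test_that("many-to-one streams end in a decodable pointer to the tool's primers", {
  fx <- store_fixture("M-1CI")
  store <- fx$store
  for (f in fx$corpus$files) {
    pair <- store$plan$file_primer_map[[as.character(f$fid)]]
    tp <- store$plan$tool_primer_map[[as.character(f$tool_fid)]]
    sel <- pcr_select(store$pool, pair$forward, pair$reverse)
    stream <- assemble(as.character(sel),
                       fragment_layout(220, 20, store$plan$L_addr))$data
    ptr <- substr(stream, nchar(stream) - 39, nchar(stream))
    expect_identical(ptr, paste0(tp$forward, tp$reverse))
  }
  # each tool's bytes appear exactly once, under the tool's own primers
  for (t in fx$corpus$tools) {
    tp <- store$plan$tool_primer_map[[as.character(t$fid)]]
    sel <- pcr_select(store$pool, tp$forward, tp$reverse)
    layout <- fragment_layout(220, 20, store$plan$L_addr)
    frs <- dnastore:::filter_fragment_class(as.character(sel), layout, "tool")
    trec <- parse_tool_record(bits_to_bytes(decode_bits(
      assemble(frs, layout)$tool, dna_codec(store$params$codec),
      nbits = store$plan$stream_bits[[paste0("tool:", t$fid)]])))
    expect_identical(trec$tool, t$data)
  }
})

test_that("one-to-many tool fragments carry the universal primer and every client reverse primer", {
  fx <- store_fixture("1-MCI")
  store <- fx$store
  plan <- store$plan
  uni <- fx$primers$universal
  layout <- fragment_layout(220, 20, plan$L_addr,
                            n_shared = 2) # tool1 serves two clients
  tool1 <- fx$corpus$tools[[1]]
  clients <- plan$shared_clients[[as.character(tool1$fid)]]
  expect_length(clients, 2)
  sel <- pcr_select(store$pool, uni$forward,
                    plan$file_primer_map[[as.character(clients[1])]]$reverse)
  frs <- dnastore:::filter_fragment_class(as.character(sel), layout, "tool")
  expect_gt(length(frs), 0)
  for (fr in frs) {
    expect_true(grepl(uni$forward, fr, fixed = TRUE))
    for (fid in clients) {
      expect_true(grepl(plan$file_primer_map[[as.character(fid)]]$reverse,
                        fr, fixed = TRUE))
    }
  }
  # round trip for every stored file
  registry <- corpus_registry(fx$corpus)
  for (f in fx$corpus$files) {
    expect_identical(retrieve(store, f$fid, registry)$data, f$data)
  }
})

test_that("pool payload bits agree with the closed-form stored-bits models", {
  # uniform-size corpus so the per-group model applies directly
  spec <- corpus_spec(file_sizes_bits = rep(3200, 3), redundancy = rep(0.5, 3),
                      file_tools = c(1, 1, 1), tool_sizes_bits = 2016,
                      tool_codecs = "xz", seed = 5)
  corpus <- generate_corpus(spec)
  params <- storage_params()
  registry <- corpus_registry(corpus)
  primers <- generate_primer_library(4, seed = 5)
  bits <- sapply(c("1-1CS", "M-1CI", "1-MCI"), function(m) {
    plan <- make_store_plan(corpus, m, primers)
    pool_payload_bits(store_corpus(corpus, plan, params, registry))
  })
  model <- sapply(c("1-1CS", "M-1CI", "1-MCI"), function(m) {
    dnastore:::model_stored_bits(corpus, m, registry, params)
  })
  # allowance: one 19-bit codec block per fragment stream plus the 40-bit
  # tool-record header the closed forms omit
  streams <- c("1-1CS" = 3, "M-1CI" = 4, "1-MCI" = 4)
  headers <- c("1-1CS" = 0, "M-1CI" = 40, "1-MCI" = 40)
  for (m in names(bits)) {
    expect_lte(abs(bits[[m]] - model[[m]]), streams[[m]] * 19 + headers[[m]])
  }
  # the structural saving: separate storage beats continuous by (n-1) * S_T
  expect_true(bits[["1-MCI"]] <= bits[["M-1CI"]])
  expect_true(bits[["1-MCI"]] <= bits[["1-1CS"]])
})
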