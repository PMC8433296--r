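# Independent oracles kept deliberately naive: they re-derive quantities by
# brute force so the tested code path never checks itself.

# Pairwise Hamming distance matrix by double loop over character vectors.
brute_force_hamming <- function(seqs) {
  n <- length(seqs)
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- strsplit(seqs[i], "")[[1]]
      b <- strsplit(seqs[j], "")[[1]]
      m[i, j] <- sum(a != b)
    }
  }
  m
}

# Defining 2-bit mapping, written out longhand.
oracle_quaternary <- function(bitstring) {
  bits <- as.integer(strsplit(bitstring, "")[[1]])
  out <- character(0)
  for (k in seq(1, length(bits), by = 2)) {
    out <- c(out, switch(paste0(bits[k], bits[k + 1]),
                         "00" = "A", "01" = "C", "10" = "G", "11" = "T"))
  }
  paste(out, collapse = "")
}

# Longest run by direct scan.
oracle_max_run <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  best <- 0L
  run <- 0L
  prev <- ""
  for (ch in chars) {
    run <- if (ch == prev) run + 1L else 1L
    prev <- ch
    best <- max(best, run)
  }
  best
}

# Random bytes helper for fixtures built in code.
rand_raw <- function(n) as.raw(sample(0:255, n, replace = TRUE))

# Small random corpus for property loops: 1-3 files, 1-2 tools, occasionally
# an unprocessed (tool-less) file.
random_small_corpus <- function(seed) {
  withr::with_seed(seed, {
    nf <- sample(1:3, 1)
    nt <- sample(1:2, 1)
    tools <- sample(c(NA, seq_len(nt)), nf, replace = TRUE,
                    prob = c(0.2, rep(0.8 / nt, nt)))
    if (all(is.na(tools))) tools[1] <- 1L
    corpus_spec(
      file_sizes_bits = sample(400:4000, nf) * 8,
      redundancy = round(runif(nf), 2),
      file_tools = tools,
      tool_sizes_bits = sample(100:400, nt) * 8,
      tool_codecs = sample(c("gzip", "xz", "none"), nt, replace = TRUE),
      seed = seed
    )
  })
}
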