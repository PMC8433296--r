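#' Binary-to-nucleotide codecs
#'
#' A codec transcodes bit strings into nucleotide sequences and back. Each
#' codec declares its base factor \code{a} (bases emitted per input bit); the
#' storage density of a bare codec stream is \code{d = 1/a} bits per base.
#' Two reference codecs ship with the package:
#' \describe{
#'   \item{\code{"quaternary"}}{the defining 2-bit mapping A=00, C=01, G=10,
#'     T=11; \code{a = 0.5} bases/bit (2 bits/base).}
#'   \item{\code{"rotating"}}{a run-length-constrained block code: every 19
#'     input bits become 12 ternary digits, and each digit advances the
#'     current base by 1..3 positions (mod 4), so consecutive bases always
#'     differ. Declared \code{a = 1/1.6} bases/bit; the realised asymptotic
#'     rate is 12/19, about 1% away. No homopolymer longer than 1 nt is ever
#'     emitted.}
#' }
#'
#' @param name codec name, \code{"quaternary"} or \code{"rotating"}.
#' @return an object of class \code{dna_codec} with fields \code{name},
#'   \code{base_factor} (declared \code{a}), \code{block_bits} and
#'   \code{bases_per_block}.
#' @examples
#' codec <- dna_codec("quaternary")
#' encode_bits("00011011", codec)  # "ACGT"
#' @export
dna_codec <- function(name = c("quaternary", "rotating")) {
  name <- match.arg(name)
  spec <- switch(name,
    quaternary = list(base_factor = 0.5, block_bits = 2L, bases_per_block = 1L),
    rotating   = list(base_factor = 1 / 1.6, block_bits = 19L, bases_per_block = 12L)
  )
  structure(c(list(name = name), spec), class = "dna_codec")
}

#' @export
print.dna_codec <- function(x, ...) {
  cat(sprintf("<dna_codec '%s': a = %.4f bases/bit, block %d bits -> %d nt>\n",
              x$name, x$base_factor, x$block_bits, x$bases_per_block))
  invisible(x)
}

#' Encode a bit string as DNA
#'
#' Input bits are zero-padded up to the codec's block size; the pad length is
#' not recorded in the DNA stream (callers keep the true bit length, e.g. in
#' a store plan or manifest).
#'
#' @param payload bits: a \code{"0"}/\code{"1"} character scalar, a 0/1
#'   vector, or a raw vector.
#' @param codec a \code{\link{dna_codec}}.
#' @return nucleotide string over A/C/G/T.
#' @export
encode_bits <- function(payload, codec = dna_codec("quaternary")) {
  stopifnot(inherits(codec, "dna_codec"))
  bits <- as_bits(payload)
  if (length(bits) == 0L) return("")
  pad <- (codec$block_bits - length(bits) %% codec$block_bits) %% codec$block_bits
  if (pad > 0L) bits <- c(bits, integer(pad))
  switch(codec$name,
         quaternary = encode_quaternary(bits),
         rotating = encode_rotating(bits))
}

#' Decode a DNA sequence back to bits
#'
#' Exact inverse of \code{\link{encode_bits}}. If \code{nbits} is supplied
#' the decoded stream is truncated to that many bits (stripping codec block
#' padding); otherwise all decoded bits, padding included, are returned.
#'
#' @param sequence nucleotide string produced by the same codec.
#' @param codec a \code{\link{dna_codec}}.
#' @param nbits optional true payload bit length.
#' @return integer 0/1 vector (see \code{\link{bits_to_string}} to render).
#' @export
decode_bits <- function(sequence, codec = dna_codec("quaternary"), nbits = NULL) {
  stopifnot(inherits(codec, "dna_codec"), is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) {
    if (!is.null(nbits) && nbits > 0) stop("empty sequence cannot yield bits")
    return(integer(0))
  }
  if (nchar(sequence) %% codec$bases_per_block != 0L) {
    stop(sprintf("sequence length %d is not a multiple of the codec block (%d nt)",
                 nchar(sequence), codec$bases_per_block))
  }
  vals <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], DNA_BASES) - 1L
  if (anyNA(vals)) {
    stop(sprintf("non-decodable symbol at position %d", which(is.na(vals))[1L]))
  }
  bits <- switch(codec$name,
                 quaternary = decode_quaternary(vals),
                 rotating = decode_rotating(vals))
  if (!is.null(nbits)) {
    if (nbits > length(bits)) stop("sequence too short for requested bit count")
    bits <- bits[seq_len(nbits)]
  }
  bits
}

# -- quaternary reference codec ----------------------------------------------

encode_quaternary <- function(bits) {
  m <- matrix(bits, nrow = 2L)
  vals <- m[1L, ] * 2L + m[2L, ]
  paste(DNA_BASES[vals + 1L], collapse = "")
}

decode_quaternary <- function(vals) {
  as.vector(rbind(vals %/% 2L, vals %% 2L))
}

# -- rotating constrained codec ----------------------------------------------
# 19 bits -> value < 2^19 -> 12 ternary digits (big-endian) -> each digit t
# moves the emitted base to (prev + t + 1) mod 4. Since t + 1 is in 1..3 the
# next base never equals the previous one; decoding inverts with a diff.

encode_rotating <- function(bits) {
  nblocks <- length(bits) %/% 19L
  m <- matrix(bits, nrow = 19L)
  vals <- as.vector(2^(18:0) %*% m) # exact: < 2^19
  trits <- vapply(seq_len(12L), function(j) vals %/% 3^(12L - j) %% 3,
                  numeric(nblocks))
  trits <- as.vector(t(matrix(trits, nrow = nblocks)))
  pos <- cumsum(trits + 1) %% 4
  paste(DNA_BASES[pos + 1L], collapse = "")
}

decode_rotating <- function(vals) {
  prev <- c(0L, vals[-length(vals)])
  trits <- (vals - prev - 1L) %% 4L
  bad <- which(trits == 3L)
  if (length(bad)) {
    stop(sprintf("invalid repeated base at position %d: not a rotating-codec stream",
                 bad[1L]))
  }
  nblocks <- length(trits) %/% 12L
  m <- matrix(trits, nrow = 12L)
  vals19 <- as.vector(3^(11:0) %*% m)
  bits <- vapply(seq_len(19L), function(j) vals19 %/% 2^(19L - j) %% 2,
                 numeric(nblocks))
  as.integer(t(matrix(bits, nrow = nblocks)))
}

# Number of bases the codec emits for nbits of input (after block padding).
codec_bases_for_bits <- function(nbits, codec) {
  if (nbits == 0) return(0)
  ceiling(nbits / codec$block_bits) * codec$bases_per_block
}

# Padded bit count represented by a whole-block stream of len nt.
codec_bits_for_bases <- function(len_nt, codec) {
  (len_nt %/% codec$bases_per_block) * codec$block_bits
}
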