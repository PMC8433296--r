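# Low-level bit / byte / base-4 helpers shared by the codec, container and
# fragmentation layers. Bit vectors are integer vectors of 0/1 in
# most-significant-bit-first order (byte 0x68 -> 0 1 1 0 1 0 0 0).

DNA_BASES <- c("A", "C", "G", "T")

#' Coerce bits
#'
#' Accepts a character scalar of \code{"0"}/\code{"1"}, a numeric 0/1 vector,
#' or a raw vector (expanded MSB-first) and returns an integer 0/1 vector.
#'
#' @param x bits in any of the accepted forms.
#' @return integer vector of 0s and 1s.
#' @export
as_bits <- function(x) {
  if (is.raw(x)) return(bytes_to_bits(x))
  if (is.character(x)) {
    if (length(x) != 1L) stop("bit strings must be length-1 character vectors")
    if (!nzchar(x)) return(integer(0))
    v <- as.integer(strsplit(x, "", fixed = TRUE)[[1L]])
    if (anyNA(v) || any(v < 0L | v > 1L)) {
      stop("bit string may contain only '0' and '1'")
    }
    return(v)
  }
  if (is.numeric(x) || is.logical(x)) {
    v <- as.integer(x)
    if (anyNA(v) || any(v < 0L | v > 1L)) stop("bits must be 0 or 1")
    return(v)
  }
  stop("cannot interpret input as bits")
}

#' Render a bit vector as a character string
#' @param bits integer 0/1 vector.
#' @return character scalar such as \code{"00011011"}.
#' @export
bits_to_string <- function(bits) paste(bits, collapse = "")

#' Expand raw bytes to bits (MSB first)
#' @param bytes raw vector.
#' @return integer 0/1 vector of length \code{8 * length(bytes)}.
#' @export
bytes_to_bits <- function(bytes) {
  if (length(bytes) == 0L) return(integer(0))
  m <- matrix(as.integer(rawToBits(bytes)), nrow = 8L)
  as.vector(m[8:1, , drop = FALSE])
}

#' Pack bits (MSB first) back into raw bytes
#' @param bits integer 0/1 vector; length must be a multiple of 8.
#' @return raw vector.
#' @export
bits_to_bytes <- function(bits) {
  bits <- as_bits(bits)
  if (length(bits) %% 8L != 0L) {
    stop("bit vector length must be a multiple of 8 to form bytes")
  }
  if (length(bits) == 0L) return(raw(0))
  m <- matrix(bits, nrow = 8L)
  packBits(as.logical(m[8:1, , drop = FALSE]), type = "raw")
}

# Vectorised non-negative integer -> fixed-width base-4 string (big-endian),
# used for fragment addresses.
int_to_base4 <- function(x, width) {
  x <- as.numeric(x)
  if (any(x < 0) || any(x >= 4^width)) stop("value out of base-4 address range")
  if (length(x) == 0L) return(character(0))
  digits <- vapply(seq_len(width), function(j) x %/% 4^(width - j) %% 4,
                   numeric(length(x)))
  digits <- matrix(digits, nrow = length(x))
  apply(digits, 1L, function(d) paste(DNA_BASES[d + 1], collapse = ""))
}

# Fixed-width base-4 string(s) -> integer value(s).
base4_to_int <- function(s) {
  vapply(s, function(one) {
    d <- match(strsplit(one, "", fixed = TRUE)[[1L]], DNA_BASES) - 1L
    if (anyNA(d)) stop("invalid base-4 address: ", one)
    sum(d * 4^(rev(seq_along(d)) - 1L))
  }, numeric(1), USE.NAMES = FALSE)
}

# Longest homopolymer run in a nucleotide string (0 for empty input).
max_homopolymer_run <- function(sequence) {
  if (!nzchar(sequence)) return(0L)
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1L]])
  max(r$lengths)
}

# GC fraction of a nucleotide string.
gc_fraction <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  mean(chars %in% c("G", "C"))
}

# Hamming distance between two equal-length nucleotide strings.
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("Hamming distance requires equal lengths")
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# Split a nucleotide string into single characters, erroring on non-ACGT with
# the first offending position.
dna_chars <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% DNA_BASES))
  if (length(bad)) {
    stop(sprintf("non-ACGT symbol '%s' at position %d", chars[bad[1L]], bad[1L]))
  }
  chars
}
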