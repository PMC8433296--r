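# Closed-form storage-overhead models: compression efficiency, stored
# binary size Sb per method, stored base count Sd per method, storage
# density, break-even size and parameter sweeps. All sizes are in bits; the
# base factor a is bases per bit; density d = 1/a is bits per base.

#' Model parameters
#'
#' One container for the symbols of the closed-form cost models.
#'
#' @param n number of data files (integer >= 0).
#' @param S_D per-file original sizes in bits: a scalar (uniform size) or a
#'   length-n vector.
#' @param S_h per-file header size in bits (default 10).
#' @param S_T tool size in bits (default 2010).
#' @param L_s,L_p fragment and primer lengths in nt (defaults 220, 20).
#' @param a base factor, bases per bit (default 1/1.6).
#' @param r_c compression ratio S_c/S_o (default 0.34).
#' @return object of class \code{system_parameters}.
#' @export
system_parameters <- function(n = 3L, S_D = 100000, S_h = 10, S_T = 2010,
                              L_s = 220L, L_p = 20L, a = 1 / 1.6, r_c = 0.34) {
  stopifnot(n >= 0, all(S_D > 0), S_h >= 0, S_T >= 0, L_s > 0, L_p > 0,
            a > 0, r_c >= 0)
  if (!length(S_D) %in% c(1L, max(1L, n))) {
    stop("S_D must be a scalar or one size per file")
  }
  structure(list(n = as.integer(n), S_D = S_D, S_h = S_h, S_T = S_T,
                 L_s = L_s, L_p = L_p, a = a, r_c = r_c),
            class = "system_parameters")
}

per_file_sizes <- function(params) {
  n <- params$n
  if (n == 0L) return(numeric(0))
  if (length(params$S_D) == 1L) rep(params$S_D, n)
  else if (length(params$S_D) == n) params$S_D
  else stop("S_D must be scalar or length n")
}

#' Compression efficiency with tool overhead
#'
#' \code{e_c = 1 - e}, where \code{e = (r_c * S_o + S_T) / S_o}. With no
#' stored tool (\code{S_T = 0}) this reduces to the ideal \code{1 - r_c};
#' it drops to zero or below once \code{S_T >= (1 - r_c) * S_o}.
#'
#' @param r_c compression ratio.
#' @param S_o original data size in bits (> 0).
#' @param S_T tool size in bits.
#' @return compression efficiency (dimensionless, can be negative).
#' @examples
#' compression_efficiency(0.34, 1e6, 0)  # 0.66, the ideal case
#' @export
compression_efficiency <- function(r_c, S_o, S_T) {
  if (any(S_o <= 0)) stop("domain error: S_o must be positive")
  1 - (r_c * S_o + S_T) / S_o
}

#' Break-even original size
#'
#' The minimal \code{S_o} at which storing the tool still pays for itself:
#' \code{S_T / (1 - r_c)}, i.e. the root of
#' \code{compression_efficiency(r_c, S_o, S_T)}.
#'
#' @param r_c compression ratio (< 1).
#' @param S_T tool size in bits.
#' @return break-even size in bits.
#' @export
breakeven_S_o <- function(r_c, S_T) {
  if (any(r_c >= 1)) stop("no break-even: r_c >= 1 never recovers the tool cost")
  S_T / (1 - r_c)
}

#' Stored binary size per method
#'
#' The amount of binary data each self-containment method must store:
#' continuous storage repeats the tool per file
#' (\code{sum(r_c * S_Di) + n * (S_h + S_T)}); many-to-one indexing stores
#' the tool once plus a 2*L_p pointer per file
#' (\code{sum(r_c * S_Di) + n * (S_h + 2 * L_p) + S_T}); one-to-many
#' indexing stores the tool once with no pointer
#' (\code{sum(r_c * S_Di) + n * S_h + S_T}).
#'
#' @param method \code{"1-1CS"}, \code{"M-1CI"} or \code{"1-MCI"}.
#' @param params a \code{\link{system_parameters}}.
#' @return stored size in bits.
#' @export
stored_bits <- function(method = c("1-1CS", "M-1CI", "1-MCI"), params) {
  method <- match.arg(method)
  stopifnot(inherits(params, "system_parameters"))
  sizes <- per_file_sizes(params)
  compressed <- sum(params$r_c * sizes)
  n <- params$n
  switch(method,
         "1-1CS" = compressed + n * (params$S_h + params$S_T),
         "M-1CI" = compressed + n * (params$S_h + 2 * params$L_p) + params$S_T,
         "1-MCI" = compressed + n * params$S_h + params$S_T)
}

#' Stored base count per method
#'
#' Total bases after fragmentation adds primers. Ordinary fragments carry
#' one primer at each end, so continuous and many-to-one storage scale their
#' stored bits by \code{a * (1 + 2*L_p / (L_s - 2*L_p))}. One-to-many
#' storage prices the data fragments' primers against \code{L_s} and the
#' tool fragments' \code{(n+1)} primers against the reduced tool payload
#' \code{L_s - (n+1)*L_p}.
#'
#' @inheritParams stored_bits
#' @return stored size in bases (real-valued: fragment counts are not
#'   rounded, exactly as in the closed form; the pool emission path uses
#'   integer ceilings).
#' @export
stored_bases <- function(method = c("1-1CS", "M-1CI", "1-MCI"), params) {
  method <- match.arg(method)
  stopifnot(inherits(params, "system_parameters"))
  a <- params$a
  L_s <- params$L_s
  L_p <- params$L_p
  if (method %in% c("1-1CS", "M-1CI")) {
    if (L_s - 2 * L_p <= 0) stop("capacity error: L_s - 2*L_p must be positive")
    sb <- stored_bits(method, params)
    return(a * sb * (1 + 2 * L_p / (L_s - 2 * L_p)))
  }
  n <- params$n
  if (L_s - (n + 1) * L_p <= 0) {
    stop("capacity error: L_s - (n+1)*L_p must be positive for one-to-many tools")
  }
  sb <- stored_bits("1-MCI", params)
  compressed_plus_headers <- sum(params$r_c * per_file_sizes(params)) + n * params$S_h
  sb * a +
    (compressed_plus_headers * a / L_s) * 2 * L_p +
    (params$S_T * a / (L_s - (n + 1) * L_p)) * (n + 1) * L_p
}

#' Storage density
#'
#' Bits represented per stored base, \code{d = S_o / S_b}; a bare codec
#' stream with no primers or headers attains \code{1/a}.
#'
#' @param S_o stored information in bits.
#' @param S_b stored bases.
#' @return bits per base.
#' @export
storage_density <- function(S_o, S_b) {
  if (any(S_b <= 0)) stop("domain error: S_b must be positive")
  S_o / S_b
}

#' Sweep the cost models over parameter ranges
#'
#' Evaluates Sb and Sd for all three methods (plus the ideal compression
#' efficiency and bare-codec density) over a grid of file counts and
#' fragment lengths.
#'
#' @param params baseline \code{\link{system_parameters}}.
#' @param n integer vector of file counts (default: the baseline n).
#' @param L_s numeric vector of fragment lengths (default: baseline L_s).
#' @return data.frame with one row per (n, L_s) combination and columns
#'   \code{n, L_s, ratio, Sb_1_1CS, Sb_M_1CI, Sb_1_MCI, Sd_1_1CS, Sd_M_1CI,
#'   Sd_1_MCI, e_c, d_codec}.
#' @export
overhead_sweep <- function(params, n = NULL, L_s = NULL) {
  stopifnot(inherits(params, "system_parameters"))
  n <- if (is.null(n)) params$n else n
  L_s <- if (is.null(L_s)) params$L_s else L_s
  if (length(params$S_D) != 1L) {
    stop("sweeps require a uniform per-file size S_D")
  }
  grid <- expand.grid(n = n, L_s = L_s, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- system_parameters(n = grid$n[i], S_D = params$S_D, S_h = params$S_h,
                           S_T = params$S_T, L_s = grid$L_s[i], L_p = params$L_p,
                           a = params$a, r_c = params$r_c)
    data.frame(n = p$n, L_s = p$L_s, ratio = p$L_s / p$L_p,
               Sb_1_1CS = stored_bits("1-1CS", p),
               Sb_M_1CI = stored_bits("M-1CI", p),
               Sb_1_MCI = stored_bits("1-MCI", p),
               Sd_1_1CS = stored_bases("1-1CS", p),
               Sd_M_1CI = stored_bases("M-1CI", p),
               Sd_1_MCI = stored_bases("1-MCI", p),
               e_c = compression_efficiency(p$r_c, sum(per_file_sizes(p)), p$S_T),
               d_codec = 1 / p$a)
  })
  do.call(rbind, rows)
}
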