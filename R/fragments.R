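# Fragmentation: split an encoded long DNA sequence into fixed-format
# synthesizable oligos and reassemble sequenced fragments.
#
# Fragment field order (5' -> 3'):
#   head_primer | 'A' | address | C | payload | RS | 'T' | tail_primer(s)
# The A/T literals mark the direction of the sequence; C is a 1-nt class
# flag (A = data file, T = tool file); the address is a fixed-width
# big-endian quaternary integer giving the offset of the payload in the
# file; RS is a reserved (default zero-length) error-correction field.

C_FLAG <- c(data = "A", tool = "T")

#' Fragment layout parameters
#'
#' @param L_s maximal fragment length in nt, direction markers excluded
#'   (default 220).
#' @param L_p primer length in nt (default 20).
#' @param L_addr address-field width in nt.
#' @param n_shared number of tail primers carried by tool fragments (1 for
#'   continuous / many-to-one storage; n, the client-file count, for
#'   one-to-many tool fragments).
#' @param rs_len reserved error-correction field length in nt (default 0;
#'   the field is defined but unpopulated).
#' @return object of class \code{fragment_layout}.
#' @export
fragment_layout <- function(L_s = 220L, L_p = 20L, L_addr = 1L, n_shared = 1L,
                            rs_len = 0L) {
  stopifnot(L_s > 0L, L_p > 0L, L_addr >= 1L, n_shared >= 1L, rs_len >= 0L)
  structure(list(L_s = as.integer(L_s), L_p = as.integer(L_p),
                 L_addr = as.integer(L_addr), n_shared = as.integer(n_shared),
                 rs_len = as.integer(rs_len)),
            class = "fragment_layout")
}

#' Gross payload capacity of a fragment
#'
#' For ordinary fragments (data files, and tool files under continuous or
#' many-to-one storage) the capacity is \code{L_s - 2*L_p}: one primer at
#' each end. One-to-many tool fragments carry the universal primer plus the
#' reverse primers of all \code{n} client files, leaving
#' \code{L_s - (n+1)*L_p}. Address, class-flag and RS fields are carved out
#' of this gross capacity downstream.
#'
#' @param L_s,L_p fragment and primer lengths in nt.
#' @param role \code{"data"} (ordinary) or \code{"mci-tool"}.
#' @param n client-file count for \code{"mci-tool"}.
#' @return capacity in nt; non-positive capacity raises a capacity error.
#' @examples
#' payload_capacity(220, 20)                      # 180
#' payload_capacity(220, 20, "mci-tool", n = 2)   # 160
#' @export
payload_capacity <- function(L_s, L_p, role = c("data", "mci-tool"), n = 1L) {
  role <- match.arg(role)
  stopifnot(L_s > 0L, L_p > 0L)
  if (role == "mci-tool") stopifnot(n >= 1L)
  cap <- if (role == "data") L_s - 2L * L_p else L_s - (n + 1L) * L_p
  if (cap <= 0L) {
    stop(sprintf("capacity error: %s fragment has no payload room (L_s = %d, L_p = %d%s)",
                 role, L_s, L_p,
                 if (role == "mci-tool") sprintf(", n = %d", n) else ""))
  }
  as.integer(cap)
}

# Net per-fragment payload once address, class flag and RS are carved out.
net_payload <- function(gross, layout) {
  net <- gross - layout$L_addr - 1L - layout$rs_len
  if (net <= 0L) {
    stop(sprintf("capacity error: address/flag fields (%d nt) exhaust the %d-nt payload",
                 layout$L_addr + 1L + layout$rs_len, gross))
  }
  net
}

#' Split a long DNA sequence into addressed fragments
#'
#' Payloads concatenated in address order reproduce the input exactly; the
#' last fragment may be short. Addresses are 0-based consecutive integers in
#' fixed-width quaternary.
#'
#' @param long_dna nucleotide string to split.
#' @param layout a \code{\link{fragment_layout}}.
#' @param head head primer sequence (length \code{L_p}).
#' @param tails character vector of tail primer sequences (one for ordinary
#'   fragments; the n client reverse primers for one-to-many tool fragments).
#' @param class \code{"data"} or \code{"tool"}: sets the C flag.
#' @return character vector of fragment sequences (empty for empty input).
#' @export
segment <- function(long_dna, layout, head, tails, class = c("data", "tool")) {
  class <- match.arg(class)
  stopifnot(inherits(layout, "fragment_layout"),
            nchar(head) == layout$L_p, all(nchar(tails) == layout$L_p))
  if (!nzchar(long_dna)) return(character(0))
  gross <- layout$L_s - (1L + length(tails)) * layout$L_p
  if (gross <= 0L) stop("capacity error: primers exceed the fragment length")
  net <- net_payload(gross, layout)
  len <- nchar(long_dna)
  nfrag <- ceiling(len / net)
  if (nfrag > 4^layout$L_addr) {
    stop(sprintf("address overflow: %d fragments exceed the 4^%d address space",
                 nfrag, layout$L_addr))
  }
  starts <- seq(1L, by = net, length.out = nfrag)
  payloads <- substring(long_dna, starts, pmin(starts + net - 1L, len))
  addresses <- int_to_base4(seq_len(nfrag) - 1L, layout$L_addr)
  paste0(head, "A", addresses, C_FLAG[[class]], payloads,
         strrep("A", layout$rs_len), "T", paste(tails, collapse = ""))
}

#' Parse one fragment into its fields
#'
#' @param fragment fragment sequence.
#' @param layout a \code{\link{fragment_layout}}; \code{n_shared} gives the
#'   tail-primer count of tool-class fragments.
#' @return list with \code{head}, \code{address} (integer), \code{class},
#'   \code{payload}, \code{tails} (character vector).
#' @export
parse_fragment <- function(fragment, layout) {
  L_p <- layout$L_p
  La <- layout$L_addr
  if (substr(fragment, L_p + 1L, L_p + 1L) != "A") {
    stop("malformed fragment: missing head direction marker")
  }
  cflag <- substr(fragment, L_p + La + 2L, L_p + La + 2L)
  class <- names(C_FLAG)[match(cflag, C_FLAG)]
  if (is.na(class)) stop("malformed fragment: unknown class flag '", cflag, "'")
  ntails <- if (class == "tool") layout$n_shared else 1L
  len <- nchar(fragment)
  tail_block <- ntails * L_p
  marker_pos <- len - tail_block
  if (marker_pos <= L_p + La + 2L || substr(fragment, marker_pos, marker_pos) != "T") {
    stop("malformed fragment: missing tail direction marker")
  }
  payload <- substr(fragment, L_p + La + 3L, marker_pos - 1L - layout$rs_len)
  tails <- substring(fragment,
                     len - tail_block + (seq_len(ntails) - 1L) * L_p + 1L,
                     len - tail_block + seq_len(ntails) * L_p)
  list(head = substr(fragment, 1L, L_p),
       address = base4_to_int(substr(fragment, L_p + 2L, L_p + 1L + La)),
       class = class, payload = payload, tails = tails)
}

#' Reassemble fragments into long sequences, one per class
#'
#' Order-independent inverse of \code{\link{segment}}: fragments are parsed,
#' sorted by decoded address within each class, checked for completeness,
#' and their payloads concatenated with primers and markers stripped.
#' Duplicate addresses are tolerated when their payloads agree (a pool is a
#' multiset); conflicting duplicates raise an error rather than guessing.
#'
#' @param fragments character vector of fragment sequences, any order.
#' @param layout a \code{\link{fragment_layout}}.
#' @return list with \code{data} and \code{tool} long sequences (NULL for an
#'   absent class).
#' @export
assemble <- function(fragments, layout) {
  parsed <- lapply(fragments, parse_fragment, layout = layout)
  out <- list(data = NULL, tool = NULL)
  for (cls in c("data", "tool")) {
    sel <- Filter(function(p) p$class == cls, parsed)
    if (!length(sel)) next
    addr <- vapply(sel, `[[`, numeric(1), "address")
    payloads <- vapply(sel, `[[`, character(1), "payload")
    keep <- !duplicated(addr)
    for (a in unique(addr[duplicated(addr)])) {
      if (length(unique(payloads[addr == a])) > 1L) {
        stop(sprintf("conflict error: %s-class address %d has divergent payloads",
                     cls, a))
      }
    }
    addr <- addr[keep]
    payloads <- payloads[keep]
    expected <- seq(0L, max(addr))
    missing <- setdiff(expected, addr)
    if (length(missing)) {
      stop(sprintf("gap error: %s-class fragments missing address(es) %s",
                   cls, paste(missing, collapse = ", ")))
    }
    out[[cls]] <- paste(payloads[order(addr)], collapse = "")
  }
  out
}

# Keep only fragments of one class (reads the C flag). PCR amplification can
# co-select fragments of the other class -- e.g. a data fragment whose
# payload ends in a tool-primer pointer -- which is what the class flag is
# for.
filter_fragment_class <- function(fragments, layout, class) {
  if (!length(fragments)) return(fragments)
  cls <- vapply(fragments, function(f) parse_fragment(f, layout)$class,
                character(1), USE.NAMES = FALSE)
  fragments[cls == class]
}

# Smallest address width such that every stream fits its address space.
# stream_nt: nt lengths of the long sequences; gross_caps: per-stream gross
# payload capacities (same length).
choose_address_width <- function(stream_nt, gross_caps, rs_len = 0L, max_width = 16L) {
  stopifnot(length(stream_nt) == length(gross_caps))
  for (w in seq_len(max_width)) {
    nets <- gross_caps - w - 1L - rs_len
    if (any(nets <= 0L)) next
    if (all(ceiling(stream_nt / nets) <= 4^w)) return(w)
  }
  stop("address overflow: no feasible address width up to ", max_width, " nt")
}
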