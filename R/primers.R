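#' Primer design constraints
#'
#' Primers double as file indexes: every stored file is amplified (and hence
#' addressed) through its primer pair, so primers must be biologically
#' plausible oligos and mutually distinguishable. Homology between primers is
#' operationalised as a minimum pairwise Hamming distance.
#'
#' @param gc_min,gc_max allowed GC fraction range (defaults 0.4--0.6, the
#'   usual oligo design heuristic).
#' @param max_homopolymer longest allowed single-base run (default 3 nt).
#' @param min_pairwise_distance minimum Hamming distance between any two
#'   primers in a library (default 8 nt for 20-nt primers).
#' @param max_attempts consecutive rejected candidates tolerated before the
#'   library is declared infeasible.
#' @return object of class \code{primer_constraints}.
#' @export
primer_constraints <- function(gc_min = 0.4, gc_max = 0.6, max_homopolymer = 3L,
                               min_pairwise_distance = 8L, max_attempts = 2000L) {
  stopifnot(gc_min >= 0, gc_max <= 1, gc_min <= gc_max,
            min_pairwise_distance >= 1L, max_homopolymer >= 1L, max_attempts >= 1L)
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 min_pairwise_distance = as.integer(min_pairwise_distance),
                 max_attempts = as.integer(max_attempts)),
            class = "primer_constraints")
}

#' Validate one primer sequence against design constraints
#'
#' @param sequence nucleotide string (non-empty, A/C/G/T only; any other
#'   symbol raises an alphabet error).
#' @param constraints a \code{\link{primer_constraints}} object.
#' @return list with \code{pass} (logical) and \code{violations} (character
#'   vector naming each violated rule: \code{"gc"}, \code{"homopolymer"}).
#' @export
check_primer_constraints <- function(sequence, constraints = primer_constraints()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  dna_chars(sequence) # alphabet error on non-ACGT
  violations <- character(0)
  gc <- gc_fraction(sequence)
  if (gc < constraints$gc_min || gc > constraints$gc_max) {
    violations <- c(violations, "gc")
  }
  if (max_homopolymer_run(sequence) > constraints$max_homopolymer) {
    violations <- c(violations, "homopolymer")
  }
  list(pass = length(violations) == 0L, violations = violations)
}

#' Generate a primer library by seeded rejection sampling
#'
#' Draws uniform random L_p-mers, rejecting candidates that violate the
#' constraints or fall within \code{min_pairwise_distance} Hamming distance
#' of any already-accepted primer. Each pair consists of two independent
#' sequences (forward and reverse); a universal pair, shared by all tool
#' files under the one-to-many indexing method, is generated last under the
#' same distance discipline.
#'
#' @param count number of file primer pairs.
#' @param L_p primer length in nt (default 20).
#' @param constraints a \code{\link{primer_constraints}} object.
#' @param seed integer RNG seed; identical inputs yield identical libraries.
#' @param include_universal also generate the universal tool pair.
#' @return object of class \code{primer_library}: fields \code{pairs} (list of
#'   \code{count} pairs, each \code{list(id, forward, reverse)}),
#'   \code{universal} (a pair or NULL), \code{L_p}, \code{constraints}.
#' @export
generate_primer_library <- function(count, L_p = 20L, constraints = primer_constraints(),
                                    seed = 1L, include_universal = TRUE) {
  stopifnot(count >= 0L, L_p >= 4L)
  needed <- 2L * count + if (include_universal) 2L else 0L
  seqs <- character(0)
  if (needed > 0L) {
    withr::with_seed(seed, {
      rejections <- 0L
      while (length(seqs) < needed) {
        cand <- paste(sample(DNA_BASES, L_p, replace = TRUE), collapse = "")
        ok <- check_primer_constraints(cand, constraints)$pass &&
          all(vapply(seqs, hamming_distance, numeric(1), b = cand) >=
                constraints$min_pairwise_distance)
        if (ok) {
          seqs <- c(seqs, cand)
          rejections <- 0L
        } else {
          rejections <- rejections + 1L
          if (rejections >= constraints$max_attempts) {
            stop(sprintf(paste0("primer library infeasible: %d consecutive ",
                                "rejections while drawing primer %d of %d ",
                                "(L_p = %d, min distance = %d)"),
                         rejections, length(seqs) + 1L, needed, L_p,
                         constraints$min_pairwise_distance))
          }
        }
      }
    })
  }
  pairs <- lapply(seq_len(count), function(i) {
    list(id = i, forward = seqs[2L * i - 1L], reverse = seqs[2L * i])
  })
  universal <- if (include_universal) {
    list(id = "universal", forward = seqs[needed - 1L], reverse = seqs[needed])
  }
  structure(list(pairs = pairs, universal = universal, L_p = as.integer(L_p),
                 constraints = constraints),
            class = "primer_library")
}

#' @export
length.primer_library <- function(x) length(x$pairs)

#' @export
print.primer_library <- function(x, ...) {
  cat(sprintf("<primer_library: %d pairs, L_p = %d%s>\n", length(x$pairs), x$L_p,
              if (!is.null(x$universal)) " + universal pair" else ""))
  invisible(x)
}

# All primer sequences in a library, libraries being checked pairwise.
library_sequences <- function(lib) {
  c(unlist(lapply(lib$pairs, function(p) c(p$forward, p$reverse))),
    if (!is.null(lib$universal)) c(lib$universal$forward, lib$universal$reverse))
}

#' Write / read a primer library as FASTA
#'
#' Record ids follow \code{pair<ID>_F}, \code{pair<ID>_R}, \code{universal_F},
#' \code{universal_R}.
#'
#' @param lib a \code{primer_library}.
#' @param path FASTA file path.
#' @return \code{write_primer_fasta} returns \code{path} invisibly;
#'   \code{read_primer_fasta} returns a \code{primer_library} (constraints are
#'   not stored in FASTA and default on read).
#' @export
write_primer_fasta <- function(lib, path) {
  seqs <- character(0)
  for (p in lib$pairs) {
    seqs[[sprintf("pair%d_F", p$id)]] <- p$forward
    seqs[[sprintf("pair%d_R", p$id)]] <- p$reverse
  }
  if (!is.null(lib$universal)) {
    seqs[["universal_F"]] <- lib$universal$forward
    seqs[["universal_R"]] <- lib$universal$reverse
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' @rdname write_primer_fasta
#' @export
read_primer_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  ids <- sort(unique(as.integer(sub("^pair(\\d+)_[FR]$", "\\1",
                                    grep("^pair\\d+_[FR]$", names(seqs), value = TRUE)))))
  pairs <- lapply(ids, function(i) {
    list(id = i, forward = unname(seqs[[sprintf("pair%d_F", i)]]),
         reverse = unname(seqs[[sprintf("pair%d_R", i)]]))
  })
  universal <- if ("universal_F" %in% names(seqs)) {
    list(id = "universal", forward = unname(seqs[["universal_F"]]),
         reverse = unname(seqs[["universal_R"]]))
  }
  L_p <- if (length(pairs)) nchar(pairs[[1L]]$forward) else
    if (!is.null(universal)) nchar(universal$forward) else NA_integer_
  structure(list(pairs = pairs, universal = universal, L_p = as.integer(L_p),
                 constraints = primer_constraints()),
            class = "primer_library")
}
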