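---
title: "Self-contained DNA storage: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-contained DNA storage: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnastore)
```

## The problem

DNA can archive data for centuries, but an archive is only as durable as the
tools needed to open it. The common practice of compressing files before
transcoding them to nucleotides quietly makes the archive depend on a
decompression program that may no longer exist when the pool is finally
sequenced. `dnastore` implements a *self-contained* storage system: the tool
a file needs travels in the same oligo pool as the file, under a format that
still supports random access (retrieve one file without sequencing
everything) and avoids paying for a tool copy per file.

The package is entirely in-silico: it models the digital half of the
pipeline (containers, codecs, fragmentation, primer indexing, PCR selection
and sequencing rounds), not synthesis or sequencing chemistry.

## Containers

Files are packed into fixed-offset binary records. A data record is
`FT(1B) | FID(4B) | SM(1B) | DL-or-TFID(4B) | D | TD`, with big-endian
integers; a tool record is `FT(1B) | FID(4B) | TD`. The storage-method byte
`SM` selects one of three shapes: **OF** (unprocessed bytes), **CPF**
(compressed bytes with the tool's bytes embedded as `TD`), and **SPF**
(compressed bytes with the tool referenced by its FID and stored
separately). `read_file()` implements the self-extraction procedure: find
the record by FID, branch on `SM`, resolve `TFID` against the tool array
when needed.

Two byte-layout details were unspecified and are fixed here as package
conventions: integers are big-endian, and the offset-6 field always exists
(it holds `DL` even for OF records), so every record parses from its printed
offsets. Stored tools are opaque blobs; decompression is dispatched through
a registry of built-in codecs (`memCompress`/`memDecompress` gzip, bzip2,
xz, or identity) keyed by tool FID — executing stored bytes is deliberately
out of scope. A CPF record embeds tool *bytes* but no tool FID, so the
file-to-tool map in the store plan decides which registered codec interprets
them.

## Codecs

A codec declares its base factor `a` (bases per bit); density of a bare
stream is `d = 1/a` bits per base. Two reference codecs ship:

* **quaternary** — A=00, C=01, G=10, T=11; `a = 0.5`.
* **rotating** — a run-length-constrained block code: 19 bits become one
  integer below 2^19, re-expressed as 12 ternary digits, and each digit
  advances the current base by 1–3 positions mod 4. Consecutive bases never
  repeat, so homopolymer runs never exceed 1 nt (well inside the usual
  synthesis limit of 3). The realised rate is 12/19 ≈ 0.6316 bases/bit,
  within about 1% of the declared `a = 1/1.6 = 0.625`, which is the value
  the cost models use.

Inputs are zero-padded to whole codec blocks. The pad is *not* recorded in
the DNA; the exact container bit length of every stream lives in the store
plan (the traditional-storage side of this hybrid design), and decoding
truncates to it. All model quantities are in bits; the single place this
convention enters the code is `bytes_to_bits()`/`bits_to_bytes()`.

## Fragments

Encoded streams are split into synthesizable oligos laid out as

```
head_primer | A | address | C | payload | RS | T | tail_primer(s)
```

The literal `A`/`T` mark the read direction and sit outside the `L_s`
budget; `address` is a fixed-width big-endian quaternary integer (the
offset of the payload in the file); `C` is a 1-nt class flag (A = data
file, T = tool file); `RS` is a reserved error-correction field, zero-length
by default. Gross payload capacity is `L_s − 2·L_p` for ordinary fragments
and `L_s − (n+1)·L_p` for one-to-many tool fragments carrying `n` client
primers — at the reference geometry `L_s = 220`, `L_p = 20` that is 180 nt,
and 160/140 nt for `n` = 2/3. Address and class flag are then carved out of
the gross capacity.

Two choices where the format was open: the address width is computed once
per pool (smallest width that fits the largest stream, recorded in the
plan), because a per-file width would move the class flag's position and
make mixed data/tool selections unparseable before the class is known; and
the last fragment is simply emitted short rather than padded, which keeps
`segment()`/`assemble()` exactly inverse with no side information.
`assemble()` is order-independent, tolerates exact duplicate fragments (a
pool is a multiset), and raises on gaps or conflicting duplicates rather
than guessing.

## Primers as file indexes

Every file is assigned a primer pair (forward/reverse, default
`L_p = 20` nt) and is retrieved by PCR selection on those two sites, so the
primer library *is* the file index. `generate_primer_library()` uses seeded
rejection sampling: draw uniform 20-mers, reject on GC outside
[0.4, 0.6], homopolymer runs above 3, or Hamming distance below 8 to any
accepted primer. The GC and homopolymer bounds are standard oligo
heuristics; the distance floor operationalises "avoid homology" — at
distance ≥ 8 no primer can be mistaken for another by exact substring
matching, which is how this simulator models PCR. Infeasible requests (too
many primers for the length/constraints) fail after a bounded number of
consecutive rejections rather than looping. Reverse primers are independent
sequences; reverse-complement strand chemistry is not modelled anywhere, so
nothing cancels out by complementarity. Whether primers should also be
screened against payload content is left open; collisions are astronomically
unlikely (a specific 20-mer in a megabase pool ~ 10^6/4^20) and the
selectivity tests would catch them.

## The three storage methods

With `n` files sharing one tool of size `S_T` and per-file header `S_h`,
the stored binary sizes are:

* **1-1CS** (one-to-one continuous): each file is one CPF container with a
  full tool copy. `Sb = Σ r_c·S_Di + n·(S_h + S_T)`. One sequencing round.
* **M-1CI** (many-to-one chain indexing): each file is an SPF container
  whose encoded stream ends with a *pointer* — the tool's forward and
  reverse primer sequences, 2·L_p nt appended in DNA space; the tool is
  stored once under its own pair.
  `Sb = Σ r_c·S_Di + n·(S_h + 2·L_p) + S_T`. Retrieval must sequence the
  file first to learn the tool's primers: two rounds.
* **1-MCI** (one-to-many chain indexing): files are plain SPF containers;
  every *tool* fragment carries the universal forward primer at its head
  and the reverse primers of all `n` client files at its tail, so one
  amplification (file pair + universal-F with the file's reverse) returns
  both classes at once and the C flag separates them.
  `Sb = Σ r_c·S_Di + n·S_h + S_T`. One round. The tail budget bounds
  sharing: `0 < n < ⌊L_s/L_p⌋`, enforced together with positive payload
  capacity (the printed bound alone admits a zero-payload corner).

The pointer is counted at one unit per nucleotide in the bit models, which
is how the closed forms price it; the pool bit counter follows the same
convention so that model and measurement are comparable. The models omit
the 5-byte tool-record header, so agreement tests allow that constant plus
at most one codec block of padding per fragment stream.

After fragmentation the base counts are

```
Sd_1-1CS = a·Sb·(1 + 2·L_p/(L_s − 2·L_p))          (same form for M-1CI)
Sd_1-MCI = a·Sb + (Σ r_c·S_Di + n·S_h)·a/L_s·2·L_p
           + S_T·a/(L_s − (n+1)·L_p)·(n+1)·L_p
```

implemented verbatim in `stored_bases()` (real-valued fragment counts; the
emission path uses integer ceilings). One consequence worth knowing: the
bit ordering `Sb(1-MCI) ≤ Sb(M-1CI) ≤ Sb(1-1CS)` is an identity (the
differences are `2n·L_p` and `(n−1)·S_T`), but the *base* ordering of
1-MCI versus M-1CI is parameter-dependent — with a very large tool and few
clients, the `(n+1)`-primer tool fragments of 1-MCI cost more bases than
M-1CI's ordinary tool fragments, exactly as the third `Sd` term predicts.
Under the reference model parameters (`S_h = 10`, `S_T = 2010`, `L_p = 20`,
`a = 1/1.6`, `S_D = 1e5`, `r_c = 0.34`, `L_s` 100–400) the familiar
ordering `Sd(1-MCI) ≤ Sd(M-1CI) ≤ Sd(1-1CS)` holds in every sweep row.

Compression-side economics are captured by
`e_c = 1 − (r_c·S_o + S_T)/S_o`: with no stored tool this is the ideal
`1 − r_c` (0.66 at the 7z text ratio `r_c = 0.34`), and it crosses zero at
`S_o = S_T/(1 − r_c)` (`breakeven_S_o()`), below which self-containment
costs more than it saves.

## The pool simulator

A pool is an unordered multiset of fragment strings; retrieval never uses
insertion order or FASTA ids. `pcr_select()` models PCR as exact substring
co-occurrence of the two primer sites — no strand chemistry, no
amplification bias, no copy numbers, no errors (the reserved RS field
exists for an error code, but sequencing here is error-free).
`sequence_pool()` returns each fragment once in seeded-random order and is
the unit the round counter counts. One modelling subtlety the class flag
resolves: in M-1CI, round-2 selection by the tool's primers legitimately
co-amplifies the data fragment whose payload ends with the literal pointer;
retrieval filters by class after sequencing, which is precisely the flag's
documented purpose.

## The synthetic corpus

`default_corpus_spec()` defines the study conditions: five data files of
40/28/20/12/8 KB at redundancy 0.9/0.8/0.6/0.3/0, a 194 KB tool (xz
registry codec, serving the first three files) and an 87 KB tool (gzip,
serving the last two). Redundant files are tiled from a seeded pool of
distinct 1 KB blocks (fraction `1 − redundancy` distinct), which makes the
measured compression ratio fall monotonically with the redundancy dial;
non-redundant files are uniform random bytes (measured `r_c > 0.95`). Tool
blobs are uniform random bytes — tools round-trip as opaque payloads, so
their compressibility is irrelevant. What the generator does *not* emulate:
real file-format structure (headers, long-range repetition), real tool
binaries, and any sequencing noise — so passing tests demonstrate the
indexing and accounting logic, not robustness to wet-lab errors.

## Problem sizes and numerical choices

The property suites run 50 seeded random corpora (1–3 files of 0.4–4 KB,
tools of 100–400 bytes) through all three methods; the storage-saving
experiment uses the full-size 194 KB/87 KB tools, where separate storage
saves `(3−1)·S_T1 + (2−1)·S_T2 = 3,891,200` payload bits over continuous
storage, give or take the padding allowance. These sizes keep the default
`R CMD check`-style run comfortable on one CPU while still exercising the
full-scale tool blobs once. Other fixed choices: FT codes data=0/tool=1,
SM codes OF=0/CPF=1/SPF=2, class flag A=data/T=tool, addresses big-endian
quaternary, seeds everywhere explicit with `withr::with_seed` so identical
inputs give byte-identical pools.

## Worked example

```{r example, eval = FALSE}
spec <- corpus_spec(file_sizes_bits = c(4000, 3000, 2500) * 8,
                    redundancy = c(0.8, 0, 0.5),
                    file_tools = c(1, 1, 2),
                    tool_sizes_bits = c(2016, 1504) * 8,
                    tool_codecs = c("xz", "gzip"), seed = 42)
corpus <- generate_corpus(spec)
report <- run_end_to_end(corpus, "1-MCI", storage_params(), seed = 7)
report$payload_bits
vapply(report$files, `[[`, integer(1), "sequencing_rounds")
```

## Limitations

* PCR and sequencing are idealised; there is no dropout, error, or
  consensus model, and densities reported from pools are upper bounds on
  what error-tolerant configurations would achieve.
* The "intuitive" monolithic package (everything in one archive) is only
  represented in the cost models, not as a write path, since it forfeits
  random access.
* Tool blobs are never executed; self-extraction is simulated through the
  codec registry, so the system demonstrates the *format's* completeness,
  not binary preservation.
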