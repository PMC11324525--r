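# Low-level sequence helpers shared by the simulator, the short-read caller
# and the long-read annotator. All coordinates are 0-based half-open unless a
# function name says otherwise; conversion to 1-based happens only at the
# Biostrings/GRanges boundary.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of character sequences
#' @param x character vector of DNA sequences (A/C/G/T/N)
#' @return character vector
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open substring
subseq0 <- function(s, start0, end0) {
  substr(s, start0 + 1L, end0)
}

# raw-vector view of a sequence (bytes), for fast per-base comparison
as_raw_seq <- function(s) charToRaw(s)

# complement lookup on raw bytes
.COMP <- local({
  m <- raw(256)
  m[as.integer(charToRaw("A")) + 1L] <- charToRaw("T")
  m[as.integer(charToRaw("C")) + 1L] <- charToRaw("G")
  m[as.integer(charToRaw("G")) + 1L] <- charToRaw("C")
  m[as.integer(charToRaw("T")) + 1L] <- charToRaw("A")
  m[as.integer(charToRaw("N")) + 1L] <- charToRaw("N")
  m
})

comp_raw <- function(r) .COMP[as.integer(r) + 1L]

# Hamming distance between two equal-length strings
mismatch_count <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# k-mers of a sequence at a stride (always including the final position)
seq_kmers <- function(s, k, stride = 1L) {
  L <- nchar(s)
  if (L < k) {
    return(data.table::data.table(pos0 = integer(), kmer = character()))
  }
  pos0 <- unique(c(seq.int(0L, L - k, by = stride), L - k))
  data.table::data.table(pos0 = pos0, kmer = substring(s, pos0 + 1L, pos0 + k))
}

# Build a keyed k-mer index over named reference sequences.
# Returns a data.table (kmer, rpos0, ref) keyed on kmer.
kmer_index <- function(seqs, k) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  dt <- data.table::rbindlist(lapply(names(seqs), function(nm) {
    d <- seq_kmers(seqs[[nm]], k, stride = 1L)
    if (nrow(d)) d[, ref := nm]
    d
  }), fill = TRUE)
  data.table::setnames(dt, "pos0", "rpos0")
  # drop k-mers containing N: they never anchor
  dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  data.table::setkey(dt, kmer)
  dt
}

# Anchor hits of a query against a forward k-mer index, both strands.
# Columns: pos0 (query, 0-based), rpos0 (ref, 0-based), ref, strand.
# For "+" hits query base q maps to ref base q + (rpos0 - pos0).
# For "-" hits query base q maps to ref base (rpos0 + pos0 + k - 1) - q.
anchor_hits <- function(query, index, k, stride = 1L) {
  q <- seq_kmers(query, k, stride)
  fw <- index[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  L <- nchar(query)
  qrc <- seq_kmers(revcomp(query), k, stride)
  rv <- index[qrc, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(rv)) rv[, pos0 := L - pos0 - k]
  if (nrow(fw)) fw[, strand := "+"] else fw[, strand := character()]
  if (nrow(rv)) rv[, strand := "-"] else rv[, strand := character()]
  data.table::rbindlist(list(fw, rv), use.names = TRUE)
}

# Tolerant base-by-base extension used to refine segment boundaries.
# Walks from read position `q0` in direction `dir` (+1/-1) while the read
# matches the reference through the affine map of the segment. An isolated
# mismatch is crossed when at least `min_look_match` of the next `look`
# positions match; otherwise extension stops. Returns the number of read
# positions successfully consumed (mismatches included when crossed).
extend_match <- function(read_raw, ref_raw, q0, r0, dir, rdir, negate = FALSE,
                        look = 10L, min_look_match = 7L, tolerant = TRUE) {
  n <- 0L
  q <- q0; r <- r0
  Lq <- length(read_raw); Lr <- length(ref_raw)
  repeat {
    if (q < 1L || q > Lq || r < 1L || r > Lr) break
    rb <- ref_raw[r]
    if (negate) rb <- .COMP[as.integer(rb) + 1L]
    if (read_raw[q] == rb) {
      n <- n + 1L; q <- q + dir; r <- r + rdir
      next
    }
    if (!tolerant) break
    # lookahead across the mismatch
    ok <- 0L; tot <- 0L
    for (j in seq_len(look)) {
      qq <- q + dir * j; rr <- r + rdir * j
      if (qq < 1L || qq > Lq || rr < 1L || rr > Lr) break
      tot <- tot + 1L
      rb2 <- ref_raw[rr]
      if (negate) rb2 <- .COMP[as.integer(rb2) + 1L]
      if (read_raw[qq] == rb2) ok <- ok + 1L
    }
    if (tot >= 3L && ok >= ceiling(min_look_match * tot / look)) {
      n <- n + 1L; q <- q + dir; r <- r + rdir
    } else {
      break
    }
  }
  n
}

# write a named character vector of sequences as FASTA
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# write reads with a constant quality as (optionally gzipped) FASTQ
write_fastq <- function(seqs, names, path, q = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n) {
    paste(rep(q, n), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# deterministic seeded evaluation that does not disturb the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# apply substitution errors at a per-base rate; deterministic under the
# caller's RNG state
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    L <- nchar(s)
    n_err <- rbinom(1L, L, rate)
    if (n_err == 0L) return(s)
    pos <- sample.int(L, n_err)
    r <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) {
      r[p] <- sample(setdiff(DNA_BASES, r[p]), 1L)
    }
    paste(r, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
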