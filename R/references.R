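# Toy reference forging: host genome, annotated ITR-to-ITR vector genome,
# and the auxiliary references used for vector-prep QC.

#' Construct an annotated AAV vector genome model
#'
#' The vector genome is modelled as an ordered tiling of seven components:
#' 5' ITR, enhancer, promoter, intron, transgene cDNA, polyA and 3' ITR.
#' Component sequences are random (seeded); the two toy ITRs are independent
#' random sequences, not palindromes. An ITR is considered *intact* when its
#' observed length falls inside `itr_intact_window` (closed, in bases);
#' truncation break points are modelled inside `bb_loop_interval`, the
#' B-B' palindromic-loop region, expressed as offsets from the ITR outer end.
#'
#' @param seed integer seed for the component sequences
#' @param component_lengths named integer vector with names
#'   `ITR5, enhancer, promoter, intron, cdna, polyA, ITR3`; both ITRs must
#'   have the same length
#' @param itr_intact_window closed length interval defining an intact ITR
#' @param bb_loop_interval half-open interval of break-point offsets from the
#'   ITR outer end
#' @return object of class `aav_vector_model`: list with `components`
#'   (data.frame label/start0/end0), `sequence`, `full_length`,
#'   `itr_canonical_length`, `itr_intact_window`, `bb_loop_interval`, and
#'   `anchor` (the outer 20-mer of the 5' ITR used as the ITR primer anchor)
#' @examples
#' vm <- vector_model(seed = 7)
#' vm$components
#' @export
vector_model <- function(seed = 1L,
                         component_lengths = c(ITR5 = 169L, enhancer = 300L,
                                               promoter = 400L, intron = 200L,
                                               cdna = 2400L, polyA = 225L,
                                               ITR3 = 169L),
                         itr_intact_window = c(165L, 173L),
                         bb_loop_interval = c(50L, 85L)) {
  want <- c("ITR5", "enhancer", "promoter", "intron", "cdna", "polyA", "ITR3")
  stopifnot(identical(names(component_lengths), want))
  if (component_lengths[["ITR5"]] != component_lengths[["ITR3"]]) {
    stop("the two ITRs must have equal canonical length")
  }
  itr_len <- as.integer(component_lengths[["ITR5"]])
  if (!(itr_len >= itr_intact_window[1] && itr_len <= itr_intact_window[2])) {
    stop("itr_intact_window must contain the canonical ITR length")
  }
  if (bb_loop_interval[1] < 0 || bb_loop_interval[2] > itr_len) {
    stop("bb_loop_interval must lie within the ITR")
  }
  seqs <- with_seed(seed, lapply(component_lengths, random_dna))
  ends <- cumsum(component_lengths)
  comp <- data.frame(
    label = want,
    start0 = as.integer(ends - component_lengths),
    end0 = as.integer(ends),
    stringsAsFactors = FALSE
  )
  full <- paste(unlist(seqs), collapse = "")
  structure(list(
    components = comp,
    sequence = full,
    full_length = nchar(full),
    itr_canonical_length = itr_len,
    itr_intact_window = as.integer(itr_intact_window),
    bb_loop_interval = as.integer(bb_loop_interval),
    anchor = substr(full, 1L, 20L)
  ), class = "aav_vector_model")
}

#' @export
print.aav_vector_model <- function(x, ...) {
  cat(sprintf("AAV vector model: %d bp, ITR %d bp (intact window [%d, %d])\n",
              x$full_length, x$itr_canonical_length,
              x$itr_intact_window[1], x$itr_intact_window[2]))
  print(x$components)
  invisible(x)
}

# component interval helper
component_interval <- function(vector, label) {
  row <- vector$components[vector$components$label == label, ]
  c(row$start0, row$end0)
}

#' Forge a toy host genome
#'
#' Random chromosomes with one planted run of Ns per chromosome (emulating
#' assembly gaps), deterministic under the seed.
#'
#' @param seed integer seed
#' @param n_chromosomes number of chromosomes
#' @param chromosome_length length of each chromosome in bases (>= 10 kb)
#' @param n_run_length length of the N run planted per chromosome; 0 disables
#' @return object of class `aav_host_genome`: list with `seqs` (named
#'   character), `lengths`, `total_length`
#' @examples
#' hg <- forge_host_genome(seed = 7, n_chromosomes = 2,
#'                         chromosome_length = 20000)
#' hg$total_length
#' @export
forge_host_genome <- function(seed = 1L, n_chromosomes = 4L,
                              chromosome_length = 100000L,
                              n_run_length = 500L) {
  if (chromosome_length < 10000L) {
    stop("requested chromosome size below the 10 kb minimum")
  }
  seqs <- with_seed(seed, {
    s <- vapply(seq_len(n_chromosomes), function(i) random_dna(chromosome_length),
                character(1))
    if (n_run_length > 0L) {
      for (i in seq_along(s)) {
        lo <- floor(chromosome_length * 0.2)
        hi <- floor(chromosome_length * 0.8) - n_run_length
        at <- sample(lo:hi, 1L)
        substr(s[i], at + 1L, at + n_run_length) <-
          paste(rep("N", n_run_length), collapse = "")
      }
    }
    s
  })
  names(seqs) <- paste0("chr", seq_len(n_chromosomes))
  structure(list(
    seqs = seqs,
    lengths = setNames(nchar(seqs), names(seqs)),
    total_length = sum(nchar(seqs))
  ), class = "aav_host_genome")
}

#' @export
print.aav_host_genome <- function(x, ...) {
  cat(sprintf("Toy host genome: %d chromosomes, %d bp total\n",
              length(x$seqs), x$total_length))
  invisible(x)
}

# logical mask of non-N positions for one chromosome (0-based indexing via
# position i -> mask[i+1])
non_n_mask <- function(host, chrom) {
  charToRaw(host$seqs[[chrom]]) != charToRaw("N")
}

#' Forge the host genome and vector model for a simulation
#'
#' Convenience wrapper producing both references from one configuration, and
#' optionally writing them as FASTA.
#'
#' @param config an [sim_config()] object
#' @param out_dir optional directory; when given, `host.fasta` and
#'   `vector.fasta` are written there
#' @return list with `host` ([forge_host_genome()]) and `vector`
#'   ([vector_model()])
#' @examples
#' refs <- forge_references(sim_config(seed = 7, chromosome_length = 20000))
#' @export
forge_references <- function(config, out_dir = NULL) {
  host <- forge_host_genome(seed = config$seed,
                            n_chromosomes = config$n_chromosomes,
                            chromosome_length = config$chromosome_length,
                            n_run_length = config$n_run_length)
  vec <- vector_model(seed = config$seed + 1L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(host$seqs, file.path(out_dir, "host.fasta"))
    write_fasta(setNames(vec$sequence, "vector"),
                file.path(out_dir, "vector.fasta"))
  }
  list(host = host, vector = vec)
}

#' Forge auxiliary references for vector-prep QC
#'
#' Random stand-ins for the plasmid backbone, the trans/helper plasmid, the
#' producer-cell host and the lambda DNase spike-in.
#'
#' @param seed integer seed
#' @return named character vector of sequences
#'   (`backbone`, `helper`, `producer_host`, `lambda`)
#' @export
forge_prep_refs <- function(seed = 1L) {
  with_seed(seed + 99L, c(
    backbone = random_dna(3000L),
    helper = random_dna(5000L),
    producer_host = random_dna(20000L),
    lambda = random_dna(10000L)
  ))
}
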