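# Forging long consensus reads containing episomal or integrated vector
# concatemers, plus vector-prep reads for QC, with full segment-level truth.

# ---- segment plumbing shared with the annotator --------------------------

# Build the read sequence for a segment list. Each segment row has:
# ref ("vector" or a chromosome name), ref_start0, ref_end0, orientation,
# and optionally an `ops` spec string ("M:a,D:d,M:b" / "M:a,I:d,M:b") with
# `ins_seq` for insertions. Returns list(seq, segments) with read_start0 /
# read_end0 filled in.
build_read_from_segments <- function(segments, refs) {
  pieces <- character(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    sg <- segments[i, ]
    s <- subseq0(refs[[sg$ref]], sg$ref_start0, sg$ref_end0)
    if (!is.na(sg$ops) && nzchar(sg$ops)) {
      s <- apply_ops_to_ref(s, sg$ops, sg$ins_seq)
    }
    if (sg$orientation == "-") s <- revcomp(s)
    pieces[i] <- s
  }
  lens <- nchar(pieces)
  segments$read_end0 <- cumsum(lens)
  segments$read_start0 <- segments$read_end0 - lens
  list(seq = paste(pieces, collapse = ""), segments = segments)
}

# apply a one-indel ops spec to a reference slice (read-strand orientation
# applied afterwards)
apply_ops_to_ref <- function(refseg, ops, ins_seq = NA) {
  p <- parse_ops(ops)
  stopifnot(nrow(p) == 3L, p$op[1] == "M", p$op[3] == "M")
  a <- p$len[1]; d <- p$len[2]
  if (p$op[2] == "D") {
    paste0(substr(refseg, 1L, a), substr(refseg, a + d + 1L, nchar(refseg)))
  } else if (p$op[2] == "I") {
    stopifnot(!is.na(ins_seq), nchar(ins_seq) == d)
    paste0(substr(refseg, 1L, a), ins_seq,
           substr(refseg, a + 1L, nchar(refseg)))
  } else {
    stop("unsupported op spec: ", ops)
  }
}

parse_ops <- function(ops) {
  parts <- strsplit(ops, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([MIDX]):([0-9]+)$", parts))
  stopifnot(all(lengths(m) == 3L))
  data.frame(op = vapply(m, `[`, "", 2L),
             len = as.integer(vapply(m, `[`, "", 3L)))
}

ops_counts <- function(ops) {
  if (is.na(ops) || !nzchar(ops)) {
    return(c(M = 0L, X = 0L, I = 0L, D = 0L))
  }
  p <- parse_ops(ops)
  out <- c(M = 0L, X = 0L, I = 0L, D = 0L)
  for (i in seq_len(nrow(p))) out[p$op[i]] <- out[p$op[i]] + p$len[i]
  out
}

# Canonicalize segment boundaries left-maximally: each internal boundary is
# pushed right while the left segment's reference continues to match the read
# base at the boundary. This makes boundaries at junction micro-homology
# well defined, so truth and inference agree exactly on error-free data.
canonicalize_segments <- function(segments, read, refs) {
  if (nrow(segments) < 2L) return(segments)
  read_raw <- charToRaw(read)
  ref_raw <- lapply(refs, charToRaw)
  for (i in seq_len(nrow(segments) - 1L)) {
    # never shift across a segment carrying an interior indel spec: the
    # planted indel is interior, shifts of a few bases cannot reach it, but
    # the ref interval bookkeeping below assumes plain segments
    repeat {
      b <- segments$read_end0[i]            # boundary, 0-based read pos
      if (b >= length(read_raw)) break
      if (segments$read_end0[i + 1L] - segments$read_start0[i + 1L] <= 1L) break
      lr <- ref_raw[[segments$ref[i]]]
      if (segments$orientation[i] == "+") {
        nxt <- segments$ref_end0[i]          # next ref base, 0-based
        if (nxt >= length(lr)) break
        ref_base <- lr[nxt + 1L]
      } else {
        nxt <- segments$ref_start0[i] - 1L
        if (nxt < 0L) break
        ref_base <- .COMP[as.integer(lr[nxt + 1L]) + 1L]
      }
      if (read_raw[b + 1L] != ref_base) break
      # shift the boundary one base right
      if (segments$orientation[i] == "+") {
        segments$ref_end0[i] <- segments$ref_end0[i] + 1L
      } else {
        segments$ref_start0[i] <- segments$ref_start0[i] - 1L
      }
      segments$read_end0[i] <- b + 1L
      if (segments$orientation[i + 1L] == "+") {
        segments$ref_start0[i + 1L] <- segments$ref_start0[i + 1L] + 1L
      } else {
        segments$ref_end0[i + 1L] <- segments$ref_end0[i + 1L] - 1L
      }
      segments$read_start0[i + 1L] <- b + 1L
    }
  }
  segments
}

# ---- long-read forging ---------------------------------------------------

#' Forge long consensus reads with planted concatemer structure
#'
#' Emits a mixture of episomal reads (concatemer only), integrated reads
#' (host flank + concatemer + host flank, or a single flank emulating
#' incomplete capture) drawn from the planted events, and pure host
#' fragments. ITR truncations follow the planted per-copy break points in
#' the B-B' loop region; host flanks optionally carry one small planted
#' indel. Segment boundaries in the truth tables are canonicalized
#' left-maximally so micro-homology at junctions cannot make the truth
#' ambiguous.
#'
#' @param events [plant_events()] result
#' @param host,vector,config as in [plant_events()]
#' @return list with `reads` (named character), `reads_truth`,
#'   `segments_truth` and `itrs_truth` data.frames
#' @examples
#' cfg <- sim_config(seed = 7, n_events = 3, n_long_reads = 10,
#'                   chromosome_length = 20000)
#' refs <- forge_references(cfg)
#' ev <- plant_events(refs$host, refs$vector, cfg)
#' lr <- make_long_reads(ev, refs$host, refs$vector, cfg)
#' table(lr$reads_truth$class)
#' @export
make_long_reads <- function(events, host, vector, config) {
  refs <- c(host$seqs, list(vector = vector$sequence))
  usable <- usable_positions(host, margin = 4200L)
  with_seed(config$seed + 3L, {
    n <- config$n_long_reads
    p_host <- config$host_only_fraction
    p_epi <- (1 - p_host) * config$episome_fraction
    p_int <- (1 - p_host) * (1 - config$episome_fraction)
    types <- sample(c("host_only", "episome", "integrated"), n,
                    replace = TRUE, prob = c(p_host, p_epi, p_int))
    reads <- character(n)
    rt <- vector("list", n); st <- vector("list", n); it <- vector("list", n)
    for (i in seq_len(n)) {
      rid <- sprintf("lr%05d", i)
      if (types[i] == "host_only") {
        ch <- sample(names(usable), 1L, prob = lengths(usable))
        p <- usable[[ch]][sample.int(length(usable[[ch]]), 1L)]
        len <- sample(1000:4000, 1L)
        segs <- data.frame(ref = ch, ref_start0 = p, ref_end0 = p + len,
                           orientation = "+", ops = NA_character_,
                           ins_seq = NA_character_)
      } else {
        if (types[i] == "episome") {
          cp <- draw_copies(vector, config)
          segs <- data.frame(ref = "vector", ref_start0 = cp$vstart0,
                             ref_end0 = cp$vend0, orientation = cp$orientation,
                             ops = NA_character_, ins_seq = NA_character_)
        } else {
          ei <- sample.int(nrow(events$events), 1L)
          evr <- events$events[ei, ]
          cp <- events$copies[events$copies$event_id == evr$event_id, ]
          flanks <- if (runif(1) < config$both_flank_prob) c(TRUE, TRUE)
                    else if (runif(1) < 0.5) c(TRUE, FALSE) else c(FALSE, TRUE)
          fl <- config$flank_length_range
          vseg <- data.frame(ref = "vector", ref_start0 = cp$vstart0,
                             ref_end0 = cp$vend0, orientation = cp$orientation,
                             ops = NA_character_, ins_seq = NA_character_)
          segs <- vseg
          if (flanks[1]) {
            L <- sample(fl[1]:fl[2], 1L)
            hseg <- plant_flank_indel(evr$chrom, evr$pos0 - L, evr$pos0,
                                      config, refs)
            segs <- rbind(hseg, segs)
          }
          if (flanks[2]) {
            L <- sample(fl[1]:fl[2], 1L)
            hseg <- plant_flank_indel(evr$chrom, evr$pos0, evr$pos0 + L,
                                      config, refs)
            segs <- rbind(segs, hseg)
          }
        }
      }
      built <- build_read_from_segments(segs, refs)
      segs <- canonicalize_segments(built$segments, built$seq, refs)
      # boundary canonicalization can grow a flank's matched tail; restate
      # any planted indel in canonical form on the final intervals
      if (any(!is.na(segs$ops))) {
        read_raw <- charToRaw(built$seq)
        for (jj in which(!is.na(segs$ops))) {
          segs$ops[jj] <- recompute_indel_ops(segs[jj, ], read_raw,
                                              charToRaw(refs[[segs$ref[jj]]]))
        }
      }
      plain <- is.na(segs$ops)
      segs$ops[plain] <- sprintf("M:%d", segs$read_end0[plain] -
                                   segs$read_start0[plain])
      reads[i] <- built$seq
      names(reads)[i] <- rid
      segs$read_id <- rid
      segs$seg_index <- seq_len(nrow(segs))
      st[[i]] <- segs
      truth <- summarize_true_structure(segs, vector, types[i])
      truth$read_id <- rid
      truth$event_id <- if (types[i] == "integrated") evr$event_id else NA_character_
      rt[[i]] <- truth
      ir <- itr_records(segs, vector)
      if (nrow(ir)) {
        ir$read_id <- rid
        it[[i]] <- ir
      }
    }
    reads <- apply_substitutions(reads, config$substitution_error_rate) |>
      setNames(names(reads))
    list(reads = reads,
         reads_truth = do.call(rbind, rt),
         segments_truth = do.call(rbind, st),
         itrs_truth = if (length(it)) do.call(rbind, it) else
           data.frame(read_id = character(0)))
  })
}

# host flank segment, optionally with one planted interior indel
plant_flank_indel <- function(chrom, s0, e0, config, refs) {
  seg <- data.frame(ref = chrom, ref_start0 = s0, ref_end0 = e0,
                    orientation = "+", ops = NA_character_,
                    ins_seq = NA_character_)
  L <- e0 - s0
  if (config$flank_indel_prob > 0 && runif(1) < config$flank_indel_prob &&
      L >= 60L) {
    d <- sample.int(config$flank_indel_max, 1L)
    a <- sample(20:(L - 20L - d), 1L)
    if (runif(1) < 0.5) {
      # deletion, canonicalized right: shift while the deleted window is
      # periodic at the boundary
      refseg <- subseq0(refs[[chrom]], s0, e0)
      rr <- charToRaw(refseg)
      while (a + d < L - 20L && rr[a + 1L] == rr[a + d + 1L]) a <- a + 1L
      seg$ops <- sprintf("M:%d,D:%d,M:%d", a, d, L - a - d)
    } else {
      ins <- random_dna(d)
      refseg <- subseq0(refs[[chrom]], s0, e0)
      rr <- charToRaw(refseg)
      ir <- charToRaw(ins)
      # canonicalize right: rotate the insertion while its first base equals
      # the next reference base
      while (a < L - 20L && ir[1L] == rr[a + 1L]) {
        ir <- c(ir[-1L], rr[a + 1L])
        a <- a + 1L
      }
      seg$ops <- sprintf("M:%d,I:%d,M:%d", a, d, L - a)
      seg$ins_seq <- rawToChar(ir)
    }
  }
  seg
}

# truth-side read classification and flags from a canonical segment list
summarize_true_structure <- function(segs, vector, type) {
  is_vec <- segs$ref == "vector"
  jn <- junction_types(segs)
  fc <- functional_cassette(segs, vector)
  ir <- itr_records(segs, vector)
  cls <- if (!any(is_vec)) "host_only"
         else if (!any(!is_vec)) "vector_only"
         else "vector_plus_flank"
  vec_idx <- which(is_vec)
  both <- cls == "vector_plus_flank" &&
    length(vec_idx) > 0L &&
    min(vec_idx) > 1L && max(vec_idx) < nrow(segs)
  data.frame(
    class = cls,
    both_flanks = both,
    n_copies = sum(is_vec),
    n_itrs = nrow(ir),
    n_intact_itrs = if (nrow(ir)) sum(ir$intact) else 0L,
    functional_cdna = fc$functional_cdna,
    promoter_upstream = fc$promoter_upstream,
    junctions = paste(jn, collapse = ","),
    read_length = max(segs$read_end0),
    stringsAsFactors = FALSE
  )
}

# ---- vector-prep reads ---------------------------------------------------

#' Forge a simulated vector-prep long-read library for QC
#'
#' Read composition follows `fractions`: complete ITR-to-ITR vector genomes,
#' truncated vector genomes, plasmid backbone, producer-cell host DNA and the
#' lambda DNase-control spike-in.
#'
#' @param vector [vector_model()] object
#' @param prep_refs named character vector from [forge_prep_refs()]
#' @param n_reads number of reads
#' @param fractions named numeric vector over
#'   `c(vector_full, vector_trunc, backbone, producer_host, lambda)`
#' @param seed integer seed
#' @param substitution_error_rate per-base substitution probability
#' @return list with `reads` (named character) and `truth` (data.frame:
#'   read_id, source, truncated, vstart0, vend0)
#' @export
make_prep_reads <- function(vector, prep_refs, n_reads = 1000L,
                            fractions = c(vector_full = 0.70,
                                          vector_trunc = 0.20,
                                          backbone = 0.05,
                                          producer_host = 0.03,
                                          lambda = 0.02),
                            seed = 1L, substitution_error_rate = 0) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  full <- vector$full_length
  with_seed(seed + 4L, {
    kinds <- sample(names(fractions), n_reads, replace = TRUE,
                    prob = fractions)
    reads <- character(n_reads)
    truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      rid <- sprintf("prep%05d", i)
      ori <- sample(c("+", "-"), 1L)
      if (kinds[i] == "vector_full") {
        s <- 0L; e <- full
        sq <- vector$sequence
        src <- "vector_genome"; trunc <- FALSE
      } else if (kinds[i] == "vector_trunc") {
        # a truncated genome misses at least 50 bases from one end
        if (sample(c(TRUE, FALSE), 1L)) {
          s <- sample(50:(full - 600L), 1L); e <- full
        } else {
          s <- 0L; e <- sample(600:(full - 50L), 1L)
        }
        sq <- subseq0(vector$sequence, s, e)
        src <- "vector_genome"; trunc <- TRUE
      } else {
        ref <- prep_refs[[kinds[i]]]
        len <- sample(800:min(3000L, nchar(ref)), 1L)
        s <- sample.int(nchar(ref) - len + 1L, 1L) - 1L
        e <- s + len
        sq <- subseq0(ref, s, e)
        src <- switch(kinds[i], lambda = "lambda_spike",
                      backbone = "plasmid_backbone",
                      helper = "helper_or_trans", kinds[i])
        trunc <- NA
      }
      if (ori == "-") sq <- revcomp(sq)
      reads[i] <- sq
      names(reads)[i] <- rid
      truth[[i]] <- data.frame(read_id = rid, source = src,
                               truncated = trunc, vstart0 = s, vend0 = e,
                               stringsAsFactors = FALSE)
    }
    reads <- apply_substitutions(reads, substitution_error_rate) |>
      setNames(names(reads))
    list(reads = reads, truth = do.call(rbind, truth))
  })
}
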