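# Structural annotation of long consensus reads: k-mer anchored segment
# decomposition against vector and host, concatemer junction typing, ITR
# integrity, functional-cassette detection, read classification, flank
# integrity bookkeeping and the cohort summary.

#' Parameters for long-read structure annotation
#'
#' @param k anchor k-mer length
#' @param stride anchor sampling stride along the read
#' @param min_segment minimum reported segment length (bases)
#' @param min_anchors minimum anchors supporting a candidate segment
#' @param min_identity minimum alignment identity per segment
#' @param max_gap maximum uncovered read gap between adjoined segments
#' @param overlap_tol maximum overlap allowed between chained segments before
#'   boundary trimming (micro-homology)
#' @param indel_max maximum diagonal shift treated as a small indel within
#'   one segment
#' @param min_itr minimum ITR alignment length counted as one ITR record
#' @param min_flank minimum host-segment length to call integration
#' @param cdna_coverage,cdna_identity coverage and identity required to call
#'   a functional transgene cDNA
#' @param promoter_gap maximum read gap between promoter and cDNA coverage
#' @param end_slack tolerance at vector ends when calling a prep read
#'   truncated
#' @return list of class `aav_longread_params`
#' @export
longread_params <- function(k = 13L, stride = 5L, min_segment = 50L,
                            min_anchors = 3L, min_identity = 0.9,
                            max_gap = 50L, overlap_tol = 25L,
                            indel_max = 25L, min_itr = 30L, min_flank = 50L,
                            cdna_coverage = 0.99, cdna_identity = 0.98,
                            promoter_gap = 10L, end_slack = 10L) {
  structure(list(k = as.integer(k), stride = as.integer(stride),
                 min_segment = as.integer(min_segment),
                 min_anchors = as.integer(min_anchors),
                 min_identity = min_identity, max_gap = as.integer(max_gap),
                 overlap_tol = as.integer(overlap_tol),
                 indel_max = as.integer(indel_max),
                 min_itr = as.integer(min_itr),
                 min_flank = as.integer(min_flank),
                 cdna_coverage = cdna_coverage,
                 cdna_identity = cdna_identity,
                 promoter_gap = as.integer(promoter_gap),
                 end_slack = as.integer(end_slack)),
            class = "aav_longread_params")
}

#' Build the combined k-mer index over vector and host references
#'
#' @param vector [vector_model()] object
#' @param host [forge_host_genome()] object (or `NULL` for vector-only)
#' @param params [longread_params()]
#' @return list with `index` (keyed data.table), `refs` (named character) and
#'   the parameters
#' @export
longread_index <- function(vector, host = NULL, params = longread_params()) {
  refs <- c(if (!is.null(host)) host$seqs,
            list(vector = vector$sequence))
  list(index = kmer_index(refs, params$k), refs = refs, params = params)
}

# ---- segment decomposition -----------------------------------------------

#' Decompose a long read into host and vector segments
#'
#' Anchors the read on the combined k-mer index, clusters anchors by
#' reference, strand and (anti)diagonal, refines segment boundaries by
#' tolerant base-level extension, and selects the highest-scoring
#' non-overlapping chain by weighted-interval scheduling (most matched
#' bases; ties broken toward fewer, leftmost segments). Boundaries at
#' junction micro-homology are canonicalized left-maximally. A diagonal
#' shift of at most `indel_max` within one cluster is resolved as a single
#' small insertion or deletion and recorded in the segment's operation list.
#'
#' @param read a DNA sequence (character)
#' @param idx index from [longread_index()]
#' @return data.frame of segments (seg_index, ref, ref_start0, ref_end0,
#'   orientation, read_start0, read_end0, n_match, n_mismatch, n_ins, n_del,
#'   identity, ops)
#' @export
decompose_read <- function(read, idx) {
  params <- idx$params
  k <- params$k
  read_raw <- charToRaw(read)
  L <- length(read_raw)
  hits <- anchor_hits(read, idx$index, k, params$stride)
  empty <- data.frame(seg_index = integer(0), ref = character(0),
                      ref_start0 = integer(0), ref_end0 = integer(0),
                      orientation = character(0), read_start0 = integer(0),
                      read_end0 = integer(0), n_match = integer(0),
                      n_mismatch = integer(0), n_ins = integer(0),
                      n_del = integer(0), identity = numeric(0),
                      ops = character(0))
  if (nrow(hits) == 0L) return(empty)
  hits[, diag0 := ifelse(strand == "+", rpos0 - pos0, rpos0 + pos0)]
  data.table::setorder(hits, ref, strand, diag0, pos0)
  # cluster anchors: same ref/strand, diagonal within indel_max, contiguous
  # on the read
  grp <- hits[, {
    key_break <- c(TRUE, diff(diag0) > params$indel_max)
    kcl <- cumsum(key_break)
    .(pos0 = pos0, rpos0 = rpos0, diag0 = diag0, kcl = kcl)
  }, by = .(ref, strand)]
  grp[, cl := paste(ref, strand, kcl, sep = "|")]
  data.table::setorder(grp, cl, pos0)
  grp <- grp[, {
    read_break <- c(TRUE, diff(pos0) > 60L)
    .(pos0 = pos0, rpos0 = rpos0, diag0 = diag0,
      scl = paste(cl, cumsum(read_break), sep = "|"))
  }, by = .(ref, strand, cl)]

  cands <- list()
  for (s in unique(grp$scl)) {
    g <- grp[grp$scl == s, ]
    if (nrow(g) < params$min_anchors) next
    cand <- refine_candidate(g, read_raw, idx$refs, params)
    if (!is.null(cand)) cands[[length(cands) + 1L]] <- cand
  }
  if (!length(cands)) return(empty)
  cands <- do.call(rbind, cands)
  cands <- cands[cands$read_end0 - cands$read_start0 >= params$min_segment &
                 cands$identity >= params$min_identity, , drop = FALSE]
  if (!nrow(cands)) return(empty)

  sel <- chain_segments(cands, params$overlap_tol)
  segs <- cands[sel, , drop = FALSE]
  segs <- segs[order(segs$read_start0), , drop = FALSE]
  segs <- snap_junction_boundaries(segs, read_raw, idx$refs, params)
  # recompute alignment bookkeeping on the final intervals; segments whose
  # ref and read spans disagree carry one small indel whose canonical
  # placement is re-derived from the final boundaries
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    ref_raw <- charToRaw(idx$refs[[seg$ref]])
    delta <- (seg$ref_end0 - seg$ref_start0) -
      (seg$read_end0 - seg$read_start0)
    if (delta != 0L) {
      seg$ops <- recompute_indel_ops(seg, read_raw, ref_raw)
      segs$ops[i] <- seg$ops
      segs$n_ins[i] <- if (delta < 0L) -delta else 0L
      segs$n_del[i] <- if (delta > 0L) delta else 0L
    } else {
      seg$ops <- NA_character_
      segs$n_ins[i] <- 0L; segs$n_del[i] <- 0L
    }
    st <- segment_stats_raw(seg, read_raw, ref_raw)
    segs$n_match[i] <- st$n_match
    segs$n_mismatch[i] <- st$n_mismatch
    segs$identity[i] <- st$identity
    if (is.na(seg$ops)) segs$ops[i] <- st$ops
  }
  segs$seg_index <- seq_len(nrow(segs))
  rownames(segs) <- NULL
  segs[, c("seg_index", "ref", "ref_start0", "ref_end0", "orientation",
           "read_start0", "read_end0", "n_match", "n_mismatch", "n_ins",
           "n_del", "identity", "ops")]
}

# Turn one anchor cluster into a refined candidate segment. Handles one
# diagonal shift (single small indel) inside the cluster.
refine_candidate <- function(g, read_raw, refs, params) {
  ref_raw <- charToRaw(refs[[g$ref[1]]])
  strand <- g$strand[1]
  k <- params$k
  Lr <- length(ref_raw)
  diags <- sort(unique(g$diag0))
  # collapse to at most two diagonal blocks (one indel)
  if (length(diags) > 2L) {
    keep <- names(sort(table(g$diag0), decreasing = TRUE))[1:2]
    g <- g[g$diag0 %in% as.integer(keep), ]
    diags <- sort(unique(g$diag0))
  }
  blocks <- lapply(diags, function(d) {
    gb <- g[g$diag0 == d, ]
    list(diag = d, p_min = min(gb$pos0), p_max = max(gb$pos0))
  })
  # order blocks along the read
  blocks <- blocks[order(vapply(blocks, function(b) b$p_min, numeric(1)))]

  map_ref1 <- function(q1, d) {
    if (strand == "+") q1 + d else d + k + 1L - q1
  }
  rdir <- if (strand == "+") 1L else -1L
  neg <- strand == "-"

  b1 <- blocks[[1L]]
  # extend the first block leftward
  q1 <- b1$p_min          # 1-based read index just left of anchor start
  nL <- extend_match(read_raw, ref_raw, q1, map_ref1(q1, b1$diag), -1L,
                     -rdir, negate = neg)
  a0 <- b1$p_min - nL     # 0-based read start
  bl <- blocks[[length(blocks)]]
  qe <- bl$p_max + k + 1L # 1-based read index just right of anchor end
  nR <- extend_match(read_raw, ref_raw, qe, map_ref1(qe, bl$diag), 1L,
                     rdir, negate = neg)
  b0 <- bl$p_max + k + nR # 0-based read end (half-open)

  n_ins <- 0L; n_del <- 0L; ops <- NA_character_
  if (length(blocks) == 2L) {
    # resolve the interior breakpoint by maximal exact extension from the
    # left block (canonical right-shifted indel placement)
    d1 <- blocks[[1L]]$diag; d2 <- blocks[[2L]]$diag
    qm <- blocks[[1L]]$p_max + k + 1L
    nM <- extend_match(read_raw, ref_raw, qm, map_ref1(qm, d1), 1L, rdir,
                       negate = neg, tolerant = FALSE)
    brk <- blocks[[1L]]$p_max + k + nM   # 0-based read pos of breakpoint
    delta <- if (strand == "+") d2 - d1 else d1 - d2
    if (delta > 0L) n_del <- delta else n_ins <- -delta
    a_len <- brk - a0
    skip <- if (delta < 0L) -delta else 0L
    b_len <- b0 - brk - skip
    if (a_len <= 0L || b_len <= 0L) return(NULL)
    ops <- if (delta > 0L) {
      sprintf("M:%d,D:%d,M:%d", a_len, delta, b_len)
    } else {
      sprintf("M:%d,I:%d,M:%d", a_len, -delta, b_len)
    }
  }
  # reference interval across blocks (0-based half-open, forward ref coords)
  ref_pts <- unlist(lapply(seq_along(blocks), function(i) {
    bb <- blocks[[i]]
    x0 <- if (i == 1L) a0 else bb$p_min
    x1 <- if (i == length(blocks)) b0 else bb$p_max + k
    r_a <- map_ref1(x0 + 1L, bb$diag)
    r_b <- map_ref1(x1, bb$diag)
    c(r_a, r_b)
  }))
  rs0 <- max(0L, min(ref_pts) - 1L)
  re0 <- min(Lr, max(ref_pts))
  cand <- data.frame(
    seg_index = NA_integer_, ref = g$ref[1], ref_start0 = rs0,
    ref_end0 = re0, orientation = strand, read_start0 = a0, read_end0 = b0,
    n_match = NA_integer_, n_mismatch = NA_integer_, n_ins = n_ins,
    n_del = n_del, identity = NA_real_, ops = ops,
    # exact-match anchor zone and edge diagonals, used to re-derive
    # junction boundaries without tolerant-extension overshoot
    anchor_lo = blocks[[1L]]$p_min, anchor_hi = bl$p_max + k,
    diag_lo = blocks[[1L]]$diag, diag_hi = bl$diag,
    stringsAsFactors = FALSE
  )
  st <- segment_stats_raw(cand, read_raw, ref_raw)
  cand$n_match <- st$n_match; cand$n_mismatch <- st$n_mismatch
  cand$identity <- st$identity
  cand
}

# Re-derive each internal boundary between consecutive chained segments by
# exact-match extension from the k-mer-verified anchor zones. The boundary is
# the maximal exact right-extension of the left segment (left-maximal
# canonical form), so junction micro-homology is attributed exactly as in
# the simulator truth and tolerant-extension overshoot cannot occur. Under
# sequencing errors the left segment may stop early, in which case the right
# segment absorbs the remaining bases as mismatches.
snap_junction_boundaries <- function(segs, read_raw, refs, params) {
  if (nrow(segs) < 2L) return(segs)
  k <- params$k
  ref_raws <- lapply(segs$ref, function(r) charToRaw(refs[[r]]))
  map1 <- function(q1, d, strand) {
    if (strand == "+") q1 + d else d + k + 1L - q1
  }
  for (i in seq_len(nrow(segs) - 1L)) {
    A <- segs[i, ]; B <- segs[i + 1L, ]
    qa <- A$anchor_hi + 1L  # 1-based read position just past A's exact zone
    nA <- extend_match(read_raw, ref_raws[[i]], qa,
                       map1(qa, A$diag_hi, A$orientation), 1L,
                       if (A$orientation == "+") 1L else -1L,
                       negate = A$orientation == "-", tolerant = FALSE)
    a_limit <- A$anchor_hi + nA           # 0-based half-open exact end of A
    qb <- B$anchor_lo                     # 1-based base just left of B's zone
    nB <- extend_match(read_raw, ref_raws[[i + 1L]], qb,
                       map1(qb, B$diag_lo, B$orientation), -1L,
                       if (B$orientation == "+") -1L else 1L,
                       negate = B$orientation == "-", tolerant = FALSE)
    g_limit <- B$anchor_lo - nB           # 0-based exact start of B
    if (g_limit - a_limit > params$max_gap) next   # genuine uncovered gap
    b <- max(a_limit, A$anchor_hi)
    b <- min(b, B$read_end0 - 1L)
    # keep both mapped reference intervals inside their references
    lenA <- length(ref_raws[[i]]); lenB <- length(ref_raws[[i + 1L]])
    b_max <- if (A$orientation == "+") lenA - A$diag_hi else A$diag_hi + k
    b_min <- if (B$orientation == "+") -B$diag_lo else B$diag_lo + k - lenB
    b_min <- max(b_min, A$read_start0 + 1L, 0L)
    b_max <- min(b_max, B$read_end0 - 1L, length(read_raw))
    if (b_min > b_max) next
    b <- min(max(b, b_min), b_max)
    segs$read_end0[i] <- b
    if (A$orientation == "+") {
      segs$ref_end0[i] <- b + A$diag_hi
    } else {
      segs$ref_start0[i] <- A$diag_hi + k - b
    }
    segs$read_start0[i + 1L] <- b
    if (B$orientation == "+") {
      segs$ref_start0[i + 1L] <- b + B$diag_lo
    } else {
      segs$ref_end0[i + 1L] <- B$diag_lo + k - b
    }
  }
  # safety: clip any residual overlap left by unsnapped pairs
  for (i in seq_len(nrow(segs) - 1L)) {
    ov <- segs$read_end0[i] - segs$read_start0[i + 1L]
    if (ov > 0L) {
      segs$read_start0[i + 1L] <- segs$read_start0[i + 1L] + ov
      if (segs$orientation[i + 1L] == "+") {
        segs$ref_start0[i + 1L] <- segs$ref_start0[i + 1L] + ov
      } else {
        segs$ref_end0[i + 1L] <- segs$ref_end0[i + 1L] - ov
      }
    }
  }
  ok <- segs$read_end0 > segs$read_start0 &
    segs$ref_end0 > segs$ref_start0 & segs$ref_start0 >= 0L &
    segs$ref_end0 <= vapply(ref_raws, length, integer(1))
  segs[ok, , drop = FALSE]
}

# mismatch bookkeeping for a plain or one-indel segment against raw refs
segment_stats_raw <- function(seg, read_raw, ref_raw) {
  a <- seg$read_start0; b <- seg$read_end0
  rseq <- read_raw[(a + 1L):b]
  ref_slice <- ref_raw[(seg$ref_start0 + 1L):seg$ref_end0]
  if (seg$orientation == "-") {
    ref_slice <- rev(comp_raw(ref_slice))
  }
  if (!is.na(seg$ops)) {
    cnt <- ops_counts(seg$ops)
    # reconstruct the aligned columns around the single indel
    p <- parse_ops(seg$ops)
    a1 <- p$len[1]; d <- p$len[2]
    if (p$op[2] == "D") {
      aln_read <- rseq
      aln_ref <- c(ref_slice[seq_len(a1)], ref_slice[(a1 + d + 1L):length(ref_slice)])
    } else {
      aln_read <- c(rseq[seq_len(a1)], rseq[(a1 + d + 1L):length(rseq)])
      aln_ref <- ref_slice
    }
    n_cols <- min(length(aln_read), length(aln_ref))
    mism <- sum(aln_read[seq_len(n_cols)] != aln_ref[seq_len(n_cols)])
    nm <- n_cols - mism
    tot <- n_cols + d
    list(n_match = nm, n_mismatch = mism, identity = nm / tot,
         ops = seg$ops)
  } else {
    n_cols <- min(length(rseq), length(ref_slice))
    mism <- sum(rseq[seq_len(n_cols)] != ref_slice[seq_len(n_cols)])
    nm <- n_cols - mism
    ops <- if (mism == 0L) sprintf("M:%d", n_cols) else
      rle_ops(rseq[seq_len(n_cols)] == ref_slice[seq_len(n_cols)])
    list(n_match = nm, n_mismatch = mism, identity = nm / n_cols, ops = ops)
  }
}

# Canonical (right-shifted) placement of the single indel implied by a
# segment whose reference and read spans differ: the matched prefix is
# extended maximally, the indel follows, the remainder matches.
recompute_indel_ops <- function(seg, read_raw, ref_raw) {
  rseq <- read_raw[(seg$read_start0 + 1L):seg$read_end0]
  ref_slice <- ref_raw[(seg$ref_start0 + 1L):seg$ref_end0]
  if (seg$orientation == "-") ref_slice <- rev(comp_raw(ref_slice))
  delta <- length(ref_slice) - length(rseq)
  n <- min(length(rseq), length(ref_slice))
  eq <- rseq[seq_len(n)] == ref_slice[seq_len(n)]
  a <- if (all(eq)) n else which(!eq)[1] - 1L
  if (delta > 0L) {
    sprintf("M:%d,D:%d,M:%d", a, delta, length(rseq) - a)
  } else {
    sprintf("M:%d,I:%d,M:%d", a, -delta, length(rseq) - a + delta)
  }
}

rle_ops <- function(match_vec) {
  r <- rle(match_vec)
  paste(sprintf("%s:%d", ifelse(r$values, "M", "X"), r$lengths),
        collapse = ",")
}

# weighted-interval scheduling over candidate segments: maximize matched
# bases, ties toward fewer segments then leftmost starts; `tol` bases of
# overlap are allowed (trimmed later)
chain_segments <- function(cands, tol) {
  n <- nrow(cands)
  ord <- order(cands$read_end0, cands$read_start0)
  cands <- cands[ord, , drop = FALSE]
  w <- cands$n_match
  best <- numeric(n); nseg <- integer(n); prev <- integer(n)
  for (i in seq_len(n)) {
    best[i] <- w[i]; nseg[i] <- 1L; prev[i] <- 0L
    for (j in seq_len(i - 1L)) {
      if (cands$read_end0[j] <= cands$read_start0[i] + tol) {
        cand_best <- best[j] + w[i]
        if (cand_best > best[i] ||
            (cand_best == best[i] && nseg[j] + 1L < nseg[i])) {
          best[i] <- cand_best; nseg[i] <- nseg[j] + 1L; prev[i] <- j
        }
      }
    }
  }
  end <- which.max(best)
  sel <- integer(0)
  while (end > 0L) {
    sel <- c(end, sel)
    end <- prev[end]
  }
  ord[sel]
}

# ---- junction / ITR / cassette / classification --------------------------

#' Label concatemer junctions between adjacent vector segments
#'
#' Junctions between same-orientation copies are head-to-tail; opposite
#' orientations meeting at the vector 3' ends are tail-to-tail and at the
#' vector 5' ends head-to-head. Adjacency interrupted by a host segment or a
#' read gap larger than `max_gap` emits no junction.
#'
#' @param segments a segment data.frame (see [decompose_read()])
#' @param max_gap maximum read gap between adjoined vector segments
#' @return character vector of junction labels in read order
#' @examples
#' segs <- data.frame(ref = c("vector", "vector"), orientation = c("+", "-"),
#'                    read_start0 = c(0, 100), read_end0 = c(100, 200))
#' junction_types(segs)  # "tail_to_tail"
#' @export
junction_types <- function(segments, max_gap = 50L) {
  if (nrow(segments) < 2L) return(character(0))
  out <- character(0)
  for (i in seq_len(nrow(segments) - 1L)) {
    a <- segments[i, ]; b <- segments[i + 1L, ]
    if (a$ref != "vector" || b$ref != "vector") next
    if (b$read_start0 - a$read_end0 > max_gap) next
    lab <- if (a$orientation == b$orientation) {
      "head_to_tail"
    } else if (a$orientation == "+" && b$orientation == "-") {
      "tail_to_tail"
    } else {
      "head_to_head"
    }
    out <- c(out, lab)
  }
  out
}

#' ITR records from decomposed segments
#'
#' Every maximal alignment of a vector segment onto an ITR interval of at
#' least `min_itr` bases yields one record. An ITR is intact when its
#' observed length lies inside the vector model's intact window; for
#' truncated ITRs the break-point offset (distance from the retained ITR
#' terminus to the break) is recorded.
#'
#' @param segments segment data.frame
#' @param vector [vector_model()]
#' @param min_itr minimum ITR alignment length counted
#' @return data.frame (segment_index, end, observed_length, intact,
#'   breakpoint_offset), ordered along the read
#' @export
itr_records <- function(segments, vector, min_itr = 30L) {
  itr <- vector$itr_canonical_length
  full <- vector$full_length
  win <- vector$itr_intact_window
  out <- list()
  for (i in seq_len(nrow(segments))) {
    sg <- segments[i, ]
    if (sg$ref != "vector") next
    o5 <- max(0L, min(sg$ref_end0, itr) - max(sg$ref_start0, 0L))
    o3 <- max(0L, min(sg$ref_end0, full) - max(sg$ref_start0, full - itr))
    recs <- list()
    if (o5 >= min_itr) {
      recs <- c(recs, list(data.frame(segment_index = i, end = "5p",
                                      observed_length = o5)))
    }
    if (o3 >= min_itr) {
      recs <- c(recs, list(data.frame(segment_index = i, end = "3p",
                                      observed_length = o3)))
    }
    if (!length(recs)) next
    recs <- do.call(rbind, recs)
    # read order within the segment: 5' first on "+", 3' first on "-"
    if (sg$orientation == "-" && nrow(recs) == 2L) recs <- recs[2:1, ]
    out <- c(out, list(recs))
  }
  if (!length(out)) {
    return(data.frame(segment_index = integer(0), end = character(0),
                      observed_length = integer(0), intact = logical(0),
                      breakpoint_offset = integer(0)))
  }
  res <- do.call(rbind, out)
  res$intact <- itr_intact(res$observed_length, win)
  res$breakpoint_offset <- ifelse(res$intact, NA_integer_,
                                  res$observed_length)
  rownames(res) <- NULL
  res
}

#' Intact-ITR rule
#'
#' An ITR is intact when its observed length falls inside the closed window
#' (165-173 bases by default).
#'
#' @param observed_length integer vector of observed ITR lengths
#' @param window closed length interval
#' @return logical vector
#' @examples
#' itr_intact(c(102, 165, 173, 174))  # FALSE TRUE TRUE FALSE
#' @export
itr_intact <- function(observed_length, window = c(165L, 173L)) {
  observed_length >= window[1] & observed_length <= window[2]
}

#' Detect a functional transgene cassette in decomposed segments
#'
#' `functional_cdna` is true when some vector segment covers the cDNA
#' component end-to-end (at the configured coverage and identity, with no
#' internal breakpoint); `promoter_upstream` additionally requires the
#' promoter interval covered contiguously in the same orientation 5' of the
#' cDNA, either within the same segment or in an adjoined same-orientation
#' segment within `promoter_gap` read bases.
#'
#' @param segments segment data.frame
#' @param vector [vector_model()]
#' @param params [longread_params()]
#' @return list(functional_cdna, promoter_upstream)
#' @export
functional_cassette <- function(segments, vector, params = longread_params()) {
  cdna <- component_interval(vector, "cdna")
  prom <- component_interval(vector, "promoter")
  vsegs <- which(segments$ref == "vector")
  func <- FALSE; prom_up <- FALSE
  for (i in vsegs) {
    sg <- segments[i, ]
    cov <- max(0L, min(sg$ref_end0, cdna[2]) - max(sg$ref_start0, cdna[1]))
    idv <- if ("identity" %in% names(segments)) sg$identity else NA_real_
    idok <- is.na(idv) || idv >= params$cdna_identity
    if (cov >= params$cdna_coverage * (cdna[2] - cdna[1]) && idok) {
      func <- TRUE
      pcov <- max(0L, min(sg$ref_end0, prom[2]) - max(sg$ref_start0, prom[1]))
      if (pcov >= (prom[2] - prom[1])) {
        prom_up <- TRUE
      } else {
        # promoter supplied by an adjoined same-orientation segment
        nb <- if (sg$orientation == "+") i - 1L else i + 1L
        if (nb >= 1L && nb <= nrow(segments)) {
          ng <- segments[nb, ]
          gap <- if (nb < i) sg$read_start0 - ng$read_end0 else
            ng$read_start0 - sg$read_end0
          pc2 <- max(0L, min(ng$ref_end0, prom[2]) - max(ng$ref_start0, prom[1]))
          if (ng$ref == "vector" && ng$orientation == sg$orientation &&
              gap <= params$promoter_gap && pc2 >= (prom[2] - prom[1])) {
            prom_up <- TRUE
          }
        }
      }
    }
  }
  list(functional_cdna = func, promoter_upstream = prom_up)
}

#' Classify a decomposed read
#'
#' @param segments segment data.frame
#' @param params [longread_params()]
#' @return list(classification, has_flank, both_flanks)
#' @export
classify_read <- function(segments, params = longread_params()) {
  if (nrow(segments) == 0L) {
    return(list(classification = "ambiguous", has_flank = FALSE,
                both_flanks = FALSE))
  }
  len <- segments$read_end0 - segments$read_start0
  is_vec <- segments$ref == "vector"
  is_host <- !is_vec & len >= params$min_flank
  has_vec <- any(is_vec)
  # a host flank counts when adjoined to a vector segment within max_gap
  adjoined <- rep(FALSE, nrow(segments))
  for (i in which(is_host)) {
    lhs <- i > 1L && is_vec[i - 1L] &&
      segments$read_start0[i] - segments$read_end0[i - 1L] <= params$max_gap
    rhs <- i < nrow(segments) && is_vec[i + 1L] &&
      segments$read_start0[i + 1L] - segments$read_end0[i] <= params$max_gap
    adjoined[i] <- lhs || rhs
  }
  has_flank <- has_vec && any(adjoined)
  cls <- if (has_flank) {
    "vector_plus_flank"
  } else if (has_vec && !any(!is_vec)) {
    "vector_only"
  } else if (!has_vec && any(!is_vec)) {
    "host_only"
  } else {
    "ambiguous"
  }
  both <- FALSE
  if (has_flank) {
    vec_idx <- which(is_vec)
    both <- any(adjoined & seq_len(nrow(segments)) < min(vec_idx)) &&
      any(adjoined & seq_len(nrow(segments)) > max(vec_idx))
  }
  list(classification = cls, has_flank = has_flank, both_flanks = both)
}

#' Flank integrity bookkeeping
#'
#' Pools matched, mismatched, inserted and deleted bases over the host
#' segments of a read (or cohort) and reports percentages of the total
#' aligned host bases (matched + mismatched + inserted + deleted).
#'
#' @param segments segment data.frame (host segments are used)
#' @return list(match_pct, mismatch_pct, insertion_pct, deletion_pct,
#'   n_bases); all-`NA` when there is no host segment
#' @export
flank_integrity <- function(segments) {
  hs <- segments[segments$ref != "vector", , drop = FALSE]
  if (!nrow(hs)) {
    return(list(match_pct = NA_real_, mismatch_pct = NA_real_,
                insertion_pct = NA_real_, deletion_pct = NA_real_,
                n_bases = 0L))
  }
  cnt <- Reduce(`+`, lapply(hs$ops, ops_counts))
  tot <- sum(cnt)
  list(match_pct = 100 * cnt[["M"]] / tot,
       mismatch_pct = 100 * cnt[["X"]] / tot,
       insertion_pct = 100 * cnt[["I"]] / tot,
       deletion_pct = 100 * cnt[["D"]] / tot,
       n_bases = tot)
}

# ---- cohort driver -------------------------------------------------------

#' Annotate a cohort of long reads
#'
#' Runs [decompose_read()] on every read and derives per-read structure
#' records in the same layout as the simulator truth tables, enabling exact
#' oracle comparison.
#'
#' @param reads named character vector of read sequences
#' @param vector [vector_model()]
#' @param host [forge_host_genome()]
#' @param params [longread_params()]
#' @return object of class `aav_read_structures`: list with `reads`,
#'   `segments` and `itrs` data.frames
#' @export
annotate_long_reads <- function(reads, vector, host,
                                params = longread_params()) {
  idx <- longread_index(vector, host, params)
  rt <- vector("list", length(reads))
  st <- vector("list", length(reads))
  it <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    rid <- names(reads)[i]
    segs <- decompose_read(reads[[i]], idx)
    cls <- classify_read(segs, params)
    jn <- junction_types(segs, params$max_gap)
    fc <- functional_cassette(segs, vector, params)
    ir <- itr_records(segs, vector, params$min_itr)
    rt[[i]] <- data.frame(
      read_id = rid,
      class = cls$classification,
      both_flanks = cls$both_flanks,
      n_copies = sum(segs$ref == "vector"),
      n_itrs = nrow(ir),
      n_intact_itrs = if (nrow(ir)) sum(ir$intact) else 0L,
      functional_cdna = fc$functional_cdna,
      promoter_upstream = fc$promoter_upstream,
      junctions = paste(jn, collapse = ","),
      read_length = nchar(reads[[i]]),
      stringsAsFactors = FALSE
    )
    if (nrow(segs)) {
      segs$read_id <- rid
      st[[i]] <- segs
    }
    if (nrow(ir)) {
      ir$read_id <- rid
      it[[i]] <- ir
    }
  }
  structure(list(
    reads = do.call(rbind, rt),
    segments = data.table::rbindlist(st, fill = TRUE) |> as.data.frame(),
    itrs = data.table::rbindlist(it, fill = TRUE) |> as.data.frame()
  ), class = "aav_read_structures")
}

#' @export
print.aav_read_structures <- function(x, ...) {
  cat(sprintf("Long-read structures: %d reads\n", nrow(x$reads)))
  print(table(x$reads$class))
  invisible(x)
}

#' Cohort summary of long-read structures
#'
#' Mirrors the per-sample summary-table semantics: vector reads, confirmed
#' integrated (vector + flank) reads, mean ITRs per flanked read, functional
#' cDNA counts, ITR intactness and flank integrity, the latter three over
#' flanked reads only.
#'
#' @param structures [annotate_long_reads()] result (or a compatible list of
#'   truth tables with elements `reads`, `segments`, `itrs`)
#' @return list of class `aav_cohort_summary`
#' @export
summarize_cohort <- function(structures) {
  rd <- structures$reads
  flanked <- rd[rd$class == "vector_plus_flank", , drop = FALSE]
  fl_ids <- flanked$read_id
  itrs <- structures$itrs
  itrs_fl <- itrs[itrs$read_id %in% fl_ids, , drop = FALSE]
  segs_fl <- structures$segments[structures$segments$read_id %in% fl_ids, ,
                                 drop = FALSE]
  fi <- if (nrow(segs_fl)) flank_integrity(segs_fl) else
    list(match_pct = NA_real_, mismatch_pct = NA_real_,
         insertion_pct = NA_real_, deletion_pct = NA_real_, n_bases = 0L)
  out <- list(
    total_reads = nrow(rd),
    vector_reads = sum(rd$class %in% c("vector_only", "vector_plus_flank")),
    vector_plus_flank = nrow(flanked),
    mean_itrs_per_flanked_read = if (nrow(flanked)) mean(flanked$n_itrs)
                                 else NA_real_,
    functional_cdna = sum(rd$functional_cdna),
    cdna_plus_flank = sum(rd$functional_cdna &
                            rd$class == "vector_plus_flank"),
    pct_flanked_with_ge1_itr = if (nrow(flanked))
      100 * mean(flanked$n_itrs >= 1L) else NA_real_,
    pct_flanked_with_ge2_itr = if (nrow(flanked))
      100 * mean(flanked$n_itrs >= 2L) else NA_real_,
    pct_intact_itrs = if (nrow(itrs_fl)) 100 * mean(itrs_fl$intact)
                      else NA_real_,
    mean_itr_length = if (nrow(itrs_fl)) mean(itrs_fl$observed_length)
                      else NA_real_,
    flank_match_pct = fi$match_pct,
    flank_insertion_pct = fi$insertion_pct,
    flank_deletion_pct = fi$deletion_pct
  )
  structure(out, class = "aav_cohort_summary")
}

#' @export
print.aav_cohort_summary <- function(x, ...) {
  cat("Long-read cohort summary\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.numeric(v)) format(round(v, 3)) else format(v)))
  }
  invisible(x)
}

# ---- vector-prep QC ------------------------------------------------------

#' Classify vector-prep long reads against the production references
#'
#' Each read is assigned to the best-anchoring reference among the vector
#' ITR-to-ITR genome, plasmid backbone, trans/helper plasmid, producer-cell
#' host and the lambda spike-in. Vector reads are marked truncated when the
#' covered vector interval misses more than `end_slack` bases from either
#' end.
#'
#' @param reads named character vector
#' @param vector [vector_model()]
#' @param prep_refs named character vector from [forge_prep_refs()]
#' @param params [longread_params()]
#' @return data.frame (read_id, source, truncated, vstart0, vend0)
#' @export
classify_prep_read <- function(reads, vector, prep_refs,
                               params = longread_params()) {
  refs <- c(list(vector = vector$sequence), as.list(prep_refs))
  index <- kmer_index(refs, params$k)
  full <- vector$full_length
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    read <- reads[[i]]
    hits <- anchor_hits(read, index, params$k, stride = 10L)
    if (nrow(hits) < params$min_anchors) {
      out[[i]] <- data.frame(read_id = names(reads)[i],
                             source = "unclassified", truncated = NA,
                             vstart0 = NA_integer_, vend0 = NA_integer_)
      next
    }
    tab <- sort(table(hits$ref), decreasing = TRUE)
    best <- names(tab)[1]
    n_expected <- max(1L, nchar(read) %/% 10L)
    if (tab[1] < max(params$min_anchors, 0.2 * n_expected)) {
      best <- "unclassified"
    }
    src <- switch(best,
      vector = "vector_genome",
      backbone = "plasmid_backbone",
      helper = "helper_or_trans",
      producer_host = "producer_host",
      lambda = "lambda_spike",
      "unclassified")
    trunc <- NA; vs <- NA_integer_; ve <- NA_integer_
    if (src == "vector_genome") {
      h <- hits[hits$ref == "vector", ]
      read_raw <- charToRaw(read)
      ref_raw <- charToRaw(vector$sequence)
      strand <- names(sort(table(h$strand), decreasing = TRUE))[1]
      h <- h[h$strand == strand, ]
      k <- params$k
      if (strand == "+") {
        d <- as.integer(names(sort(table(h$rpos0 - h$pos0),
                                   decreasing = TRUE))[1])
        p_min <- min(h$pos0[h$rpos0 - h$pos0 == d])
        p_max <- max(h$pos0[h$rpos0 - h$pos0 == d])
        nL <- extend_match(read_raw, ref_raw, p_min, p_min + d, -1L, -1L)
        nR <- extend_match(read_raw, ref_raw, p_max + k + 1L,
                           p_max + k + 1L + d, 1L, 1L)
        vs <- p_min - nL + d
        ve <- p_max + k + nR + d
      } else {
        cs <- as.integer(names(sort(table(h$rpos0 + h$pos0),
                                    decreasing = TRUE))[1])
        h <- h[h$rpos0 + h$pos0 == cs, ]
        p_min <- min(h$pos0); p_max <- max(h$pos0)
        map1 <- function(q1) cs + k + 1L - q1
        nL <- extend_match(read_raw, ref_raw, p_min, map1(p_min), -1L, 1L,
                           negate = TRUE)
        nR <- extend_match(read_raw, ref_raw, p_max + k + 1L,
                           map1(p_max + k + 1L), 1L, -1L, negate = TRUE)
        ve <- map1(p_min - nL + 1L)
        vs <- map1(p_max + k + nR) - 1L
      }
      vs <- max(0L, vs); ve <- min(full, ve)
      trunc <- vs > params$end_slack || ve < full - params$end_slack
    }
    out[[i]] <- data.frame(read_id = names(reads)[i], source = src,
                           truncated = trunc, vstart0 = vs, vend0 = ve,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
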