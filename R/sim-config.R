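# Simulation configuration and the small discrete-distribution vocabulary
# used for clone counts, duplicate counts and concatemer copy numbers.

#' Specify a discrete distribution for the simulator
#'
#' Three kinds are supported: `constant(value)`, `uniform_int(min, max)` and
#' `table(values, probs)`.
#'
#' @param kind one of `"constant"`, `"uniform_int"`, `"table"`
#' @param ... parameters of the kind: `value`; `min` and `max`; or `values`
#'   and `probs`
#' @return a list of class `aav_dist`
#' @examples
#' dist_spec("uniform_int", min = 1, max = 5)
#' @export
dist_spec <- function(kind = c("constant", "uniform_int", "table"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  d <- switch(kind,
    constant = {
      stopifnot(is.numeric(p$value), length(p$value) == 1)
      list(kind = kind, value = as.integer(p$value))
    },
    uniform_int = {
      stopifnot(is.numeric(p$min), is.numeric(p$max), p$min <= p$max)
      list(kind = kind, min = as.integer(p$min), max = as.integer(p$max))
    },
    table = {
      stopifnot(length(p$values) == length(p$probs), all(p$probs >= 0),
                sum(p$probs) > 0)
      list(kind = kind, values = as.integer(p$values),
           probs = p$probs / sum(p$probs))
    })
  structure(d, class = "aav_dist")
}

# draw n values from a dist_spec under the current RNG state
draw_dist <- function(dist, n) {
  switch(dist$kind,
    constant = rep(dist$value, n),
    uniform_int = dist$min + (sample.int(dist$max - dist$min + 1L, n,
                                         replace = TRUE) - 1L),
    table = sample(dist$values, n, replace = TRUE, prob = dist$probs),
    stop("unknown distribution kind: ", dist$kind))
}

dist_max <- function(dist) {
  switch(dist$kind,
    constant = dist$value,
    uniform_int = dist$max,
    table = max(dist$values))
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data module with study-condition
#' defaults: 200 integration events on a 4 x 100 kb toy host, clone counts
#' uniform on 1..5, 0-3 PCR duplicates per clone, paired 150-base reads with
#' an ITR primer anchor on read 1 and barcode+UMI on read 2, and 500 long
#' concatemer reads mixing episomes and integrations with heterogeneously
#' truncated ITRs.
#'
#' @param seed integer seed; fixed seed gives byte-identical outputs
#' @param n_events number of integration events to plant
#' @param clone_count_distribution [dist_spec()] for cells per unique junction
#' @param n_pcr_duplicates_per_read [dist_spec()] for PCR re-emissions per
#'   clone template
#' @param substitution_error_rate per-base substitution probability
#' @param read_length short-read length in bases
#' @param fragment_size_mean,fragment_size_sd sonication fragment size (bases)
#' @param min_fragment_size lower clamp on fragment size
#' @param n_long_reads number of long consensus reads
#' @param concatemer_copy_distribution [dist_spec()] for vector copies per
#'   concatemer
#' @param episome_fraction probability a long read is episomal (no host)
#' @param host_only_fraction probability a long read is pure host DNA
#' @param both_flank_prob probability an integrated long read captures host
#'   flanks on both sides of the concatemer
#' @param flank_length_range host-flank length range for long reads (bases)
#' @param inversion_prob probability each successive concatemer copy flips
#'   orientation relative to the previous one
#' @param itr_intact_prob probability a terminal ITR of a copy is left intact
#'   (truncations otherwise break inside the B-B' loop region)
#' @param internal_trunc_prob probability a copy is an internally truncated
#'   genome (starts or ends inside the cassette)
#' @param flank_indel_prob probability a host flank carries one small planted
#'   indel (long reads)
#' @param flank_indel_max maximum planted indel length (bases)
#' @param n_chromosomes,chromosome_length toy host geometry
#' @param n_run_length length of the N run planted per chromosome (0 disables)
#' @param min_event_spacing minimum distance between planted events (bases)
#' @param barcode sample barcode carried by read 2
#' @param itr_residual_length ITR bases between the primer anchor and the host
#'   junction on read 1
#' @return a list of class `aav_sim_config`
#' @examples
#' cfg <- sim_config(seed = 7, n_events = 20)
#' cfg$clone_count_distribution
#' @export
sim_config <- function(seed = 1L,
                       n_events = 200L,
                       clone_count_distribution = dist_spec("uniform_int", min = 1, max = 5),
                       n_pcr_duplicates_per_read = dist_spec("uniform_int", min = 0, max = 3),
                       substitution_error_rate = 0,
                       read_length = 150L,
                       fragment_size_mean = 350,
                       fragment_size_sd = 50,
                       min_fragment_size = 160L,
                       n_long_reads = 500L,
                       concatemer_copy_distribution = dist_spec("uniform_int", min = 1, max = 5),
                       episome_fraction = 0.5,
                       host_only_fraction = 0.03,
                       both_flank_prob = 0.5,
                       flank_length_range = c(300L, 1500L),
                       inversion_prob = 0.3,
                       itr_intact_prob = 0.10,
                       internal_trunc_prob = 0.15,
                       flank_indel_prob = 0,
                       flank_indel_max = 10L,
                       n_chromosomes = 4L,
                       chromosome_length = 100000L,
                       n_run_length = 500L,
                       min_event_spacing = 700L,
                       barcode = "ACGTACGT",
                       itr_residual_length = 25L) {
  cfg <- list(
    seed = as.integer(seed),
    n_events = as.integer(n_events),
    clone_count_distribution = clone_count_distribution,
    n_pcr_duplicates_per_read = n_pcr_duplicates_per_read,
    substitution_error_rate = substitution_error_rate,
    read_length = as.integer(read_length),
    fragment_size_mean = fragment_size_mean,
    fragment_size_sd = fragment_size_sd,
    min_fragment_size = as.integer(min_fragment_size),
    n_long_reads = as.integer(n_long_reads),
    concatemer_copy_distribution = concatemer_copy_distribution,
    episome_fraction = episome_fraction,
    host_only_fraction = host_only_fraction,
    both_flank_prob = both_flank_prob,
    flank_length_range = as.integer(flank_length_range),
    inversion_prob = inversion_prob,
    itr_intact_prob = itr_intact_prob,
    internal_trunc_prob = internal_trunc_prob,
    flank_indel_prob = flank_indel_prob,
    flank_indel_max = as.integer(flank_indel_max),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    n_run_length = as.integer(n_run_length),
    min_event_spacing = as.integer(min_event_spacing),
    barcode = barcode,
    itr_residual_length = as.integer(itr_residual_length)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "aav_sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$substitution_error_rate, cfg$episome_fraction,
             cfg$host_only_fraction, cfg$both_flank_prob, cfg$inversion_prob,
             cfg$itr_intact_prob, cfg$internal_trunc_prob,
             cfg$flank_indel_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("simulation probabilities must lie in [0, 1]")
  }
  if (cfg$chromosome_length < 10000L) {
    stop("requested chromosome size below the 10 kb minimum")
  }
  if (cfg$n_events < 0L || cfg$n_long_reads < 0L) {
    stop("counts must be non-negative")
  }
  if (!grepl("^[ACGT]+$", cfg$barcode)) stop("barcode must be A/C/G/T")
  invisible(cfg)
}

#' @export
print.aav_sim_config <- function(x, ...) {
  cat("AAV simulation config\n")
  cat(sprintf("  seed %d | %d events on %d x %d kb host | %d long reads\n",
              x$seed, x$n_events, x$n_chromosomes,
              x$chromosome_length %/% 1000L, x$n_long_reads))
  cat(sprintf("  substitution error rate %.4g | episome fraction %.2f\n",
              x$substitution_error_rate, x$episome_fraction))
  invisible(x)
}
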