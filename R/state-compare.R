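# Jump distributions of discretized connectivity and their comparison by
# the two-sample Kolmogorov-Smirnov statistic: the distance between the
# empirical CDFs of single-step state transitions is the headline measure
# of how similarly two modalities' connectivity fluctuates.

#' Single-step jump distribution of a state sequence
#'
#' Signed single-step differences `state[t+1] - state[t]` of a discretized
#' connectivity series, with their empirical CDF — the empirical probability
#' function for single-step transitions between degrees of connectivity.
#' Missing states break transitions: no jump is counted across a gap.
#'
#' @param seq A `state_sequence` from [bin_states()], length at least 2.
#' @param absolute Use absolute jump magnitudes instead of signed jumps
#'   (variant analysis; default FALSE).
#' @return A `jump_distribution` with `jumps`, `ecdf` (right-continuous step
#'   function) and `n`.
#' @export
jump_distribution <- function(seq, absolute = FALSE) {
  stopifnot(inherits(seq, "state_sequence"))
  s <- seq$states
  if (length(s) < 2L) stop("sequence must have at least 2 steps", call. = FALSE)
  d <- diff(s)
  d <- d[!is.na(d)]  # NA diff marks a transition into/out of a missing state
  if (length(d) == 0L) stop("no valid transitions (all states missing?)",
                            call. = FALSE)
  if (absolute) d <- abs(d)
  structure(list(jumps = as.integer(d), ecdf = stats::ecdf(d),
                 n = length(d), absolute = absolute),
            class = "jump_distribution")
}

#' @export
print.jump_distribution <- function(x, ...) {
  cat(sprintf("<jump_distribution> %d %s jumps, range [%d, %d]\n",
              x$n, if (x$absolute) "absolute" else "signed",
              min(x$jumps), max(x$jumps)))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov statistic on jump distributions
#'
#' `D = sup_v |F_a(v) - F_b(v)|` over the union of observed jump values —
#' the distance between the two jump ECDFs, sensitive to differences in
#' both their location and shape. Used as a distance (no p-value): lower
#' values mean more similar single-step connectivity dynamics.
#'
#' @param a,b `jump_distribution` objects.
#' @param label_a,label_b Optional modality labels carried in the result.
#' @return A `ks_result` with `statistic` in `[0, 1]` and the pair labels.
#' @export
ks_two_sample <- function(a, b, label_a = "a", label_b = "b") {
  stopifnot(inherits(a, "jump_distribution"), inherits(b, "jump_distribution"))
  if (a$n == 0L || b$n == 0L) stop("empty jump distribution", call. = FALSE)
  u <- sort(unique(c(a$jumps, b$jumps)))
  stat <- max(abs(a$ecdf(u) - b$ecdf(u)))
  structure(list(statistic = stat, pair = c(label_a, label_b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4g (%s vs %s)\n",
              x$statistic, x$pair[1], x$pair[2]))
  invisible(x)
}

#' Per-band K-S profile of one modality against another
#'
#' Compares a slow-modality state sequence against each band's fast-modality
#' state sequence, returning one K-S statistic per band. Bands are
#' independent: permuting the input bands permutes the rows identically.
#'
#' @param slow_seq `state_sequence` of the slow modality.
#' @param fast_seqs Named list of per-band `state_sequence`s.
#' @param measure Label recorded per row (e.g. `"coherence"` or `"blp"`).
#' @return Data frame with columns `band`, `measure`, `ks_statistic`.
#' @export
ks_band_profile <- function(slow_seq, fast_seqs, measure = "coherence") {
  jd_slow <- jump_distribution(slow_seq)
  stats_ <- vapply(fast_seqs, function(fseq) {
    ks_two_sample(jd_slow, jump_distribution(fseq))$statistic
  }, numeric(1))
  data.frame(band = names(fast_seqs), measure = measure,
             ks_statistic = unname(stats_), row.names = NULL)
}

#' Frobenius distance between transition matrices (diagnostic)
#'
#' Empirical one-step transition matrices of two state sequences compared by
#' Frobenius norm — a diagnostic alternative to the jump-ECDF K-S distance
#' that retains the full transition structure.
#'
#' @param seq_a,seq_b `state_sequence`s with equal `n_states`.
#' @return Frobenius norm of the difference of row-normalized transition
#'   matrices.
#' @export
transition_matrix_distance <- function(seq_a, seq_b) {
  stopifnot(seq_a$n_states == seq_b$n_states)
  emp <- function(s, k) {
    tm <- matrix(0, k, k)
    for (t in seq_len(length(s$states) - 1L)) {
      i <- s$states[t]; j <- s$states[t + 1L]
      if (!is.na(i) && !is.na(j)) tm[i, j] <- tm[i, j] + 1
    }
    rs <- rowSums(tm)
    tm[rs > 0, ] <- tm[rs > 0, ] / rs[rs > 0]
    tm
  }
  k <- seq_a$n_states
  norm(emp(seq_a, k) - emp(seq_b, k), type = "F")
}
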