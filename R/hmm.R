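#' Binarize windowed mark counts against a Poisson background
#'
#' The ChromHMM-style presence call: a window is called 1 for a mark when the
#' Poisson upper-tail probability `P(X >= count)` under the background rate is
#' below `p_threshold`. The background rate defaults to the mark's genome-wide
#' mean count. A count of 0 always yields 0 (the tail probability is 1).
#'
#' @param track a [simulate_mark_tracks()] `MarkTrack`, or any `data.table`
#'   with `chrom`, `start`, `end` and one count column per mark.
#' @param marks mark columns to binarize (default: the track's mark columns).
#' @param p_threshold upper-tail significance threshold (ChromHMM's usual
#'   1e-4).
#' @param background optional named per-mark background rates overriding the
#'   genome-wide means.
#' @return A `MarkBinaryMatrix`: list with `windows` (`chrom`, `start`,
#'   `end`), `marks`, `calls` (windows x marks 0/1 integer matrix) and
#'   `window` (bp).
#' @export
binarize <- function(track, marks = NULL, p_threshold = 1e-4,
                     background = NULL) {
  dt <- as.data.table(track)
  marks <- marks %||% attr(track, "marks") %||%
    setdiff(names(dt), c("chrom", "start", "end"))
  stopifnot(length(marks) >= 1L, all(marks %in% names(dt)))
  calls <- matrix(0L, nrow(dt), length(marks),
                  dimnames = list(NULL, marks))
  for (m in marks) {
    x <- dt[[m]]
    if (any(x < 0)) stop("negative counts for mark ", m)
    lambda <- if (!is.null(background) && m %in% names(background)) {
      background[[m]]
    } else {
      mean(x)
    }
    if (lambda <= 0) stop("mark ", m, " has zero genome-wide coverage")
    # P(X >= count; lambda) < p_threshold, and count 0 is never called
    tail_p <- ppois(x - 1, lambda, lower.tail = FALSE)
    calls[, m] <- as.integer(x > 0 & tail_p < p_threshold)
  }
  structure(list(windows = dt[, .(chrom, start, end)], marks = marks,
                 calls = calls,
                 window = attr(track, "window") %||%
                   as.integer(dt$end[1] - dt$start[1])),
            class = "MarkBinaryMatrix")
}

# per-window state-conditional likelihoods under product-Bernoulli emissions
.emission_lik <- function(calls, emission) {
  logb <- calls %*% t(log(emission)) +
    (1 - calls) %*% t(log(1 - emission))
  exp(logb)
}

.split_sequences <- function(mat) {
  r <- rle(mat$windows$chrom)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(function(s, e) s:e, starts, ends)
}

#' Fit a multivariate Bernoulli-emission HMM to binarized mark calls
#'
#' Baum-Welch EM with per-contig sequence resets: each contig is treated as an
#' independent observation sequence of the same model. Emissions are the
#' per-state Bernoulli presence probabilities of each mark (conditionally
#' independent given the state); the forward-backward recursions use per-step
#' scaling, so long sequences cannot underflow. Emissions are floored away
#' from 0/1 and transitions receive a small pseudocount to avoid degenerate EM
#' fixed points. The log-likelihood is checked to be non-decreasing at every
#' iteration.
#'
#' @param mat a [binarize()] `MarkBinaryMatrix`.
#' @param n_states number of chromatin states (explicit, never inferred).
#' @param seed seed for the emission initialisation (uniform draws in
#'   `(0.2, 0.8)`); transitions and the initial distribution start uniform.
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations or a
#'   log-likelihood improvement below `tol`.
#' @param n_restarts independent seeded restarts; the best final
#'   log-likelihood wins.
#' @param eps emission floor and transition pseudocount.
#' @return A `ChromatinStateModel`: `emission` (states x marks), `transition`
#'   (row-stochastic), `initial`, `log_likelihood_trace`, `n_states`, `marks`.
#' @export
fit_hmm <- function(mat, n_states, seed = 1L, max_iter = 200L, tol = 1e-4,
                    n_restarts = 1L, eps = 1e-6) {
  stopifnot(inherits(mat, "MarkBinaryMatrix"), n_states >= 1L)
  Tn <- nrow(mat$calls)
  if (n_states > Tn) stop("n_states (", n_states, ") exceeds window count (", Tn, ")")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .fit_hmm_once(mat, n_states, sub_seed(seed, r - 1L), max_iter, tol, eps)
    if (is.null(best) || tail(fit$log_likelihood_trace, 1) >
        tail(best$log_likelihood_trace, 1)) {
      best <- fit
    }
  }
  best
}

.fit_hmm_once <- function(mat, n_states, seed, max_iter, tol, eps) {
  K <- n_states
  M <- length(mat$marks)
  X <- mat$calls
  storage.mode(X) <- "double"
  seqs <- .split_sequences(mat)

  E <- with_seed(seed, matrix(runif(K * M, 0.2, 0.8), K, M,
                              dimnames = list(NULL, mat$marks)))
  A <- matrix(1 / K, K, K)
  pi0 <- rep(1 / K, K)
  trace <- numeric(0)

  for (it in seq_len(max_iter)) {
    B <- .emission_lik(X, E)
    ll <- 0
    gamma_sum <- numeric(K)
    gamma_obs <- matrix(0, K, M)
    gamma1 <- numeric(K)
    xi_sum <- matrix(0, K, K)
    gammas <- vector("list", length(seqs))
    for (si in seq_along(seqs)) {
      idx <- seqs[[si]]
      res <- fb_core(B[idx, , drop = FALSE], A, pi0)
      if (!is.finite(res$loglik)) {
        stop("non-finite likelihood at EM iteration ", it)
      }
      ll <- ll + res$loglik
      g <- res$gamma
      gamma_sum <- gamma_sum + colSums(g)
      gamma_obs <- gamma_obs + t(g) %*% X[idx, , drop = FALSE]
      gamma1 <- gamma1 + g[1, ]
      xi_sum <- xi_sum + res$xi_sum
    }
    if (length(trace) && ll < tail(trace, 1) - 1e-8 * max(1, abs(ll))) {
      stop("EM log-likelihood decreased at iteration ", it,
           " (", tail(trace, 1), " -> ", ll, ")")
    }
    converged <- length(trace) > 0 && (ll - tail(trace, 1)) < tol
    trace <- c(trace, ll)
    if (converged) break

    # M-step
    E <- gamma_obs / pmax(gamma_sum, .Machine$double.xmin)
    E <- pmin(pmax(E, eps), 1 - eps)
    A <- xi_sum + eps
    A <- A / rowSums(A)
    pi0 <- gamma1 / sum(gamma1)
    if (K == 1L) { A <- matrix(1, 1, 1); pi0 <- 1 }
  }
  structure(list(emission = E, transition = A, initial = pi0,
                 log_likelihood_trace = trace, n_states = K,
                 marks = mat$marks, seed = seed),
            class = "ChromatinStateModel")
}

#' @export
print.ChromatinStateModel <- function(x, ...) {
  cat("ChromatinStateModel:", x$n_states, "states x", length(x$marks),
      "marks;", length(x$log_likelihood_trace), "EM iterations; logLik",
      format(tail(x$log_likelihood_trace, 1), digits = 8), "\n")
  em <- round(x$emission, 3)
  rownames(em) <- paste0("state", seq_len(x$n_states))
  print(em)
  invisible(x)
}

#' Total forward log-likelihood of binarized calls under a model
#'
#' @param model a [fit_hmm()] model.
#' @param mat a `MarkBinaryMatrix` with the same marks.
#' @return The summed log-likelihood over per-contig sequences.
#' @export
hmm_loglik <- function(model, mat) {
  .check_marks(model, mat)
  X <- mat$calls
  storage.mode(X) <- "double"
  B <- .emission_lik(X, model$emission)
  sum(vapply(.split_sequences(mat), function(idx) {
    fb_core(B[idx, , drop = FALSE], model$transition, model$initial)$loglik
  }, numeric(1)))
}

.check_marks <- function(model, mat) {
  if (!identical(model$marks, mat$marks)) {
    stop("model marks (", paste(model$marks, collapse = ","),
         ") do not match matrix marks (", paste(mat$marks, collapse = ","), ")")
  }
}

#' Posterior-decode a state track
#'
#' Per-window state labels are the argmax of the forward-backward posterior;
#' ties break toward the lowest state index.
#'
#' @param model a [fit_hmm()] model.
#' @param mat the `MarkBinaryMatrix` to decode.
#' @return A `StateTrack`: `data.table` with `chrom`, `start`, `end`,
#'   `state`; attributes `n_states`, `window`, `occupancy` (fractions summing
#'   to 1 over all windows).
#' @export
decode_states <- function(model, mat) {
  .check_marks(model, mat)
  X <- mat$calls
  storage.mode(X) <- "double"
  B <- .emission_lik(X, model$emission)
  state <- integer(nrow(X))
  for (idx in .split_sequences(mat)) {
    g <- fb_core(B[idx, , drop = FALSE], model$transition, model$initial)$gamma
    state[idx] <- max.col(g, ties.method = "first")
  }
  out <- copy(mat$windows)
  out[, state := state]
  occ <- tabulate(state, nbins = model$n_states) / length(state)
  setattr(out, "n_states", model$n_states)
  setattr(out, "window", mat$window)
  setattr(out, "occupancy", occ)
  setattr(out, "class", c("StateTrack", class(out)))
  out[]
}

#' Per-state distribution of single-site methylation levels
#'
#' Maps depth-filtered site levels (see [site_levels()]) to the chromatin
#' state of the window containing each site and summarises the per-state
#' distributions.
#'
#' @param track a [decode_states()] `StateTrack`.
#' @param sites a [site_levels()] table (`chrom`, `pos`, `level`).
#' @return A `data.table` with `state`, `n`, `median`, `q1`, `q3` (quartiles
#'   `NA` for empty states).
#' @export
state_methylation <- function(track, sites) {
  w <- attr(track, "window")
  n_states <- attr(track, "n_states")
  st <- as.data.table(track)
  si <- as.data.table(sites)
  si <- si[, .(chrom, start = as.integer((pos - 1L) %/% w) * as.integer(w), level)]
  m <- merge(si, st[, .(chrom, start, state)], by = c("chrom", "start"))
  agg <- m[, .(n = .N, median = stats::median(level),
               q1 = unname(quantile(level, 0.25)),
               q3 = unname(quantile(level, 0.75))), by = state]
  out <- merge(data.table(state = seq_len(n_states)), agg,
               by = "state", all.x = TRUE)
  out[is.na(n), n := 0L]
  setorder(out, state)
  out[]
}

#' Chromatin-state composition of delta strata
#'
#' For each stratum of differentially methylated bins, the fraction of
#' windows in each chromatin state among all windows falling inside the
#' stratum's bins. Rows sum to 1 (strata without windows are all-`NA`).
#'
#' @param track a [decode_states()] `StateTrack`.
#' @param strata a [stratify_by_delta()] table; its `bin_size` must be a
#'   multiple of the track's window size.
#' @return A strata x states matrix of fractions.
#' @export
state_composition <- function(track, strata) {
  w <- attr(track, "window")
  bin_size <- attr(strata, "bin_size")
  if (is.null(bin_size)) stop("strata carry no bin_size attribute")
  if (bin_size %% w != 0) {
    stop("bin_size (", bin_size, ") is not a multiple of the window (", w, ")")
  }
  n_states <- attr(track, "n_states")
  st <- copy(as.data.table(track))
  st[, bin_start := as.integer(start %/% bin_size) * as.integer(bin_size)]
  levs <- levels(strata$stratum)
  out <- matrix(NA_real_, length(levs), n_states,
                dimnames = list(levs, paste0("state", seq_len(n_states))))
  for (s in levs) {
    bins <- strata[stratum == s]
    if (nrow(bins) == 0L) next
    sel <- st[paste(chrom, bin_start) %in% paste(bins$chrom, bins$start)]
    if (nrow(sel) == 0L) next
    out[s, ] <- tabulate(sel$state, nbins = n_states) / nrow(sel)
  }
  out
}

#' Order model states by a mark's emission for stable display
#'
#' State labels out of EM are arbitrary; reporting orders them by descending
#' emission of one mark (H3K36me3 by default) so repeated runs display
#' comparably.
#'
#' @param model a [fit_hmm()] model.
#' @param mark mark name to sort on.
#' @return The model with states permuted; element `order` gives the
#'   old-to-new permutation.
#' @export
sort_states_by_mark <- function(model, mark = "H3K36me3") {
  stopifnot(mark %in% model$marks)
  o <- order(model$emission[, mark], decreasing = TRUE)
  model$emission <- model$emission[o, , drop = FALSE]
  model$transition <- model$transition[o, o, drop = FALSE]
  model$initial <- model$initial[o]
  model$order <- o
  model
}

#' Export a chromatin-state model as JSON
#'
#' @param model a [fit_hmm()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    n_states = model$n_states, marks = model$marks,
    emission = model$emission, transition = model$transition,
    initial = model$initial,
    log_likelihood = tail(model$log_likelihood_trace, 1)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Export a decoded state track as BED
#'
#' Adjacent same-state windows are merged into one interval labeled
#' `stateN`.
#'
#' @param track a [decode_states()] `StateTrack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_state_bed <- function(track, path) {
  dt <- as.data.table(track)
  r <- rle(paste(dt$chrom, dt$state))
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  bed <- data.table(chrom = dt$chrom[starts], start = dt$start[starts],
                    end = dt$end[ends],
                    label = paste0("state", dt$state[starts]))
  write_bed(bed, path)
}
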