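# Independent brute-force oracles and tiny fixtures shared across tests.
# Oracles deliberately use naive loops / enumeration, never the package's own
# code paths.

# quick record table builder
rec <- function(chrom, pos, strand, meth, unmeth,
                context = "CG", trinucleotide = "CGA") {
  n <- max(lengths(list(chrom, pos, strand, meth, unmeth)))
  cytosine_records(rep_len(chrom, n), rep_len(pos, n), rep_len(strand, n),
                   rep_len(meth, n), rep_len(unmeth, n),
                   rep_len(context, n), rep_len(trinucleotide, n))
}

# naive per-bin pooled levels by explicit looping over bins and sites
oracle_bin_levels <- function(records, bin_size, min_sites = 1L,
                              min_depth = 0L) {
  df <- as.data.frame(records)
  df <- df[df$count_meth + df$count_unmeth > 0, ]
  out <- list()
  for (cm in unique(df$chrom)) {
    sub <- df[df$chrom == cm, ]
    for (b in seq(0, max(sub$pos) - 1, by = bin_size)) {
      inb <- sub[sub$pos > b & sub$pos <= b + bin_size, ]
      lv <- if (nrow(inb) >= min_sites &&
                sum(inb$count_meth + inb$count_unmeth) >= max(min_depth, 1)) {
        sum(inb$count_meth) / sum(inb$count_meth + inb$count_unmeth)
      } else {
        NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(chrom = cm, start = b, level = lv)
    }
  }
  do.call(rbind, out)
}

# naive threshold scan for differential bins
oracle_dm_sets <- function(level_control, level_test, threshold) {
  delta <- 100 * (level_test - level_control)
  ok <- !is.na(delta)
  list(hyper = which(ok & delta >= threshold),
       hypo = which(ok & delta <= -threshold))
}

# exhaustive-path HMM log-likelihood: sums the joint probability over every
# one of the K^T state paths
oracle_hmm_loglik <- function(X, emission, transition, initial) {
  K <- nrow(emission)
  Tn <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  emit <- function(k, t) {
    prod(ifelse(X[t, ] == 1, emission[k, ], 1 - emission[k, ]))
  }
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- initial[s[1]] * emit(s[1], 1)
    if (Tn > 1) {
      for (t in 2:Tn) p <- p * transition[s[t - 1], s[t]] * emit(s[t], t)
    }
    total <- total + p
  }
  log(total)
}

# exhaustive posterior state probabilities (marginal over all paths)
oracle_hmm_posterior <- function(X, emission, transition, initial) {
  K <- nrow(emission)
  Tn <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  emit <- function(k, t) {
    prod(ifelse(X[t, ] == 1, emission[k, ], 1 - emission[k, ]))
  }
  post <- matrix(0, Tn, K)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- initial[s[1]] * emit(s[1], 1)
    if (Tn > 1) {
      for (t in 2:Tn) p <- p * transition[s[t - 1], s[t]] * emit(s[t], t)
    }
    total <- total + p
    for (t in seq_len(Tn)) post[t, s[t]] <- post[t, s[t]] + p
  }
  post / total
}

# smallest count called present: direct tail summation, no ppois
oracle_min_called_count <- function(lambda, p_threshold) {
  k <- 0
  repeat {
    k <- k + 1
    tail_p <- 1 - sum(dpois(0:(k - 1), lambda))
    if (tail_p < p_threshold) return(k)
    if (k > 1000) stop("no k found")
  }
}

# sample binarized windows from a known Bernoulli-emission HMM
sample_hmm_data <- function(n, emission, transition, initial, seed,
                            chrom = "chr1", window = 200L) {
  set.seed(seed)
  K <- nrow(emission)
  M <- ncol(emission)
  states <- integer(n)
  states[1] <- sample.int(K, 1, prob = initial)
  for (t in 2:n) states[t] <- sample.int(K, 1, prob = transition[states[t - 1], ])
  calls <- matrix(rbinom(n * M, 1, emission[states, ]), n, M)
  colnames(calls) <- colnames(emission) %||% paste0("mark", seq_len(M))
  mat <- structure(list(
    windows = data.table::data.table(
      chrom = chrom, start = (seq_len(n) - 1L) * window,
      end = seq_len(n) * window),
    marks = colnames(calls), calls = calls, window = window
  ), class = "MarkBinaryMatrix")
  list(mat = mat, states = states)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small default fixture shared by slower tests (built once per test run)
fixture_env <- new.env()
default_fixture <- function() {
  if (is.null(fixture_env$report)) {
    fixture_env$report <- run_comparison(run_config(seed = 101L))
  }
  fixture_env$report
}
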