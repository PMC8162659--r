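test_that("binarization thresholds the Poisson upper tail", {
  track <- data.table::data.table(
    chrom = "c1", start = seq(0L, 1900L, 100L), end = seq(100L, 2000L, 100L),
    mk = c(rep(0L, 10), 1L, 2L, 5L, 10L, 15L, 20L, 30L, 3L, 4L, 6L))
  bm <- binarize(track, marks = "mk", p_threshold = 1e-4, background = c(mk = 5))
  expect_true(all(bm$calls[track$mk == 0L, 1] == 0L))  # count 0 is never called
  kmin <- oracle_min_called_count(5, 1e-4)
  expect_equal(as.vector(bm$calls[, 1]), as.integer(track$mk >= kmin))

  # all-equal counts give a uniform call, never mixed
  flat <- data.table::data.table(chrom = "c1", start = 0:9 * 100L,
                                 end = 1:10 * 100L, mk = 7L)
  bmf <- binarize(flat, marks = "mk")
  expect_equal(length(unique(bmf$calls[, 1])), 1L)

  zero <- data.table::data.table(chrom = "c1", start = 0L, end = 100L, mk = 0L)
  expect_error(binarize(zero, marks = "mk"), "zero genome-wide coverage")
})

test_that("forward log-likelihood matches exhaustive path enumeration", {
  set.seed(41)
  for (Tn in c(1, 3, 6, 8)) {
    E <- matrix(runif(2 * 2, 0.1, 0.9), 2, 2,
                dimnames = list(NULL, c("m1", "m2")))
    A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
    pinit <- c(0.6, 0.4)
    X <- matrix(rbinom(Tn * 2, 1, 0.5), Tn, 2, dimnames = list(NULL, c("m1", "m2")))
    mat <- structure(list(
      windows = data.table::data.table(chrom = "c1", start = (seq_len(Tn) - 1L) * 200L,
                                       end = seq_len(Tn) * 200L),
      marks = c("m1", "m2"), calls = X, window = 200L
    ), class = "MarkBinaryMatrix")
    model <- structure(list(emission = E, transition = A, initial = pinit,
                            n_states = 2L, marks = c("m1", "m2")),
                       class = "ChromatinStateModel")
    expect_equal(hmm_loglik(model, mat),
                 oracle_hmm_loglik(X, E, A, pinit), tolerance = 1e-10)
  }
})

test_that("posterior decoding matches exhaustive marginalisation", {
  set.seed(42)
  Tn <- 6
  E <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2, dimnames = list(NULL, c("m1", "m2")))
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  pinit <- c(0.5, 0.5)
  X <- matrix(rbinom(Tn * 2, 1, 0.5), Tn, 2, dimnames = list(NULL, c("m1", "m2")))
  B <- methylandscape:::.emission_lik(X, E)
  g <- methylandscape:::fb_core(B, A, pinit)$gamma
  expect_equal(rowSums(g), rep(1, Tn), tolerance = 1e-12)
  expect_equal(g, oracle_hmm_posterior(X, E, A, pinit), tolerance = 1e-10)
})

test_that("a one-state model reduces to empirical mark frequencies", {
  sim <- sample_hmm_data(500, matrix(c(0.3, 0.6), 1, 2), matrix(1, 1, 1), 1,
                         seed = 43)
  fit <- fit_hmm(sim$mat, n_states = 1, seed = 1, max_iter = 20)
  expect_equal(as.vector(fit$emission), unname(colMeans(sim$mat$calls)),
               tolerance = 1e-6)
  expect_equal(as.vector(fit$transition), 1)
  tr <- decode_states(fit, sim$mat)
  expect_true(all(tr$state == 1L))
  expect_equal(attr(tr, "occupancy"), 1)
})

test_that("EM recovers a known two-state model and its log-likelihood is monotone", {
  E <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, dimnames = list(NULL, c("m1", "m2")))
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE)
  sim <- sample_hmm_data(20000, E, A, c(0.5, 0.5), seed = 44)
  fit <- fit_hmm(sim$mat, n_states = 2, seed = 7, max_iter = 100)
  expect_true(all(diff(fit$log_likelihood_trace) >= -1e-8))
  # resolve label permutation by matching emissions to the truth
  perm <- if (sum(abs(fit$emission - E)) < sum(abs(fit$emission[2:1, ] - E))) {
    1:2
  } else {
    2:1
  }
  expect_lt(max(abs(fit$emission[perm, ] - E)), 0.05)
  expect_lt(max(abs(fit$transition[perm, perm] - A)), 0.05)

  # near-deterministic emissions decode back to the generating labels
  tr <- decode_states(fit, sim$mat)
  agree <- mean(perm[sim$states] == tr$state)
  expect_gte(max(agree, 1 - agree), 0.95)
  expect_equal(sum(attr(tr, "occupancy")), 1, tolerance = 1e-12)
})

test_that("fitting is invariant to contig order up to state relabeling", {
  E <- matrix(c(0.85, 0.15, 0.2, 0.9), 2, 2, dimnames = list(NULL, c("m1", "m2")))
  A <- matrix(c(0.9, 0.1, 0.15, 0.85), 2, byrow = TRUE)
  s1 <- sample_hmm_data(800, E, A, c(0.5, 0.5), seed = 45, chrom = "c1")
  s2 <- sample_hmm_data(800, E, A, c(0.5, 0.5), seed = 46, chrom = "c2")
  join <- function(a, b) {
    structure(list(
      windows = rbind(a$mat$windows, b$mat$windows),
      marks = a$mat$marks, calls = rbind(a$mat$calls, b$mat$calls),
      window = 200L), class = "MarkBinaryMatrix")
  }
  f12 <- fit_hmm(join(s1, s2), n_states = 2, seed = 3, max_iter = 200, tol = 1e-8)
  f21 <- fit_hmm(join(s2, s1), n_states = 2, seed = 3, max_iter = 200, tol = 1e-8)
  m12 <- sort_states_by_mark(f12, "m1")
  m21 <- sort_states_by_mark(f21, "m1")
  expect_equal(m12$emission, m21$emission, tolerance = 0.05)
})

test_that("fit and decode guard their inputs", {
  sim <- sample_hmm_data(10, matrix(c(0.3, 0.6), 1, 2), matrix(1, 1, 1), 1,
                         seed = 47)
  expect_error(fit_hmm(sim$mat, n_states = 50), "exceeds window count")
  fit <- fit_hmm(sim$mat, n_states = 1, seed = 1, max_iter = 5)
  other <- sim$mat
  other$marks <- c("x", "y")
  colnames(other$calls) <- other$marks
  expect_error(decode_states(fit, other), "do not match")
})

test_that("state methylation and composition summarise tracks correctly", {
  track <- data.table::data.table(
    chrom = "c1", start = 0:9 * 200L, end = 1:10 * 200L,
    state = rep(c(1L, 2L), each = 5))
  data.table::setattr(track, "n_states", 2L)
  data.table::setattr(track, "window", 200L)
  data.table::setattr(track, "class", c("StateTrack", class(track)))

  sites <- data.table::data.table(
    chrom = "c1", pos = c(100L, 300L, 1100L, 1300L),
    strand = "+", depth = 20L, level = c(0, 0, 1, 1))
  sm <- state_methylation(track, sites)
  expect_equal(sm$median, c(0, 1))
  expect_equal(sm$n, c(2L, 2L))

  # composition: single stratum entirely inside state-2 windows
  strata <- data.table::data.table(chrom = "c1", start = 1000L, end = 2000L,
                                   delta = 30,
                                   stratum = factor("[20,100]"))
  data.table::setattr(strata, "bin_size", 1000L)
  comp <- state_composition(track, strata)
  expect_equal(as.vector(comp), c(0, 1))
  expect_equal(sum(comp), 1)
  bad <- data.table::copy(strata)
  data.table::setattr(bad, "bin_size", 300L)
  expect_error(state_composition(track, bad), "not a multiple")
})
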