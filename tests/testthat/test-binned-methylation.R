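test_that("global level pools counts rather than averaging site fractions", {
  two <- cytosine_records(c("c1", "c1"), c(1L, 3L), c("+", "+"),
                          c(10L, 0L), c(0L, 10L), c("CG", "CG"),
                          c("CGA", "CGA"))
  expect_equal(global_level(two, "CG"), 0.5)

  uneven <- cytosine_records(c("c1", "c1"), c(1L, 3L), c("+", "+"),
                             c(3L, 1L), c(7L, 29L), c("CG", "CG"),
                             c("CGA", "CGA"))
  expect_equal(global_level(uneven, "CG"), 0.1)  # 4/40, not mean(0.3, 1/30)

  expect_error(global_level(rec("c1", 1L, "+", 0L, 0L), "CG"), "no covered sites")
})

test_that("bin levels match a brute-force pooling oracle exactly", {
  set.seed(21)
  n <- 400
  r <- cytosine_records(
    chrom = sample(c("c1", "c2"), n, TRUE),
    pos = sample.int(5000, n),
    strand = "+",
    count_meth = rbinom(n, 20, 0.3), count_unmeth = rbinom(n, 20, 0.6),
    context = "CG", trinucleotide = "CGA")
  r <- unique(r, by = c("chrom", "pos", "strand"))
  bt <- bin_levels(r, bin_size = 1000, context = "CG", min_sites = 3,
                   min_depth_per_bin = 10)
  oracle <- oracle_bin_levels(r, 1000, min_sites = 3, min_depth = 10)
  m <- merge(as.data.frame(bt), oracle, by = c("chrom", "start"),
             suffixes = c("", "_oracle"))
  expect_equal(nrow(m), nrow(oracle))
  expect_equal(m$level, m$level_oracle, tolerance = 1e-15)
})

test_that("bins honour coverage filters and missingness semantics", {
  r <- cytosine_records(c("c1", "c1"), c(10L, 20L), c("+", "+"),
                        c(5L, 5L), c(0L, 0L), c("CG", "CG"), c("CGA", "CGA"))
  bt <- bin_levels(r, bin_size = 100, min_sites = 1)
  expect_equal(bt$level[1], 1.0)

  # a bin with zero covered sites is missing, not 0
  bt2 <- bin_levels(r, bin_size = 100, min_sites = 1,
                    seqlengths = c(c1 = 300L))
  expect_equal(nrow(bt2), 3L)
  expect_true(is.na(bt2$level[2]) && is.na(bt2$level[3]))
  expect_equal(bt2$n_sites[2], 0L)

  # site count bookkeeping: sums over non-missing bins never exceed coverage
  expect_lte(sum(bt2$n_sites), 2L)
})

test_that("global level equals the depth-weighted mean of bin levels", {
  g <- generate_genome(genome_config(contig_lengths = c(chrA = 50000L),
                                     satellite_copies = 0L,
                                     spike_in_length = 1000L), seed = 13)
  r <- simulate_methylome(g, genotype_params(depth_mean = 15, seed = 14))
  r <- r[r$chrom == "chrA" & r$context == "CG", ]
  bt <- bin_levels(r, bin_size = 5000, min_sites = 1, context = "CG")
  expect_true(all(!is.na(bt$level)))
  pooled <- sum(bt$level * bt$total_depth) / sum(bt$total_depth)
  expect_equal(pooled, global_level(r, "CG"), tolerance = 1e-12)
})

test_that("annotation levels pool across intervals and share multi-label sites", {
  ann <- data.table::data.table(
    chrom = c("c1", "c1", "c1"), start = c(0L, 200L, 150L),
    end = c(100L, 300L, 250L), label = c("sat", "sat", "gene"))
  r <- cytosine_records(c("c1", "c1", "c1"), c(50L, 250L, 240L), rep("+", 3),
                        c(2L, 6L, 10L), c(8L, 4L, 0L), rep("CG", 3),
                        rep("CGA", 3))
  lv <- annotation_levels(r, ann, context = "CG")
  sat <- lv[lv$label == "sat", ]
  expect_equal(sat$level, 18 / 30)  # pooled over two intervals
  gene <- lv[lv$label == "gene", ]
  expect_equal(gene$level, 16 / 20)  # site 250 counts toward both labels

  fully <- cytosine_records("c1", 50L, "+", 10L, 0L, "CG", "CGA")
  lv2 <- annotation_levels(fully, ann)
  expect_equal(lv2[lv2$label == "sat", ]$level, 1.0)
  expect_true(is.na(lv2[lv2$label == "gene", ]$level))
})

test_that("single-site depth filter uses an inclusive boundary", {
  r <- cytosine_records(c("c1", "c1"), c(1L, 5L), c("+", "+"),
                        c(8L, 7L), c(8L, 8L), c("CG", "CG"), c("CGA", "CGA"))
  sl <- site_levels(r, min_depth = 16L)  # depth > 15
  expect_equal(nrow(sl), 1L)
  expect_equal(sl$level, 0.5)
  expect_equal(sl$depth, 16L)
  # oracle scan
  df <- as.data.frame(r)
  expect_equal(nrow(sl), sum(df$count_meth + df$count_unmeth >= 16))
})

test_that("level histogram bins levels with a closed top interval", {
  mk <- function(levels) {
    bt <- data.table::data.table(chrom = "c1",
                                 start = (seq_along(levels) - 1L) * 100L,
                                 end = seq_along(levels) * 100L,
                                 level = levels, n_sites = 1L, total_depth = 10)
    data.table::setattr(bt, "bin_size", 100L)
    bt
  }
  h <- level_histogram(mk(rep(1, 5)), 10)
  expect_equal(h$count[h$lower == 90], 5L)
  expect_equal(sum(h$count), 5L)

  h2 <- level_histogram(mk(c(0.05, 0.15, 0.95, NA)), 10)
  expect_equal(h2$count[h2$lower %in% c(0, 10, 90)], c(1L, 1L, 1L))
  expect_equal(sum(h2$count), 3L)  # missing bins excluded
  expect_error(level_histogram(mk(0.5), 30), "divide 100")
})

test_that("the synthetic methylome has the expected bimodal bin histogram", {
  report <- default_fixture()
  h <- level_histogram(report$cg_bins$control, 10)
  # modes at the simulated low (~20%) and high (~85%) domain levels
  top2 <- h$lower[order(-h$count)][1:2]
  expect_true(any(top2 >= 70))
  expect_true(any(top2 <= 30))
})
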