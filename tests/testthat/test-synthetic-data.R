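test_that("genome generation is deterministic and satisfies its geometry", {
  cfg <- genome_config()
  g1 <- generate_genome(cfg, seed = 1)
  g2 <- generate_genome(cfg, seed = 1)
  expect_identical(g1$contigs, g2$contigs)
  expect_identical(as.data.frame(g1$domains), as.data.frame(g2$domains))

  # satellite arithmetic: monomer length x copies
  sat <- g1$domains[g1$domains$label == "satellite", ]
  expect_equal(sum(sat$end - sat$start), 234L * 100L)
  # the satellite region really is a tandem repeat of a 234-mer
  s <- substr(g1$contigs[[sat$chrom]], sat$start + 1L, sat$end)
  mono <- substr(s, 1, 234)
  expect_identical(s, strrep(mono, 100))

  # spike-in carries no domain labels, sequences are ACGT
  expect_false(g1$spike_in_name %in% g1$domains$chrom)
  expect_true(all(strsplit(paste(g1$contigs, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  # domains are non-overlapping and within contig bounds
  d <- g1$domains[order(g1$domains$chrom, g1$domains$start), ]
  for (cm in unique(d$chrom)) {
    dd <- d[d$chrom == cm, ]
    expect_true(all(dd$start[-1] >= dd$end[-nrow(dd)]))
    expect_true(all(dd$end <= nchar(g1$contigs[[cm]])))
  }
})

test_that("domain fractions are honoured up to placement granularity", {
  cfg <- genome_config(contig_lengths = c(chr1 = 500000L),
                       domain_fractions = c(K36 = 0.3, K27 = 0.2),
                       satellite_copies = 0L)
  g <- generate_genome(cfg, seed = 2)
  k36 <- sum(with(g$domains, end - start)[g$domains$label == "K36"])
  expect_equal(k36, 150000L)
  k27 <- sum(with(g$domains, end - start)[g$domains$label == "K27"])
  expect_equal(k27, 100000L)
  expect_error(genome_config(domain_fractions = c(K36 = 0.7, K27 = 0.5)),
               "sum to more than 1")
})

test_that("mark tracks follow the Poisson enrichment model", {
  g <- generate_genome(genome_config(), seed = 1)
  flat <- simulate_mark_tracks(g, marks = "H3K36me3", window = 200,
                               enrichment = list(H3K36me3 = c(K36 = 1)),
                               background_rate = 5, seed = 4)
  m <- mean(flat$H3K36me3)
  se <- sqrt(5 / nrow(flat))
  expect_lt(abs(m - 5), 3 * se)

  # zero enrichment silences every window of the domain
  zero <- simulate_mark_tracks(g, marks = "H3K36me3", window = 200,
                               enrichment = list(H3K36me3 = c(K36 = 0)),
                               background_rate = 5, seed = 4)
  k36 <- g$domains[g$domains$label == "K36", ]
  mid <- zero$start + (zero$end - zero$start) %/% 2
  in_k36 <- rep(FALSE, nrow(zero))
  for (j in seq_len(nrow(k36))) {
    in_k36 <- in_k36 | (zero$chrom == k36$chrom[j] &
                          mid >= k36$start[j] & mid < k36$end[j])
  }
  expect_true(all(zero$H3K36me3[in_k36] == 0L))

  # determinism and configuration errors
  again <- simulate_mark_tracks(g, marks = "H3K36me3", window = 200,
                                enrichment = list(H3K36me3 = c(K36 = 1)),
                                background_rate = 5, seed = 4)
  expect_identical(flat$H3K36me3, again$H3K36me3)
  expect_error(
    simulate_mark_tracks(g, marks = "H3K36me3",
                         enrichment = list(H3K36me3 = c(nosuch = 2))),
    "unknown domain")
  expect_error(simulate_mark_tracks(g, marks = "H3K99me9"), "no enrichment map")
})

test_that("methylome simulation recovers its generating parameters", {
  g <- generate_genome(genome_config(contig_lengths = c(chrA = 200000L),
                                     domain_fractions = c(K36 = 1),
                                     satellite_copies = 0L,
                                     spike_in_length = 20000L), seed = 5)
  # degenerate case: p = 0 everywhere, no conversion error
  p0 <- genotype_params(cg_level_by_domain = c(K36 = 0),
                        ch_level_by_dinucleotide = c(CA = 0, CT = 0, CC = 0),
                        conversion_error = 0, depth_mean = 10, seed = 6)
  r0 <- simulate_methylome(g, p0)
  expect_true(all(r0$count_meth == 0L))

  # binomial pooling: p = 0.4 at depth 30 over >= 10^4 CG sites
  p4 <- genotype_params(cg_level_by_domain = c(K36 = 0.4),
                        conversion_error = 0, depth_mean = 30, seed = 7)
  r4 <- simulate_methylome(g, p4)
  cg <- r4[r4$chrom == "chrA" & r4$context == "CG", ]
  expect_gt(nrow(cg), 10000)
  lvl <- global_level(cg, "CG")
  tot <- sum(cg$count_meth + cg$count_unmeth)
  expect_lt(abs(lvl - 0.4), 3 * sqrt(0.4 * 0.6 / tot))

  # spike-in reflects pure conversion error
  pe <- genotype_params(conversion_error = 0.005, depth_mean = 30, seed = 8)
  re <- simulate_methylome(g, pe)
  sp <- re[re$chrom == g$spike_in_name, ]
  expect_lt(abs(global_level(sp, "all") - 0.005), 0.001)
})

test_that("conversion error monotonically inflates apparent methylation", {
  g <- generate_genome(genome_config(contig_lengths = c(chrA = 50000L),
                                     satellite_copies = 0L,
                                     spike_in_length = 30000L), seed = 9)
  lv <- vapply(c(0, 0.005, 0.02, 0.05), function(err) {
    p <- genotype_params(conversion_error = err, depth_mean = 20, seed = 10)
    r <- simulate_methylome(g, p)
    global_level(r[r$chrom == g$spike_in_name, ], "all")
  }, numeric(1))
  expect_true(all(diff(lv) > 0))
})

test_that("mutant gain lands in non-K36 domains at the bin level", {
  report <- default_fixture()
  hyper <- hyper_bins(report$cg_comparison)
  expect_gt(nrow(hyper), 0)
  lab <- methylandscape:::domain_label_at(
    report$genome, hyper$chrom,
    hyper$start + (hyper$end - hyper$start) %/% 2L + 1L)
  frac_nonk36 <- mean(lab != "K36")
  expect_gte(frac_nonk36, 0.9)
  expect_lt(mean(lab == "K36"), 0.05)
  # hypo set is (close to) empty, hyper bins dominate
  expect_lte(nrow(hypo_bins(report$cg_comparison)), 1)
})
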