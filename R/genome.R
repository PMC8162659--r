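#' Configure the synthetic genome fixture
#'
#' The fixture emulates the chromatin landscape an oocyte methylome sits on:
#' transcribed H3K36me2/3 domains carrying high CG methylation, Polycomb
#' (H3K27me3) domains, bivalent domains, H3K9me2 blocks, a pericentromeric
#' satellite tandem array, unmarked background, and an unmethylated spike-in
#' contig used for conversion-rate QC.
#'
#' Domain labels are placed as shuffled blocks of `domain_block` bp so that the
#' realised base fraction per label matches the requested fraction up to
#' placement granularity. The satellite array is a tandem repeat of a random
#' monomer overlaid at a block boundary of the first contig.
#'
#' @param contig_lengths named integer vector of main contig lengths.
#' @param spike_in_name,spike_in_length unmethylated control contig; the
#'   default length matches the lambda phage genome commonly spiked in.
#' @param domain_fractions named fractions of each main contig assigned to the
#'   labels `K36`, `K27`, `bivalent`, `K9me2`; the remainder is `unmarked`.
#'   Must sum to at most 1.
#' @param domain_block placement granularity in bp.
#' @param satellite_monomer_length,satellite_copies tandem-array geometry.
#' @param gc fraction of G+C in the random background sequence.
#' @return A `genome_config` list.
#' @export
genome_config <- function(contig_lengths = c(chr1 = 500000L, chr2 = 500000L),
                          spike_in_name = "lambda_spike",
                          spike_in_length = 48502L,
                          domain_fractions = c(K36 = 0.35, K27 = 0.10,
                                               bivalent = 0.05, K9me2 = 0.10),
                          domain_block = 10000L,
                          satellite_monomer_length = 234L,
                          satellite_copies = 100L,
                          gc = 0.42) {
  if (sum(domain_fractions) > 1 + 1e-12) {
    stop("domain fractions sum to more than 1")
  }
  if (is.null(names(contig_lengths))) {
    names(contig_lengths) <- paste0("chr", seq_along(contig_lengths))
  }
  structure(list(
    contig_lengths = contig_lengths, spike_in_name = spike_in_name,
    spike_in_length = as.integer(spike_in_length),
    domain_fractions = domain_fractions, domain_block = as.integer(domain_block),
    satellite_monomer_length = as.integer(satellite_monomer_length),
    satellite_copies = as.integer(satellite_copies), gc = gc
  ), class = "genome_config")
}

.random_seq <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate the synthetic genome fixture
#'
#' @param config a [genome_config()].
#' @param seed integer seed; the fixture is deterministic for a fixed seed.
#' @return A `GenomeFixture`: `contigs` (named character sequences),
#'   `spike_in_name`, and `domains` (0-based half-open labeled intervals
#'   tiling the main contigs; the spike-in carries no labels).
#' @export
generate_genome <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  with_seed(seed, {
    contigs <- vapply(config$contig_lengths, .random_seq, character(1),
                      gc = config$gc)
    spike <- .random_seq(config$spike_in_length, config$gc)
    contigs <- c(contigs, structure(spike, names = config$spike_in_name))

    # domain placement: a deterministic count of blocks per label, shuffled
    domains <- vector("list", length(config$contig_lengths))
    for (i in seq_along(config$contig_lengths)) {
      nm <- names(config$contig_lengths)[i]
      len <- config$contig_lengths[[i]]
      n_blocks <- ceiling(len / config$domain_block)
      n_per <- round(config$domain_fractions * n_blocks)
      labels <- c(rep(names(n_per), n_per),
                  rep("unmarked", max(0L, n_blocks - sum(n_per))))
      labels <- sample(labels[seq_len(n_blocks)])
      starts <- (seq_len(n_blocks) - 1L) * config$domain_block
      domains[[i]] <- data.table(
        chrom = nm, start = starts,
        end = pmin(starts + config$domain_block, len), label = labels
      )
    }
    domains <- rbindlist(domains)

    # satellite tandem array overlaid on the first contig
    sat_len <- config$satellite_monomer_length * config$satellite_copies
    first <- names(config$contig_lengths)[1]
    if (sat_len > 0L) {
      if (sat_len > config$contig_lengths[[1]]) {
        stop("satellite array longer than the first contig")
      }
      monomer <- .random_seq(config$satellite_monomer_length, config$gc)
      n_blocks1 <- ceiling(config$contig_lengths[[1]] / config$domain_block)
      max_block <- n_blocks1 - ceiling(sat_len / config$domain_block)
      sat_start <- (sample.int(max_block, 1L) - 1L) * config$domain_block
      sat_end <- sat_start + sat_len
      seq1 <- contigs[[first]]
      contigs[[first]] <- paste0(
        substr(seq1, 1L, sat_start),
        strrep(monomer, config$satellite_copies),
        substr(seq1, sat_end + 1L, nchar(seq1))
      )
      # carve the satellite interval out of the block-domain layer
      domains <- domains[!(chrom == first & start < sat_end & end > sat_start)]
      domains <- rbind(
        domains,
        data.table(chrom = first, start = sat_start, end = sat_end,
                   label = "satellite")
      )
    }
    setorder(domains, chrom, start)
    # re-tile gaps left by the satellite carve-out as unmarked
    domains <- .fill_domain_gaps(domains, config$contig_lengths)
    structure(list(contigs = contigs, spike_in_name = config$spike_in_name,
                   domains = domains, config = config),
              class = "GenomeFixture")
  })
}

# the satellite overlay removes whole overlapped blocks; refill uncovered
# main-contig bases as unmarked so domains tile every main contig exactly
.fill_domain_gaps <- function(domains, contig_lengths) {
  out <- list(domains)
  for (nm in names(contig_lengths)) {
    d <- domains[chrom == nm][order(start)]
    cover_end <- 0L
    gaps <- list()
    for (j in seq_len(nrow(d))) {
      if (d$start[j] > cover_end) {
        gaps[[length(gaps) + 1L]] <-
          data.table(chrom = nm, start = cover_end, end = d$start[j],
                     label = "unmarked")
      }
      cover_end <- max(cover_end, d$end[j])
    }
    if (cover_end < contig_lengths[[nm]]) {
      gaps[[length(gaps) + 1L]] <-
        data.table(chrom = nm, start = cover_end,
                   end = contig_lengths[[nm]], label = "unmarked")
    }
    if (length(gaps)) out[[length(out) + 1L]] <- rbindlist(gaps)
  }
  res <- rbindlist(out)
  setorder(res, chrom, start)
  res[]
}

#' @export
print.GenomeFixture <- function(x, ...) {
  cat("GenomeFixture:", length(x$contigs), "contigs,",
      sum(nchar(x$contigs)), "bp total\n")
  cat("  spike-in:", x$spike_in_name, "\n")
  occ <- x$domains[, .(bp = sum(end - start)), by = label]
  for (j in seq_len(nrow(occ))) {
    cat(sprintf("  %-10s %9d bp\n", occ$label[j], occ$bp[j]))
  }
  invisible(x)
}

#' Default mark-to-domain fold-enrichment map of the fixture
#'
#' Five histone H3 marks with fold enrichments over the Poisson background in
#' the domains they decorate; domains not listed have fold 1, the spike-in
#' contig is always background.
#'
#' @return A named list: mark -> named numeric vector of per-domain folds.
#' @export
default_mark_enrichment <- function() {
  list(
    H3K36me3 = c(K36 = 8),
    H3K36me2 = c(K36 = 6),
    H3K27me3 = c(K27 = 8, bivalent = 6, K9me2 = 3, satellite = 4),
    H3K4me3  = c(bivalent = 8),
    H3K9me2  = c(K9me2 = 8, satellite = 6)
  )
}

#' Simulate windowed histone-mark count tracks
#'
#' Emulates ChIP-seq coverage: counts per fixed non-overlapping window are
#' Poisson with mean `background_rate` times the fold enrichment of the domain
#' covering the window midpoint. The spike-in contig always receives
#' background-rate counts.
#'
#' @param genome a [GenomeFixture].
#' @param marks mark names; must all appear in `enrichment`.
#' @param window window size in bp (windows tile from 0 per contig; the last
#'   partial window is retained).
#' @param enrichment named list mark -> named per-domain fold vector; domain
#'   names must exist in the fixture's domain labels.
#' @param background_rate mean reads per window outside enriched domains.
#' @param seed integer seed.
#' @return A `MarkTrack`: `data.table` with `chrom`, `start`, `end` and one
#'   integer count column per mark; attribute `window`.
#' @export
simulate_mark_tracks <- function(genome, marks = names(default_mark_enrichment()),
                                 window = 200L,
                                 enrichment = default_mark_enrichment(),
                                 background_rate = 5, seed = 1L) {
  stopifnot(inherits(genome, "GenomeFixture"), window > 0)
  miss <- setdiff(marks, names(enrichment))
  if (length(miss)) stop("no enrichment map for mark(s): ",
                         paste(miss, collapse = ", "))
  # validate against the configured label vocabulary, not the realised labels:
  # a small fixture may drop a domain through placement rounding
  known <- unique(c(genome$domains$label, "unmarked", "satellite",
                    names(genome$config$domain_fractions %||% character())))
  for (m in marks) {
    bad <- setdiff(names(enrichment[[m]]), known)
    if (length(bad)) stop("mark ", m, " maps to unknown domain(s): ",
                          paste(bad, collapse = ", "))
  }
  lens <- nchar(genome$contigs)
  wins <- rbindlist(lapply(names(lens), function(nm) {
    starts <- seq(0L, lens[[nm]] - 1L, by = window)
    data.table(chrom = nm, start = starts, end = pmin(starts + window, lens[[nm]]))
  }))
  mid <- wins$start + (wins$end - wins$start) %/% 2L
  lab <- domain_label_at(genome, wins$chrom, mid + 1L)
  with_seed(seed, {
    for (m in marks) {
      fold <- rep(1, nrow(wins))
      f <- enrichment[[m]]
      hit <- lab %in% names(f)
      fold[hit] <- f[lab[hit]]
      fold[wins$chrom == genome$spike_in_name] <- 1
      wins[, (m) := rpois(.N, background_rate * fold)]
    }
  })
  setattr(wins, "window", as.integer(window))
  setattr(wins, "marks", marks)
  setattr(wins, "class", c("MarkTrack", class(wins)))
  wins[]
}

#' Domain label at 1-based positions
#' @keywords internal
domain_label_at <- function(genome, chrom, pos) {
  out <- rep(NA_character_, length(chrom))
  d <- genome$domains
  for (nm in unique(chrom)) {
    sel <- chrom == nm
    dd <- d[d$chrom == nm]
    if (nrow(dd) == 0L) next
    setorder(dd, start)
    idx <- findInterval(pos[sel] - 1L, dd$start)  # 0-based position vs starts
    ok <- idx >= 1L & (pos[sel] - 1L) < dd$end[pmax(idx, 1L)]
    res <- rep(NA_character_, sum(sel))
    res[ok] <- dd$label[idx[ok]]
    out[sel] <- res
  }
  out
}
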