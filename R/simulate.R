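#' Genotype parameters for methylome simulation
#'
#' Encodes the statistical structure of one genotype's methylome: per-domain
#' CG methylation probabilities (plus an additive mutant gain), CH methylation
#' probabilities per dinucleotide modulated by the base following the CH site,
#' a bisulfite conversion error, and a Poisson read-depth model.
#'
#' Defaults for the two preset genotypes emulate the oocyte contrast this
#' package is built around: the control carries a bimodal CG landscape (high
#' in transcribed H3K36me2/3 domains, low elsewhere) and CA-dominant CH
#' methylation; the PWWP-mutant preset adds CG gain confined to domains
#' lacking H3K36me2/3 — largest at the satellite array — and a modest CA gain,
#' while K36-domain levels are untouched.
#'
#' @param name genotype label.
#' @param cg_level_by_domain named probabilities per domain label.
#' @param cg_gain_by_domain named additive gains (levels clipped to `[0, 1]`).
#' @param ch_level_by_dinucleotide named probabilities for `CA`, `CT`, `CC`;
#'   defaults keep CA highest, mirroring oocyte CH methylation.
#' @param next_base_weights relative methylation propensity by the base
#'   following the CH site (mean 1 over a uniform base so the dinucleotide
#'   level stays interpretable); the default prefers C, the DNMT3A signature.
#' @param conversion_error probability an unmethylated C reads as methylated.
#' @param depth_mean mean Poisson read depth per cytosine.
#' @param seed integer seed.
#' @return A `GenotypeParams` list.
#' @export
genotype_params <- function(name = "control",
                            cg_level_by_domain = c(K36 = 0.85, K27 = 0.15,
                                                   bivalent = 0.10, K9me2 = 0.20,
                                                   satellite = 0.30,
                                                   unmarked = 0.20),
                            cg_gain_by_domain = c(K36 = 0, K27 = 0,
                                                  bivalent = 0, K9me2 = 0,
                                                  satellite = 0, unmarked = 0),
                            ch_level_by_dinucleotide = c(CA = 0.059, CT = 0.012,
                                                         CC = 0.009),
                            next_base_weights = c(A = 1.2, C = 1.6,
                                                  G = 0.4, T = 0.8),
                            conversion_error = 0.005,
                            depth_mean = 30,
                            seed = 1L) {
  p <- list(name = name,
            cg_level_by_domain = cg_level_by_domain,
            cg_gain_by_domain = cg_gain_by_domain,
            ch_level_by_dinucleotide = ch_level_by_dinucleotide,
            next_base_weights = next_base_weights,
            conversion_error = conversion_error,
            depth_mean = depth_mean,
            seed = as.integer(seed))
  probs <- c(cg_level_by_domain, ch_level_by_dinucleotide, conversion_error)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(next_base_weights < 0)) stop("next-base weights must be non-negative")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (!all(c("CA", "CT", "CC") %in% names(ch_level_by_dinucleotide))) {
    stop("ch_level_by_dinucleotide needs CA, CT and CC entries")
  }
  structure(p, class = "GenotypeParams")
}

#' Mutant preset mirroring the PWWP-mutant contrast
#'
#' CG gain is confined to chromatin lacking H3K36me2/3 (Polycomb, H3K9me2,
#' unmarked), greatest at the satellite array, absent from K36 domains and
#' nearly absent from bivalent chromatin; CA methylation rises moderately.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [genotype_params()].
#' @return A `GenotypeParams` list.
#' @export
mutant_params <- function(seed = 2L, ...) {
  defaults <- list(
    name = "mutant",
    cg_gain_by_domain = c(K36 = 0, K27 = 0.35, bivalent = 0.04,
                          K9me2 = 0.30, satellite = 0.45, unmarked = 0.30),
    ch_level_by_dinucleotide = c(CA = 0.072, CT = 0.014, CC = 0.011),
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(genotype_params, args)
}

#' Simulate a genotype's per-cytosine methylome on a genome fixture
#'
#' For every cytosine template of the genome (both strands), read depth is
#' Poisson(`depth_mean`) and the methylated count is Binomial(depth, p_eff)
#' with `p_eff = p + (1 - p) * conversion_error`, the conversion error acting
#' only in the unmethylated-to-methylated direction. The site probability `p`
#' is the (gain-adjusted, clipped) domain CG level for CG sites — both strands
#' of a CpG share the site-level `p` — or the dinucleotide level times the
#' next-base weight for CH sites. Spike-in cytosines use `p = 0`.
#'
#' @param genome a [GenomeFixture].
#' @param params a [genotype_params()].
#' @param templates optional precomputed [classify_contexts()] output (saves
#'   rescanning the genome when simulating several genotypes).
#' @return A `data.table` of cytosine records (zero-depth sites retained).
#' @export
simulate_methylome <- function(genome, params, templates = NULL) {
  stopifnot(inherits(genome, "GenomeFixture"), inherits(params, "GenotypeParams"))
  tpl <- if (is.null(templates)) classify_contexts(genome) else copy(templates)
  if (nrow(tpl) == 0L) stop("genome contains no cytosines")

  # site-level methylation probability
  p <- numeric(nrow(tpl))
  is_cg <- tpl$context == "CG"
  # CpG strands share the plus-strand site: look the domain up at the C of
  # the plus strand
  lookup_pos <- tpl$pos
  lookup_pos[is_cg & tpl$strand == "-"] <- lookup_pos[is_cg & tpl$strand == "-"] - 1L
  lab <- domain_label_at(genome, tpl$chrom, lookup_pos)
  # a lone minus-strand CG at pos 1 has no plus-strand partner position;
  # fall back to its own position for the domain lookup
  na_fix <- is.na(lab) & tpl$chrom != genome$spike_in_name
  if (any(na_fix)) {
    lab[na_fix] <- domain_label_at(genome, tpl$chrom[na_fix], tpl$pos[na_fix])
  }
  cg_p <- params$cg_level_by_domain
  gain <- params$cg_gain_by_domain
  all_lab <- unique(lab[is_cg & !is.na(lab)])
  miss <- setdiff(all_lab, names(cg_p))
  if (length(miss)) stop("no CG level for domain(s): ", paste(miss, collapse = ", "))
  lvl <- cg_p[lab[is_cg]] + ifelse(lab[is_cg] %in% names(gain),
                                   gain[lab[is_cg]], 0)
  p[is_cg] <- pmin(pmax(lvl, 0), 1)

  is_ch <- !is_cg
  din <- ch_dinucleotide(tpl$trinucleotide[is_ch])
  nb <- ch_next_base(tpl$trinucleotide[is_ch])
  ch_p <- rep(0, sum(is_ch))
  known <- din %in% names(params$ch_level_by_dinucleotide)
  ch_p[known] <- params$ch_level_by_dinucleotide[din[known]]
  w <- rep(1, sum(is_ch))
  wn <- nb %in% names(params$next_base_weights)
  w[wn] <- params$next_base_weights[nb[wn]]
  p[is_ch] <- pmin(pmax(ch_p * w, 0), 1)

  p[tpl$chrom == genome$spike_in_name] <- 0
  p_eff <- p + (1 - p) * params$conversion_error

  with_seed(params$seed, {
    depth <- rpois(nrow(tpl), params$depth_mean)
    meth <- rbinom(nrow(tpl), depth, p_eff)
  })
  out <- tpl[, .(chrom, pos, strand, count_meth = meth,
                 count_unmeth = depth - meth, context, trinucleotide)]
  setorder(out, chrom, pos, strand)
  out[]
}
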