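#' Default configuration for an end-to-end synthetic comparison
#'
#' One top-level seed drives every stage through fixed labeled sub-seeds, so a
#' run is reproducible from the config alone.
#'
#' @param seed top-level integer seed.
#' @param out_dir output directory (`NULL` for no file output).
#' @param depth_mean mean read depth per cytosine for both genotypes.
#' @param cg_threshold,ca_threshold differential-bin thresholds in percentage
#'   points (the conventional 20 for CG and 10 for CA).
#' @param site_min_depth single-CG depth filter (16 means depth > 15).
#' @param bin_size differential bin width in bp.
#' @param n_states,window,hmm_max_iter chromatin-state HMM settings (8 states
#'   over 5 marks in 200-bp windows by default).
#' @param min_sites_per_bin coverage filter for bin levels.
#' @param genome a [genome_config()].
#' @param control,mutant [genotype_params()] for the two genotypes (sub-seeded
#'   from `seed` when left `NULL`).
#' @return A `RunConfig` list.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, depth_mean = 30,
                       cg_threshold = 20, ca_threshold = 10,
                       site_min_depth = 16L, bin_size = 10000L,
                       n_states = 8L, window = 200L, hmm_max_iter = 100L,
                       min_sites_per_bin = 5L,
                       genome = genome_config(),
                       control = NULL, mutant = NULL) {
  stopifnot(cg_threshold > 0, ca_threshold > 0, site_min_depth >= 0)
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, depth_mean = depth_mean,
    cg_threshold = cg_threshold, ca_threshold = ca_threshold,
    site_min_depth = as.integer(site_min_depth), bin_size = as.integer(bin_size),
    n_states = as.integer(n_states), window = as.integer(window),
    hmm_max_iter = as.integer(hmm_max_iter),
    min_sites_per_bin = as.integer(min_sites_per_bin),
    genome = genome,
    control = control %||% genotype_params(depth_mean = depth_mean,
                                           seed = sub_seed(seed, 11L)),
    mutant = mutant %||% mutant_params(depth_mean = depth_mean,
                                       seed = sub_seed(seed, 12L))
  ), class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [run_config()]; nested
#' `genome`, `control` and `mutant` blocks override the corresponding
#' constructor defaults field by field.
#'
#' @param path YAML file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), setdiff(names(formals(run_config)),
                                        c("genome", "control", "mutant")))]
  cfg <- do.call(run_config, args)
  if (!is.null(y$genome)) {
    ga <- y$genome
    if (!is.null(ga$contig_lengths)) ga$contig_lengths <- unlist(ga$contig_lengths)
    if (!is.null(ga$domain_fractions)) ga$domain_fractions <- unlist(ga$domain_fractions)
    cfg$genome <- do.call(genome_config, ga)
  }
  for (g in c("control", "mutant")) {
    if (!is.null(y[[g]])) {
      ov <- lapply(y[[g]], function(v) if (is.list(v)) unlist(v) else v)
      base_fun <- if (g == "control") genotype_params else mutant_params
      cfg[[g]] <- do.call(base_fun, utils::modifyList(
        list(depth_mean = cfg$depth_mean, seed = sub_seed(cfg$seed,
                                                          if (g == "control") 11L else 12L)),
        ov))
    }
  }
  cfg
}

#' Run the full two-genotype methylome comparison
#'
#' Orchestrates the pipeline on a synthetic fixture: genome generation,
#' per-genotype methylome simulation, conversion QC on the spike-in, global
#' and binned CG levels, differential CG and CA bins, annotation levels,
#' chromatin-state model fit plus decoding, per-state single-CG methylation,
#' state composition across hypermethylation strata, CH dinucleotide levels
#' and next-base preference. All outputs are returned as one report list; with
#' `out_dir` set, tables are also written as TSV/BED/bedGraph plus a
#' machine-readable `summary.json`.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return The report list, invisibly when written to disk.
#' @export
run_comparison <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  genome <- stage("genome", generate_genome(config$genome, sub_seed(config$seed, 1L)))
  templates <- stage("contexts", classify_contexts(genome))
  marks <- stage("marks", simulate_mark_tracks(
    genome, window = config$window, seed = sub_seed(config$seed, 2L)))

  meth <- list(
    control = stage("methylome-control",
                    simulate_methylome(genome, config$control, templates)),
    mutant = stage("methylome-mutant",
                   simulate_methylome(genome, config$mutant, templates))
  )
  qc <- lapply(meth, function(r) {
    stage("conversion-qc", estimate_conversion(r, genome$spike_in_name))
  })

  main <- lapply(meth, function(r) r[chrom != genome$spike_in_name])
  merged <- lapply(main, function(r) stage("merge-strands", merge_cg_strands(r)))
  seqlen <- nchar(genome$contigs)
  seqlen <- seqlen[names(seqlen) != genome$spike_in_name]

  global_cg <- vapply(merged, global_level, numeric(1), context = "CG")
  cg_bins <- lapply(merged, function(r) {
    stage("bins", bin_levels(r, bin_size = config$bin_size, context = "CG",
                             min_sites = config$min_sites_per_bin,
                             seqlengths = seqlen))
  })
  cg_cmp <- stage("diff-cg", compare_bins(cg_bins$control, cg_bins$mutant,
                                          config$cg_threshold))
  ca_bins <- lapply(main, function(r) {
    stage("bins-ca", bin_levels(r, bin_size = config$bin_size, context = "CA",
                                min_sites = config$min_sites_per_bin,
                                seqlengths = seqlen))
  })
  ca_cmp <- stage("diff-ca", compare_bins(ca_bins$control, ca_bins$mutant,
                                          config$ca_threshold))

  ann <- lapply(main, function(r) {
    stage("annotation-levels", annotation_levels(r, genome$domains, context = "CG"))
  })

  bmat <- stage("binarize", binarize(marks[marks$chrom != genome$spike_in_name]))
  model <- stage("hmm-fit", fit_hmm(bmat, n_states = config$n_states,
                                    seed = sub_seed(config$seed, 3L),
                                    max_iter = config$hmm_max_iter))
  model <- sort_states_by_mark(model, "H3K36me3")
  track <- stage("hmm-decode", decode_states(model, bmat))
  state_meth <- lapply(merged, function(r) {
    stage("state-methylation",
          state_methylation(track, site_levels(filter_context(r, "CG"),
                                               config$site_min_depth)))
  })
  strata <- stage("stratify", stratify_by_delta(cg_cmp))
  composition <- stage("state-composition", state_composition(track, strata))
  genome_comp <- tabulate(track$state, nbins = config$n_states) / nrow(track)

  ch <- lapply(main, function(r) stage("ch-levels", ch_levels(r, "dinucleotide")))
  ch_tri <- lapply(main, function(r) {
    stage("ch-trinucleotide", ch_levels(r, "chh_trinucleotide"))
  })
  pref <- lapply(main, function(r) {
    stage("next-base", next_nucleotide_preference(r, genome))
  })

  report <- list(
    config = config, genome = genome, mark_track = marks, qc = qc,
    global_cg = global_cg, cg_bins = cg_bins, cg_comparison = cg_cmp,
    ca_bins = ca_bins, ca_comparison = ca_cmp, annotation_levels = ann,
    model = model, state_track = track, state_methylation = state_meth,
    strata = strata, state_composition = composition,
    genome_state_occupancy = genome_comp,
    ch_levels = ch, chh_trinucleotide_levels = ch_tri,
    next_base_preference = pref
  )
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    return(invisible(report))
  }
  report
}

#' Write a comparison report bundle to disk
#'
#' @param report a [run_comparison()] report.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_fasta(report$genome, p("genome.fa"))
  write_bed(report$genome$domains, p("domains.bed"))
  for (g in names(report$qc)) write_conversion_tsv(report$qc[[g]],
                                                   p(paste0("qc_", g, ".tsv")))
  for (g in names(report$cg_bins)) {
    write_bedgraph(report$cg_bins[[g]], p(paste0("cg_bins_", g, ".bedGraph")))
  }
  fwrite(as.data.table(report$cg_comparison), p("cg_comparison.tsv"), sep = "\t")
  fwrite(as.data.table(report$ca_comparison), p("ca_comparison.tsv"), sep = "\t")
  write_bed(hyper_bins(report$cg_comparison)[, .(chrom, start, end,
                                                 label = "hyper")],
            p("cg_hyper.bed"))
  for (g in names(report$annotation_levels)) {
    fwrite(report$annotation_levels[[g]], p(paste0("annotation_levels_", g, ".tsv")),
           sep = "\t")
  }
  write_model_json(report$model, p("chromatin_model.json"))
  write_state_bed(report$state_track, p("chromatin_states.bed"))
  for (g in names(report$state_methylation)) {
    fwrite(report$state_methylation[[g]], p(paste0("state_methylation_", g, ".tsv")),
           sep = "\t")
  }
  comp <- as.data.table(report$state_composition, keep.rownames = "stratum")
  fwrite(comp, p("state_composition.tsv"), sep = "\t")
  for (g in names(report$ch_levels)) {
    fwrite(report$ch_levels[[g]], p(paste0("ch_levels_", g, ".tsv")), sep = "\t")
    fwrite(report$next_base_preference[[g]],
           p(paste0("next_base_preference_", g, ".tsv")), sep = "\t")
  }
  jsonlite::write_json(summarize_report(report), p("summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Machine-readable summary of a comparison report
#'
#' @param report a [run_comparison()] report.
#' @return A plain list ready for JSON serialisation.
#' @export
summarize_report <- function(report) {
  cmp <- report$cg_comparison
  ca <- report$ca_comparison
  list(
    seed = report$config$seed,
    global_cg = as.list(report$global_cg),
    conversion_rate = lapply(report$qc, function(q) q$rate),
    n_paired_bins = nrow(cmp),
    n_hyper = sum(cmp$status == "hyper"),
    n_hypo = sum(cmp$status == "hypo"),
    n_hyper_ca = sum(ca$status == "hyper"),
    ch_levels = lapply(report$ch_levels, function(t) {
      stats::setNames(as.list(t$level), t$context)
    }),
    next_base_preference = lapply(report$next_base_preference, function(t) {
      stats::setNames(as.list(t$preference), t$base)
    }),
    state_occupancy = report$genome_state_occupancy,
    hmm_loglik = tail(report$model$log_likelihood_trace, 1)
  )
}
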