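#' Select records by sequence context
#'
#' Context filters used across the level functions: `"CG"` selects CG records
#' (strand-merged or not, as supplied); `"CH"` selects all non-CG records;
#' `"CA"`, `"CT"`, `"CC"` select CH records by dinucleotide; a 3-mer such as
#' `"CAG"` selects by exact trinucleotide; `"all"` keeps everything.
#'
#' @param records cytosine record table.
#' @param context filter keyword as above.
#' @return The filtered `data.table`.
#' @export
filter_context <- function(records, context = "CG") {
  dt <- as.data.table(records)
  if (identical(context, "all")) return(dt)
  if (identical(context, "CG")) return(dt[dt$context == "CG"])
  if (identical(context, "CH")) return(dt[dt$context != "CG"])
  if (context %in% c("CA", "CT", "CC")) {
    keep <- dt$context != "CG" & ch_dinucleotide(dt$trinucleotide) == context
    return(dt[keep])
  }
  if (nchar(context) == 3L) return(dt[dt$trinucleotide == context])
  stop("unknown context filter: ", context)
}

#' Global weighted methylation level
#'
#' The pooled level `sum(count_meth) / sum(count_meth + count_unmeth)` over all
#' covered sites passing the context filter — counts are pooled before
#' dividing, so deep sites weigh more than shallow ones (the standard WGBS
#' "weighted methylation level").
#'
#' @inheritParams filter_context
#' @return A fraction in `[0, 1]`.
#' @export
global_level <- function(records, context = "CG") {
  dt <- filter_context(records, context)
  dt <- dt[(count_meth + count_unmeth) > 0L]
  if (nrow(dt) == 0L) {
    stop("global level undefined: no covered sites for context ", context)
  }
  weighted_level(dt$count_meth, dt$count_unmeth)
}

#' Weighted methylation in fixed genomic bins
#'
#' Bins tile each contig from coordinate 0; the last partial bin is retained.
#' A bin's level pools counts over its covered sites; bins with fewer than
#' `min_sites` covered sites or total depth below `min_depth_per_bin` are
#' reported missing (`NA`), never 0.
#'
#' @inheritParams filter_context
#' @param bin_size bin width in bp (default 10 kb, the unit of all
#'   differential comparisons here).
#' @param min_sites minimum covered sites per bin.
#' @param min_depth_per_bin minimum pooled depth per bin.
#' @param seqlengths named contig lengths; if supplied, all bins of every
#'   contig are enumerated (otherwise bins run to the last covered site).
#' @return A `BinTrack`: `data.table` with `chrom`, `start`, `end`, `level`,
#'   `n_sites`, `total_depth`; attributes `bin_size` and `context`.
#' @export
bin_levels <- function(records, bin_size = 10000L, context = "CG",
                       min_sites = 5L, min_depth_per_bin = 0L,
                       seqlengths = NULL) {
  stopifnot(bin_size > 0)
  dt <- filter_context(records, context)
  dt <- dt[(count_meth + count_unmeth) > 0L]
  if (nrow(dt)) {
    dt <- dt[, .(chrom, pos, count_meth, count_unmeth)]
    dt[, bin_start := as.integer((pos - 1L) %/% bin_size) * as.integer(bin_size)]
    agg <- dt[, .(
      meth = sum(as.numeric(count_meth)),
      total = sum(as.numeric(count_meth) + as.numeric(count_unmeth)),
      n_sites = .N
    ), by = .(chrom, bin_start)]
  } else {
    agg <- data.table(chrom = character(), bin_start = integer(),
                      meth = numeric(), total = numeric(), n_sites = integer())
  }
  if (is.null(seqlengths)) {
    if (nrow(agg) == 0L) {
      grid <- data.table(chrom = character(), bin_start = integer(),
                         end = integer())
    } else {
      grid <- agg[, .(bin_start = seq(0L, max(bin_start), by = bin_size)),
                  by = chrom]
      grid[, end := bin_start + as.integer(bin_size)]
    }
  } else {
    grid <- rbindlist(lapply(names(seqlengths), function(nm) {
      starts <- seq(0L, max(0L, seqlengths[[nm]] - 1L), by = bin_size)
      data.table(chrom = nm, bin_start = as.integer(starts),
                 end = as.integer(pmin(starts + bin_size, seqlengths[[nm]])))
    }))
  }
  out <- merge(grid, agg, by = c("chrom", "bin_start"), all.x = TRUE)
  out[is.na(n_sites), `:=`(n_sites = 0L, meth = 0, total = 0)]
  out[, level := fifelse(
    n_sites >= min_sites & total >= min_depth_per_bin & total > 0,
    meth / total, NA_real_)]
  setnames(out, c("bin_start", "total"), c("start", "total_depth"))
  res <- out[, .(chrom, start, end, level, n_sites, total_depth)]
  setorder(res, chrom, start)
  setattr(res, "bin_size", as.integer(bin_size))
  setattr(res, "context", context)
  setattr(res, "class", c("BinTrack", class(res)))
  res[]
}

#' Weighted methylation per annotation label
#'
#' Pools counts over all covered sites falling inside any interval of each
#' label (BED convention: 0-based half-open, so a 1-based site position `p`
#' is inside `[start, end)` when `start < p <= end`). A site under two labels
#' counts toward both; a site under two intervals of the same label counts
#' once. Labels with no covered site get `NA`.
#'
#' @inheritParams filter_context
#' @param annotations `data.table` with `chrom`, `start`, `end`, `label`.
#' @return A `data.table` with `label`, `level`, `n_sites`, `total_depth`.
#' @export
annotation_levels <- function(records, annotations, context = "CG") {
  ann <- as.data.table(annotations)
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(ann)))
  if (any(ann$start >= ann$end)) stop("annotation interval with start >= end")
  dt <- filter_context(records, context)
  dt <- dt[(count_meth + count_unmeth) > 0L]
  labels <- unique(ann$label)
  if (nrow(dt) == 0L) {
    return(data.table(label = labels, level = NA_real_,
                      n_sites = 0L, total_depth = 0))
  }
  sites <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
  iv <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start + 1L, ann$end))
  hits <- GenomicRanges::findOverlaps(sites, iv)
  hd <- data.table(site = S4Vectors::queryHits(hits),
                   label = ann$label[S4Vectors::subjectHits(hits)])
  hd <- unique(hd)  # one contribution per site x label
  hd[, `:=`(meth = as.numeric(dt$count_meth[site]),
            total = as.numeric(dt$count_meth[site] + dt$count_unmeth[site]))]
  agg <- hd[, .(level = sum(meth) / sum(total), n_sites = .N,
                total_depth = sum(total)), by = label]
  out <- merge(data.table(label = labels), agg, by = "label", all.x = TRUE)
  out[is.na(n_sites), `:=`(n_sites = 0L, total_depth = 0)]
  out[]
}

#' Per-site methylation fractions above a depth cutoff
#'
#' Used for single-CG analyses: only sites with total depth of at least
#' `min_depth` reads are retained (the default 16 corresponds to the usual
#' "depth > 15" filter).
#'
#' @param records cytosine record table.
#' @param min_depth minimum total read depth.
#' @return A `data.table` with `chrom`, `pos`, `strand`, `depth`, `level`.
#' @export
site_levels <- function(records, min_depth = 16L) {
  stopifnot(min_depth >= 0)
  dt <- as.data.table(records)
  validate_cytosine_records(dt)
  dt <- dt[(count_meth + count_unmeth) >= min_depth &
             (count_meth + count_unmeth) > 0L]
  dt[, .(chrom, pos, strand, depth = count_meth + count_unmeth,
         level = count_meth / (count_meth + count_unmeth))]
}

#' Frequency of bins across methylation-level intervals
#'
#' Histogram of non-missing bin levels over intervals of `bin_width_pct`
#' percentage points: `[k*w, (k+1)*w)`, top interval closed at 100.
#'
#' @param bins a [bin_levels()] `BinTrack`.
#' @param bin_width_pct interval width in percentage points; must divide 100.
#' @return A `data.table` with `lower`, `upper`, `count`.
#' @export
level_histogram <- function(bins, bin_width_pct = 10) {
  if (100 %% bin_width_pct != 0) stop("bin_width_pct must divide 100")
  lv <- 100 * bins$level[!is.na(bins$level)]
  k <- pmin(lv %/% bin_width_pct, 100 %/% bin_width_pct - 1)
  lower <- seq(0, 100 - bin_width_pct, by = bin_width_pct)
  data.table(lower = lower, upper = lower + bin_width_pct,
             count = as.integer(tabulate(k + 1, nbins = length(lower))))
}
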