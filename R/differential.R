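#' Compare two bin tracks and call differential bins
#'
#' Bins missing in either track are excluded from pairing. Per paired bin the
#' delta is `100 * (test - control)` percentage points; bins with delta at or
#' above the threshold are hyper, at or below the negated threshold hypo
#' (inclusive comparisons on both sides).
#'
#' @param bins_control,bins_test [bin_levels()] tracks on the same bin grid.
#' @param threshold_pct calling threshold in percentage points (20 is the
#'   usual CG threshold, 10 the CA one).
#' @return A `MethylomeComparison`: `data.table` of paired bins with
#'   `level_control`, `level_test`, `delta`, `status` in
#'   `hyper`/`hypo`/`none`; attributes `threshold_pct` and `bin_size`.
#' @export
compare_bins <- function(bins_control, bins_test, threshold_pct = 20) {
  stopifnot(threshold_pct > 0)
  bs_c <- attr(bins_control, "bin_size")
  bs_t <- attr(bins_test, "bin_size")
  if (!is.null(bs_c) && !is.null(bs_t) && bs_c != bs_t) {
    stop("bin grids differ: bin_size ", bs_c, " vs ", bs_t)
  }
  a <- as.data.table(bins_control)[, .(chrom, start, end, level)]
  b <- as.data.table(bins_test)[, .(chrom, start, end, level)]
  key_a <- paste(a$chrom, a$start, a$end)
  key_b <- paste(b$chrom, b$start, b$end)
  if (length(key_a) != length(key_b) || !setequal(key_a, key_b)) {
    stop("bin grids differ: tracks do not enumerate the same bins")
  }
  m <- merge(a, b, by = c("chrom", "start", "end"), suffixes = c("_control", "_test"))
  m <- m[!is.na(level_control) & !is.na(level_test)]
  m[, delta := 100 * (level_test - level_control)]
  m[, status := fifelse(delta >= threshold_pct, "hyper",
                        fifelse(delta <= -threshold_pct, "hypo", "none"))]
  setorder(m, chrom, start)
  setattr(m, "threshold_pct", threshold_pct)
  setattr(m, "bin_size", bs_c %||% bs_t)
  setattr(m, "class", c("MethylomeComparison", class(m)))
  m[]
}

#' @export
print.MethylomeComparison <- function(x, ...) {
  cat(sprintf(
    "MethylomeComparison: %d paired bins, threshold %.4g pp -> %d hyper, %d hypo\n",
    nrow(x), attr(x, "threshold_pct"),
    sum(x$status == "hyper"), sum(x$status == "hypo")))
  invisible(x)
}

#' Hyper/hypo bin sets of a comparison
#'
#' @param cmp a [compare_bins()] result.
#' @return A `data.table` of the bins with the requested status.
#' @export
hyper_bins <- function(cmp) {
  out <- as.data.table(cmp)[status == "hyper"]
  setattr(out, "bin_size", attr(cmp, "bin_size"))
  out
}

#' @rdname hyper_bins
#' @export
hypo_bins <- function(cmp) {
  out <- as.data.table(cmp)[status == "hypo"]
  setattr(out, "bin_size", attr(cmp, "bin_size"))
  out
}

.bin_ids <- function(x) {
  if (is.character(x)) return(x)
  dt <- as.data.table(x)
  stopifnot(all(c("chrom", "start") %in% names(dt)))
  paste0(dt$chrom, ":", dt$start)
}

#' Overlap statistics between two bin sets
#'
#' Venn-style counts over bins of the same grid, with the percentage of each
#' set covered by the intersection. Percentages over an empty set are
#' undefined (`NA`), never 0.
#'
#' @param set_a,set_b bin sets: `data.table`s with `chrom`/`start` (e.g.
#'   [hyper_bins()] output) or character bin-id vectors.
#' @return A list: `n_a`, `n_b`, `n_common`, `n_a_only`, `n_b_only`,
#'   `pct_a` (= 100 * common / n_a) and `pct_b`.
#' @export
bin_overlap <- function(set_a, set_b) {
  bs_a <- attr(set_a, "bin_size")
  bs_b <- attr(set_b, "bin_size")
  if (!is.null(bs_a) && !is.null(bs_b) && bs_a != bs_b) {
    stop("bin sets come from different grids (bin_size mismatch)")
  }
  a <- unique(.bin_ids(set_a))
  b <- unique(.bin_ids(set_b))
  common <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_common = common,
       n_a_only = length(a) - common, n_b_only = length(b) - common,
       pct_a = if (length(a)) 100 * common / length(a) else NA_real_,
       pct_b = if (length(b)) 100 * common / length(b) else NA_real_)
}

#' Group hyper bins into delta strata
#'
#' Strata are `[b_i, b_{i+1})` on the per-bin delta, the last stratum closed
#' at 100, so every bin with delta at or above the first break falls in
#' exactly one stratum.
#'
#' @param cmp a [compare_bins()] result.
#' @param breaks strictly increasing percentage-point breaks; defaults mirror
#'   the usual hypermethylation strata of 20-40, 40-60 and 60+ points.
#' @return A `data.table` of stratified bins with a `stratum` factor;
#'   attribute `breaks`.
#' @export
stratify_by_delta <- function(cmp, breaks = c(20, 40, 60)) {
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be strictly increasing")
  dt <- as.data.table(cmp)[delta >= breaks[1]]
  labs <- c(if (length(breaks) > 1L) {
    paste0("[", head(breaks, -1), ",", breaks[-1], ")")
  }, paste0("[", tail(breaks, 1), ",100]"))
  idx <- findInterval(dt$delta, breaks)
  dt[, stratum := factor(labs[idx], levels = labs)]
  setattr(dt, "breaks", breaks)
  setattr(dt, "bin_size", attr(cmp, "bin_size"))
  dt[]
}
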