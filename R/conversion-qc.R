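#' Estimate the bisulfite conversion rate from the spike-in contig
#'
#' Every cytosine of the unmethylated spike-in is truly unmethylated, so reads
#' still showing C measure conversion failure. All contexts are pooled:
#' `rate = sum(count_unmeth) / sum(count_meth + count_unmeth)` over spike-in
#' records, and the complementary apparent-methylation error is reported
#' alongside.
#'
#' @param records cytosine record table.
#' @param spike_in_name contig name of the unmethylated control.
#' @return A `ConversionEstimate` list: `rate`, `error_rate`,
#'   `n_cytosines_observed` (sites with depth >= 1), `total_depth`.
#' @export
estimate_conversion <- function(records, spike_in_name) {
  dt <- as.data.table(records)
  validate_cytosine_records(dt)
  sp <- dt[chrom == spike_in_name & (count_meth + count_unmeth) > 0L]
  if (nrow(sp) == 0L) {
    stop("conversion QC failed: no covered cytosines on spike-in contig '",
         spike_in_name, "'")
  }
  meth <- sum(as.numeric(sp$count_meth))
  unmeth <- sum(as.numeric(sp$count_unmeth))
  structure(list(
    rate = unmeth / (meth + unmeth),
    error_rate = meth / (meth + unmeth),
    n_cytosines_observed = nrow(sp),
    total_depth = meth + unmeth,
    spike_in_name = spike_in_name
  ), class = "ConversionEstimate")
}

#' @export
print.ConversionEstimate <- function(x, ...) {
  cat(sprintf(
    "Bisulfite conversion rate: %.4f (error %.4f) from %d cytosines, depth %d on %s\n",
    x$rate, x$error_rate, x$n_cytosines_observed, x$total_depth, x$spike_in_name))
  invisible(x)
}

#' Write a conversion estimate as a one-row TSV
#'
#' @param est a `ConversionEstimate`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conversion_tsv <- function(est, path) {
  stopifnot(inherits(est, "ConversionEstimate"))
  fwrite(data.table(spike_in = est$spike_in_name, conversion_rate = est$rate,
                    error_rate = est$error_rate,
                    n_cytosines = est$n_cytosines_observed,
                    total_depth = est$total_depth),
         path, sep = "\t")
  invisible(path)
}
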