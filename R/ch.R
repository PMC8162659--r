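#' Weighted CH methylation levels by sequence context
#'
#' Pools counts per CH context group, strand-resolved, excluding CG records.
#' Groupings:
#' \describe{
#'   \item{`dinucleotide`}{`CA`, `CT`, `CC` over all CH records (the usual
#'     per-dinucleotide summary).}
#'   \item{`trinucleotide`}{all CH trinucleotides (`CAA` .. `CTT`, including
#'     `CxG` ones), so dinucleotide levels are exactly the count-weighted
#'     averages of their constituent trinucleotides.}
#'   \item{`chh_trinucleotide`}{only CHH trinucleotides (third base not G).}
#' }
#'
#' @param records cytosine record table.
#' @param grouping one of the groupings above.
#' @return A `ContextLevelTable` `data.table`: `context`, `level`,
#'   `count_meth`, `total_depth`, `n_sites`.
#' @export
ch_levels <- function(records, grouping = c("dinucleotide", "trinucleotide",
                                            "chh_trinucleotide")) {
  grouping <- match.arg(grouping)
  dt <- as.data.table(records)
  validate_cytosine_records(dt)
  dt <- dt[context != "CG" & (count_meth + count_unmeth) > 0L]
  if (grouping == "chh_trinucleotide") dt <- dt[context == "CHH"]
  if (nrow(dt) == 0L) stop("no covered CH sites")
  grp <- if (grouping == "dinucleotide") {
    ch_dinucleotide(dt$trinucleotide)
  } else {
    dt$trinucleotide
  }
  out <- dt[, .(
    level = weighted_level(count_meth, count_unmeth),
    count_meth = sum(as.numeric(count_meth)),
    total_depth = sum(as.numeric(count_meth) + as.numeric(count_unmeth)),
    n_sites = .N
  ), by = .(context = grp)]
  setorder(out, context)
  out[]
}

#' Next-nucleotide preference of CH methylation
#'
#' The distribution over the base following methylated CH positions, weighted
#' by methylated read count, next to the all-read background distribution.
#' The following base is read 3' on the cytosine's own strand (the third base
#' of the trinucleotide); records whose following base is unresolved (`N`,
#' contig edges) are dropped. The preference shifts toward the methylating
#' enzyme's flanking signature — DNMT3A prefers C after the CH, DNMT3B
#' prefers G.
#'
#' @param records cytosine record table.
#' @param genome optional genome to resolve following bases for records whose
#'   trinucleotide carries `N`.
#' @return A `data.table` with `base`, `preference` (methylation-weighted,
#'   sums to 1) and `background` (total-read weighted, sums to 1).
#' @export
next_nucleotide_preference <- function(records, genome = NULL) {
  dt <- as.data.table(records)
  validate_cytosine_records(dt)
  dt <- dt[context != "CG" & (count_meth + count_unmeth) > 0L]
  if (nrow(dt) == 0L) stop("no covered CH sites")
  nb <- ch_next_base(dt$trinucleotide)
  if (!is.null(genome) && any(nb == "N")) {
    # re-read the unresolved following base from the genome
    seqs <- genome_sequences(genome)
    idx <- which(nb == "N")
    for (i in idx) {
      s <- seqs[[dt$chrom[i]]]
      if (is.null(s)) next
      p <- if (dt$strand[i] == "+") dt$pos[i] + 2L else dt$pos[i] - 2L
      if (p >= 1L && p <= nchar(s)) {
        b <- toupper(substr(s, p, p))
        nb[i] <- if (dt$strand[i] == "+") b else unname(.complement[b])
      }
    }
  }
  keep <- nb %in% c("A", "C", "G", "T")
  dt <- dt[keep]
  nb <- nb[keep]
  if (nrow(dt) == 0L) stop("no CH sites with a resolved following base")
  meth <- tapply(as.numeric(dt$count_meth), factor(nb, c("A", "C", "G", "T")),
                 sum, default = 0)
  tot <- tapply(as.numeric(dt$count_meth + dt$count_unmeth),
                factor(nb, c("A", "C", "G", "T")), sum, default = 0)
  data.table(base = c("A", "C", "G", "T"),
             preference = as.numeric(meth) / sum(meth),
             background = as.numeric(tot) / sum(tot))
}
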