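#' Construct a table of per-cytosine methylation records
#'
#' The atomic observation of the pipeline: one strand-resolved cytosine with
#' methylated/unmethylated read counts and its sequence context. Positions are
#' 1-based and always refer to the plus strand of the reference; a minus-strand
#' cytosine is reported at the position of the G it pairs with (the Bismark
#' cytosine-report convention). The trinucleotide is read on the cytosine's own
#' strand.
#'
#' @param chrom character contig names.
#' @param pos 1-based integer positions.
#' @param strand `"+"` or `"-"`.
#' @param count_meth,count_unmeth non-negative integer read counts.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param trinucleotide 3-mer starting with `C` on the cytosine's strand
#'   (may contain `N` near contig ends).
#' @return A `data.table` with one row per cytosine.
#' @export
cytosine_records <- function(chrom, pos, strand, count_meth, count_unmeth,
                             context, trinucleotide) {
  dt <- data.table(
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = as.character(strand),
    count_meth = as.integer(count_meth), count_unmeth = as.integer(count_unmeth),
    context = as.character(context), trinucleotide = as.character(trinucleotide)
  )
  validate_cytosine_records(dt)
  dt
}

#' @keywords internal
validate_cytosine_records <- function(dt) {
  stopifnot(is.data.frame(dt))
  need <- c("chrom", "pos", "strand", "count_meth", "count_unmeth",
            "context", "trinucleotide")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing record columns: ", paste(miss, collapse = ", "))
  if (any(dt$count_meth < 0, na.rm = TRUE) || any(dt$count_unmeth < 0, na.rm = TRUE)) {
    stop("negative read counts")
  }
  if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(dt)
}

#' Read a cytosine report
#'
#' Parses the tab-separated Bismark-style cytosine report dialect:
#' `chrom, pos (1-based), strand, count_meth, count_unmeth, context,
#' trinucleotide`, with no header. Gzipped files are read transparently.
#' Malformed lines raise an error naming the first offending line.
#'
#' @param path file path.
#' @return A `data.table` of cytosine records (empty for an empty file).
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- tryCatch(
    .fread_auto(path, header = FALSE, sep = "\t",
                colClasses = list(character = c(1, 3, 6, 7), integer = c(2, 4, 5))),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(dt) == 0L) {
    return(cytosine_records(character(), integer(), character(), integer(),
                            integer(), character(), character()))
  }
  if (ncol(dt) != 7L) {
    stop("cytosine report must have 7 columns, found ", ncol(dt), " in ", path)
  }
  setnames(dt, c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                 "context", "trinucleotide"))
  bad <- which(!(dt$strand %in% c("+", "-")))
  if (length(bad)) stop("invalid strand at line ", bad[1], " of ", path)
  bad <- which(is.na(dt$pos) | dt$pos < 1L)
  if (length(bad)) stop("invalid position at line ", bad[1], " of ", path)
  bad <- which(is.na(dt$count_meth) | is.na(dt$count_unmeth) |
                 dt$count_meth < 0L | dt$count_unmeth < 0L)
  if (length(bad)) stop("invalid counts at line ", bad[1], " of ", path)
  dt[]
}

#' Write a cytosine report
#'
#' Writes the seven canonical columns tab-separated without a header; a `.gz`
#' suffix triggers gzip compression.
#'
#' @param records cytosine record table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  validate_cytosine_records(records)
  cols <- c("chrom", "pos", "strand", "count_meth", "count_unmeth",
            "context", "trinucleotide")
  fwrite(as.data.table(records)[, cols, with = FALSE], path,
         sep = "\t", col.names = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# fread with transparent gzip via a base connection (no extra dependency)
.fread_auto <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    txt <- readLines(con)
    if (length(txt) == 0L) return(data.table())
    return(fread(text = txt, ...))
  }
  if (file.size(path) == 0L) return(data.table())
  fread(path, ...)
}

#' Classify every cytosine context in a genome
#'
#' Scans both strands and emits one zero-count record template per cytosine,
#' with its trinucleotide (on the cytosine's strand) and context: `CG` if the
#' next base is G, `CHG` if the base after next is G, otherwise `CHH`.
#' Cytosines whose trinucleotide runs off the contig end are classified from
#' the available bases (missing bases written as `N`) and flagged in the
#' `flagged` column. Sites whose own base is not A/C/G/T are skipped and the
#' skip count is attached as the `n_skipped` attribute.
#'
#' @param genome a [GenomeFixture], a named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @return A `data.table` of zero-count cytosine record templates with an
#'   extra logical `flagged` column.
#' @export
classify_contexts <- function(genome) {
  seqs <- genome_sequences(genome)
  out <- vector("list", 2L * length(seqs))
  n_skipped <- 0L
  for (i in seq_along(seqs)) {
    nm <- names(seqs)[i]
    ch <- strsplit(toupper(seqs[[i]]), "", fixed = TRUE)[[1]]
    L <- length(ch)
    # non-ACGT bases can never be called as cytosines; count them as skipped
    n_skipped <- n_skipped + sum(!(ch %in% c("A", "C", "G", "T")))

    # plus strand: every C; trinucleotide is the forward 3-mer
    p <- which(ch == "C")
    if (length(p)) {
      b2 <- ifelse(p + 1L <= L, ch[pmin(p + 1L, L)], "N")
      b3 <- ifelse(p + 2L <= L, ch[pmin(p + 2L, L)], "N")
      b2[!(b2 %in% names(.complement))] <- "N"
      b3[!(b3 %in% names(.complement))] <- "N"
      out[[2L * i - 1L]] <- data.table(
        chrom = nm, pos = p, strand = "+",
        trinucleotide = paste0("C", b2, b3),
        flagged = (p + 2L > L) | b2 == "N" | b3 == "N"
      )
    }
    # minus strand: every G on the plus strand is a C on the minus strand;
    # its trinucleotide reads 3' along the minus strand, i.e. the reverse
    # complement of the plus-strand bases at pos, pos-1, pos-2
    m <- which(ch == "G")
    if (length(m)) {
      b2 <- ifelse(m - 1L >= 1L, ch[pmax(m - 1L, 1L)], "N")
      b3 <- ifelse(m - 2L >= 1L, ch[pmax(m - 2L, 1L)], "N")
      b2[!(b2 %in% names(.complement))] <- "N"
      b3[!(b3 %in% names(.complement))] <- "N"
      out[[2L * i]] <- data.table(
        chrom = nm, pos = m, strand = "-",
        trinucleotide = paste0("C", unname(.complement[b2]), unname(.complement[b3])),
        flagged = (m - 2L < 1L) | b2 == "N" | b3 == "N"
      )
    }
  }
  dt <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(dt) == 0L) {
    dt <- data.table(chrom = character(), pos = integer(), strand = character(),
                     trinucleotide = character(), flagged = logical())
  }
  b2 <- substr(dt$trinucleotide, 2L, 2L)
  b3 <- substr(dt$trinucleotide, 3L, 3L)
  dt[, context := fifelse(b2 == "G", "CG", fifelse(b3 == "G", "CHG", "CHH"))]
  dt[, `:=`(count_meth = 0L, count_unmeth = 0L)]
  setcolorder(dt, c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                    "context", "trinucleotide", "flagged"))
  setorder(dt, chrom, pos, strand)
  setattr(dt, "n_skipped", n_skipped)
  dt[]
}

#' Dinucleotide and following base of CH records
#'
#' @param trinucleotide character 3-mers starting with `C`.
#' @return `ch_dinucleotide()`: `"CA"`, `"CT"`, `"CC"` (or `"CG"`, `"CN"`).
#'   `ch_next_base()`: the base following the CH dinucleotide on the
#'   cytosine's strand.
#' @export
ch_dinucleotide <- function(trinucleotide) {
  paste0("C", substr(trinucleotide, 2L, 2L))
}

#' @rdname ch_dinucleotide
#' @export
ch_next_base <- function(trinucleotide) {
  substr(trinucleotide, 3L, 3L)
}

#' Combine the two strands of each CpG site
#'
#' A plus-strand CG record at position p pairs with the minus-strand record at
#' p + 1; counts are summed and the merged record is keyed to the plus-strand
#' position. Unpaired CG records pass through unchanged, and non-CG records
#' are never merged. Two records at the same position and strand indicate a
#' double-counted input and raise an error.
#'
#' @param records cytosine record table.
#' @return A `data.table` with one record per CpG site (plus untouched
#'   non-CG records).
#' @export
merge_cg_strands <- function(records) {
  dt <- as.data.table(records)
  validate_cytosine_records(dt)
  cg <- dt[context == "CG"]
  if (anyDuplicated(cg, by = c("chrom", "pos", "strand"))) {
    d <- cg[duplicated(cg, by = c("chrom", "pos", "strand"))][1]
    stop("duplicate CG record at ", d$chrom, ":", d$pos, d$strand,
         "; inputs may be double-counted")
  }
  plus <- cg[strand == "+"]
  minus <- cg[strand == "-"]
  minus[, pos := pos - 1L]  # key to the plus-strand C of the CpG
  setkey(plus, chrom, pos)
  setkey(minus, chrom, pos)
  merged <- merge(plus, minus, by = c("chrom", "pos"), all = TRUE,
                  suffixes = c("", ".m"))
  res <- merged[, .(
    chrom, pos,
    strand = fifelse(is.na(strand), "-", "+"),
    count_meth = fifelse(is.na(count_meth), 0L, count_meth) +
      fifelse(is.na(count_meth.m), 0L, count_meth.m),
    count_unmeth = fifelse(is.na(count_unmeth), 0L, count_unmeth) +
      fifelse(is.na(count_unmeth.m), 0L, count_unmeth.m),
    context = "CG",
    trinucleotide = fifelse(is.na(trinucleotide), trinucleotide.m,
                            trinucleotide)
  )]
  # a lone minus-strand record keeps its own (un-shifted) position
  res[strand == "-", pos := pos + 1L]
  out <- rbind(res, dt[context != "CG"],
               use.names = TRUE, fill = FALSE)
  setorder(out, chrom, pos, strand)
  out[]
}

#' Read and write BED interval annotations
#'
#' BED intervals are 0-based, half-open; the fourth column is the label.
#'
#' @param path file path.
#' @return `read_bed()`: a `data.table` with `chrom`, `start`, `end`, `label`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- .fread_auto(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), label = character()))
  }
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns: ", path)
  if (ncol(dt) == 3L) dt[, V4 := "."]
  dt <- dt[, 1:4]
  setnames(dt, c("chrom", "start", "end", "label"))
  dt[, `:=`(start = as.integer(start), end = as.integer(end),
            chrom = as.character(chrom), label = as.character(label))]
  if (any(dt$start >= dt$end)) stop("BED interval with start >= end in ", path)
  dt[]
}

#' @rdname read_bed
#' @param intervals a `data.table` with `chrom`, `start`, `end`, `label`.
#' @export
write_bed <- function(intervals, path) {
  dt <- as.data.table(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(dt)))
  if (!"label" %in% names(dt)) dt[, label := "."]
  if (any(dt$start >= dt$end)) stop("interval with start >= end")
  fwrite(dt[, .(chrom, start, end, label)], path, sep = "\t",
         col.names = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Write a bedGraph track
#'
#' @param track a `data.table` with `chrom`, `start`, `end` and one value
#'   column named by `value_col`.
#' @param path output path.
#' @param value_col name of the value column.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value_col = "level") {
  dt <- as.data.table(track)
  stopifnot(all(c("chrom", "start", "end", value_col) %in% names(dt)))
  out <- dt[, c("chrom", "start", "end", value_col), with = FALSE]
  out <- out[!is.na(out[[value_col]])]
  fwrite(out, path, sep = "\t", col.names = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Extract plain character sequences from any supported genome representation
#' @keywords internal
genome_sequences <- function(genome) {
  if (inherits(genome, "GenomeFixture")) return(genome$contigs)
  if (inherits(genome, "DNAStringSet")) {
    s <- as.character(genome)
    if (is.null(names(s))) stop("unnamed sequences")
    return(s)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    s <- as.character(Biostrings::readDNAStringSet(genome))
    names(s) <- sub("\\s.*$", "", names(s))
    return(s)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("named character vector required")
    return(genome)
  }
  stop("unsupported genome representation")
}

#' Write genome sequences as FASTA
#'
#' @param genome a [GenomeFixture] or named character vector.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  seqs <- genome_sequences(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
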