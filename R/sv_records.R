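## SV record collections are plain data.frames with a fixed set of core
## columns; extra columns (ref/alt carried from a VCF, vaf from the
## simulator, supp from ensembles) ride along untouched.

SV_TYPES <- c("DEL", "DUP", "INS", "INV", "CNV", "BND")
SV_CORE_COLS <- c("id", "chrom", "pos", "end", "svtype",
                  "mate_id", "event", "filter_pass", "subset")

#' Construct a collection of structural-variant records
#'
#' Builds the canonical SV record table used throughout svbench. Each row
#' is one called or known SV with 1-based inclusive breakpoints (`pos`,
#' `end`), an SV type from the controlled vocabulary
#' `DEL, DUP, INS, INV, CNV, BND`, optional break-end mate linkage
#' (`mate_id`, `event`), a FILTER status, and a train/test subset label
#' assigned against masked regions by [assign_train_test()].
#'
#' @param id character vector of record identifiers.
#' @param chrom chromosome (contig) names.
#' @param pos,end 1-based inclusive start and end breakpoints; `end >=
#'   pos` is required for all non-BND records. Single-breakpoint events
#'   (insertions, unpaired break-ends) use `end == pos`.
#' @param svtype SV type, one of `DEL, DUP, INS, INV, CNV, BND`.
#' @param mate_id,event optional break-end mate id and event tag (`NA`
#'   when absent).
#' @param filter_pass logical; `FALSE` marks records that failed FILTER.
#' @param subset `"train"`, `"test"` or `"unassigned"`.
#' @param ... further equal-length columns carried along (e.g. `vaf`).
#' @return a `data.frame` with one row per SV.
#' @examples
#' sv_records(id = "d1", chrom = "chr1", pos = 1000, end = 5000,
#'            svtype = "DEL")
#' @export
sv_records <- function(id, chrom, pos, end, svtype,
                       mate_id = NA_character_, event = NA_character_,
                       filter_pass = TRUE, subset = "unassigned", ...) {
  n <- max(length(id), length(chrom), length(pos))
  if (length(id) == 0 || length(pos) == 0) n <- 0
  df <- data.frame(
    id = rep_len(as.character(id), n), chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.numeric(pos), n), end = rep_len(as.numeric(end), n),
    svtype = rep_len(as.character(svtype), n),
    mate_id = rep_len(as.character(mate_id), n),
    event = rep_len(as.character(event), n),
    filter_pass = rep_len(as.logical(filter_pass), n),
    subset = rep_len(as.character(subset), n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  validate_sv_records(df)
  df
}

validate_sv_records <- function(df) {
  stopifnot(is.data.frame(df), all(SV_CORE_COLS %in% names(df)))
  if (any(df$pos <= 0, na.rm = TRUE))
    stop("SV records must have positive 1-based POS coordinates")
  bad <- !df$svtype %in% c(SV_TYPES, "MSK")
  if (any(bad))
    stop("unknown SVTYPE: ", paste(unique(df$svtype[bad]), collapse = ", "))
  non_bnd <- df$svtype != "BND"
  if (any(df$end[non_bnd] < df$pos[non_bnd], na.rm = TRUE))
    stop("end < pos for a non-BND record")
  if (!all(df$subset %in% c("train", "test", "unassigned")))
    stop("subset must be train/test/unassigned")
  invisible(df)
}

empty_sv_records <- function() {
  sv_records(id = character(), chrom = character(), pos = numeric(),
             end = numeric(), svtype = character())
}

#' Construct a set of masked (held-out) genomic regions
#'
#' Mask regions mark the portion of the genome whose overlapping truth
#' SVs form the held-out testing set. Inside truth VCFs they are encoded
#' as `SVTYPE=MSK` rows; they may also be supplied as a BED file (0-based
#' half-open, converted here to 1-based inclusive).
#'
#' @param chrom,start,end equal-length vectors of 1-based inclusive
#'   intervals. Regions may overlap; overlap fractions are always
#'   computed against their union.
#' @return a `data.frame` with columns `chrom`, `start`, `end`.
#' @export
mask_set <- function(chrom = character(), start = numeric(),
                     end = numeric()) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("mask region with start > end")
  df
}

#' Read mask regions from a BED file
#'
#' @param path BED file (0-based, half-open intervals).
#' @return a mask `data.frame` in 1-based inclusive coordinates.
#' @export
read_mask_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  mask_set(chrom = bed[[1]], start = bed[[2]] + 1, end = bed[[3]])
}

## union of mask intervals on one chromosome as an IRanges
mask_ranges <- function(masks, chrom) {
  m <- masks[masks$chrom == chrom, , drop = FALSE]
  IRanges::reduce(IRanges::IRanges(start = m$start, end = m$end))
}
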