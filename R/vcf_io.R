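## VCF v4.1 input/output for SV records. Reading goes through
## vcfR::read.vcfR; a light pre-scan reports malformed data rows with
## their line numbers, which vcfR does not. Writing is a small text
## formatter emitting the INFO keys this model round-trips
## (SVTYPE, END, MATEID, EVENT, plus VAF/SUPP when present).

#' Parse structural variants from a VCF v4.1 file
#'
#' Reads a VCF of called or known SVs into the svbench record table.
#' `END` is resolved in this order: the INFO `END` value, then
#' `POS + nchar(REF) - 1`, then `POS` itself. Rows with `SVTYPE=MSK`
#' describe masked (held-out) regions and are routed to the returned
#' mask set instead of the record table. Records whose FILTER value is
#' neither `PASS` nor `.` are kept but flagged `filter_pass = FALSE`
#' (removed later by [preprocess_vcf()]).
#'
#' @param path a VCF v4.1 file. SV entries may be typed (`SVTYPE=DEL`,
#'   symbolic ALTs) or break-end style (`SVTYPE=BND` with bracket ALTs
#'   and `MATEID`).
#' @return a list with `records` (SV record `data.frame`, including
#'   `ref`/`alt` columns used by BND conversion) and `masks` (a mask
#'   `data.frame`, see [mask_set()]).
#' @seealso [preprocess_vcf()], [write_sv_vcf()]
#' @export
parse_sv_vcf <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8)) {
    bad <- which(body)[which(nf < 8)[1]]
    stop("malformed VCF row at line ", bad, ": fewer than 8 fields")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0)
    return(list(records = empty_sv_records(), masks = mask_set()))

  pos <- as.numeric(fix[, "POS"])
  if (any(is.na(pos) | pos <= 0))
    stop("non-positive or missing POS in VCF: ", path)
  info <- vcf@fix[, "INFO"]
  svtype <- info_field(info, "SVTYPE")
  end <- suppressWarnings(as.numeric(info_field(info, "END")))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  ## symbolic ALT (<DEL> etc.) supplies the type when INFO lacks SVTYPE;
  ## bracket ALTs imply break-ends
  sym <- regmatches(alt, regexec("^<([A-Za-z]+)>$", alt))
  sym <- vapply(sym, function(m) if (length(m)) m[2] else NA_character_, "")
  svtype <- ifelse(is.na(svtype), sym, svtype)
  svtype <- ifelse(is.na(svtype) & grepl("[][]", alt), "BND", svtype)
  no_end <- is.na(end)
  end[no_end] <- pos[no_end] + nchar(ref[no_end]) - 1
  filt <- fix[, "FILTER"]
  filter_pass <- is.na(filt) | filt %in% c("PASS", ".")
  id <- fix[, "ID"]
  id[is.na(id)] <- "."

  df <- data.frame(
    id = id, chrom = fix[, "CHROM"], pos = pos, end = end,
    svtype = svtype,
    mate_id = info_field(info, "MATEID"),
    event = info_field(info, "EVENT"),
    filter_pass = filter_pass,
    subset = "unassigned",
    ref = ref, alt = alt,
    stringsAsFactors = FALSE
  )
  vaf <- suppressWarnings(as.numeric(info_field(info, "VAF")))
  if (any(!is.na(vaf))) df$vaf <- vaf
  is_msk <- !is.na(df$svtype) & df$svtype == "MSK"
  masks <- mask_set(chrom = df$chrom[is_msk], start = df$pos[is_msk],
                    end = df$end[is_msk])
  list(records = df[!is_msk, , drop = FALSE], masks = masks)
}

## pull one INFO key out of raw INFO strings
info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x)) x[2] else NA_character_, "")
}

#' Write structural-variant records to a VCF v4.1 file
#'
#' Emits a minimal VCF carrying `SVTYPE`, `END`, and when present
#' `MATEID`, `EVENT`, `VAF` and `SUPP` in INFO. Mask regions are written
#' as `SVTYPE=MSK` rows, the convention used to mark held-out testing
#' regions inside a truth VCF. [parse_sv_vcf()] round-trips the output.
#'
#' @param records SV record `data.frame`.
#' @param path output file.
#' @param masks optional mask `data.frame` appended as MSK rows.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, path, masks = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"ID of associated event\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=SUPP,Number=1,Type=Integer,Description=\"Number of supporting submissions\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  fmt_row <- function(chrom, pos, id, ref, alt, filter, info)
    paste(chrom, format(pos, scientific = FALSE, trim = TRUE), id, ref,
          alt, ".", filter, info, sep = "\t")
  rows <- character(0)
  if (nrow(records)) {
    info <- paste0("SVTYPE=", records$svtype, ";END=",
                   format(records$end, scientific = FALSE, trim = TRUE))
    opt <- function(col, key) {
      v <- records[[col]]
      if (is.null(v)) return("")
      ifelse(is.na(v), "", paste0(";", key, "=", v))
    }
    info <- paste0(info, opt("mate_id", "MATEID"), opt("event", "EVENT"),
                   opt("vaf", "VAF"), opt("supp", "SUPP"))
    ref <- if (!is.null(records$ref)) ifelse(is.na(records$ref), "N", records$ref) else rep("N", nrow(records))
    alt <- if (!is.null(records$alt)) records$alt else rep(NA_character_, nrow(records))
    alt <- ifelse(is.na(alt), paste0("<", records$svtype, ">"), alt)
    filter <- ifelse(records$filter_pass, "PASS", "FAIL")
    rows <- fmt_row(records$chrom, records$pos, records$id, ref, alt,
                    filter, info)
  }
  if (!is.null(masks) && nrow(masks)) {
    minfo <- paste0("SVTYPE=MSK;END=",
                    format(masks$end, scientific = FALSE, trim = TRUE))
    rows <- c(rows, fmt_row(masks$chrom, masks$start,
                            paste0("msk_", seq_len(nrow(masks))), "N",
                            "<MSK>", "PASS", minfo))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## decompose a break-end ALT like A[chr2:321682[ into its parts;
## returns NULL when the ALT is not breakend-shaped
parse_bnd_alt <- function(alt) {
  m <- regexec("^([A-Za-z.]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([A-Za-z.]*)$",
               alt, perl = TRUE)
  g <- regmatches(alt, m)[[1]]
  if (!length(g) || g[3] != g[6]) return(NULL)
  list(t_first = nzchar(g[2]), bracket = g[3],
       chrom = g[4], pos = as.numeric(g[5]))
}
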