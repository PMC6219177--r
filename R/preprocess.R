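## Challenge-style VCF preprocessing: filter-failing rows dropped,
## break-end mate pairs completed and sanity-checked, IDs reassigned to
## be unambiguous, and canonical same-chromosome BND pairs rewritten as
## typed DEL/DUP/INV records.

#' Normalize a parsed SV record collection
#'
#' Applies the preprocessing a call set receives before scoring:
#'
#' 1. records that failed FILTER are removed;
#' 2. records whose `SVTYPE` is outside `DEL, DUP, INS, INV, CNV, BND`
#'    are dropped with a warning (invalid types are excluded rather than
#'    coerced, keeping downstream scoring type-blind);
#' 3. every `MATEID` reference is made to resolve to exactly one
#'    partner: missing partners are synthesized from the break-end ALT
#'    of the surviving mate;
#' 4. IDs and MATEIDs are reassigned so references are unambiguous;
#' 5. same-chromosome BND mate pairs whose ALT adjacency geometry
#'    matches a canonical deletion, tandem duplication or inversion are
#'    rewritten as one typed record spanning `[min(pos), max(pos)]`;
#'    all other break-ends are retained as BND.
#'
#' @param records SV record `data.frame` as returned by
#'   [parse_sv_vcf()] (an `alt` column is needed to synthesize mates and
#'   convert break-ends; without it those steps are skipped for records
#'   lacking it).
#' @return the normalized SV record `data.frame`.
#' @export
preprocess_vcf <- function(records) {
  df <- records[records$filter_pass, , drop = FALSE]
  bad <- !df$svtype %in% SV_TYPES
  if (any(bad)) {
    warning("excluding ", sum(bad), " record(s) with invalid SVTYPE: ",
            paste(unique(df$svtype[bad]), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  if (is.null(df$alt)) df$alt <- NA_character_
  if (is.null(df$ref)) df$ref <- NA_character_
  rownames(df) <- NULL

  ## -- complete mate pairs ------------------------------------------------
  has_mate <- !is.na(df$mate_id)
  missing <- has_mate & !(df$mate_id %in% df$id)
  if (any(missing)) {
    for (i in which(missing)) {
      adj <- parse_bnd_alt(df$alt[i])
      if (is.null(adj))
        stop("record ", df$id[i], " references absent mate ", df$mate_id[i],
             " and its ALT is not a break-end; cannot synthesize the pair")
      partner <- df[i, , drop = FALSE]
      partner$id <- df$mate_id[i]
      partner$mate_id <- df$id[i]
      partner$chrom <- adj$chrom
      partner$pos <- partner$end <- adj$pos
      partner$svtype <- "BND"
      partner$ref <- "N"
      partner$alt <- reciprocal_bnd_alt(adj, df$chrom[i], df$pos[i])
      df <- rbind(df, partner)
    }
    rownames(df) <- NULL
  }

  ## -- referential sanity -------------------------------------------------
  has_mate <- !is.na(df$mate_id)
  if (any(duplicated(df$id[has_mate | df$id %in% df$mate_id])))
    stop("duplicate IDs among mated records: MATEID references are ambiguous")
  idx_of <- match(df$mate_id, df$id)
  for (i in which(has_mate)) {
    j <- idx_of[i]
    back <- df$mate_id[j]
    if (is.na(back) || back != df$id[i])
      stop("MATEID chain longer than a mutual pair at record ", df$id[i])
    if (df$chrom[j] != df$chrom[i] && df$svtype[i] != "BND")
      stop("record ", df$id[i], " has SVTYPE ", df$svtype[i],
           " but a mate on a different chromosome")
  }

  ## -- reassign IDs -------------------------------------------------------
  new_id <- sprintf("sv_%d", seq_len(nrow(df)))
  df$mate_id <- ifelse(has_mate, new_id[idx_of], NA_character_)
  df$id <- new_id

  ## -- canonical BND pair -> typed record --------------------------------
  df <- convert_bnd_pairs(df)
  rownames(df) <- NULL
  df
}

reciprocal_bnd_alt <- function(adj, back_chrom, back_pos) {
  loc <- paste0(back_chrom, ":", format(back_pos, scientific = FALSE))
  if (adj$t_first && adj$bracket == "[") paste0("]", loc, "]N")
  else if (!adj$t_first && adj$bracket == "]") paste0("N[", loc, "[")
  else if (adj$t_first && adj$bracket == "]") paste0("N]", loc, "]")
  else paste0("[", loc, "[N")
}

## classify a same-chromosome BND mate pair from its two ALT geometries;
## left = lower-coordinate mate. Canonical adjacencies:
##   DEL  t[p[  /  ]p]t     (left joins forward to the right, spanned
##                           interval lost)
##   DUP  ]p]t  /  t[p[     (head-to-tail join back, tandem duplication)
##   INV  t]p]  /  t]p]  or  [p[t / [p[t
classify_bnd_pair <- function(left_alt, right_alt) {
  a <- parse_bnd_alt(left_alt); b <- parse_bnd_alt(right_alt)
  if (is.null(a) || is.null(b)) return(NA_character_)
  if (a$t_first && a$bracket == "[" && !b$t_first && b$bracket == "]")
    return("DEL")
  if (!a$t_first && a$bracket == "]" && b$t_first && b$bracket == "[")
    return("DUP")
  if ((a$t_first && a$bracket == "]" && b$t_first && b$bracket == "]") ||
      (!a$t_first && a$bracket == "[" && !b$t_first && b$bracket == "["))
    return("INV")
  NA_character_
}

convert_bnd_pairs <- function(df) {
  is_bnd <- df$svtype == "BND" & !is.na(df$mate_id)
  done <- rep(FALSE, nrow(df))
  drop <- rep(FALSE, nrow(df))
  for (i in which(is_bnd)) {
    if (done[i]) next
    j <- match(df$mate_id[i], df$id)
    done[c(i, j)] <- TRUE
    if (df$chrom[i] != df$chrom[j]) next
    lo <- if (df$pos[i] <= df$pos[j]) i else j
    hi <- if (lo == i) j else i
    type <- classify_bnd_pair(df$alt[lo], df$alt[hi])
    if (is.na(type)) next
    df$svtype[lo] <- type
    df$pos[lo] <- min(df$pos[i], df$pos[j])
    df$end[lo] <- max(df$pos[i], df$pos[j])
    df$mate_id[lo] <- NA_character_
    df$alt[lo] <- NA_character_
    drop[hi] <- TRUE
  }
  df[!drop, , drop = FALSE]
}

#' Allocate SVs to the training or testing set by mask overlap
#'
#' An SV whose region `[pos, end]` overlaps the union of masked regions
#' by at least 50% of its length is allocated to the testing set;
#' otherwise it belongs to the training set. The rule is evaluated on
#' the union of masks, so overlapping or abutting mask pieces are never
#' double counted.
#'
#' @param records SV record `data.frame`.
#' @param masks mask `data.frame` (see [mask_set()]).
#' @return `records` with the `subset` column set to `"train"`/`"test"`.
#' @export
assign_train_test <- function(records, masks) {
  records$subset <- "train"
  if (!nrow(records)) return(records)
  for (chr in unique(records$chrom)) {
    sel <- which(records$chrom == chr)
    mr <- mask_ranges(masks, chr)
    if (!length(mr)) next
    ## masks are reduced (disjoint), so clipping them to the SV interval
    ## and summing widths gives the union overlap without double counting
    covered <- vapply(sel, function(k) {
      sum(IRanges::width(IRanges::restrict(mr, start = records$pos[k],
                                           end = records$end[k])))
    }, numeric(1))
    frac <- covered / (records$end[sel] - records$pos[sel] + 1)
    records$subset[sel][frac >= 0.5] <- "test"
  }
  records
}
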