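# isomiR classification: anchor reads on their precursor around the canonical
# mature position, then classify end variation and internal changes into the
# taxonomy canonical / 5p|3p templated / 5p|3p non-templated / polymorphic /
# mixed 5p+3p.

ISOMIR_CATEGORIES <- c("canonical", "5p_templated", "3p_templated",
                       "5p_nontemplated", "3p_nontemplated", "polymorphic",
                       "mixed_5p3p")

#' Anchor a read on its precursor
#'
#' Slides the read over the precursor at start offsets within `max_shift` nt
#' of the canonical mature start and picks the offset minimizing mismatches;
#' ties break by smallest absolute shift from the canonical start, then
#' 5'-ward. Returns `NULL` when the best offset still has more than
#' `max_mismatch` mismatches, or the read cannot be placed.
#'
#' @param read read sequence (RNA).
#' @param hairpin precursor sequence (RNA).
#' @param mature_start 0-based canonical mature start on the precursor.
#' @param max_shift maximum shift from the canonical start (nt).
#' @param max_mismatch maximum mismatches tolerated.
#' @return list with `start` (0-based read start on the precursor) and
#'   `mismatch_read_pos` (1-based mismatch positions within the read), or
#'   `NULL`.
#' @export
anchor_read <- function(read, hairpin, mature_start, max_shift = 5L,
                        max_mismatch = 2L) {
  L <- nchar(read)
  H <- nchar(hairpin)
  if (L > H) return(NULL)
  rv <- strsplit(read, "")[[1]]
  hv <- strsplit(hairpin, "")[[1]]
  starts <- (mature_start - max_shift):(mature_start + max_shift)
  starts <- starts[starts >= 0 & starts + L <= H]
  if (!length(starts)) return(NULL)
  mm <- lapply(starts, function(s) which(hv[(s + 1):(s + L)] != rv))
  nmm <- vapply(mm, length, integer(1))
  o <- order(nmm, abs(starts - mature_start), starts)
  best <- o[1]
  if (nmm[best] > max_mismatch) return(NULL)
  list(start = starts[best], mismatch_read_pos = mm[[best]])
}

#' Classify a read against its canonical mature
#'
#' Decision cascade after anchoring: (1) a mismatch inside the region the
#' read shares with the canonical mature makes it `polymorphic`; (2) else
#' modifications at both ends make it `mixed_5p3p`; (3) else a single-end
#' extension whose extra bases all match the flanking precursor sequence, or
#' any single-end trimming, is `5p_templated`/`3p_templated`; (4) else a
#' single-end extension carrying a non-matching extra base is
#' `5p_nontemplated`/`3p_nontemplated`; (5) else `canonical`. A removal can
#' never introduce foreign bases, so trimming is always templated.
#' A->G changes at internal positions are flagged as potential A-to-I
#' editing signatures but remain `polymorphic`.
#'
#' @param read read sequence (RNA).
#' @param hairpin precursor sequence (RNA).
#' @param mature_start,mature_end canonical mature interval on the precursor,
#'   0-based half-open.
#' @param max_shift,max_mismatch anchoring tolerances (see [anchor_read()]).
#' @return list of class `isomir_call`: `category`, `offset5` (negative =
#'   5' extension, positive = 5' trimming), `offset3` (positive = 3'
#'   extension, negative = 3' trimming), `mismatch_positions` (1-based, on
#'   the read), `editing_ag` (logical).
#' @export
classify_isomir <- function(read, hairpin, mature_start, mature_end,
                            max_shift = 5L, max_mismatch = 2L) {
  anc <- anchor_read(read, hairpin, mature_start, max_shift, max_mismatch)
  if (is.null(anc)) {
    return(structure(list(category = "unassigned", offset5 = NA_integer_,
                          offset3 = NA_integer_,
                          mismatch_positions = integer(0),
                          editing_ag = FALSE),
                     class = "isomir_call"))
  }
  s <- anc$start
  L <- nchar(read)
  offset5 <- s - mature_start
  offset3 <- (s + L) - mature_end
  mm <- anc$mismatch_read_pos
  # read position p sits on hairpin 1-based position s + p
  core <- mm[(s + mm) >= (mature_start + 1) & (s + mm) <= mature_end]
  editing <- FALSE
  if (length(core)) {
    hv <- strsplit(hairpin, "")[[1]]
    rv <- strsplit(read, "")[[1]]
    editing <- any(hv[s + core] == "A" & rv[core] == "G")
    category <- "polymorphic"
  } else if (offset5 != 0 && offset3 != 0) {
    category <- "mixed_5p3p"
  } else if (offset5 != 0) {
    if (offset5 > 0) {
      category <- "5p_templated"
    } else {
      ext <- seq_len(-offset5)           # read positions upstream of canonical
      category <- if (any(mm %in% ext)) "5p_nontemplated" else "5p_templated"
    }
  } else if (offset3 != 0) {
    if (offset3 < 0) {
      category <- "3p_templated"
    } else {
      ext <- (L - offset3 + 1):L          # read positions past canonical end
      category <- if (any(mm %in% ext)) "3p_nontemplated" else "3p_templated"
    }
  } else {
    category <- if (length(mm)) "polymorphic" else "canonical"
  }
  structure(list(category = category, offset5 = as.integer(offset5),
                 offset3 = as.integer(offset3),
                 mismatch_positions = as.integer(mm),
                 editing_ag = editing),
            class = "isomir_call")
}

#' Classify a read stack against its candidates
#'
#' For each read, tries every mature arm its precursor encodes and keeps the
#' call with the fewest mismatches, then the smallest total end offset, then
#' the 5p arm.
#'
#' @param reads data.frame with columns `read_seq`, `count`, `precursor_id`
#'   and optionally `sample`.
#' @param candidates candidate data.frame.
#' @param max_shift,max_mismatch anchoring tolerances.
#' @return `reads` with added columns `arm`, `category`, `offset5`,
#'   `offset3`, `editing_ag`.
#' @export
classify_reads <- function(reads, candidates, max_shift = 5L,
                           max_mismatch = 2L) {
  cand <- candidates[match(reads$precursor_id, candidates$id), , drop = FALSE]
  if (any(is.na(cand$id)))
    stop("read assigned to unknown precursor: ",
         reads$precursor_id[is.na(cand$id)][1])
  n <- nrow(reads)
  arm <- character(n); category <- character(n)
  off5 <- integer(n); off3 <- integer(n); edit <- logical(n)
  # memoise identical (read, precursor) pairs: stacks repeat reads rarely but
  # the same variant sequence recurs across samples
  key <- paste(reads$read_seq, reads$precursor_id, sep = "\r")
  first <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (i in which(first)) {
    calls <- list()
    for (a in c("5p", "3p")) {
      sq <- cand[[paste0("mature", a, "_seq")]][i]
      if (is.na(sq)) next
      ms <- cand[[paste0("mature", a, "_offset")]][i]
      cl <- classify_isomir(reads$read_seq[i], cand$hairpin_seq[i],
                            ms, ms + nchar(sq), max_shift, max_mismatch)
      calls[[a]] <- cl
    }
    pick <- if (length(calls) == 1) names(calls) else {
      score <- vapply(names(calls), function(a) {
        cl <- calls[[a]]
        if (cl$category == "unassigned") Inf
        else length(cl$mismatch_positions) * 100 +
          abs(cl$offset5) + abs(cl$offset3)
      }, numeric(1))
      names(calls)[order(score, names(calls) != "5p")][1]
    }
    assign(key[i], list(arm = pick, call = calls[[pick]]), envir = cache)
  }
  for (i in seq_len(n)) {
    hit <- get(key[i], envir = cache)
    cl <- hit$call
    arm[i] <- if (cl$category == "unassigned") NA_character_ else hit$arm
    category[i] <- cl$category
    off5[i] <- cl$offset5; off3[i] <- cl$offset3; edit[i] <- cl$editing_ag
  }
  reads$arm <- arm
  reads$category <- category
  reads$offset5 <- off5
  reads$offset3 <- off3
  reads$editing_ag <- edit
  reads
}

#' Read-weighted isomiR category distribution
#'
#' Fractions are weighted by read count over assigned categories; unassigned
#' reads are excluded from the denominator and reported separately.
#'
#' @param calls data.frame with columns `category`, `count` and optionally
#'   `sample`.
#' @param tissue_of optional named character vector sample -> tissue enabling
#'   per-tissue strata.
#' @return list: `overall` (named fractions over assigned categories),
#'   `per_tissue` (matrix tissues x categories, or `NULL`),
#'   `unassigned_fraction` (share of all reads left unassigned).
#' @export
isomir_distribution <- function(calls, tissue_of = NULL) {
  stopifnot(all(calls$count >= 1))
  assigned <- calls[calls$category != "unassigned", , drop = FALSE]
  lev <- ISOMIR_CATEGORIES
  frac <- function(df) {
    w <- tapply(df$count, factor(df$category, levels = lev), sum,
                default = 0)
    if (sum(w) == 0) return(stats::setNames(rep(0, length(lev)), lev))
    w / sum(w)
  }
  per_tissue <- NULL
  if (!is.null(tissue_of) && "sample" %in% names(calls)) {
    tis <- unname(tissue_of[assigned$sample])
    per_tissue <- t(vapply(split(assigned, tis), frac,
                           numeric(length(lev))))
    colnames(per_tissue) <- lev
  }
  list(
    overall = frac(assigned),
    per_tissue = per_tissue,
    unassigned_fraction = 1 - sum(assigned$count) / sum(calls$count)
  )
}
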