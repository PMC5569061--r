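# Post-processing filters that reduce the raw discovery candidate list to the
# final precursor set: score threshold by signal-to-noise against a
# permuted-genome control, structural-RNA screen, repetitive-locus screen,
# and a minimum-expression rule.

#' Score bins for signal-to-noise threshold selection
#'
#' @param thresholds ascending numeric score cut-offs.
#' @param n_signal number of real candidates with score >= each threshold.
#' @param n_control number of permuted-control candidates with score >= each
#'   threshold.
#' @return data.frame of class `score_bins`.
#' @export
score_bins <- function(thresholds, n_signal, n_control) {
  stopifnot(length(thresholds) == length(n_signal),
            length(thresholds) == length(n_control),
            length(thresholds) >= 1)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  if (any(diff(n_signal) > 0) || any(diff(n_control) > 0))
    stop("cumulative counts must be non-increasing in the threshold")
  if (any(n_signal < 0) || any(n_control < 0)) stop("negative counts")
  structure(
    data.frame(threshold = thresholds, n_signal = n_signal,
               n_control = n_control),
    class = c("score_bins", "data.frame")
  )
}

#' Build score bins from raw score vectors
#'
#' Counts, at each threshold, the real and control candidates whose score is
#' greater than or equal to it.
#'
#' @param signal_scores scores of the real candidates.
#' @param control_scores scores of the permuted-genome control candidates.
#' @param thresholds candidate cut-offs to evaluate (default `0:10`).
#' @return `score_bins` data.frame.
#' @export
score_bins_from_scores <- function(signal_scores, control_scores,
                                   thresholds = 0:10) {
  n_sig <- vapply(thresholds, function(t) sum(signal_scores >= t), numeric(1))
  n_ctl <- vapply(thresholds, function(t) sum(control_scores >= t), numeric(1))
  score_bins(thresholds, n_sig, n_ctl)
}

#' Select the score threshold by signal-to-noise ratio
#'
#' Returns the smallest threshold whose signal-to-noise ratio
#' (real candidates at or above the threshold divided by control candidates at
#' or above it) strictly exceeds `min_snr`. The ratio is `+Inf` when the
#' control count is zero but the signal count positive.
#'
#' @param bins `score_bins` data.frame.
#' @param min_snr required ratio (default 10, i.e. 10:1).
#' @return the selected threshold, with attribute `snr` giving the ratio
#'   achieved there.
#' @export
select_score_threshold <- function(bins, min_snr = 10) {
  stopifnot(nrow(bins) >= 1, min_snr > 0)
  snr <- ifelse(bins$n_control == 0,
                ifelse(bins$n_signal > 0, Inf, NaN),
                bins$n_signal / bins$n_control)
  ok <- which(!is.nan(snr) & snr > min_snr)
  if (!length(ok)) stop("no admissible threshold")
  i <- ok[1]
  structure(bins$threshold[i], snr = snr[i])
}

is_structural_rna <- function(subject_id) {
  grepl("^(rRNA|tRNA|snRNA|snoRNA|scaRNA)", subject_id, ignore.case = TRUE)
}

# Count distinct chromosomal areas among genome hits: merge overlapping
# subject intervals per subject sequence, then count merged intervals.
count_distinct_loci <- function(hits) {
  if (nrow(hits) == 0) return(0L)
  lo <- pmin(hits$s_start, hits$s_end)
  hi <- pmax(hits$s_start, hits$s_end)
  total <- 0L
  for (sj in unique(hits$subject_id)) {
    sel <- hits$subject_id == sj
    o <- order(lo[sel])
    a <- lo[sel][o]; b <- hi[sel][o]
    n <- 1L
    cur_end <- b[1]
    for (k in seq_along(a)[-1]) {
      if (a[k] > cur_end) {
        n <- n + 1L
        cur_end <- b[k]
      } else {
        cur_end <- max(cur_end, b[k])
      }
    }
    total <- total + n
  }
  total
}

#' Apply the post-processing filter cascade
#'
#' Rejects each candidate for at most one reason, tested in a fixed order:
#' `low_score` (score below `min_score`), `other_rna` (a hit against an
#' rRNA/tRNA/sn(o)RNA subject at E-value <= `recovery_max_evalue`),
#' `repetitive` (more than `max_genome_hits` distinct genomic loci with
#' E-value < `genome_hit_evalue`), `low_expression` (no mature of the
#' candidate reaches `min_count` reads in any single sample).
#'
#' @param candidates candidate data.frame (see [read_candidates()]).
#' @param counts mature x sample integer count matrix; matures are rows named
#'   `<precursor>-5p` / `<precursor>-3p`; absent matures count as zero.
#' @param genome_hits hit table of candidates vs the genome.
#' @param ncrna_hits hit table of candidates vs structural-RNA collections
#'   (subject ids prefixed with their RNA class, e.g. `rRNA_...`).
#' @param params [pipeline_params()].
#' @return list of class `filter_report`: `kept` (character vector of ids) and
#'   `rejected` (named character vector id -> reason).
#' @export
apply_filters <- function(candidates, counts, genome_hits, ncrna_hits,
                          params = pipeline_params()) {
  kept <- character()
  rejected <- character()
  matures <- if (nrow(candidates)) mature_table(candidates) else NULL
  for (i in seq_len(nrow(candidates))) {
    id <- candidates$id[i]
    reason <- NA_character_
    if (candidates$score[i] < params$min_score) {
      reason <- "low_score"
    } else {
      nc <- ncrna_hits[ncrna_hits$query_id == id &
                         ncrna_hits$evalue <= params$recovery_max_evalue &
                         is_structural_rna(ncrna_hits$subject_id), ,
                       drop = FALSE]
      if (nrow(nc) > 0) {
        reason <- "other_rna"
      } else {
        gh <- genome_hits[genome_hits$query_id == id &
                            genome_hits$evalue < params$genome_hit_evalue, ,
                          drop = FALSE]
        if (count_distinct_loci(gh) > params$max_genome_hits) {
          reason <- "repetitive"
        } else {
          mids <- matures$mature_id[matures$precursor_id == id]
          mids <- intersect(mids, rownames(counts))
          mx <- if (length(mids)) max(counts[mids, , drop = FALSE]) else 0L
          if (mx < params$min_count) reason <- "low_expression"
        }
      }
    }
    if (is.na(reason)) kept <- c(kept, id)
    else rejected[id] <- reason
  }
  structure(list(kept = kept, rejected = rejected), class = "filter_report")
}

#' Filter report as a data.frame
#' @param x `filter_report`.
#' @param ... unused.
#' @return data.frame with columns `id`, `status` (`kept`/`rejected`),
#'   `reason`.
#' @export
as.data.frame.filter_report <- function(x, ...) {
  rbind(
    data.frame(id = x$kept,
               status = rep("kept", length(x$kept)),
               reason = rep(NA_character_, length(x$kept)),
               stringsAsFactors = FALSE),
    data.frame(id = names(x$rejected),
               status = rep("rejected", length(x$rejected)),
               reason = unname(x$rejected), stringsAsFactors = FALSE)
  )
}
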