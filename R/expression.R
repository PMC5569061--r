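# Per-tissue expression summarization, 5p/3p arm dominance and switching,
# duplicate-mature grouping, sample clustering and reference-miRNA selection.

#' Counts-per-million normalization
#'
#' Scales each sample column to sum to one million.
#'
#' @param counts mature x sample count matrix with positive column sums.
#' @return numeric matrix with every column summing to 1e6.
#' @export
normalize_cpm <- function(counts) {
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("all-zero sample column: ", colnames(counts)[cs == 0][1])
  sweep(counts, 2, cs / 1e6, "/")
}

#' Per-precursor, per-tissue arm usage
#'
#' Sums reads over all replicate samples of a tissue and calls the dominant
#' arm by strict majority of raw reads; equal positive counts are a `tie` and
#' two zero counts give `none`.
#'
#' @param counts mature x sample count matrix (rows `<precursor>-5p`/`-3p`).
#' @param candidates candidate data.frame (defines the precursor/arm map).
#' @param tissue_of named character vector sample -> tissue.
#' @return data.frame: `precursor_id`, `tissue`, `reads5p`, `reads3p`,
#'   `dominant` in `{5p, 3p, tie, none}`.
#' @export
arm_usage <- function(counts, candidates, tissue_of) {
  matures <- mature_table(candidates)
  unknown <- setdiff(rownames(counts), matures$mature_id)
  if (length(unknown))
    stop("mature id with unknown precursor: ", unknown[1])
  if (!all(colnames(counts) %in% names(tissue_of)))
    stop("sample without tissue label")
  tissues <- unique(unname(tissue_of[colnames(counts)]))
  arm_reads <- function(prec, arm, tis) {
    mid <- paste0(prec, "-", arm)
    if (!(mid %in% rownames(counts))) return(0L)
    cols <- colnames(counts)[tissue_of[colnames(counts)] == tis]
    sum(counts[mid, cols])
  }
  grid <- expand.grid(precursor_id = candidates$id, tissue = tissues,
                      stringsAsFactors = FALSE)
  grid$reads5p <- mapply(arm_reads, grid$precursor_id, "5p", grid$tissue)
  grid$reads3p <- mapply(arm_reads, grid$precursor_id, "3p", grid$tissue)
  grid$dominant <- ifelse(
    grid$reads5p == 0 & grid$reads3p == 0, "none",
    ifelse(grid$reads5p > grid$reads3p, "5p",
           ifelse(grid$reads3p > grid$reads5p, "3p", "tie")))
  grid[order(grid$precursor_id, grid$tissue, method = "radix"), ,
       drop = FALSE]
}

#' Detect arm-switching precursors
#'
#' A precursor switches when its per-tissue dominant arm (computed only over
#' tissues whose combined 5p+3p reads reach `min_tissue_reads`) takes both
#' values `5p` and `3p` across tissues. Ties never count as a switch.
#'
#' @param usage arm-usage data.frame from [arm_usage()].
#' @param min_tissue_reads minimum per-tissue read total for a tissue to vote.
#' @return data.frame restricted to switching precursors with columns
#'   `precursor_id`, `tissue`, `dominant` (eligible tissues only).
#' @export
detect_arm_switches <- function(usage, min_tissue_reads = 10L) {
  eligible <- usage[usage$reads5p + usage$reads3p >= min_tissue_reads, ,
                    drop = FALSE]
  voting <- eligible[eligible$dominant %in% c("5p", "3p"), , drop = FALSE]
  has_both <- tapply(voting$dominant, voting$precursor_id,
                     function(d) all(c("5p", "3p") %in% d))
  switchers <- names(has_both)[unlist(has_both)]
  out <- voting[voting$precursor_id %in% switchers,
                c("precursor_id", "tissue", "dominant"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize arm usage across precursors
#'
#' @param usage arm-usage data.frame from [arm_usage()].
#' @param min_tissue_reads threshold passed to [detect_arm_switches()].
#' @param presence_min_reads read count from an arm (in at least one tissue)
#'   required to call that arm expressed (default 1).
#' @return list of class `arm_summary`: `n_expressed`, `n_both_arms`,
#'   `n_5p_only`, `n_3p_only`, `frac_dominant_5p`, `frac_dominant_3p`,
#'   `overall_dominant` (named vector), `switches` (data.frame).
#' @export
summarize_arms <- function(usage, min_tissue_reads = 10L,
                           presence_min_reads = 1L) {
  if (nrow(usage) == 0) {
    return(structure(list(
      n_expressed = 0L, n_both_arms = 0L, n_5p_only = 0L, n_3p_only = 0L,
      frac_dominant_5p = NA_real_, frac_dominant_3p = NA_real_,
      overall_dominant = character(0),
      switches = usage[c("precursor_id", "tissue", "dominant")]
    ), class = "arm_summary"))
  }
  tot5 <- tapply(usage$reads5p, usage$precursor_id, sum)
  tot3 <- tapply(usage$reads3p, usage$precursor_id, sum)
  any5 <- tapply(usage$reads5p, usage$precursor_id,
                 function(x) any(x >= presence_min_reads))
  any3 <- tapply(usage$reads3p, usage$precursor_id,
                 function(x) any(x >= presence_min_reads))
  expressed <- tot5 + tot3 > 0
  both <- any5 & any3
  only5 <- any5 & !any3
  only3 <- any3 & !any5
  overall <- ifelse(tot5 + tot3 == 0, "none",
                    ifelse(tot5 > tot3, "5p",
                           ifelse(tot3 > tot5, "3p", "tie")))
  defined <- overall %in% c("5p", "3p")
  structure(list(
    n_expressed = sum(expressed),
    n_both_arms = sum(both),
    n_5p_only = sum(only5),
    n_3p_only = sum(only3),
    frac_dominant_5p = if (any(defined)) mean(overall[defined] == "5p") else NA,
    frac_dominant_3p = if (any(defined)) mean(overall[defined] == "3p") else NA,
    overall_dominant = stats::setNames(as.character(overall), names(tot5)),
    switches = detect_arm_switches(usage, min_tissue_reads)
  ), class = "arm_summary")
}

#' Group precursors encoding the same or highly similar dominant mature
#'
#' Builds connected components of the relation "dominant mature sequences are
#' identical or within edit distance <= `max_edit`"; singleton components are
#' dropped. A group is `exact` when all member sequences are identical,
#' otherwise `similar`.
#'
#' @param dominant_matures named character vector precursor -> dominant mature
#'   sequence.
#' @param max_edit maximum Levenshtein distance counted as "highly similar".
#' @return list of groups, each a list with `members` (precursor ids) and
#'   `type` (`exact`/`similar`).
#' @export
group_duplicates <- function(dominant_matures, max_edit = 2L) {
  ids <- names(dominant_matures)
  n <- length(ids)
  if (n < 2) return(list())
  d <- utils::adist(dominant_matures)
  adj <- d <= max_edit
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(ids, comp)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  out <- lapply(groups, function(m) {
    list(members = sort(m),
         type = if (length(unique(dominant_matures[m])) == 1) "exact"
                else "similar")
  })
  names(out) <- NULL
  out
}

#' Restrict a matrix to the most expressed mature per precursor
#'
#' Keeps, for each precursor, the mature row with the highest total across
#' samples (ties resolved in favor of the 5p arm).
#'
#' @param mat mature x sample matrix (rows `<precursor>-5p`/`-3p`).
#' @param candidates candidate data.frame.
#' @return matrix with one row per precursor, rownames = kept mature ids.
#' @export
top_mature_matrix <- function(mat, candidates) {
  matures <- mature_table(candidates)
  matures <- matures[matures$mature_id %in% rownames(mat), , drop = FALSE]
  totals <- rowSums(mat)[matures$mature_id]
  keep <- vapply(split(seq_len(nrow(matures)), matures$precursor_id),
                 function(ix) {
                   ix <- ix[order(-totals[ix],
                                  matures$arm[ix] != "5p")]
                   matures$mature_id[ix[1]]
                 }, character(1))
  mat[keep, , drop = FALSE]
}

#' Hierarchical clustering of samples by Spearman correlation distance
#'
#' Distance between samples is 1 minus Spearman's rank correlation of their
#' expression columns; merging is by average linkage.
#'
#' @param mat numeric matrix (rows = features, columns = samples), typically
#'   CPM-normalized and restricted to the top mature per precursor.
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust` (the merge tree) and `labels` (named integer
#'   vector, present when `k` given).
#' @export
cluster_samples <- function(mat, k = NULL) {
  if (ncol(mat) < 2) stop("need at least two samples")
  const <- apply(mat, 2, function(x) length(unique(x)) == 1)
  if (any(const))
    stop("constant sample column (Spearman undefined): ",
         colnames(mat)[const][1])
  rho <- stats::cor(mat, method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, labels = labels)
}

#' Select reference miRNAs by coefficient of variation
#'
#' Ranks matures by sample coefficient of variation (standard deviation over
#' mean of normalized counts) ascending and returns the first `k`; ties break
#' by id. Rows with zero mean are excluded with a warning.
#'
#' @param normmat normalized mature x sample matrix.
#' @param k number of reference matures to return (default 2).
#' @return character vector of `k` mature ids, with attribute `cv`.
#' @export
select_reference_mirnas <- function(normmat, k = 2L) {
  mu <- rowMeans(normmat)
  if (any(mu == 0)) {
    warning("excluding ", sum(mu == 0), " mature(s) with zero mean")
    normmat <- normmat[mu > 0, , drop = FALSE]
    mu <- mu[mu > 0]
  }
  if (k > nrow(normmat)) stop("k exceeds the number of usable matures")
  cv <- apply(normmat, 1, stats::sd) / mu
  o <- order(cv, rownames(normmat), method = "radix")
  ids <- rownames(normmat)[o[seq_len(k)]]
  structure(ids, cv = cv[ids])
}
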