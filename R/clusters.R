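# Genomic miRNA cluster detection (same-strand chains with inter-gene gaps
# below 10 kb), chromosome distribution/density, and cluster conservation.

#' Detect genomic miRNA clusters
#'
#' Per (chromosome, strand), precursors are sorted by start and chained
#' whenever the gap from the rightmost end seen so far to the next start is
#' strictly below `max_gap` (overlapping genes are always chained). Maximal
#' chains with at least two members are returned, with cluster ids assigned
#' in genome order. Unplaced fragments are treated exactly like chromosomes.
#'
#' @param intervals data.frame with columns `precursor_id`, `chrom`, `start`
#'   (0-based), `end` (exclusive), `strand`.
#' @param max_gap maximum inter-gene distance in nt (strict inequality;
#'   default 10000).
#' @return data.frame with one row per clustered precursor: `cluster_id`,
#'   `chrom`, `strand`, `precursor_id`, `start`, `end`, `member_index`
#'   (coordinate order within the cluster).
#' @export
find_clusters <- function(intervals, max_gap = 10000L) {
  if (anyDuplicated(intervals$precursor_id))
    stop("duplicate precursor id: ",
         intervals$precursor_id[duplicated(intervals$precursor_id)][1])
  parts <- split(intervals,
                 paste(intervals$chrom, intervals$strand, sep = "\r"))
  chains <- list()
  for (p in parts) {
    p <- p[order(p$start, p$end, p$precursor_id, method = "radix"), ,
           drop = FALSE]
    grp <- integer(nrow(p))
    g <- 1L
    grp[1] <- g
    run_end <- p$end[1]
    for (i in seq_len(nrow(p))[-1]) {
      if (p$start[i] - run_end < max_gap) {
        grp[i] <- g
      } else {
        g <- g + 1L
        grp[i] <- g
      }
      run_end <- max(run_end, p$end[i])
    }
    for (gi in split(seq_len(nrow(p)), grp)) {
      if (length(gi) >= 2) chains[[length(chains) + 1L]] <- p[gi, , drop = FALSE]
    }
  }
  if (!length(chains)) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      strand = character(), precursor_id = character(),
                      start = integer(), end = integer(),
                      member_index = integer(), stringsAsFactors = FALSE))
  }
  first <- t(vapply(chains, function(ch) c(ch$chrom[1],
                                           sprintf("%012d", ch$start[1])),
                    character(2)))
  ord <- order(first[, 1], first[, 2], method = "radix")
  out <- do.call(rbind, lapply(seq_along(ord), function(k) {
    ch <- chains[[ord[k]]]
    data.frame(cluster_id = sprintf("cluster_%02d", k),
               chrom = ch$chrom, strand = ch$strand,
               precursor_id = ch$precursor_id,
               start = ch$start, end = ch$end,
               member_index = seq_len(nrow(ch)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Chromosome counts and miRNA density
#'
#' @param intervals data.frame with at least `chrom`.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp);
#'   chromosomes absent from `intervals` contribute zero counts.
#' @return list with `per_chrom` (data.frame `chrom`, `n`, `length_bp`,
#'   `density_per_mbp`) and `mean_per_chrom` (mean count over all declared
#'   chromosomes).
#' @export
chromosome_summary <- function(intervals, chrom_lengths) {
  unknown <- setdiff(unique(intervals$chrom), names(chrom_lengths))
  if (length(unknown)) stop("unknown chromosome: ", unknown[1])
  n <- table(factor(intervals$chrom, levels = names(chrom_lengths)))
  per <- data.frame(
    chrom = names(chrom_lengths),
    n = as.integer(n),
    length_bp = unname(chrom_lengths),
    density_per_mbp = as.integer(n) / (unname(chrom_lengths) / 1e6),
    stringsAsFactors = FALSE
  )
  list(per_chrom = per, mean_per_chrom = mean(per$n))
}

#' Conservation status of a cluster across species
#'
#' For each species: `conserved` when every member has an ortholog and all
#' reported ortholog chromosomes agree (that chromosome is reported);
#' `partial` when some but not all members map, or mapped chromosomes
#' disagree; `none` when no member maps.
#'
#' @param members character vector of member precursor ids.
#' @param ortholog_locations named list precursor -> named character vector
#'   species -> ortholog chromosome.
#' @param species species to evaluate; defaults to all species seen.
#' @return data.frame: `species`, `status`, `chrom` (`NA` unless conserved).
#' @export
cluster_conservation <- function(members, ortholog_locations,
                                 species = NULL) {
  maps <- lapply(members, function(m) {
    v <- ortholog_locations[[m]]
    if (is.null(v)) character(0) else v
  })
  if (is.null(species))
    species <- sort(unique(unlist(lapply(maps, names))))
  rows <- lapply(species, function(sp) {
    chroms <- vapply(maps, function(v) {
      if (sp %in% names(v)) v[[sp]] else NA_character_
    }, character(1))
    mapped <- !is.na(chroms)
    if (!any(mapped)) {
      data.frame(species = sp, status = "none", chrom = NA_character_,
                 stringsAsFactors = FALSE)
    } else if (all(mapped) && length(unique(chroms)) == 1) {
      data.frame(species = sp, status = "conserved", chrom = chroms[1],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(species = sp, status = "partial", chrom = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(), status = character(),
                      chrom = character(), stringsAsFactors = FALSE)
  out
}
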