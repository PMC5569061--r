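# End-to-end orchestration: filter -> conserve -> arms / clusters / isomiR /
# targets, with persisted intermediate artifacts and a consolidated report.

#' Pipeline run configuration
#'
#' @param input_dir directory holding the input bundle (as written by
#'   [write_fixtures()]): `candidates.tsv`, `counts.tsv`, `reads.tsv`,
#'   `sample_map.tsv`, `score_bins.tsv`, `mirbase_hits.tsv`,
#'   `genome_hits.tsv`, `ncrna_hits.tsv`, and optionally
#'   `ortholog_locations.tsv`, `family_index.tsv`, `utrs.fasta`,
#'   `specific_matures.fasta`.
#' @param out_dir directory for stage outputs and the run report.
#' @param params [pipeline_params()].
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir, params = pipeline_params()) {
  structure(list(input_dir = input_dir, out_dir = out_dir, params = params),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full post-processing pipeline
#'
#' Executes threshold selection, the filter cascade, conservation calling and
#' naming, arm-usage summarization and switch detection, duplicate grouping,
#' sample clustering, genomic cluster detection, isomiR classification and
#' (when UTR inputs are present) canonical seed-site scanning. Every stage
#' writes its artifact under `out_dir`; the returned report carries stage
#' counts and a file manifest with checksums.
#'
#' @param config [run_config()].
#' @return list of class `run_report` (also written as `run_report.json`).
#' @export
run_all <- function(config) {
  ind <- config$input_dir
  outd <- config$out_dir
  params <- config$params
  req <- c("candidates.tsv", "counts.tsv", "reads.tsv", "sample_map.tsv",
           "mirbase_hits.tsv", "genome_hits.tsv", "ncrna_hits.tsv")
  missing <- req[!file.exists(file.path(ind, req))]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  if (!dir.exists(outd)) dir.create(outd, recursive = TRUE)
  op <- function(f) file.path(outd, f)

  candidates <- stage("load", read_candidates(file.path(ind, "candidates.tsv")))
  counts <- stage("load", read_counts(file.path(ind, "counts.tsv")))
  tissue_of <- stage("load", read_sample_map(file.path(ind, "sample_map.tsv")))
  reads <- stage("load", utils::read.delim(file.path(ind, "reads.tsv"),
                                           stringsAsFactors = FALSE))
  mirbase_hits <- stage("load", read_hit_table(file.path(ind, "mirbase_hits.tsv")))
  genome_hits <- stage("load", read_hit_table(file.path(ind, "genome_hits.tsv")))
  ncrna_hits <- stage("load", read_hit_table(file.path(ind, "ncrna_hits.tsv")))
  bins_path <- file.path(ind, "score_bins.tsv")
  if (file.exists(bins_path)) {
    bins_df <- stage("load", utils::read.delim(bins_path))
    bins <- score_bins(bins_df$threshold, bins_df$n_signal, bins_df$n_control)
    thr <- stage("threshold", select_score_threshold(bins, params$min_snr))
  } else {
    thr <- structure(params$min_score, snr = NA_real_)
  }
  params$min_score <- as.numeric(thr)
  n_post_score <- sum(candidates$score >= thr)

  report_filters <- stage("filter",
    apply_filters(candidates, counts, genome_hits, ncrna_hits, params))
  utils::write.table(as.data.frame(report_filters), op("filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  kept <- candidates[candidates$id %in% report_filters$kept, , drop = FALSE]

  calls <- stage("conserve",
    call_conservation_all(kept$id, mirbase_hits, params))
  names_df <- stage("conserve", assign_names(calls, kept))
  cons_out <- merge(calls, names_df, by = "precursor_id", sort = TRUE)
  utils::write.table(cons_out, op("conservation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")

  kept_matures <- mature_table(kept)
  counts_kept <- counts[rownames(counts) %in% kept_matures$mature_id, ,
                        drop = FALSE]
  usage <- stage("arms", arm_usage(counts_kept, kept, tissue_of))
  summ <- stage("arms", summarize_arms(usage, params$min_tissue_reads))
  utils::write.table(usage, op("arm_usage.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summ$switches, op("arm_switches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summ[c("n_expressed", "n_both_arms", "n_5p_only",
                              "n_3p_only", "frac_dominant_5p",
                              "frac_dominant_3p")],
                       op("arm_summary.json"), auto_unbox = TRUE, digits = NA)

  dom <- dominant_mature_sequences(kept, summ$overall_dominant)
  dups <- stage("arms", group_duplicates(dom))

  clus <- stage("clusters", find_clusters(
    data.frame(precursor_id = kept$id, chrom = kept$chrom,
               start = kept$start, end = kept$end, strand = kept$strand,
               stringsAsFactors = FALSE),
    params$cluster_max_gap))
  utils::write.table(clus, op("clusters.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ol_path <- file.path(ind, "ortholog_locations.tsv")
  cluster_cons <- NULL
  if (file.exists(ol_path) && nrow(clus)) {
    ol <- utils::read.delim(ol_path, stringsAsFactors = FALSE)
    locs <- split(stats::setNames(ol$chrom, ol$species), ol$precursor_id)
    locs <- lapply(locs, function(v) v[!duplicated(names(v))])
    cluster_cons <- do.call(rbind, lapply(split(clus, clus$cluster_id),
      function(cl) {
        cc <- cluster_conservation(cl$precursor_id, locs,
                                   species = c("hsa", "cfa"))
        cc$cluster_id <- cl$cluster_id[1]
        cc
      }))
    rownames(cluster_cons) <- NULL
    utils::write.table(cluster_cons, op("cluster_conservation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  reads_kept <- reads[reads$precursor_id %in% kept$id, , drop = FALSE]
  calls_iso <- stage("isomir", classify_reads(reads_kept, kept,
                                              params$max_shift,
                                              params$max_mismatch))
  dist_iso <- stage("isomir", isomir_distribution(calls_iso, tissue_of))
  utils::write.table(
    data.frame(category = names(dist_iso$overall),
               fraction = as.numeric(dist_iso$overall)),
    op("isomir_distribution.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  n_sites <- NA_integer_
  utr_path <- file.path(ind, "utrs.fasta")
  mat_path <- file.path(ind, "specific_matures.fasta")
  if (file.exists(utr_path) && file.exists(mat_path)) {
    utrs <- read_fasta(utr_path, dna_to_rna = TRUE)
    specm <- read_fasta(mat_path, dna_to_rna = TRUE)
    sites <- stage("targets", scan_all_utrs(specm, utrs))
    utils::write.table(sites, op("seed_sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    n_sites <- nrow(sites)
  }

  files <- list.files(outd, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  report <- list(
    params = unclass(params),
    score_threshold = as.numeric(thr),
    snr_at_threshold = as.numeric(attr(thr, "snr")),
    counts = list(
      input_candidates = nrow(candidates),
      post_score = n_post_score,
      post_filters = length(report_filters$kept),
      conserved = sum(calls$status == "conserved"),
      cat_specific = sum(calls$status == "cat_specific"),
      matures = nrow(kept_matures),
      n_both_arms = summ$n_both_arms,
      n_5p_only = summ$n_5p_only,
      n_3p_only = summ$n_3p_only,
      n_switches = length(unique(summ$switches$precursor_id)),
      n_duplicate_groups = length(dups),
      n_clusters = length(unique(clus$cluster_id)),
      n_clustered_precursors = nrow(clus),
      n_seed_sites = n_sites
    ),
    rejected_by_reason = as.list(table(report_filters$rejected)),
    isomir_overall = as.list(dist_iso$overall),
    manifest = manifest
  )
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), op("run_report.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  report
}

#' Dominant mature sequence per precursor
#'
#' The mature of the overall dominant arm; precursors without a defined
#' dominant fall back to the 5p mature when encoded, else the 3p.
#'
#' @param candidates candidate data.frame.
#' @param overall_dominant named vector precursor -> `5p`/`3p`/`tie`/`none`
#'   (from [summarize_arms()]).
#' @return named character vector precursor -> mature sequence.
#' @export
dominant_mature_sequences <- function(candidates, overall_dominant) {
  out <- character(nrow(candidates))
  names(out) <- candidates$id
  for (i in seq_len(nrow(candidates))) {
    id <- candidates$id[i]
    arm <- overall_dominant[[id]]
    if (is.null(arm) || !(arm %in% c("5p", "3p")))
      arm <- if (!is.na(candidates$mature5p_seq[i])) "5p" else "3p"
    sq <- candidates[[paste0("mature", arm, "_seq")]][i]
    if (is.na(sq))
      sq <- candidates[[paste0("mature",
                               setdiff(c("5p", "3p"), arm), "_seq")]][i]
    out[id] <- sq
  }
  out
}
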