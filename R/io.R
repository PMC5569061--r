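# Readers/writers for every external representation the pipeline touches.
# Internal conventions: genomic intervals are 0-based half-open; sequences are
# RNA (U, never T) and uppercase; the 12-column tabular alignment dialect keeps
# its native 1-based inclusive coordinates and is converted at the boundary.

HIT_COLS <- c(
  "query_id", "subject_id", "pct_identity", "align_length", "mismatches",
  "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore"
)

CANDIDATE_COLS <- c(
  "id", "chrom", "start", "end", "strand", "score", "hairpin_seq",
  "mature5p_seq", "mature5p_offset", "mature3p_seq", "mature3p_offset"
)

#' Pipeline parameter set
#'
#' Bundles every numeric threshold used by the post-processing pipeline.
#' Defaults follow the standard published practice for miRNA discovery
#' post-processing: the score threshold is the lowest score giving a
#' signal-to-noise ratio above 10:1, expression requires >= 10 reads in at
#' least one sample, repetitive candidates have more than 5 distinct genome
#' loci at E < 2e-8, orthology requires E < 1e-5, missed-family recovery uses
#' >= 70% precursor coverage and E <= 0.1, and clusters chain precursors less
#' than 10 kb apart on one strand.
#'
#' @param min_score minimum discovery score kept (default 5).
#' @param min_snr required signal-to-noise ratio for threshold selection.
#' @param min_count minimum read count in at least one sample.
#' @param max_genome_hits maximum distinct genomic loci before a candidate is
#'   called repetitive.
#' @param genome_hit_evalue E-value below which a genome hit counts as
#'   significant for the repetitive screen.
#' @param ortholog_evalue E-value below which a miRBase hit counts as an
#'   ortholog (strict inequality).
#' @param recovery_min_coverage fraction of a precursor probe that must align
#'   for genomic evidence.
#' @param recovery_max_evalue E-value ceiling for the structural-RNA screen and
#'   the missed-family probe search.
#' @param cluster_max_gap maximum inter-gene gap (nt, exclusive) within a
#'   cluster.
#' @param seed_start,seed_end 1-based positions on the mature delimiting the
#'   seed (default 2-8).
#' @param min_tissue_reads minimum per-tissue read total for a tissue to vote
#'   in arm-switch detection.
#' @param max_shift,max_mismatch isomiR anchoring tolerances (nt offsets from
#'   the canonical start; mismatches against the precursor).
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(min_score = 5, min_snr = 10, min_count = 10L,
                            max_genome_hits = 5L, genome_hit_evalue = 2e-8,
                            ortholog_evalue = 1e-5,
                            recovery_min_coverage = 0.70,
                            recovery_max_evalue = 0.1,
                            cluster_max_gap = 10000L,
                            seed_start = 2L, seed_end = 8L,
                            min_tissue_reads = 10L,
                            max_shift = 5L, max_mismatch = 2L) {
  p <- list(
    min_score = min_score, min_snr = min_snr, min_count = as.integer(min_count),
    max_genome_hits = as.integer(max_genome_hits),
    genome_hit_evalue = genome_hit_evalue, ortholog_evalue = ortholog_evalue,
    recovery_min_coverage = recovery_min_coverage,
    recovery_max_evalue = recovery_max_evalue,
    cluster_max_gap = as.integer(cluster_max_gap),
    seed_start = as.integer(seed_start), seed_end = as.integer(seed_end),
    min_tissue_reads = as.integer(min_tissue_reads),
    max_shift = as.integer(max_shift), max_mismatch = as.integer(max_mismatch)
  )
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num) || any(unlist(p[num]) <= 0))
    stop("all pipeline parameters must be strictly positive numbers")
  if (p$seed_start >= p$seed_end)
    stop("seed interval is empty")
  structure(p, class = "pipeline_params")
}

#' Read a FASTA file into a named character vector
#'
#' @param path path to a FASTA file.
#' @param dna_to_rna if `TRUE`, T/t are converted to U/u so that DNA inputs
#'   enter the RNA-alphabet pipeline.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, dna_to_rna = FALSE) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  if (any(Biostrings::width(set) == 0))
    stop("empty sequence record: ", ids[Biostrings::width(set) == 0][1])
  seqs <- toupper(as.character(set))
  if (dna_to_rna) seqs <- chartr("T", "U", seqs)
  names(seqs) <- ids
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a 12-column tabular alignment hit table
#'
#' Parses the standard 12-column tab-separated alignment format
#' (query, subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, E-value, bit score). Coordinates stay
#' 1-based inclusive as in the format.
#'
#' @param path path to the hit table (no header).
#' @return `data.frame` with columns `query_id`, `subject_id`, `pct_identity`,
#'   `align_length`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `evalue`, `bitscore`; row order preserved.
#' @export
read_hit_table <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0 || is.null(nf)) return(empty_hits())
  bad <- which(nf != 12L)
  if (length(bad))
    stop("expected 12 tab-separated columns at line ", bad[1],
         " of ", path, " (found ", nf[bad[1]], ")")
  df <- utils::read.delim(path, header = FALSE, quote = "",
                          col.names = HIT_COLS,
                          colClasses = c("character", "character",
                                         rep("numeric", 10)))
  df$align_length <- as.integer(df$align_length)
  df$mismatches <- as.integer(df$mismatches)
  df$gap_opens <- as.integer(df$gap_opens)
  df$q_start <- as.integer(df$q_start)
  df$q_end <- as.integer(df$q_end)
  df$s_start <- as.integer(df$s_start)
  df$s_end <- as.integer(df$s_end)
  validate_hits(df)
  df
}

empty_hits <- function() {
  df <- data.frame(
    query_id = character(), subject_id = character(),
    pct_identity = numeric(), align_length = integer(),
    mismatches = integer(), gap_opens = integer(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    evalue = numeric(), bitscore = numeric(),
    stringsAsFactors = FALSE
  )
  df
}

validate_hits <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$q_start > df$q_end))
    stop("hit with q_start > q_end: query ", df$query_id[df$q_start > df$q_end][1])
  if (any(df$evalue < 0)) stop("negative E-value in hit table")
  if (any(df$pct_identity < 0 | df$pct_identity > 100))
    stop("percent identity outside [0, 100]")
  invisible(df)
}

#' Write a hit table in the 12-column tabular dialect
#' @param hits data.frame as returned by [read_hit_table()].
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(identical(names(hits), HIT_COLS))
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a candidate-precursor table
#'
#' Candidates come as a header-ed TSV with columns `id`, `chrom`, `start`,
#' `end`, `strand`, `score`, `hairpin_seq`, `mature5p_seq`, `mature5p_offset`,
#' `mature3p_seq`, `mature3p_offset`. Coordinates are 0-based half-open;
#' mature offsets are 0-based within the hairpin; absent arms are empty/NA.
#' Invariants (mature occurs at its offset, at least one arm, 5p before 3p)
#' are enforced on load.
#'
#' @param path path to the TSV.
#' @return validated candidate `data.frame`.
#' @export
read_candidates <- function(path) {
  df <- utils::read.delim(path, header = TRUE, quote = "",
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  missing_cols <- setdiff(CANDIDATE_COLS, names(df))
  if (length(missing_cols))
    stop("candidate table missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[CANDIDATE_COLS]
  validate_candidates(df)
}

#' Validate a candidate-precursor data.frame
#' @param df candidate data.frame (see [read_candidates()] for the schema).
#' @return the validated data.frame, invisibly usable.
#' @export
validate_candidates <- function(df) {
  if (anyDuplicated(df$id)) stop("duplicate candidate id: ",
                                 df$id[duplicated(df$id)][1])
  if (any(!(df$strand %in% c("+", "-"))))
    stop("strand must be '+' or '-'")
  if (any(df$start < 0 | df$start >= df$end))
    stop("invalid interval (need 0 <= start < end)")
  df$hairpin_seq <- toupper(df$hairpin_seq)
  df$mature5p_seq <- toupper(df$mature5p_seq)
  df$mature3p_seq <- toupper(df$mature3p_seq)
  for (i in seq_len(nrow(df))) {
    hp <- df$hairpin_seq[i]
    has5 <- !is.na(df$mature5p_seq[i])
    has3 <- !is.na(df$mature3p_seq[i])
    if (!has5 && !has3)
      stop("candidate ", df$id[i], " has no mature sequence")
    if (has5 && !mature_at_offset(hp, df$mature5p_seq[i], df$mature5p_offset[i]))
      stop("candidate ", df$id[i],
           ": mature5p does not occur at its stated offset in the hairpin")
    if (has3 && !mature_at_offset(hp, df$mature3p_seq[i], df$mature3p_offset[i]))
      stop("candidate ", df$id[i],
           ": mature3p does not occur at its stated offset in the hairpin")
    if (has5 && has3 && !(df$mature5p_offset[i] < df$mature3p_offset[i]))
      stop("candidate ", df$id[i], ": mature5p offset must precede mature3p")
  }
  df
}

mature_at_offset <- function(hairpin, mature, offset) {
  if (is.na(offset)) return(FALSE)
  substr(hairpin, offset + 1, offset + nchar(mature)) == mature
}

#' Write a candidate table
#' @param df candidate data.frame.
#' @param path output path.
#' @export
write_candidates <- function(df, path) {
  stopifnot(all(CANDIDATE_COLS %in% names(df)))
  utils::write.table(df[CANDIDATE_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a mature-miRNA x sample count matrix
#'
#' Header-ed TSV: first column `mature_id`, remaining columns one per sample.
#' Counts must be non-negative integers.
#'
#' @param path path to the TSV.
#' @return integer matrix with mature ids as rownames, samples as colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "mature_id") stop("first column must be 'mature_id'")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate mature id: ", ids[duplicated(ids)][1])
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("non-numeric counts")
  if (any(is.na(m))) stop("missing counts")
  if (any(m < 0)) stop("negative count")
  if (any(m != floor(m))) stop("non-integer count")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a count matrix
#' @param m integer matrix (matures x samples).
#' @param path output path.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(mature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-tissue map
#' @param path TSV with header columns `sample` and `tissue`.
#' @return named character vector: `tissue_of[sample]`.
#' @export
read_sample_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "tissue") %in% names(df)))
  if (anyDuplicated(df$sample)) stop("duplicate sample in sample map")
  stats::setNames(df$tissue, df$sample)
}

#' Write a sample-to-tissue map
#' @param tissue_of named character vector (names = samples).
#' @param path output path.
#' @export
write_sample_map <- function(tissue_of, path) {
  utils::write.table(
    data.frame(sample = names(tissue_of), tissue = unname(tissue_of)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read precursor coordinates from a BED6 file
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start` (0-based), `end` (exclusive),
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr)),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else rep(0, length(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write precursor coordinates as BED6
#' @param df data.frame with `chrom`, `start` (0-based), `end`, `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
  gr$name <- df$name
  gr$score <- if (!is.null(df$score)) df$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Mature table from a candidate data.frame
#'
#' Expands candidates into one row per encoded mature: `mature_id`
#' (`<precursor>-5p` / `<precursor>-3p`), `precursor_id`, `arm`, `sequence`,
#' `offset` (0-based on the hairpin).
#'
#' @param candidates candidate data.frame.
#' @return mature data.frame.
#' @export
mature_table <- function(candidates) {
  rows <- list()
  for (arm in c("5p", "3p")) {
    seqcol <- paste0("mature", arm, "_seq")
    offcol <- paste0("mature", arm, "_offset")
    has <- !is.na(candidates[[seqcol]])
    if (any(has)) {
      rows[[arm]] <- data.frame(
        mature_id = paste0(candidates$id[has], "-", arm),
        precursor_id = candidates$id[has],
        arm = arm,
        sequence = candidates[[seqcol]][has],
        offset = candidates[[offcol]][has],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(mature_id = character(), precursor_id = character(),
                      arm = character(), sequence = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out[order(out$precursor_id, out$arm, method = "radix"), , drop = FALSE]
}
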