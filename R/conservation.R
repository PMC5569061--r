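# Conservation calling against miRBase-style hit tables, seed-based family
# assignment, public naming, and recovery of conserved families missed by
# discovery.

#' Extract the seed of a mature miRNA
#'
#' The seed is the subsequence at 1-based positions `start`..`end` (default
#' 2-8, the 7-nt convention used for miRBase families).
#'
#' @param sequence mature RNA sequence (>= `end` nt).
#' @param start,end 1-based seed positions.
#' @return seed string.
#' @export
extract_seed <- function(sequence, start = 2L, end = 8L) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < end)
    stop("mature sequence shorter than seed end position (", end, " nt)")
  substr(sequence, start, end)
}

species_prefix <- function(subject_id) {
  ok <- grepl("^[a-z]{3,4}-", subject_id)
  if (any(!ok))
    stop("cannot parse species prefix from subject id: ",
         subject_id[!ok][1])
  sub("^([a-z]{3,4})-.*$", "\\1", subject_id)
}

#' Call conservation for one precursor
#'
#' A precursor is `conserved` when at least one miRBase hairpin hit has
#' E-value strictly below `params$ortholog_evalue`; otherwise it is
#' `cat_specific` (species-specific). Ortholog species are the distinct
#' miRBase three-letter prefixes among qualifying subjects; `n_orthologs`
#' counts distinct qualifying subject hairpins. The best ortholog (lowest
#' E-value, ties by higher bit score, then lexicographic subject id) is
#' recorded for naming.
#'
#' @param precursor_id candidate id.
#' @param mirbase_hits hit table of precursors vs miRBase hairpins.
#' @param params [pipeline_params()].
#' @return one-row data.frame: `precursor_id`, `status`, `n_orthologs`,
#'   `species` (comma-joined), `best_ortholog`.
#' @export
call_conservation <- function(precursor_id, mirbase_hits,
                              params = pipeline_params()) {
  h <- mirbase_hits[mirbase_hits$query_id == precursor_id &
                      mirbase_hits$evalue < params$ortholog_evalue, ,
                    drop = FALSE]
  if (nrow(h) == 0) {
    return(data.frame(precursor_id = precursor_id, status = "cat_specific",
                      n_orthologs = 0L, species = "",
                      best_ortholog = NA_character_,
                      stringsAsFactors = FALSE))
  }
  sp <- sort(unique(species_prefix(h$subject_id)))
  o <- order(h$evalue, -h$bitscore, h$subject_id, method = "radix")
  data.frame(
    precursor_id = precursor_id, status = "conserved",
    n_orthologs = length(unique(h$subject_id)),
    species = paste(sp, collapse = ","),
    best_ortholog = h$subject_id[o[1]],
    stringsAsFactors = FALSE
  )
}

#' Call conservation for a set of precursors
#' @param precursor_ids character vector of candidate ids.
#' @param mirbase_hits hit table of precursors vs miRBase hairpins.
#' @param params [pipeline_params()].
#' @return data.frame with one row per precursor (see [call_conservation()]).
#' @export
call_conservation_all <- function(precursor_ids, mirbase_hits,
                                  params = pipeline_params()) {
  if (!length(precursor_ids)) {
    return(data.frame(precursor_id = character(), status = character(),
                      n_orthologs = integer(), species = character(),
                      best_ortholog = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(precursor_ids, call_conservation,
                               mirbase_hits = mirbase_hits, params = params))
  rownames(out) <- NULL
  out
}

#' Assign a miRBase-style family by seed lookup
#'
#' Exact lookup of the 7-nt seed in a seed -> family index. When several
#' families share the seed, the lexicographically smallest id is the primary
#' assignment and all are recorded.
#'
#' @param sequence mature sequence.
#' @param family_index data.frame with columns `seed` and `family`.
#' @param params [pipeline_params()] (seed positions).
#' @return list with `family` (primary id or `NA`) and `families`
#'   (sorted character vector of all matches).
#' @export
assign_family <- function(sequence, family_index,
                          params = pipeline_params()) {
  seed <- extract_seed(sequence, params$seed_start, params$seed_end)
  fams <- sort(unique(family_index$family[family_index$seed == seed]))
  list(family = if (length(fams)) fams[1] else NA_character_,
       families = fams)
}

#' Assign public names to precursors
#'
#' Conserved precursors are named `fca-<stem>` after the stem of their best
#' ortholog (`hsa-mir-122` -> `fca-mir-122`); when several conserved
#' precursors share a stem they get `-1`, `-2`, ... suffixes in coordinate
#' order. Species-specific precursors are named
#' `fca-mir-<chrom>_<serial>` with serials assigned in coordinate order per
#' chromosome. Mature names replace `mir` by `miR` and append `-5p`/`-3p`.
#'
#' @param calls conservation calls (see [call_conservation_all()]).
#' @param candidates candidate data.frame (for coordinates and arms).
#' @return data.frame: `precursor_id`, `name`, `mature5p_name`,
#'   `mature3p_name`.
#' @export
assign_names <- function(calls, candidates) {
  if (nrow(calls) == 0) {
    return(data.frame(precursor_id = character(), name = character(),
                      mature5p_name = character(),
                      mature3p_name = character(), stringsAsFactors = FALSE))
  }
  df <- merge(calls, candidates[c("id", "chrom", "start",
                                  "mature5p_seq", "mature3p_seq")],
              by.x = "precursor_id", by.y = "id", sort = FALSE)
  df <- df[order(df$chrom, df$start, df$precursor_id, method = "radix"), ,
           drop = FALSE]
  name <- rep(NA_character_, nrow(df))

  cons <- df$status == "conserved"
  if (any(cons)) {
    stems <- sub("^[a-z]{3,4}-", "", df$best_ortholog[cons])
    base <- paste0("fca-", stems)
    dup_stems <- unique(stems[duplicated(stems)])
    serial <- stats::ave(seq_along(stems), stems, FUN = seq_along)
    nm <- ifelse(stems %in% dup_stems, paste0(base, "-", serial), base)
    name[cons] <- nm
  }
  spec <- !cons
  if (any(spec)) {
    serial <- stats::ave(seq_len(sum(spec)), df$chrom[spec], FUN = seq_along)
    name[spec] <- paste0("fca-mir-", df$chrom[spec], "_", serial)
  }
  if (anyDuplicated(name))
    stop("name collision after suffixing: ", name[duplicated(name)][1])

  mat_name <- function(nm) sub("-mir-", "-miR-", nm, fixed = TRUE)
  out <- data.frame(
    precursor_id = df$precursor_id,
    name = name,
    mature5p_name = ifelse(is.na(df$mature5p_seq), NA_character_,
                           paste0(mat_name(name), "-5p")),
    mature3p_name = ifelse(is.na(df$mature3p_seq), NA_character_,
                           paste0(mat_name(name), "-3p")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Recover conserved families missed by discovery
#'
#' Restricts the family table to families conserved in at least
#' `min_species` species including human, then assigns each member gene a
#' status: `detected` (gene recovered by sequencing), `family_member_detected`
#' (another gene of the family detected), `genomic_evidence` (a human mature
#' probe hit covering the complete seed at E <= `recovery_max_evalue`, or a
#' human precursor probe hit aligning at least `recovery_min_coverage` of the
#' probe), or `absent`. Family status is the best member status
#' (detected > family_member_detected > genomic_evidence > absent).
#'
#' A mature probe hit only counts as seed-complete when it covers probe
#' positions 2-8 and is mismatch-free, unless `mismatch_positions` supplies
#' per-probe mismatch positions, in which case none may fall inside 2-8.
#'
#' @param family_table data.frame with columns `family`, `gene`, `n_species`,
#'   `has_human` (logical).
#' @param detected_genes character vector of gene ids recovered by discovery.
#' @param probe_hits hit table of human probes vs the cat genome; `query_id`
#'   must be a probe id present in `probe_meta`.
#' @param probe_meta data.frame with columns `probe_id`, `gene`,
#'   `type` (`mature`/`precursor`), `length` (probe length, nt).
#' @param params [pipeline_params()].
#' @param min_species minimum species count for a family to enter the
#'   denominator (default 5).
#' @param mismatch_positions optional named list probe_id -> integer vector of
#'   1-based mismatch positions on the probe.
#' @return list with data.frames `genes` (gene-level status) and `families`
#'   (family-level rollup).
#' @export
recover_missed_families <- function(family_table, detected_genes, probe_hits,
                                    probe_meta,
                                    params = pipeline_params(),
                                    min_species = 5L,
                                    mismatch_positions = NULL) {
  stopifnot(all(c("family", "gene", "n_species", "has_human") %in%
                  names(family_table)))
  unknown <- setdiff(probe_meta$gene, family_table$gene)
  if (length(unknown))
    stop("probe references gene absent from family table: ", unknown[1])

  eligible <- family_table[family_table$n_species >= min_species &
                             family_table$has_human, , drop = FALSE]
  if (nrow(eligible) == 0)
    return(list(genes = data.frame(), families = data.frame()))

  probe_ok <- function(pid) {
    meta <- probe_meta[probe_meta$probe_id == pid, , drop = FALSE]
    h <- probe_hits[probe_hits$query_id == pid, , drop = FALSE]
    if (nrow(h) == 0) return(FALSE)
    if (meta$type == "mature") {
      covers <- h$q_start <= params$seed_start & h$q_end >= params$seed_end &
        h$evalue <= params$recovery_max_evalue
      seed_clean <- if (!is.null(mismatch_positions) &&
                        pid %in% names(mismatch_positions)) {
        mp <- mismatch_positions[[pid]]
        rep(!any(mp >= params$seed_start & mp <= params$seed_end), nrow(h))
      } else {
        h$mismatches == 0
      }
      any(covers & seed_clean)
    } else {
      any(h$align_length >= params$recovery_min_coverage * meta$length &
            h$evalue <= params$recovery_max_evalue)
    }
  }

  fam_detected <- unique(eligible$family[eligible$gene %in% detected_genes])
  gene_status <- character(nrow(eligible))
  mature_ev <- logical(nrow(eligible))
  precursor_ev <- logical(nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    g <- eligible$gene[i]
    fam <- eligible$family[i]
    probes <- probe_meta[probe_meta$gene == g, , drop = FALSE]
    m_ok <- any(vapply(probes$probe_id[probes$type == "mature"], probe_ok,
                       logical(1)))
    p_ok <- any(vapply(probes$probe_id[probes$type == "precursor"], probe_ok,
                       logical(1)))
    mature_ev[i] <- isTRUE(m_ok)
    precursor_ev[i] <- isTRUE(p_ok)
    gene_status[i] <-
      if (g %in% detected_genes) "detected"
      else if (fam %in% fam_detected) "family_member_detected"
      else if (isTRUE(m_ok) || isTRUE(p_ok)) "genomic_evidence"
      else "absent"
  }
  genes <- data.frame(
    family = eligible$family, gene = eligible$gene, status = gene_status,
    mature_evidence = mature_ev, precursor_evidence = precursor_ev,
    stringsAsFactors = FALSE
  )
  pri <- c(detected = 1, family_member_detected = 2,
           genomic_evidence = 3, absent = 4)
  fam_status <- tapply(genes$status, genes$family,
                       function(s) names(pri)[min(pri[s])])
  families <- data.frame(
    family = names(fam_status), status = unname(fam_status),
    stringsAsFactors = FALSE
  )
  families <- families[order(families$family, method = "radix"), ,
                       drop = FALSE]
  rownames(families) <- NULL
  list(genes = genes, families = families)
}
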