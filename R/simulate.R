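# Synthetic-data generator: produces every input the pipeline consumes with
# planted ground truth. Defaults emulate the study conditions of a 12-tissue,
# 27-library cat miRNAome survey: 1182 raw discovery candidates of which 378
# score >= 5 and 271 survive all filters (804 below-score, 105 low-expression
# and 2 structural-RNA decoys, one of the latter also repetitive); 204
# precursors encode both arms (475 matures in total); 201 express both arms,
# 27 the 5p arm only, 43 the 3p only; 19 precursors arm-switch; 25 precursors
# are species-specific; 109 precursors sit in 31 genomic clusters (largest 29
# members); isomiR proportions follow the reported read-weighted distribution
# (46.3% canonical, 33.4% 3' templated, 11.2% polymorphic, 6.0% 3'
# non-templated, 2.4% 5' templated, <1% rare classes).

RNA_BASES <- c("A", "C", "G", "U")

rand_seq <- function(n) paste(sample(RNA_BASES, n, replace = TRUE),
                              collapse = "")

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(RNA_BASES, x), 1), character(1))
}

default_chrom_lengths <- function() {
  c(chrA1 = 240e6, chrA2 = 169e6, chrA3 = 143e6,
    chrB1 = 205e6, chrB2 = 154e6, chrB3 = 148e6, chrB4 = 144e6,
    chrC1 = 221e6, chrC2 = 157e6,
    chrD1 = 116e6, chrD2 = 89e6, chrD3 = 96e6, chrD4 = 96e6,
    chrE1 = 63e6, chrE2 = 64e6, chrE3 = 43e6,
    chrF1 = 68e6, chrF2 = 82e6,
    chrX = 126e6, chrY = 2e6,
    chrUn_JH409706 = 1.5e6, chrC1_JH408690_random = 1.2e6)
}

default_planted_clusters <- function() {
  data.frame(
    chrom = c("chrA1", "chrA1", "chrE2", "chrE2",
              "chrA2", "chrA2", "chrA2", "chrA2",
              "chrB3", "chrB3", "chrB3",
              "chrX", "chrX", "chrX", "chrX", "chrX", "chrX", "chrX",
              "chrE1", "chrD1", "chrF1", "chrF1", "chrF1",
              "chrA3", "chrD3", "chrE3", "chrD4", "chrD4",
              "chrC1_JH408690_random", "chrC2", "chrC2"),
    size = c(2L, 6L, 3L, 2L, 2L, 2L, 3L, 2L, 4L, 2L, 29L,
             2L, 5L, 4L, 4L, 2L, 2L, 4L, 2L, 2L, 2L, 2L, 2L,
             3L, 2L, 3L, 3L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

default_singletons <- function() {
  c(chrA1 = 10L, chrA2 = 8L, chrA3 = 9L, chrB1 = 10L, chrB2 = 3L,
    chrB3 = 11L, chrB4 = 10L, chrC1 = 12L, chrC2 = 8L, chrD1 = 8L,
    chrD2 = 9L, chrD3 = 7L, chrD4 = 6L, chrE1 = 7L, chrE2 = 6L,
    chrE3 = 9L, chrF1 = 6L, chrF2 = 8L, chrX = 12L,
    chrUn_JH409706 = 1L, chrC1_JH408690_random = 2L)
}

default_tissues <- function() {
  c(lip = 1L, brain = 5L, tongue = 2L, testis = 2L, ovary = 2L,
    liver = 3L, pancreas = 2L, kidney = 3L, lymph_node = 1L,
    skin = 2L, spleen = 2L, lung = 2L)
}

default_isomir_proportions <- function() {
  c(canonical = 0.463, `3p_templated` = 0.334, polymorphic = 0.112,
    `3p_nontemplated` = 0.060, `5p_templated` = 0.024,
    `5p_nontemplated` = 0.004, mixed_5p3p = 0.003)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults are the
#' study conditions described at the top of this file; when `n_precursors`
#' differs from 271 the expression-class counts scale proportionally and
#' precursors are placed as spaced singletons unless `planted_clusters` /
#' `singletons` are supplied.
#'
#' @param rng_seed integer seed fixing the whole bundle.
#' @param n_precursors number of true precursors.
#' @param tissues named integer vector tissue -> number of replicate samples.
#' @param reads_per_sample total reads per library.
#' @param isomir_proportions named category fractions (must sum to <= 1;
#'   remainder spread over the rare classes).
#' @param arm_ratio share of a precursor's per-tissue reads assigned to its
#'   dominant arm (deterministic rounding, so dominance is noise-free).
#' @param n_switch number of planted arm-switching precursors.
#' @param n_cat_specific number of species-specific precursors.
#' @param n_duplicate_pairs,n_duplicate_triples planted groups of precursors
#'   sharing (near-)identical dominant matures.
#' @param n_decoy_low_score,n_decoy_low_expression,n_decoy_structural decoy
#'   candidates planted for the filter cascade.
#' @param planted_clusters data.frame `chrom`, `size` of planted genomic
#'   clusters (`NULL` = study default when `n_precursors` is 271, else none).
#' @param singletons named integer vector chrom -> singleton count (`NULL` =
#'   derived).
#' @param cluster_intra_gap gap between cluster members (nt, < 10 kb).
#' @param singleton_spacing spacing between independent units (> 10 kb).
#' @param chrom_lengths named chromosome lengths.
#' @param base_reads guaranteed reads per expressed precursor in each sample
#'   of its anchor tissue.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance parameters.
#' @param enriched_mirnas optional data.frame `precursor_index`, `tissue`,
#'   `log2fc` of planted tissue-enriched precursors.
#' @param stem_len,loop_len hairpin geometry passed to
#'   [simulate_precursor()].
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(rng_seed = 101L,
                              n_precursors = 271L,
                              tissues = default_tissues(),
                              reads_per_sample = 50000L,
                              isomir_proportions = default_isomir_proportions(),
                              arm_ratio = 0.75,
                              n_switch = 19L,
                              n_cat_specific = 25L,
                              n_duplicate_pairs = 17L,
                              n_duplicate_triples = 3L,
                              n_decoy_low_score = 804L,
                              n_decoy_low_expression = 105L,
                              n_decoy_structural = 2L,
                              planted_clusters = NULL,
                              singletons = NULL,
                              cluster_intra_gap = 4000L,
                              singleton_spacing = 50000L,
                              chrom_lengths = default_chrom_lengths(),
                              base_reads = 40L,
                              abundance_meanlog = 2,
                              abundance_sdlog = 1.2,
                              enriched_mirnas = NULL,
                              stem_len = 30L, loop_len = 8L) {
  if (sum(isomir_proportions) > 1 + 1e-9)
    stop("isomiR proportions sum to more than 1")
  if (is.null(planted_clusters) && n_precursors == 271L) {
    planted_clusters <- default_planted_clusters()
    if (is.null(singletons)) singletons <- default_singletons()
  }
  if (is.null(planted_clusters))
    planted_clusters <- data.frame(chrom = character(), size = integer())
  if (is.null(singletons)) {
    n_single <- n_precursors - sum(planted_clusters$size)
    auto <- setdiff(names(chrom_lengths),
                    c("chrY", "chrUn_JH409706", "chrC1_JH408690_random"))
    singletons <- table(factor(auto[(seq_len(n_single) - 1) %% length(auto) + 1],
                               levels = auto))
    singletons <- stats::setNames(as.integer(singletons), auto)
  }
  total <- sum(planted_clusters$size) + sum(singletons)
  if (total != n_precursors)
    stop("placement plan covers ", total, " precursors, expected ",
         n_precursors)
  if (cluster_intra_gap >= 10000L) stop("planted intra-cluster gap must be < 10 kb")
  if (singleton_spacing <= 10000L) stop("singleton spacing must exceed 10 kb")
  structure(list(
    rng_seed = as.integer(rng_seed), n_precursors = as.integer(n_precursors),
    tissues = tissues, reads_per_sample = as.integer(reads_per_sample),
    isomir_proportions = isomir_proportions, arm_ratio = arm_ratio,
    n_switch = as.integer(n_switch),
    n_cat_specific = as.integer(n_cat_specific),
    n_duplicate_pairs = as.integer(n_duplicate_pairs),
    n_duplicate_triples = as.integer(n_duplicate_triples),
    n_decoy_low_score = as.integer(n_decoy_low_score),
    n_decoy_low_expression = as.integer(n_decoy_low_expression),
    n_decoy_structural = as.integer(n_decoy_structural),
    planted_clusters = planted_clusters, singletons = singletons,
    cluster_intra_gap = as.integer(cluster_intra_gap),
    singleton_spacing = as.integer(singleton_spacing),
    chrom_lengths = chrom_lengths, base_reads = as.integer(base_reads),
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    enriched_mirnas = enriched_mirnas,
    stem_len = as.integer(stem_len), loop_len = as.integer(loop_len)
  ), class = "simulation_config")
}

#' Simulate one hairpin precursor
#'
#' Builds a stem-loop constructively: a random 5' stem, a loop, and the
#' reverse complement of the stem with at most `n_bulges` substitutions.
#' Mature arms (18-22 nt) are placed inside each stem, at least 3 nt from the
#' hairpin ends so that isomiR end-extensions stay templated within the
#' precursor.
#'
#' @param stem_len stem length (>= 25 nt so a 22-nt mature fits with margin).
#' @param loop_len loop length (>= 4 nt).
#' @param n_bulges number of stem substitutions (default drawn from 0:2).
#' @return list: `hairpin_seq`, `mature5p_seq`, `mature5p_offset`,
#'   `mature3p_seq`, `mature3p_offset` (offsets 0-based).
#' @export
simulate_precursor <- function(stem_len = 30L, loop_len = 8L,
                               n_bulges = NULL) {
  stopifnot(stem_len >= 25L, loop_len >= 4L)
  if (is.null(n_bulges)) n_bulges <- sample(0:2, 1)
  arm5 <- rand_seq(stem_len)
  arm3 <- rc_rna(arm5)
  if (n_bulges > 0) {
    pos <- sample(stem_len, n_bulges)
    v <- strsplit(arm3, "")[[1]]
    v[pos] <- other_base(v[pos])
    arm3 <- paste(v, collapse = "")
  }
  hairpin <- paste0(arm5, rand_seq(loop_len), arm3)
  len5 <- sample(18:22, 1)
  off5 <- sample(3:(stem_len - len5), 1)
  len3 <- sample(18:22, 1)
  off3 <- stem_len + loop_len + sample(0:(stem_len - len3 - 3), 1)
  list(
    hairpin_seq = hairpin,
    mature5p_seq = substr(hairpin, off5 + 1, off5 + len5),
    mature5p_offset = off5,
    mature3p_seq = substr(hairpin, off3 + 1, off3 + len3),
    mature3p_offset = off3
  )
}

#' Simulate genomic coordinates with planted clusters
#'
#' Places the configured clusters (intra-gaps below 10 kb) and singletons
#' (spacing above 10 kb) along the declared chromosomes. Running
#' [find_clusters()] on the output recovers exactly the planted clusters.
#'
#' @param config [simulation_config()].
#' @param hairpin_lengths integer vector of precursor lengths (recycled).
#' @return data.frame: `slot`, `chrom`, `start`, `end`, `strand`,
#'   `cluster_label` (`NA` for singletons).
#' @export
simulate_coordinates <- function(config, hairpin_lengths = 68L) {
  pc <- config$planted_clusters
  singles <- config$singletons
  chroms <- unique(c(pc$chrom, names(singles)[singles > 0]))
  rows <- list()
  slot <- 0L
  cl_id <- 0L
  len <- rep_len(hairpin_lengths, config$n_precursors)
  for (ch in chroms) {
    pos <- 1e6
    sizes <- pc$size[pc$chrom == ch]
    for (sz in sizes) {
      cl_id <- cl_id + 1L
      strand <- sample(c("+", "-"), 1)
      for (m in seq_len(sz)) {
        slot <- slot + 1L
        rows[[slot]] <- data.frame(
          slot = slot, chrom = ch, start = pos, end = pos + len[slot],
          strand = strand, cluster_label = sprintf("planted_%02d", cl_id),
          stringsAsFactors = FALSE)
        pos <- pos + len[slot] + config$cluster_intra_gap
      }
      pos <- pos - config$cluster_intra_gap + config$singleton_spacing
    }
    n_single <- if (ch %in% names(singles)) singles[[ch]] else 0L
    for (m in seq_len(n_single)) {
      slot <- slot + 1L
      rows[[slot]] <- data.frame(
        slot = slot, chrom = ch, start = pos, end = pos + len[slot],
        strand = sample(c("+", "-"), 1), cluster_label = NA_character_,
        stringsAsFactors = FALSE)
      pos <- pos + len[slot] + config$singleton_spacing
    }
    if (pos > config$chrom_lengths[[ch]])
      stop("placements exceed declared length of ", ch)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Largest-remainder apportionment of n into parts proportional to w.
apportion <- function(n, w) {
  raw <- n * w / sum(w)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Simulate the precursor cohort with planted classes
#'
#' Generates the true precursors plus decoys, assigns coordinates, encoding
#' and expression classes, dominance, planted switches, duplicate groups and
#' conservation status.
#'
#' @param config [simulation_config()].
#' @return list with `candidates` (full candidate table incl. decoys),
#'   `plan` (per-true-precursor data.frame of planted classes), and
#'   `coords` (placement table).
#' @export
simulate_cohort <- function(config) {
  n <- config$n_precursors
  coords <- simulate_coordinates(config)
  ids <- sprintf("cand_%04d", seq_len(n))

  # expression classes: study table at n = 271, proportional otherwise
  if (n == 271L) {
    n_both <- 201L; n_5only <- 27L; n_3only <- 43L
    n_both_encoded <- 204L
  } else {
    parts <- apportion(n, c(201, 27, 43))
    n_both <- parts[1]; n_5only <- parts[2]; n_3only <- parts[3]
    n_both_encoded <- n_both
  }
  cls <- sample(c(rep("both", n_both), rep("5p_only", n_5only),
                  rep("3p_only", n_3only)))
  # encoded arms: some single-expressed precursors may still encode both arms
  encode_both <- cls == "both"
  extra_both <- n_both_encoded - sum(encode_both)
  if (extra_both > 0) {
    pool <- which(!encode_both)
    encode_both[pool[seq_len(extra_both)]] <- TRUE
  }

  # overall dominant arm: forced for single-arm precursors; 53%/47% split of
  # the 271 overall among the rest
  dominant <- ifelse(cls == "5p_only", "5p",
                     ifelse(cls == "3p_only", "3p", NA))
  free <- which(is.na(dominant))
  n_dom5_total <- apportion(n, c(53, 47))[1]
  n_dom5_free <- max(0L, min(length(free), n_dom5_total - sum(dominant == "5p",
                                                              na.rm = TRUE)))
  pick5 <- sample(free, n_dom5_free)
  dominant[pick5] <- "5p"
  dominant[setdiff(free, pick5)] <- "3p"

  # planted arm switches among both-expressed precursors
  switch_idx <- sample(which(cls == "both"), config$n_switch)
  tissue_names <- names(config$tissues)
  flip_tissue <- stats::setNames(rep(NA_character_, n), ids)
  flip_tissue[switch_idx] <- sample(tissue_names, length(switch_idx),
                                    replace = TRUE)

  # species-specific set, honoring the placement plan when it is the study one
  cat_specific <- rep(FALSE, n)
  if (config$n_cat_specific > 0) {
    if (n == 271L && nrow(config$planted_clusters) == 31L) {
      pick <- integer(0)
      pick <- c(pick, which(coords$chrom == "chrE3" &
                              is.na(coords$cluster_label))[1:6])
      xpair <- which(coords$cluster_label == "planted_16")   # 2-member X pair
      pick <- c(pick, xpair)
      a2 <- which(coords$cluster_label == "planted_05")      # A2 pair, 2nd gene
      pick <- c(pick, a2[2])
      singles_on <- function(ch, k) {
        utils::head(which(coords$chrom == ch & is.na(coords$cluster_label)), k)
      }
      pick <- c(pick, singles_on("chrA2", 2), singles_on("chrA3", 2),
                singles_on("chrB1", 1), singles_on("chrB2", 1),
                singles_on("chrB4", 2), singles_on("chrC1", 1),
                singles_on("chrC2", 2), singles_on("chrD4", 1),
                singles_on("chrE1", 1), singles_on("chrE2", 1),
                utils::tail(which(coords$chrom == "chrX" &
                                    is.na(coords$cluster_label)), 2))
      cat_specific[unique(pick)[seq_len(config$n_cat_specific)]] <- TRUE
    } else {
      cat_specific[sample(n, min(config$n_cat_specific, n))] <- TRUE
    }
  }

  # duplicate groups: conserved, both-expressed, non-switching precursors
  pool <- which(cls == "both" & !cat_specific & !(seq_len(n) %in% switch_idx))
  sizes <- c(rep(2L, config$n_duplicate_pairs),
             rep(3L, config$n_duplicate_triples))
  dup_group <- rep(NA_integer_, n)
  if (length(sizes) && sum(sizes) <= length(pool)) {
    chosen <- sample(pool, sum(sizes))
    dup_group[chosen] <- rep(seq_along(sizes), times = sizes)
    # members of a group share the dominant product; compensate every forced
    # dominance flip on a free precursor so the 5p/3p split is preserved
    for (g in seq_along(sizes)) {
      mem <- which(dup_group == g)
      for (m in mem[-1]) {
        if (dominant[m] != dominant[mem[1]]) {
          free <- which(cls == "both" & is.na(dup_group) &
                          dominant == dominant[mem[1]])
          if (length(free))
            dominant[free[1]] <- dominant[m]
          dominant[m] <- dominant[mem[1]]
        }
      }
    }
  }

  # hairpins; duplicate-group members reuse the leader's layout
  prec <- vector("list", n)
  for (i in seq_len(n)) prec[[i]] <- simulate_precursor(config$stem_len,
                                                        config$loop_len)
  similar_pairs <- integer(0)
  if (any(!is.na(dup_group))) {
    for (g in unique(stats::na.omit(dup_group))) {
      mem <- which(dup_group == g)
      for (m in mem[-1]) prec[[m]] <- prec[[mem[1]]]
    }
    # a third of the pairs carry a 1-nt change in the dominant mature
    pair_groups <- which(sizes == 2L)
    similar_pairs <- utils::head(pair_groups, ceiling(length(pair_groups) / 3))
    for (g in similar_pairs) {
      m <- which(dup_group == g)[2]
      arm <- dominant[m]
      offcol <- paste0("mature", arm, "_offset")
      seqcol <- paste0("mature", arm, "_seq")
      p <- prec[[m]]
      pos <- p[[offcol]] + 12L                       # 1-based hairpin position
      v <- strsplit(p$hairpin_seq, "")[[1]]
      v[pos] <- other_base(v[pos])
      p$hairpin_seq <- paste(v, collapse = "")
      p$mature5p_seq <- substr(p$hairpin_seq, p$mature5p_offset + 1,
                               p$mature5p_offset + nchar(p$mature5p_seq))
      p$mature3p_seq <- substr(p$hairpin_seq, p$mature3p_offset + 1,
                               p$mature3p_offset + nchar(p$mature3p_seq))
      prec[[m]] <- p
    }
  }

  # ortholog stems for conserved precursors; duplicate groups share a stem
  stem <- rep(NA_character_, n)
  cons <- !cat_specific
  stem[cons] <- sprintf("mir-%d", 100 + seq_len(sum(cons)))
  if (any(!is.na(dup_group))) {
    for (g in unique(stats::na.omit(dup_group))) {
      mem <- which(dup_group == g)
      stem[mem] <- sprintf("mir-%d", 700 + g)
    }
  }

  plan <- data.frame(
    precursor_id = ids,
    chrom = coords$chrom, start = coords$start, end = coords$end,
    strand = coords$strand, cluster_label = coords$cluster_label,
    expressed = cls, encode_both = encode_both, dominant = dominant,
    is_switch = seq_len(n) %in% switch_idx, flip_tissue = unname(flip_tissue),
    cat_specific = cat_specific, dup_group = dup_group, stem = stem,
    stringsAsFactors = FALSE
  )

  make_row <- function(id, p, score, chrom, start, end, strand,
                       keep5 = TRUE, keep3 = TRUE) {
    data.frame(
      id = id, chrom = chrom, start = start, end = end, strand = strand,
      score = score, hairpin_seq = p$hairpin_seq,
      mature5p_seq = if (keep5) p$mature5p_seq else NA_character_,
      mature5p_offset = if (keep5) p$mature5p_offset else NA_integer_,
      mature3p_seq = if (keep3) p$mature3p_seq else NA_character_,
      mature3p_offset = if (keep3) p$mature3p_offset else NA_integer_,
      stringsAsFactors = FALSE
    )
  }

  good <- do.call(rbind, lapply(seq_len(n), function(i) {
    keep5 <- encode_both[i] || cls[i] == "5p_only"
    keep3 <- encode_both[i] || cls[i] == "3p_only"
    make_row(ids[i], prec[[i]], round(stats::runif(1, 5.1, 60), 1),
             coords$chrom[i], coords$start[i], coords$end[i],
             coords$strand[i], keep5, keep3)
  }))

  decoy <- function(prefix, k, score_lo, score_hi, base_pos) {
    if (k == 0) return(NULL)
    do.call(rbind, lapply(seq_len(k), function(j) {
      p <- simulate_precursor(config$stem_len, config$loop_len)
      make_row(sprintf("%s_%03d", prefix, j), p,
               round(stats::runif(1, score_lo, score_hi), 1),
               "chrB1", base_pos + (j - 1) * 50000L,
               base_pos + (j - 1) * 50000L + nchar(p$hairpin_seq), "+")
    }))
  }
  decoys <- rbind(
    decoy("decoyLS", config$n_decoy_low_score, 0.1, 4.9, 120e6),
    decoy("decoyLE", config$n_decoy_low_expression, 5.1, 30, 165e6),
    decoy("decoyRNA", config$n_decoy_structural, 5.1, 30, 175e6)
  )
  candidates <- rbind(good, decoys)
  rownames(candidates) <- NULL
  list(candidates = validate_candidates(candidates), plan = plan,
       coords = coords, similar_pairs = similar_pairs)
}

# Variant templates for one isomiR category of one mature.
isomir_variants <- function(category, hairpin, off, len) {
  canon <- substr(hairpin, off + 1, off + len)
  H <- nchar(hairpin)
  switch(category,
    canonical = canon,
    `5p_templated` = c(
      substr(hairpin, off, off + len),        # +1 templated extension
      substr(hairpin, off - 1, off + len),    # +2
      substr(hairpin, off + 2, off + len)     # 1-nt trim
    ),
    `3p_templated` = c(
      substr(hairpin, off + 1, off + len + 1),
      substr(hairpin, off + 1, off + len + 2),
      substr(hairpin, off + 1, off + len - 1),
      substr(hairpin, off + 1, off + len - 2)
    ),
    `5p_nontemplated` = {
      tmpl <- substr(hairpin, off, off)
      paste0(other_base(tmpl), canon)
    },
    `3p_nontemplated` = {
      tmpl <- substr(hairpin, off + len + 1, off + len + 1)
      paste0(canon, other_base(tmpl))
    },
    polymorphic = {
      v <- strsplit(canon, "")[[1]]
      v[10] <- other_base(v[10])
      paste(v, collapse = "")
    },
    mixed_5p3p = substr(hairpin, off, off + len + 1),  # both ends templated
    stop("unknown category ", category)
  )
}

#' Simulate per-sample read stacks
#'
#' Per sample, `reads_per_sample` reads are allocated: a guaranteed base in
#' each precursor's anchor tissue (and flip tissue for planted switchers),
#' small fixed counts for low-expression decoys, and the remainder by a
#' multinomial over log-normal precursor abundances (times planted
#' tissue-enrichment factors). Reads are split between arms by deterministic
#' rounding of `arm_ratio` toward the tissue's dominant arm (flipped in the
#' planted switch tissue), then drawn across isomiR categories
#' multinomially and mutated accordingly.
#'
#' @param config [simulation_config()].
#' @param cohort output of [simulate_cohort()].
#' @return list: `reads` (data.frame `sample`, `precursor_id`, `arm`,
#'   `category`, `read_seq`, `count`), `counts` (mature x sample matrix),
#'   `tissue_of` (named vector), `truth` (per-read-category bookkeeping).
#' @export
simulate_reads <- function(config, cohort) {
  plan <- cohort$plan
  cand <- cohort$candidates
  n <- nrow(plan)
  tissues <- config$tissues
  samples <- unlist(lapply(names(tissues), function(t)
    paste0(t, "_", seq_len(tissues[[t]]))))
  tissue_of <- stats::setNames(rep(names(tissues), tissues), samples)

  prop <- config$isomir_proportions
  rest <- 1 - sum(prop)
  if (rest > 1e-9) {
    # remainder goes to the rare classes, never to the named categories
    rare <- c("5p_nontemplated", "mixed_5p3p")
    for (r in rare) if (!(r %in% names(prop))) prop[r] <- 0
    prop[rare] <- prop[rare] + rest / length(rare)
  }
  prop <- prop / sum(prop)

  anchor <- stats::setNames(names(tissues)[(seq_len(n) - 1) %% length(tissues) + 1],
                            plan$precursor_id)
  weights <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  names(weights) <- plan$precursor_id

  enr <- config$enriched_mirnas
  le_ids <- cand$id[grepl("^decoyLE_", cand$id)]
  le_sample <- stats::setNames(sample(samples, length(le_ids), replace = TRUE),
                               le_ids)
  rna_ids <- cand$id[grepl("^decoyRNA_", cand$id)]

  cand_idx <- stats::setNames(seq_len(nrow(cand)), cand$id)
  variant_cache <- new.env(parent = emptyenv())
  get_variants <- function(pid, arm, category) {
    key <- paste(pid, arm, category, sep = "\r")
    if (!is.null(variant_cache[[key]])) return(variant_cache[[key]])
    i <- cand_idx[[pid]]
    off <- cand[[paste0("mature", arm, "_offset")]][i]
    len <- nchar(cand[[paste0("mature", arm, "_seq")]][i])
    v <- isomir_variants(category, cand$hairpin_seq[i], off, len)
    variant_cache[[key]] <- v
    v
  }

  expressed_ids <- c(plan$precursor_id, rna_ids)
  rows <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    smp <- samples[si]
    tis <- tissue_of[[smp]]
    # committed base counts
    base <- integer(length(expressed_ids))
    names(base) <- expressed_ids
    in_anchor <- anchor[plan$precursor_id] == tis
    base[plan$precursor_id[in_anchor]] <- config$base_reads
    flips <- plan$is_switch & !is.na(plan$flip_tissue) & plan$flip_tissue == tis
    base[plan$precursor_id[flips]] <-
      pmax(base[plan$precursor_id[flips]], config$base_reads)
    base[rna_ids] <- config$base_reads   # structural decoys pass expression
    le_here <- names(le_sample)[le_sample == smp]
    le_counts <- stats::setNames(rep(9L, length(le_here)), le_here)

    n_rest <- config$reads_per_sample - sum(base) - sum(le_counts)
    if (n_rest < 0) stop("reads_per_sample too small for base allocation")
    w <- c(weights, stats::setNames(rep(mean(weights), length(rna_ids)),
                                    rna_ids))
    if (!is.null(enr) && nrow(enr)) {
      for (k in seq_len(nrow(enr))) {
        if (enr$tissue[k] == tis) {
          pid <- plan$precursor_id[enr$precursor_index[k]]
          w[pid] <- w[pid] * 2^enr$log2fc[k]
        }
      }
    }
    extra <- stats::rmultinom(1, n_rest, w[expressed_ids])[, 1]
    totals <- base + extra

    srows <- list()
    for (pid in expressed_ids) {
      ntot <- totals[[pid]]
      if (pid %in% names(le_counts)) ntot <- 0L   # decoyLE handled below
      if (ntot == 0 && !(pid %in% le_here)) next
      i <- cand_idx[[pid]]
      is_true <- !grepl("^decoy", pid)
      if (is_true) {
        j <- match(pid, plan$precursor_id)
        cls <- plan$expressed[j]
        dom <- plan$dominant[j]
        if (plan$is_switch[j] && !is.na(plan$flip_tissue[j]) &&
            plan$flip_tissue[j] == tis)
          dom <- if (dom == "5p") "3p" else "5p"
        alloc <- if (cls == "both") {
          d <- as.integer(round(config$arm_ratio * ntot))
          stats::setNames(c(d, ntot - d), c(dom, setdiff(c("5p", "3p"), dom)))
        } else {
          stats::setNames(ntot, substr(cls, 1, 2))
        }
      } else {
        alloc <- stats::setNames(ntot, "5p")
      }
      for (arm in names(alloc)) {
        n_arm <- alloc[[arm]]
        if (n_arm == 0) next
        if (is.na(cand[[paste0("mature", arm, "_seq")]][i])) next
        catn <- stats::rmultinom(1, n_arm, prop)[, 1]
        for (category in names(catn)[catn > 0]) {
          v <- get_variants(pid, arm, category)
          vn <- if (length(v) == 1) stats::setNames(catn[[category]], v)
                else stats::setNames(
                  stats::rmultinom(1, catn[[category]],
                                   rep(1, length(v)))[, 1], v)
          vn <- vn[vn > 0]
          srows[[length(srows) + 1L]] <- data.frame(
            sample = smp, precursor_id = pid, arm = arm,
            category = category, read_seq = names(vn),
            count = as.integer(vn), stringsAsFactors = FALSE)
        }
      }
    }
    for (pid in le_here) {
      srows[[length(srows) + 1L]] <- data.frame(
        sample = smp, precursor_id = pid, arm = "5p", category = "canonical",
        read_seq = cand$mature5p_seq[cand_idx[[pid]]],
        count = le_counts[[pid]], stringsAsFactors = FALSE)
    }
    rows[[si]] <- do.call(rbind, srows)
  }
  reads <- do.call(rbind, rows)
  rownames(reads) <- NULL

  # mature x sample count matrix (isomiRs included in their mature's count)
  mid <- paste0(reads$precursor_id, "-", reads$arm)
  counts_tab <- tapply(reads$count, list(mid, reads$sample), sum, default = 0L)
  counts <- matrix(0L, nrow(counts_tab), length(samples),
                   dimnames = list(rownames(counts_tab), samples))
  counts[, colnames(counts_tab)] <- counts_tab
  storage.mode(counts) <- "integer"

  list(reads = reads, counts = counts, tissue_of = tissue_of,
       truth = list(anchor_tissue = anchor,
                    isomir_proportions = prop,
                    weights = weights))
}

# Planted missed-family recovery tables mirroring the study accounting:
# 268 eligible families holding 515 genes; 214 genes detected (198 families),
# 16 missed genes in detected families, 18 families recoverable from genomic
# evidence only (124 genes with qualifying mature-probe hits, 164 qualifying
# matures, 33 genes with precursor-level evidence), 52 families absent.
simulate_recovery_tables <- function() {
  fam <- sprintf("fam_%03d", 1:268)
  genes <- list(); detected <- character(); probe_meta <- list()
  hits <- list(); gid <- 0L
  add_gene <- function(f) {
    gid <<- gid + 1L
    g <- sprintf("gene_%03d", gid)
    genes[[gid]] <<- data.frame(family = f, gene = g, n_species = 8L,
                                has_human = TRUE, stringsAsFactors = FALSE)
    g
  }
  add_probe <- function(g, type, len, qualify, second = FALSE) {
    pid <- paste0(g, if (type == "mature") "_m" else "_p",
                  if (second) "2" else "")
    probe_meta[[length(probe_meta) + 1L]] <<- data.frame(
      probe_id = pid, gene = g, type = type, length = len,
      stringsAsFactors = FALSE)
    if (!is.na(qualify)) {
      if (type == "mature") {
        h <- data.frame(query_id = pid, subject_id = "chrA1",
                        pct_identity = if (qualify) 100 else 90,
                        align_length = if (qualify) len else len - 4L,
                        mismatches = if (qualify) 0L else 2L,
                        gap_opens = 0L,
                        q_start = 1L, q_end = if (qualify) len else len - 4L,
                        s_start = 5000L, s_end = 5000L + len,
                        evalue = 1e-4, bitscore = 40,
                        stringsAsFactors = FALSE)
      } else {
        al <- if (qualify) as.integer(ceiling(0.8 * len)) else
          as.integer(floor(0.5 * len))
        h <- data.frame(query_id = pid, subject_id = "chrA1",
                        pct_identity = 95, align_length = al,
                        mismatches = 1L, gap_opens = 0L,
                        q_start = 1L, q_end = al,
                        s_start = 9000L, s_end = 9000L + al,
                        evalue = 1e-6, bitscore = 60,
                        stringsAsFactors = FALSE)
      }
      hits[[length(hits) + 1L]] <<- h
    }
  }
  # 182 detected families with 1 detected gene, 16 with 2 (214 detected genes)
  for (k in 1:198) {
    f <- fam[k]
    detected <- c(detected, add_gene(f))
    if (k <= 16) detected <- c(detected, add_gene(f))
  }
  # 16 missed genes inside the first 16 detected families
  for (k in 1:16) add_gene(fam[k])
  # 106 evidence genes inside detected families (spread over families 17..)
  for (k in 1:106) {
    g <- add_gene(fam[16 + ((k - 1) %% 182) + 1])
    add_probe(g, "mature", 22L, qualify = TRUE)
    if (k <= 40) add_probe(g, "mature", 22L, qualify = TRUE, second = TRUE)
    if (k <= 25) add_probe(g, "precursor", 90L, qualify = TRUE)
  }
  # 18 families recoverable only from genomic evidence
  for (k in 199:216) {
    g <- add_gene(fam[k])
    add_probe(g, "mature", 22L, qualify = TRUE)
    if (k <= 206) add_probe(g, "precursor", 90L, qualify = TRUE)
  }
  # 52 absent families with 161 genes total and only failing probes
  for (k in 1:161) {
    g <- add_gene(fam[216 + ((k - 1) %% 52) + 1])
    add_probe(g, "mature", 22L, qualify = if (k <= 60) FALSE else NA)
    if (k <= 20) add_probe(g, "precursor", 90L, qualify = FALSE)
  }
  list(
    family_table = do.call(rbind, genes),
    detected_genes = detected,
    probe_meta = do.call(rbind, probe_meta),
    probe_hits = do.call(rbind, hits)
  )
}

# Synthetic miRBase-style hairpin hits encoding the planted conservation.
simulate_mirbase_hits <- function(config, cohort) {
  plan <- cohort$plan
  species_pool <- c("hsa", "bta", "cfa", "mmu", "rno", "ssc", "eca", "ocu",
                    "gga", "mml", "ptr", "oar", "chi", "cgr", "mdo", "aja",
                    "efu", "pal", "dno", "tch")
  species_w <- c(5, 4, 4, 3, 3, 2, 2, rep(1, 13))
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    pid <- plan$precursor_id[i]
    if (!plan$cat_specific[i]) {
      n_orth <- 1L + stats::rpois(1, 31)
      sp <- c("hsa", sample(species_pool, n_orth - 1, replace = TRUE,
                            prob = species_w))
      subj <- paste0(sp, "-", plan$stem[i])
      dup <- duplicated(subj)
      subj[dup] <- paste0(subj[dup], "-", cumsum(dup)[dup] + 1)
      ev <- c(10^stats::runif(1, -30, -12),
              10^stats::runif(n_orth - 1, -11, -5.2))
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = pid, subject_id = subj,
        pct_identity = round(stats::runif(n_orth, 85, 100), 1),
        align_length = 60L, mismatches = 2L, gap_opens = 0L,
        q_start = 1L, q_end = 60L, s_start = 1L, s_end = 60L,
        evalue = ev, bitscore = round(-10 * log10(ev) + 30, 1),
        stringsAsFactors = FALSE)
    } else if (i %% 2 == 0) {
      # weak, non-qualifying similarity for about half the specific set
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = pid, subject_id = paste0("hsa-mir-", 9000 + i),
        pct_identity = 72, align_length = 30L, mismatches = 8L,
        gap_opens = 1L, q_start = 10L, q_end = 39L, s_start = 4L,
        s_end = 33L, evalue = 10^stats::runif(1, -4.5, -0.5),
        bitscore = 28, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Genome self-hits for every candidate plus planted repetitive loci for the
# first structural decoy; structural-RNA hits for the structural decoys.
simulate_screen_hits <- function(cohort) {
  cand <- cohort$candidates
  self <- data.frame(
    query_id = cand$id, subject_id = cand$chrom,
    pct_identity = 100, align_length = nchar(cand$hairpin_seq),
    mismatches = 0L, gap_opens = 0L,
    q_start = 1L, q_end = nchar(cand$hairpin_seq),
    s_start = cand$start + 1L, s_end = cand$end,
    evalue = 1e-40, bitscore = 130, stringsAsFactors = FALSE)
  rna_ids <- cand$id[grepl("^decoyRNA_", cand$id)]
  rep_hits <- NULL
  if (length(rna_ids)) {
    rep_hits <- do.call(rbind, lapply(1:7, function(k) {
      data.frame(query_id = rna_ids[1], subject_id = "chrB2",
                 pct_identity = 96, align_length = 60L, mismatches = 2L,
                 gap_opens = 0L, q_start = 1L, q_end = 60L,
                 s_start = k * 2e6L, s_end = k * 2e6L + 60L,
                 evalue = 1e-12, bitscore = 90, stringsAsFactors = FALSE)
    }))
  }
  ncrna <- NULL
  if (length(rna_ids)) {
    ncrna <- data.frame(
      query_id = rna_ids, subject_id = "rRNA_LSU_0001",
      pct_identity = 99, align_length = 60L, mismatches = 0L, gap_opens = 0L,
      q_start = 1L, q_end = 60L, s_start = 1200L, s_end = 1260L,
      evalue = 1e-25, bitscore = 110, stringsAsFactors = FALSE)
  }
  genome <- rbind(self, rep_hits)
  rownames(genome) <- NULL
  list(genome_hits = genome,
       ncrna_hits = if (is.null(ncrna)) empty_hits() else ncrna)
}

# Ortholog chromosome assignments for cluster-conservation scoring: members
# of a planted cluster agree within human and dog; species-specific members
# are unmapped.
simulate_ortholog_locations <- function(cohort) {
  plan <- cohort$plan
  rows <- list()
  labels <- unique(stats::na.omit(plan$cluster_label))
  hsa_chr <- stats::setNames(paste0("chr", sample(c(1:22, "X"),
                                                  length(labels),
                                                  replace = TRUE)), labels)
  cfa_chr <- stats::setNames(paste0("chr", sample(c(1:38, "X"),
                                                  length(labels),
                                                  replace = TRUE)), labels)
  for (i in seq_len(nrow(plan))) {
    if (plan$cat_specific[i]) next
    lab <- plan$cluster_label[i]
    h <- if (!is.na(lab)) hsa_chr[[lab]] else
      paste0("chr", sample(c(1:22, "X"), 1))
    d <- if (!is.na(lab)) cfa_chr[[lab]] else
      paste0("chr", sample(c(1:38, "X"), 1))
    rows[[length(rows) + 1L]] <- data.frame(
      precursor_id = plan$precursor_id[i],
      species = c("hsa", "cfa"), chrom = c(h, d), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Family index: seeds of conserved dominant matures map to their stem; most
# species-specific matures also carry a conserved seed.
simulate_family_index <- function(cohort, seed_conserved_frac = 28 / 33) {
  plan <- cohort$plan
  cand <- cohort$candidates
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    j <- match(plan$precursor_id[i], cand$id)
    for (arm in c("5p", "3p")) {
      sq <- cand[[paste0("mature", arm, "_seq")]][j]
      if (is.na(sq)) next
      if (!plan$cat_specific[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          seed = extract_seed(sq), family = plan$stem[i],
          stringsAsFactors = FALSE)
      } else if (stats::runif(1) < seed_conserved_frac) {
        rows[[length(rows) + 1L]] <- data.frame(
          seed = extract_seed(sq), family = sprintf("mir-f%03d", i),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# UTR set with planted canonical seed sites for species-specific matures.
simulate_utrs <- function(cohort, n_utrs = 40L, utr_len = c(300L, 800L),
                          n_target_mirnas = 10L) {
  plan <- cohort$plan
  cand <- cohort$candidates
  spec <- plan$precursor_id[plan$cat_specific]
  matures <- list()
  for (pid in spec) {
    j <- match(pid, cand$id)
    for (arm in c("5p", "3p")) {
      sq <- cand[[paste0("mature", arm, "_seq")]][j]
      if (!is.na(sq)) matures[[paste0(pid, "-", arm)]] <- sq
    }
  }
  matures <- matures[seq_len(min(n_target_mirnas, length(matures)))]
  utrs <- stats::setNames(
    vapply(seq_len(n_utrs),
           function(i) rand_seq(sample(utr_len[1]:utr_len[2], 1)),
           character(1)),
    sprintf("utr_%03d", seq_len(n_utrs)))
  planted <- list()
  types <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
  for (m in names(matures)) {
    seq <- matures[[m]]
    core <- rc_rna(substr(seq, 2, 7))
    m8c <- rc_rna(substr(seq, 8, 8))
    not_m8 <- sample(setdiff(RNA_BASES, m8c), 1)
    for (ty in types) {
      site <- switch(ty,
        "6mer" = paste0(not_m8, core, sample(setdiff(RNA_BASES, "A"), 1)),
        "7mer-A1" = paste0(not_m8, core, "A"),
        "7mer-m8" = paste0(m8c, core, sample(setdiff(RNA_BASES, "A"), 1)),
        "8mer" = paste0(m8c, core, "A"))
      u <- sample(names(utrs), 1)
      s <- utrs[[u]]
      ins <- sample(seq_len(nchar(s) - 20), 1)
      utrs[[u]] <- paste0(substr(s, 1, ins), site,
                          substr(s, ins + 1, nchar(s)))
      # 0-based site start: guard base occupies position ins (0-based), the
      # reported site starts at the core for 6mer/7mer-A1, one base earlier
      # for m8-anchored types
      pos0 <- if (ty %in% c("7mer-m8", "8mer")) ins else ins + 1L
      planted[[length(planted) + 1L]] <- data.frame(
        mirna_id = m, utr_id = u, site_type = ty, utr_position = pos0,
        stringsAsFactors = FALSE)
    }
  }
  list(matures = unlist(matures), utrs = utrs,
       planted_sites = do.call(rbind, planted))
}

#' Write a complete synthetic fixture bundle
#'
#' Generates the full cohort under `config$rng_seed` and writes every
#' pipeline input plus a ground-truth JSON to `dir`. Two runs with equal
#' seeds produce byte-identical bundles. On failure, partially written
#' output is removed.
#'
#' @param config [simulation_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written file paths.
#' @export
write_fixtures <- function(config, dir) {
  created <- !dir.exists(dir)
  if (created) dir.create(dir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(dir, recursive = TRUE), add = TRUE)

  set.seed(config$rng_seed)
  cohort <- simulate_cohort(config)
  sim <- simulate_reads(config, cohort)
  mh <- simulate_mirbase_hits(config, cohort)
  sh <- simulate_screen_hits(cohort)
  ol <- simulate_ortholog_locations(cohort)
  fi <- simulate_family_index(cohort)
  ut <- simulate_utrs(cohort)
  rec <- simulate_recovery_tables()
  # permuted-genome control scores, scaled with the bundle so the 5-score
  # threshold is the lowest one beating the 10:1 signal-to-noise rule
  n_sig5 <- sum(cohort$candidates$score >= 5)
  ctl_at5 <- max(1L, floor(n_sig5 / 21))
  ctl_at10 <- floor(ctl_at5 / 9)
  ctl_below5 <- max(5L, round(nrow(cohort$candidates) * 582 / 1182))
  bins <- score_bins_from_scores(
    cohort$candidates$score,
    control_scores = c(stats::runif(ctl_below5, 0, 4.9),
                       stats::runif(ctl_at5 - ctl_at10, 5.1, 9.9),
                       stats::runif(ctl_at10, 10.1, 20)),
    thresholds = 0:10)

  p <- function(f) file.path(dir, f)
  write_candidates(cohort$candidates, p("candidates.tsv"))
  good <- cohort$candidates[!grepl("^decoy", cohort$candidates$id), ,
                            drop = FALSE]
  write_bed(data.frame(chrom = good$chrom, start = good$start,
                       end = good$end, name = good$id, score = 0,
                       strand = good$strand), p("precursors.bed"))
  utils::write.table(sim$reads[c("sample", "precursor_id", "read_seq",
                                 "count")],
                     p("reads.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_counts(sim$counts, p("counts.tsv"))
  write_sample_map(sim$tissue_of, p("sample_map.tsv"))
  utils::write.table(as.data.frame(unclass(bins)), p("score_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_hit_table(mh, p("mirbase_hits.tsv"))
  write_hit_table(sh$genome_hits, p("genome_hits.tsv"))
  write_hit_table(sh$ncrna_hits, p("ncrna_hits.tsv"))
  utils::write.table(ol, p("ortholog_locations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fi, p("family_index.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_fasta(ut$utrs, p("utrs.fasta"))
  write_fasta(ut$matures, p("specific_matures.fasta"))
  utils::write.table(rec$family_table, p("recovery_family_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rec$probe_meta, p("recovery_probe_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_hit_table(rec$probe_hits, p("recovery_probe_hits.tsv"))
  writeLines(rec$detected_genes, p("recovery_detected_genes.txt"))

  truth <- list(
    n_precursors = config$n_precursors,
    plan = cohort$plan,
    planted_sites = ut$planted_sites,
    isomir_proportions = as.list(sim$truth$isomir_proportions),
    anchor_tissue = as.list(sim$truth$anchor_tissue),
    similar_pairs = cohort$similar_pairs
  )
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  ok <- TRUE
  invisible(list.files(dir, full.names = TRUE))
}
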