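# Independent brute-force oracles used to check the package implementations.

# Union-find over the pairwise "same chrom+strand, gap < max_gap" relation.
oracle_clusters <- function(iv, max_gap = 10000) {
  n <- nrow(iv)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (iv$chrom[i] == iv$chrom[j] && iv$strand[i] == iv$strand[j]) {
          gap <- max(iv$start[i], iv$start[j]) - min(iv$end[i], iv$end[j])
          if (gap < max_gap) parent[find(i)] <- find(j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(iv$precursor_id, roots)
  comps <- comps[vapply(comps, length, integer(1)) >= 2]
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, character(1), 1))]
}

cluster_membership <- function(clusters_df) {
  comps <- lapply(split(clusters_df$precursor_id, clusters_df$cluster_id),
                  sort)
  unname(comps[order(vapply(comps, `[`, character(1), 1))])
}

random_interval_set <- function(n_max = 50) {
  n <- sample(2:n_max, 1)
  data.frame(
    precursor_id = sprintf("p%03d", seq_len(n)),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = st <- sample.int(200000, n, replace = TRUE),
    end = st + sample(50:150, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

rc_rna_oracle <- function(x) {
  chartr("ACGU", "UGCA",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Naive canonical-site enumerator: tests all four definitions at every UTR
# offset, then keeps the strongest type per 6mer-core locus.
oracle_sites <- function(mature, utr) {
  n <- nchar(utr)
  core <- rc_rna_oracle(substr(mature, 2, 7))
  site7m8 <- rc_rna_oracle(substr(mature, 2, 8))
  site8 <- paste0(site7m8, "A")
  site7a1 <- paste0(core, "A")
  out <- list()
  for (c0 in seq_len(max(0, n - 5))) {           # 1-based core start
    if (substr(utr, c0, c0 + 5) != core) next
    if (c0 > 1 && substr(utr, c0 - 1, c0 + 6) == site8) {
      out[[length(out) + 1L]] <- list(type = "8mer", pos = c0 - 2L)
    } else if (c0 > 1 && substr(utr, c0 - 1, c0 + 5) == site7m8) {
      out[[length(out) + 1L]] <- list(type = "7mer-m8", pos = c0 - 2L)
    } else if (substr(utr, c0, c0 + 6) == site7a1) {
      out[[length(out) + 1L]] <- list(type = "7mer-A1", pos = c0 - 1L)
    } else {
      out[[length(out) + 1L]] <- list(type = "6mer", pos = c0 - 1L)
    }
  }
  df <- data.frame(
    site_type = vapply(out, `[[`, character(1), "type"),
    utr_position = vapply(out, `[[`, integer(1), "pos"),
    stringsAsFactors = FALSE
  )
  df[order(df$utr_position), , drop = FALSE]
}

# Exhaustive threshold scan oracle.
oracle_threshold <- function(bins, min_snr) {
  best <- NULL
  for (i in seq_len(nrow(bins))) {
    s <- bins$n_signal[i]
    c <- bins$n_control[i]
    snr <- if (c == 0) (if (s > 0) Inf else NaN) else s / c
    if (!is.nan(snr) && snr > min_snr) {
      if (is.null(best) || bins$threshold[i] < best) best <- bins$threshold[i]
    }
  }
  best
}

random_score_bins <- function() {
  k <- sample(2:8, 1)
  thr <- sort(sample.int(100, k))
  sig <- sort(sample.int(500, k), decreasing = TRUE)
  ctl <- sort(sample.int(200, k), decreasing = TRUE) - sample(0:1, 1)
  ctl[ctl < 0] <- 0
  score_bins(thr, sig, ctl)
}

# Naive arm summary recomputation.
oracle_arm_summary <- function(usage, presence_min_reads = 1L) {
  ids <- unique(usage$precursor_id)
  n_both <- n5 <- n3 <- 0L
  dom5 <- dom3 <- 0L
  for (id in ids) {
    u <- usage[usage$precursor_id == id, ]
    a5 <- any(u$reads5p >= presence_min_reads)
    a3 <- any(u$reads3p >= presence_min_reads)
    if (a5 && a3) n_both <- n_both + 1L
    else if (a5) n5 <- n5 + 1L
    else if (a3) n3 <- n3 + 1L
    t5 <- sum(u$reads5p); t3 <- sum(u$reads3p)
    if (t5 > t3) dom5 <- dom5 + 1L
    else if (t3 > t5 && t3 > 0) dom3 <- dom3 + 1L
  }
  list(n_both = n_both, n_5p_only = n5, n_3p_only = n3,
       frac5 = dom5 / (dom5 + dom3), frac3 = dom3 / (dom5 + dom3))
}

random_usage <- function(n_prec = 20, n_tissue = 5) {
  grid <- expand.grid(precursor_id = sprintf("p%02d", seq_len(n_prec)),
                      tissue = paste0("t", seq_len(n_tissue)),
                      stringsAsFactors = FALSE)
  grid$reads5p <- stats::rpois(nrow(grid), 8) *
    stats::rbinom(nrow(grid), 1, 0.7)
  grid$reads3p <- stats::rpois(nrow(grid), 8) *
    stats::rbinom(nrow(grid), 1, 0.7)
  grid$dominant <- ifelse(grid$reads5p == 0 & grid$reads3p == 0, "none",
                          ifelse(grid$reads5p > grid$reads3p, "5p",
                                 ifelse(grid$reads3p > grid$reads5p, "3p",
                                        "tie")))
  grid
}

# Small deterministic candidate set for filter/conservation tests.
tiny_candidates <- function() {
  hp1 <- "ACGUACGUACGUACGUACGUACGGAAUUCCGUACGUACGUACGUACGUACGUACGUACGUACGUACGU"
  m5 <- substr(hp1, 4, 24)    # offset 3, 21 nt
  m3 <- substr(hp1, 41, 61)   # offset 40, 21 nt
  data.frame(
    id = c("candA", "candB", "candC", "candD"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(1000L, 30000L, 1000L, 5000L),
    end = c(1000L + nchar(hp1), 30000L + nchar(hp1), 1000L + nchar(hp1),
            5000L + nchar(hp1)),
    strand = c("+", "+", "-", "-"),
    score = c(4.9, 6, 6, 6),
    hairpin_seq = hp1,
    mature5p_seq = m5, mature5p_offset = 3L,
    mature3p_seq = m3, mature3p_offset = 40L,
    stringsAsFactors = FALSE
  )
}

make_hit <- function(query, subject, evalue, s_start = 100L, s_end = 160L,
                     mismatches = 0L, q_start = 1L, q_end = 60L,
                     align_length = 60L, bitscore = 80) {
  data.frame(query_id = query, subject_id = subject, pct_identity = 98,
             align_length = align_length, mismatches = mismatches,
             gap_opens = 0L, q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

empty_hit_table <- function() {
  make_hit("x", "y", 1)[0, ]
}
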