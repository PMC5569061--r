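test_that("CPM normalization scales columns to one million", {
  m <- matrix(c(1L, 1L, 2L, 7L, 0L, 0L), 3,
              dimnames = list(c("a-5p", "a-3p", "b-5p"), c("s1", "s2")))
  cpm <- normalize_cpm(m)
  expect_equal(cpm[, "s1"], c(`a-5p` = 250000, `a-3p` = 250000,
                              `b-5p` = 500000))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  expect_equal(cpm["a-3p", "s2"], 0)
  m0 <- m; m0[, 2] <- 0L
  expect_error(normalize_cpm(m0), "s2")
})

usage_fixture <- function() {
  cand <- tiny_candidates()[1:2, ]
  cand$id <- c("pA", "pB")
  counts <- matrix(0L, 4, 4,
                   dimnames = list(c("pA-5p", "pA-3p", "pB-5p", "pB-3p"),
                                   c("br1", "br2", "li1", "sk1")))
  tissue_of <- c(br1 = "brain", br2 = "brain", li1 = "liver", sk1 = "skin")
  counts["pA-5p", ] <- c(60L, 40L, 30L, 2L)
  counts["pA-3p", ] <- c(20L, 20L, 30L, 20L)
  counts["pB-5p", ] <- c(0L, 0L, 0L, 0L)
  counts["pB-3p", ] <- c(15L, 5L, 0L, 0L)
  list(cand = cand, counts = counts, tissue_of = tissue_of)
}

test_that("arm usage sums replicates per tissue and calls dominance strictly", {
  fx <- usage_fixture()
  u <- arm_usage(fx$counts, fx$cand, fx$tissue_of)
  row <- function(p, t) u[u$precursor_id == p & u$tissue == t, ]
  expect_equal(row("pA", "brain")$reads5p, 100L)  # replicates summed
  expect_identical(row("pA", "brain")$dominant, "5p")
  expect_identical(row("pA", "liver")$dominant, "tie")
  expect_identical(row("pA", "skin")$dominant, "3p")
  expect_identical(row("pB", "liver")$dominant, "none")

  bad <- fx$counts
  rownames(bad)[1] <- "ghost-5p"
  expect_error(arm_usage(bad, fx$cand, fx$tissue_of), "unknown precursor")
})

test_that("switch detection needs both dominances among voting tissues", {
  fx <- usage_fixture()
  u <- arm_usage(fx$counts, fx$cand, fx$tissue_of)
  sw <- detect_arm_switches(u, min_tissue_reads = 10)
  # pA: 5p in brain, 3p in skin -> switch; tie in liver never votes
  expect_identical(unique(sw$precursor_id), "pA")
  expect_setequal(sw$tissue[sw$precursor_id == "pA"], c("brain", "skin"))
  # raising the voting threshold above skin depth removes the switch
  expect_equal(nrow(detect_arm_switches(u, min_tissue_reads = 30)), 0)
})

test_that("arm summary partitions precursors and matches a naive recount", {
  fx <- usage_fixture()
  u <- arm_usage(fx$counts, fx$cand, fx$tissue_of)
  s <- summarize_arms(u)
  expect_equal(s$n_both_arms, 1)
  expect_equal(s$n_5p_only, 0)
  expect_equal(s$n_3p_only, 1)
  expect_equal(s$n_both_arms + s$n_5p_only + s$n_3p_only, s$n_expressed)

  set.seed(7)
  for (rep in 1:20) {
    ru <- random_usage()
    rs <- summarize_arms(ru)
    or <- oracle_arm_summary(ru)
    expect_equal(rs$n_both_arms, or$n_both)
    expect_equal(rs$n_5p_only, or$n_5p_only)
    expect_equal(rs$n_3p_only, or$n_3p_only)
    expect_equal(rs$frac_dominant_5p, or$frac5)
    expect_equal(rs$n_both_arms + rs$n_5p_only + rs$n_3p_only,
                 rs$n_expressed)
  }
})

test_that("duplicate grouping joins identical or near-identical matures only", {
  dm <- c(p1 = "UGAGGUAGUAGGUUGUAUAGUU",
          p2 = "UGAGGUAGUAGGUUGUAUAGUU",          # identical to p1
          p3 = "UGAGGUAGUAGGUUGUAUAGAA",          # distance 2 from p1
          p4 = "AAAAAAAACCCCCCCCGGGGGG",
          p5 = "AAAAAAAACCCCCCCCGGGGGG",
          p6 = "AAAAAAAACCCCCCCCGGGGGG",
          p7 = "UUUUUGGGGGCCCCCAAAAAC")
  g <- group_duplicates(dm)
  sizes <- sort(vapply(g, function(x) length(x$members), integer(1)))
  expect_equal(sizes, c(3L, 3L))
  types <- vapply(g, `[[`, character(1), "type")
  members <- lapply(g, `[[`, "members")
  tri <- which(vapply(members, function(m) "p4" %in% m, logical(1)))
  expect_identical(types[[tri]], "exact")
  sim <- which(vapply(members, function(m) "p3" %in% m, logical(1)))
  expect_identical(types[[sim]], "similar")
  # distance 3 stays apart
  expect_false("p7" %in% unlist(members))
})

test_that("sample clustering uses 1 - Spearman with average linkage", {
  set.seed(11)
  base <- matrix(rlnorm(60, 3, 1), 20, 3)
  mat <- cbind(base[, 1], base[, 1], base[, 2], base[, 2] * 2,
               base[, 3], base[, 3] + 0.01)
  colnames(mat) <- paste0("s", 1:6)
  rownames(mat) <- paste0("m", 1:20)
  res <- cluster_samples(mat, k = 3)
  # duplicated and rank-preserving columns have distance zero
  d <- as.matrix(stats::cophenetic(res$hclust))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(unname(res$labels["s3"]), unname(res$labels["s4"]))
  expect_equal(length(unique(res$labels)), 3)
  # invariance under a monotone transform of one column
  mat2 <- mat
  mat2[, 5] <- mat2[, 5]^3
  res2 <- cluster_samples(mat2, k = 3)
  expect_equal(stats::cophenetic(res2$hclust), stats::cophenetic(res$hclust))

  matc <- mat
  matc[, 2] <- 1
  expect_error(cluster_samples(matc), "s2")
})

test_that("top_mature_matrix keeps the most expressed arm, ties to 5p", {
  fx <- usage_fixture()
  top <- top_mature_matrix(fx$counts, fx$cand)
  expect_setequal(rownames(top), c("pA-5p", "pB-3p"))
  tied <- fx$counts
  tied["pA-5p", ] <- c(30L, 30L, 20L, 10L)
  tied["pA-3p", ] <- c(45L, 30L, 5L, 10L)   # equal totals of 90
  expect_true("pA-5p" %in% rownames(top_mature_matrix(tied, fx$cand)))
})

test_that("reference miRNAs are the lowest-CV rows", {
  m <- rbind(const = rep(100, 4),
             low = c(95, 100, 105, 100),
             mid = c(80, 100, 120, 100),
             high = c(10, 100, 300, 20))
  colnames(m) <- paste0("s", 1:4)
  expect_identical(as.character(select_reference_mirnas(m, 2)),
                   c("const", "low"))
  set.seed(5)
  rm <- matrix(rlnorm(200, 4, 1), 20,
               dimnames = list(paste0("m", 1:20), NULL))
  ref <- select_reference_mirnas(rm, 3)
  cv <- apply(rm, 1, sd) / rowMeans(rm)
  expect_identical(as.character(ref), names(sort(cv))[1:3])
  mz <- rbind(m, zero = rep(0, 4))
  expect_warning(select_reference_mirnas(mz, 2), "zero mean")
})
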