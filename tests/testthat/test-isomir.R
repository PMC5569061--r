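iso_fixture <- function() {
  set.seed(99)
  p <- simulate_precursor(30, 8, n_bulges = 0)
  list(hp = p$hairpin_seq,
       m5 = p$mature5p_seq, s5 = p$mature5p_offset,
       e5 = p$mature5p_offset + nchar(p$mature5p_seq),
       m3 = p$mature3p_seq, s3 = p$mature3p_offset,
       e3 = p$mature3p_offset + nchar(p$mature3p_seq))
}

test_that("anchoring prefers fewer mismatches, then the smaller shift", {
  fx <- iso_fixture()
  a <- anchor_read(fx$m5, fx$hp, fx$s5)
  expect_equal(a$start, fx$s5)
  expect_length(a$mismatch_read_pos, 0)

  # one base further into the precursor: clean at +1, noisy at 0
  shifted <- substr(fx$hp, fx$s5 + 2, fx$e5 + 1)
  a1 <- anchor_read(shifted, fx$hp, fx$s5)
  expect_equal(a1$start, fx$s5 + 1)
  expect_length(a1$mismatch_read_pos, 0)

  # an unrelated read fails everywhere
  junk <- paste(rep("A", 20), collapse = "")
  expect_null(anchor_read(junk, fx$hp, fx$s5))
  expect_null(anchor_read(strrep("ACGU", 30), fx$hp, fx$s5))
})

test_that("the classification cascade reproduces the isomiR taxonomy", {
  fx <- iso_fixture()
  cls <- function(read) classify_isomir(read, fx$hp, fx$s5, fx$e5)

  expect_identical(cls(fx$m5)$category, "canonical")

  # one extra 3' base copied from the precursor
  t3 <- substr(fx$hp, fx$s5 + 1, fx$e5 + 1)
  c3 <- cls(t3)
  expect_identical(c3$category, "3p_templated")
  expect_equal(c3$offset3, 1L)

  # one extra 3' base that contradicts the precursor
  nextb <- substr(fx$hp, fx$e5 + 1, fx$e5 + 1)
  wrong <- setdiff(c("A", "C", "G", "U"), nextb)[1]
  n3 <- cls(paste0(fx$m5, wrong))
  expect_identical(n3$category, "3p_nontemplated")

  # trimming is always templated
  tr <- cls(substr(fx$m5, 1, nchar(fx$m5) - 1))
  expect_identical(tr$category, "3p_templated")
  expect_equal(tr$offset3, -1L)
  tr5 <- cls(substr(fx$m5, 2, nchar(fx$m5)))
  expect_identical(tr5$category, "5p_templated")
  expect_equal(tr5$offset5, 1L)

  # an internal change wins over end variation
  v <- strsplit(fx$m5, "")[[1]]
  v[10] <- setdiff(c("A", "C", "G", "U"), v[10])[1]
  pm <- cls(paste(v, collapse = ""))
  expect_identical(pm$category, "polymorphic")
  expect_equal(pm$mismatch_positions, 10L)

  # A -> G internal changes carry the editing flag
  apos <- which(strsplit(fx$m5, "")[[1]] == "A")
  apos <- apos[apos > 3 & apos < nchar(fx$m5) - 2][1]
  if (!is.na(apos)) {
    v <- strsplit(fx$m5, "")[[1]]
    v[apos] <- "G"
    edited <- cls(paste(v, collapse = ""))
    expect_identical(edited$category, "polymorphic")
    expect_true(edited$editing_ag)
  }

  # both ends modified collapses to the mixed class
  mx <- cls(substr(fx$hp, fx$s5, fx$e5 + 1))
  expect_identical(mx$category, "mixed_5p3p")

  # unanchorable reads are reported as such
  un <- classify_isomir(strrep("A", 20), fx$hp, fx$s5, fx$e5)
  expect_identical(un$category, "unassigned")
})

test_that("every canonical mature classifies as canonical (identity property)", {
  set.seed(12)
  for (rep in 1:25) {
    p <- simulate_precursor(30, 8)
    for (arm in c("5p", "3p")) {
      sq <- p[[paste0("mature", arm, "_seq")]]
      off <- p[[paste0("mature", arm, "_offset")]]
      cl <- classify_isomir(sq, p$hairpin_seq, off, off + nchar(sq))
      expect_identical(cl$category, "canonical")
    }
  }
})

test_that("generated isomiR variants classify back to their planted category", {
  set.seed(13)
  cats <- c("canonical", "5p_templated", "3p_templated", "5p_nontemplated",
            "3p_nontemplated", "polymorphic", "mixed_5p3p")
  for (rep in 1:10) {
    p <- simulate_precursor(30, 8)
    for (arm in c("5p", "3p")) {
      off <- p[[paste0("mature", arm, "_offset")]]
      len <- nchar(p[[paste0("mature", arm, "_seq")]])
      for (category in cats) {
        for (v in mirnaomekit:::isomir_variants(category, p$hairpin_seq,
                                                off, len)) {
          cl <- classify_isomir(v, p$hairpin_seq, off, off + len)
          expect_identical(cl$category, category)
        }
      }
    }
  }
})

test_that("distribution is read-weighted and excludes unassigned reads", {
  calls <- data.frame(
    category = c("canonical", "canonical", "3p_templated", "unassigned"),
    count = c(30L, 10L, 40L, 20L),
    sample = c("s1", "s2", "s1", "s1"),
    stringsAsFactors = FALSE
  )
  d <- isomir_distribution(calls, tissue_of = c(s1 = "brain", s2 = "liver"))
  expect_equal(unname(d$overall["canonical"]), 0.5)
  expect_equal(unname(d$overall["3p_templated"]), 0.5)
  expect_equal(sum(d$overall), 1)
  expect_equal(d$unassigned_fraction, 0.2)
  expect_equal(unname(d$per_tissue["liver", "canonical"]), 1)
  expect_equal(unname(rowSums(d$per_tissue)), c(1, 1))

  all_canon <- data.frame(category = "canonical", count = 5L)
  expect_equal(unname(isomir_distribution(all_canon)$overall["canonical"]),
               1)
})

test_that("classification is permutation-invariant over the read stack", {
  set.seed(17)
  cfg <- simulation_config(rng_seed = 3L, n_precursors = 6L,
                           tissues = c(brain = 1L), reads_per_sample = 2000L,
                           n_switch = 2L, n_cat_specific = 1L,
                           n_duplicate_pairs = 0L, n_duplicate_triples = 0L,
                           n_decoy_low_score = 0L,
                           n_decoy_low_expression = 0L,
                           n_decoy_structural = 0L)
  set.seed(cfg$rng_seed)
  co <- simulate_cohort(cfg)
  sim <- simulate_reads(cfg, co)
  calls <- classify_reads(sim$reads, co$candidates)
  perm <- sample(nrow(sim$reads))
  calls_perm <- classify_reads(sim$reads[perm, ], co$candidates)
  expect_identical(calls_perm$category[order(perm)], calls$category)
})
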