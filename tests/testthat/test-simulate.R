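small_config <- function(seed = 5L, ...) {
  simulation_config(rng_seed = seed, n_precursors = 12L,
                    tissues = c(brain = 2L, liver = 2L, skin = 1L),
                    reads_per_sample = 4000L, n_switch = 2L,
                    n_cat_specific = 2L, n_duplicate_pairs = 1L,
                    n_duplicate_triples = 0L, n_decoy_low_score = 5L,
                    n_decoy_low_expression = 3L, n_decoy_structural = 1L,
                    ...)
}

test_that("hairpins are stem-loops with matures at their stated offsets", {
  set.seed(2)
  p0 <- simulate_precursor(22 + 5, 8, n_bulges = 0)
  hp <- p0$hairpin_seq
  stem <- 27
  expect_identical(substr(hp, stem + 8 + 1, nchar(hp)),
                   rc_rna_oracle(substr(hp, 1, stem)))
  for (rep in 1:20) {
    p <- simulate_precursor(30, 8)
    expect_identical(substr(p$hairpin_seq, p$mature5p_offset + 1,
                            p$mature5p_offset + nchar(p$mature5p_seq)),
                     p$mature5p_seq)
    expect_identical(substr(p$hairpin_seq, p$mature3p_offset + 1,
                            p$mature3p_offset + nchar(p$mature3p_seq)),
                     p$mature3p_seq)
    expect_true(nchar(p$mature5p_seq) %in% 18:22)
    expect_true(p$mature5p_offset < p$mature3p_offset)
  }
  set.seed(77); a <- simulate_precursor(30, 8)
  set.seed(77); b <- simulate_precursor(30, 8)
  expect_identical(a, b)
})

test_that("planted coordinates are recovered exactly by cluster detection", {
  cfg <- simulation_config(
    rng_seed = 9L, n_precursors = 10L,
    planted_clusters = data.frame(chrom = c("chrA1", "chrB2"),
                                  size = c(3L, 2L)),
    singletons = c(chrC1 = 3L, chrD1 = 2L))
  set.seed(cfg$rng_seed)
  coords <- simulate_coordinates(cfg)
  coords$precursor_id <- sprintf("p%02d", coords$slot)
  found <- find_clusters(coords)
  got <- split(found$precursor_id, found$cluster_id)
  want <- split(coords$precursor_id, coords$cluster_label)
  expect_identical(unname(lapply(got, sort)), unname(lapply(want, sort)))

  # moving one member 12 kb away drops it from its cluster
  moved <- coords
  third <- which(moved$cluster_label == "planted_01")[3]
  moved$start[third] <- moved$start[third] + 12000L
  moved$end[third] <- moved$end[third] + 12000L
  found2 <- find_clusters(moved)
  expect_false(moved$precursor_id[third] %in% found2$precursor_id)
  expect_equal(sum(found2$cluster_id == found2$cluster_id[
    found2$precursor_id == "p01"]), 2)

  # a placement plan that does not add up is rejected
  expect_error(simulation_config(rng_seed = 1, n_precursors = 99L,
                                 planted_clusters = data.frame(
                                   chrom = "chrA1", size = 3L),
                                 singletons = c(chrC1 = 3L)),
               "placement")
})

test_that("read totals are exact and pure-canonical settings emit only matures", {
  cfg <- small_config(seed = 6L,
                      isomir_proportions = c(canonical = 1.0))
  set.seed(cfg$rng_seed)
  co <- simulate_cohort(cfg)
  sim <- simulate_reads(cfg, co)
  per_sample <- tapply(sim$reads$count, sim$reads$sample, sum)
  expect_true(all(per_sample == cfg$reads_per_sample))
  mt <- mature_table(co$candidates)
  canon <- setNames(mt$sequence, mt$mature_id)
  expect_true(all(sim$reads$read_seq ==
                    canon[paste0(sim$reads$precursor_id, "-",
                                 sim$reads$arm)]))
})

test_that("planted truth matches the emitted bundle", {
  cfg <- small_config(seed = 8L)
  set.seed(cfg$rng_seed)
  co <- simulate_cohort(cfg)
  sim <- simulate_reads(cfg, co)
  plan <- co$plan

  # per-tissue dominant arm of switch precursors follows the planted map
  good <- co$candidates[!grepl("^decoy", co$candidates$id), ]
  usage <- arm_usage(sim$counts[rownames(sim$counts) %in%
                                  mature_table(good)$mature_id, ,
                                drop = FALSE],
                     good, sim$tissue_of)
  for (i in which(plan$is_switch)) {
    u <- usage[usage$precursor_id == plan$precursor_id[i] &
                 usage$tissue == plan$flip_tissue[i], ]
    if (u$reads5p + u$reads3p >= 10) {
      flipped <- setdiff(c("5p", "3p"), plan$dominant[i])
      expect_identical(u$dominant, flipped)
    }
  }

  # low-expression decoys never reach 10 reads in any sample
  le <- rownames(sim$counts)[grepl("^decoyLE", rownames(sim$counts))]
  if (length(le)) expect_true(max(sim$counts[le, ]) < 10)
})

test_that("fixture bundles are byte-identical under a fixed seed and reload", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- small_config(seed = 11L)
  write_fixtures(cfg, d1)
  write_fixtures(cfg, d2)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # bundle reloads through the I/O layer
  cand <- read_candidates(file.path(d1, "candidates.tsv"))
  expect_equal(nrow(cand), 12 + 5 + 3 + 1)
  counts <- read_counts(file.path(d1, "counts.tsv"))
  tissue_of <- read_sample_map(file.path(d1, "sample_map.tsv"))
  expect_true(all(colnames(counts) %in% names(tissue_of)))
  expect_s3_class(read_hit_table(file.path(d1, "mirbase_hits.tsv")),
                  "data.frame")
  truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$n_precursors, 12)
  expect_identical(sort(truth$plan$precursor_id),
                   sort(cand$id[!grepl("^decoy", cand$id)]))
})

test_that("planted seed sites are recovered with their exact type and position", {
  cfg <- small_config(seed = 14L)
  set.seed(cfg$rng_seed)
  co <- simulate_cohort(cfg)
  ut <- mirnaomekit:::simulate_utrs(co)
  sites <- scan_all_utrs(ut$matures, ut$utrs)
  key <- function(df) paste(df$mirna_id, df$utr_id, df$site_type,
                            df$utr_position)
  expect_true(all(key(ut$planted_sites) %in% key(sites)))
})

test_that("oversized proportions and overflowing placements error out", {
  expect_error(simulation_config(isomir_proportions = c(canonical = 0.9,
                                                        polymorphic = 0.2)),
               "sum")
  cfg <- simulation_config(rng_seed = 2L, n_precursors = 40L,
                           singletons = c(chrY = 40L))
  set.seed(cfg$rng_seed)
  expect_error(simulate_coordinates(cfg), "exceed")
})
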