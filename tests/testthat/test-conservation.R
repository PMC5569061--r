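test_that("seed extraction returns positions 2-8", {
  expect_identical(extract_seed("UGGAAUGUAAAGAAGUAUGUAU"), "GGAAUGU")
  expect_identical(extract_seed("ACGUACGU"), "CGUACGU")
  expect_error(extract_seed("ACGUACG"), "shorter")
})

test_that("conservation calling uses a strict E-value cut and counts orthologs", {
  p <- pipeline_params()
  hits <- make_hit("c1", "hsa-mir-124", 1e-6)
  call <- call_conservation("c1", hits, p)
  expect_identical(call$status, "conserved")
  expect_identical(call$species, "hsa")
  expect_equal(call$n_orthologs, 1L)

  # at the cut-off (strict inequality) the precursor stays species-specific
  at_cut <- make_hit("c1", "hsa-mir-124", 1e-5)
  expect_identical(call_conservation("c1", at_cut, p)$status, "cat_specific")

  # 40 qualifying hits over 20 species
  sp <- paste0(letters[1:20], "aa")
  subj <- paste0(rep(sp, each = 2), "-mir-", rep(1:2, 20))
  many <- do.call(rbind, lapply(subj, function(s) make_hit("c1", s, 1e-8)))
  call40 <- call_conservation("c1", many, p)
  expect_equal(call40$n_orthologs, 40L)
  expect_equal(length(strsplit(call40$species, ",")[[1]]), 20L)

  bad <- make_hit("c1", "NOPREFIX", 1e-8)
  expect_error(call_conservation("c1", bad, p), "NOPREFIX")
})

test_that("the best ortholog has the lowest E-value with deterministic ties", {
  hits <- rbind(make_hit("c1", "hsa-mir-122", 1e-20, bitscore = 100),
                make_hit("c1", "bta-mir-122", 1e-20, bitscore = 120),
                make_hit("c1", "cfa-mir-9", 1e-8))
  expect_identical(call_conservation("c1", hits)$best_ortholog,
                   "bta-mir-122")
})

test_that("family assignment is an exact seed lookup with a lexicographic tie rule", {
  idx <- data.frame(seed = c("GAGGUAG", "GAGGUAG", "CCCCCCC"),
                    family = c("let-7", "mir-98", "mir-x"),
                    stringsAsFactors = FALSE)
  res <- assign_family("UGAGGUAGUAGGUUGUAUAGUU", idx)
  expect_identical(res$family, "let-7")
  expect_identical(res$families, c("let-7", "mir-98"))
  expect_true(is.na(assign_family("AAAAAAAAAAAAAAAAAA", idx)$family))
})

naming_fixture <- function() {
  cand <- tiny_candidates()
  cand$id <- c("p1", "p2", "p3", "p4")
  cand$chrom <- c("chrX", "chrX", "chrA1", "chrA1")
  cand$start <- c(5000L, 1000L, 100L, 900L)
  calls <- data.frame(
    precursor_id = c("p1", "p2", "p3", "p4"),
    status = c("cat_specific", "cat_specific", "conserved", "conserved"),
    n_orthologs = c(0L, 0L, 10L, 12L),
    species = c("", "", "hsa", "hsa"),
    best_ortholog = c(NA, NA, "hsa-mir-138", "hsa-mir-138"),
    stringsAsFactors = FALSE
  )
  list(cand = cand, calls = calls)
}

test_that("naming is coordinate-ordered, collision-suffixed and stable", {
  fx <- naming_fixture()
  nm <- assign_names(fx$calls, fx$cand)
  named <- setNames(nm$name, nm$precursor_id)
  # species-specific serials follow coordinate order on the chromosome
  expect_identical(named[["p2"]], "fca-mir-chrX_1")
  expect_identical(named[["p1"]], "fca-mir-chrX_2")
  # shared ortholog stem gets -1/-2 in coordinate order
  expect_identical(named[["p3"]], "fca-mir-138-1")
  expect_identical(named[["p4"]], "fca-mir-138-2")
  expect_equal(anyDuplicated(nm$name), 0)
  # mature names flip mir -> miR and append the arm
  expect_identical(nm$mature5p_name[nm$precursor_id == "p3"],
                   "fca-miR-138-1-5p")

  # stable under input reordering
  perm <- sample(nrow(fx$calls))
  nm2 <- assign_names(fx$calls[perm, ], fx$cand[sample(4), ])
  expect_identical(setNames(nm2$name, nm2$precursor_id)[names(named)],
                   named)

  # a unique stem keeps its plain name
  calls1 <- fx$calls[3, ]
  calls1$best_ortholog <- "hsa-mir-122"
  expect_identical(assign_names(calls1, fx$cand)$name, "fca-mir-122")
})

recovery_fixture <- function() {
  family_table <- data.frame(
    family = c("famA", "famA", "famB", "famC", "famD", "famE"),
    gene = c("g1", "g2", "g3", "g4", "g5", "g6"),
    n_species = c(8L, 8L, 6L, 5L, 4L, 9L),
    has_human = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  probe_meta <- data.frame(
    probe_id = c("g3_m", "g4_p", "g6_m"),
    gene = c("g3", "g4", "g6"),
    type = c("mature", "precursor", "mature"),
    length = c(22L, 100L, 22L),
    stringsAsFactors = FALSE
  )
  probe_hits <- rbind(
    make_hit("g3_m", "chr1", 1e-3, q_start = 1L, q_end = 22L,
             align_length = 22L, mismatches = 0L),
    make_hit("g4_p", "chr2", 1e-4, q_start = 1L, q_end = 69L,
             align_length = 69L),
    make_hit("g6_m", "chr3", 1e-2, q_start = 1L, q_end = 22L,
             align_length = 22L, mismatches = 1L)
  )
  list(family_table = family_table, probe_meta = probe_meta,
       probe_hits = probe_hits)
}

test_that("missed-family recovery applies the species, seed and coverage rules", {
  fx <- recovery_fixture()
  res <- recover_missed_families(fx$family_table, detected_genes = "g1",
                                 fx$probe_hits, fx$probe_meta)
  genes <- setNames(res$genes$status, res$genes$gene)
  expect_identical(genes[["g1"]], "detected")
  expect_identical(genes[["g2"]], "family_member_detected")
  expect_identical(genes[["g3"]], "genomic_evidence")
  # 69 aligned bases of a 100-nt precursor probe miss the 70% rule
  expect_identical(genes[["g4"]], "absent")
  # famD has 4 species only: excluded from the denominator entirely
  expect_false("g5" %in% res$genes$gene)
  # a mismatch inside the seed disqualifies a mature probe hit
  res2 <- recover_missed_families(fx$family_table, "g1", fx$probe_hits,
                                  fx$probe_meta,
                                  mismatch_positions = list(g6_m = 5L))
  expect_identical(setNames(res2$genes$status, res2$genes$gene)[["g6"]],
                   "absent")
  # the same mismatch outside the seed keeps the evidence
  res3 <- recover_missed_families(fx$family_table, "g1", fx$probe_hits,
                                  fx$probe_meta,
                                  mismatch_positions = list(g6_m = 15L))
  expect_identical(setNames(res3$genes$status, res3$genes$gene)[["g6"]],
                   "genomic_evidence")

  fams <- setNames(res$families$status, res$families$family)
  expect_identical(unname(fams[c("famA", "famB", "famC", "famE")]),
                   c("detected", "genomic_evidence", "absent", "absent"))

  # recomputing with recovered genes marked detected keeps the recovered set
  recovered <- res$genes$gene[res$genes$status %in%
                                c("detected", "genomic_evidence")]
  res4 <- recover_missed_families(fx$family_table, recovered,
                                  fx$probe_hits, fx$probe_meta)
  rec_fams <- function(r) sort(r$families$family[r$families$status !=
                                                   "absent"])
  expect_identical(rec_fams(res4), rec_fams(res))

  bad_meta <- fx$probe_meta
  bad_meta$gene[1] <- "ghost"
  expect_error(recover_missed_families(fx$family_table, "g1",
                                       fx$probe_hits, bad_meta), "ghost")
})
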