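test_that("ORF enumeration respects the length floor and frames", {
  s <- paste0("ATG", strrep("GCT", 99), "TAA")
  o <- enumerate_orfs(s, min_aa = 100)
  expect_length(o, 1L)
  expect_equal(o[[1]]$aa_length, 100L)
  expect_equal(o[[1]]$orf_start, 0L)
  expect_equal(o[[1]]$orf_stop, 303L)
  expect_true(o[[1]]$has_start && o[[1]]$has_stop)
  expect_equal(nchar(o[[1]]$protein_seq), 100L)
  # one codon short fails the floor
  expect_length(enumerate_orfs(paste0("ATG", strrep("GCT", 98), "TAA"),
                               min_aa = 100), 0L)
  # 5'-incomplete: open frame, no ATG, stop-terminated
  s2 <- paste0(strrep("GCT", 120), "TAA", strrep("C", 30))
  o2 <- enumerate_orfs(s2, min_aa = 100)
  expect_true(any(!vapply(o2, function(x) x$has_start, TRUE)))
  expect_error(enumerate_orfs("ATGXXY"), "non-ACGTN")
})

test_that("ORF enumeration equals the brute-force forward-frame scan", {
  set.seed(31)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
    got <- enumerate_orfs(s, min_aa = 20)
    want <- oracle_orfs(s, min_aa = 20)
    got_keys <- sort(vapply(got, function(o)
      paste(o$orf_start, o$orf_stop), ""))
    want_keys <- sort(vapply(want, function(o) paste(o[1], o[2]), ""))
    expect_identical(got_keys, want_keys)
  }
  # (orf_stop - orf_start) is always a codon multiple
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  for (o in enumerate_orfs(s, min_aa = 10))
    expect_equal((o$orf_stop - o$orf_start) %% 3L, 0L)
})

test_that("best-ORF selection ranks homology above length", {
  s <- paste0(strrep("C", 2),                       # frame filler
              "ATG", strrep("GCA", 150), "TAA",     # long ORF, frame 2
              "ATG", strrep("GAC", 60), "TGA")      # short ORF
  cand <- enumerate_orfs(s, min_aa = 50)
  expect_gte(length(cand), 2L)
  lens <- vapply(cand, function(o) o$aa_length, 0L)
  short_i <- which.min(lens)
  hits <- data.frame(query = paste0("tx1.orf", short_i), hit = "P1",
                     evalue = 1e-20, bitscore = 200,
                     stringsAsFactors = FALSE)
  rec <- select_best_orf("tx1", cand, homology_hits = hits)
  expect_equal(rec$orf_id, paste0("tx1.orf", short_i))
  expect_equal(rec$best_reference_hit, "P1")
  # without hits the longest wins; full tie falls back to 5'-most start
  rec <- select_best_orf("tx1", cand)
  expect_equal(nchar(rec$protein_seq), max(lens))
  # a non-significant e-value does not count as homology
  weak <- transform(hits, evalue = 1e-3)
  rec <- select_best_orf("tx1", cand, homology_hits = weak)
  expect_equal(nchar(rec$protein_seq), max(lens))
  # permuting candidates never changes the choice (ids follow order, so
  # compare coordinates)
  expect_null(select_best_orf("tx1", list()))
})

test_that("global identity matches hand-verified values and the DP oracle", {
  expect_equal(global_identity("ACDEFG", "ACDEFG"), 100)
  expect_equal(global_identity("ACDEFG", "ACDQFG"), 5 / 6 * 100,
               tolerance = 1e-9)
  expect_error(global_identity("", "ACD"), "empty")
  set.seed(7)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:20) {
    a <- paste(sample(aas, sample(8:30, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(8:30, 1), TRUE), collapse = "")
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10,
      gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), gotoh_score(a, b),
                 tolerance = 1e-9)
  }
  # identity(x, x) = 100 for random sequences
  for (i in 1:5) {
    x <- paste(sample(aas, 40, TRUE), collapse = "")
    expect_equal(global_identity(x, x), 100)
  }
})

test_that("reference comparison reports deltas and novelty", {
  orf <- structure(list(transcript_id = "t", orf_id = "t.orf1",
                        protein_seq = "MAAAACDEFGHIKLMN",
                        best_reference_hit = "P1",
                        domain_set = c("PF001", "PF999"),
                        tm_region_count = 0L,
                        localization = "Nucleus"),
                   class = "OrfRecord")
  prot <- Biostrings::AAStringSet(c(P1 = "MAAAACDEFGHIKLMN"))
  cmp <- compare_to_reference(
    orf, prot,
    ref_domains = data.frame(protein = "P1", domain_id = "PF001"),
    ref_tm = data.frame(protein = "P1", tm_count = 2L),
    ref_loc = data.frame(protein = "P1", label = "Cell membrane"))
  expect_equal(cmp$identity_pct, 100)
  expect_false(cmp$novel_protein)
  expect_equal(cmp$domains_gained, "PF999")
  expect_length(cmp$domains_lost, 0L)
  expect_equal(cmp$tm_lost, 2L)
  expect_true(cmp$localization_switch)
  # missing hit -> novel with undefined deltas
  orf$best_reference_hit <- NA_character_
  cmp <- compare_to_reference(orf, prot)
  expect_true(cmp$novel_protein)
  expect_true(is.na(cmp$identity_pct))
})

test_that("NMD rule: 55-nt boundary, terminal exon, strand invariance", {
  # '+' strand: 3 exons of 100 nt; last junction at transcript pos 200
  plus <- transcript_model("t", "g", "chr1", "+",
                           cbind(c(0, 200, 400), c(100, 300, 500)))
  # '-' strand mirror of the same transcript (reflect about 500)
  minus <- transcript_model("t", "g", "chr1", "-",
                            cbind(c(0, 200, 400), c(100, 300, 500)))
  orf_at <- function(stop_first) list(orf_stop = stop_first + 3L,
                                      has_stop = TRUE)
  for (tx in list(plus, minus)) {
    expect_true(predict_nmd(orf_at(200 - 56), tx))
    expect_false(predict_nmd(orf_at(200 - 55), tx))
    expect_false(predict_nmd(orf_at(230), tx))  # terminal exon
    expect_true(predict_nmd(orf_at(100), tx))
  }
  mono <- transcript_model("t", "g", "chr1", "+", cbind(0, 300))
  expect_false(predict_nmd(orf_at(10), mono))
  expect_error(predict_nmd(list(orf_stop = 400, has_stop = TRUE), plus),
               "past transcript end")
  expect_false(predict_nmd(list(orf_stop = 120, has_stop = FALSE), plus))
})

test_that("peptides map to the four support classes", {
  orf_db <- c(o1 = "MAAAPEPTIDEKLLR", o2 = "MXPEPTIDEKW",
              o3 = "MZZZZQQQQQQWWWW")
  genes <- c(o1 = "gA", o2 = "gA", o3 = "gB")
  refp <- c(U1 = "MAAAPEPTIDEKLLR")
  expect_equal(classify_peptide("QQQQQQWW", orf_db, genes, refp),
               "unique_PacBio")
  expect_equal(classify_peptide("XPEPTIDEKW", orf_db, genes, refp),
               "unique_PacBio")
  expect_equal(classify_peptide("PEPTIDEK", orf_db, genes, refp),
               "nonunique_PacBio_UniProt")
  expect_equal(classify_peptide("PEPTIDEK", orf_db, genes,
                                c(U1 = "NOPE")), "non_unique_PacBio")
  both <- c(orf_db, o4 = "MPEPTIDEKYY")
  genes2 <- c(genes, o4 = "gB")
  expect_equal(classify_peptide("PEPTIDEK", both, genes2, refp),
               "multigene")
  expect_true(is.na(classify_peptide("AAPEPTIDEKLL",
                                     c(o1 = "MMM"), c(o1 = "gA"), refp)))
  expect_error(classify_peptide("SHORT", orf_db, genes, refp), "6 aa")
})

test_that("translation cutoffs hit the target housekeeping fraction", {
  m <- data.frame(orf_id = sprintf("o%03d", 1:100),
                  f1 = seq(0.01, 1, length.out = 100),
                  pme = seq(0.01, 1, length.out = 100), reads = 50)
  ct <- derive_translation_cutoffs(m, m$orf_id, target_frac = 0.8)
  expect_equal(ct$f1_cutoff, m$f1[21])     # 20th-percentile grid value
  expect_equal(ct$pme_cutoff, m$pme[21])
  tr <- classify_translated(m, ct)
  expect_gte(mean(tr), 0.8)
  # target 1.0 -> the minima among well-covered housekeeping ORFs
  m$reads[1:3] <- 5
  ct <- derive_translation_cutoffs(m, m$orf_id, target_frac = 1.0)
  expect_equal(ct$f1_cutoff, m$f1[4])
  expect_equal(ct$pme_cutoff, m$pme[4])
  # read floor gates translation regardless of metrics
  one <- data.frame(orf_id = "x", f1 = 0.99, pme = 0.99, reads = 9)
  expect_false(classify_translated(one, ct)[["x"]])
  expect_error(derive_translation_cutoffs(m, "absent"), "housekeeping")
  # self-consistency on scrambled metrics
  set.seed(5)
  m2 <- data.frame(orf_id = sprintf("h%03d", 1:200),
                   f1 = runif(200), pme = runif(200),
                   reads = sample(5:100, 200, TRUE))
  ct2 <- derive_translation_cutoffs(m2, m2$orf_id, 0.8)
  hk <- m2[m2$reads >= 10, ]
  expect_gte(mean(hk$f1 >= ct2$f1_cutoff & hk$pme >= ct2$pme_cutoff), 0.8)
})
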