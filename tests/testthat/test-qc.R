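# minimal genome for boundary cases: one '+' gene, 2 exons
qc_world <- function(downstream20 = strrep("A", 20)) {
  # exon1 [100,200), intron [200,300) GT..AG, exon2 [300,400), then the
  # 3'-downstream window [400,420)
  s <- strrep("C", 650)
  substr(s, 201, 202) <- "GT"
  substr(s, 299, 300) <- "AG"
  substr(s, 401, 420) <- downstream20
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  tx <- transcript_model("t1", "g1", "chr1", "+",
                         cbind(c(100, 300), c(200, 400)))
  ref <- build_reference_index(list(tx))
  list(genome = genome, tx = tx, ref = ref)
}

test_that("intrapriming needs all three 3'-end conditions", {
  w <- qc_world()
  # 3' end exactly at annotated TTS -> reliable despite downstream As
  ip <- detect_intrapriming(w$tx, w$genome, NULL, w$ref)
  expect_false(ip$far_from_tts)
  expect_true(ip$a_rich_downstream)
  expect_false(ip$unreliable_3prime)
  # shifted 3' end, 150 bp past the TTS, A-rich, no polyA db
  far <- transcript_model("q", "", "chr1", "+",
                          cbind(c(100, 300), c(200, 550)))
  s <- as.character(w$genome[[1]])
  substr(s, 551, 570) <- strrep("A", 20)
  genome2 <- Biostrings::DNAStringSet(c(chr1 = s))
  ip <- detect_intrapriming(far, genome2, NULL, w$ref)
  expect_true(ip$far_from_tts)
  expect_true(ip$unreliable_3prime)
  # exactly 80% A (16/20) fails the strict > 0.80 test
  substr(s, 551, 570) <- paste0(strrep("A", 16), "CCCC")
  genome3 <- Biostrings::DNAStringSet(c(chr1 = s))
  ip <- detect_intrapriming(far, genome3, NULL, w$ref)
  expect_equal(ip$a_fraction, 0.8)
  expect_false(ip$a_rich_downstream)
  expect_false(ip$unreliable_3prime)
  # a polyA-db hit rescues the A-rich far end
  db <- peak_index(GenomicRanges::GRanges("chr1",
                                          IRanges::IRanges(545, 555)))
  ip <- detect_intrapriming(far, genome2, db, w$ref)
  expect_false(ip$no_polyA_db_overlap)
  expect_false(ip$unreliable_3prime)
})

test_that("junction support passes by coverage or by sample count", {
  w <- qc_world()
  key <- junction_keys(w$tx)
  expect_true(junction_support_filter(w$tx, setNames(5, key), 1))
  expect_true(junction_support_filter(w$tx, setNames(4, key), 3))
  expect_false(junction_support_filter(w$tx, setNames(0, key), 2))
  expect_false(junction_support_filter(w$tx, numeric(0), 1))  # absent = 0
  mono <- transcript_model("m", "", "chr1", "+", cbind(100, 200))
  expect_true(junction_support_filter(mono, numeric(0), 1))
})

test_that("canonical dinucleotides are strand-corrected", {
  s <- strrep("C", 400)
  substr(s, 201, 202) <- "GT"; substr(s, 299, 300) <- "AG"
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  expect_equal(canonical_status("chr1", 200, 300, "+", g), "canonical")
  # CT..AC read on '-' is GT..AG in the sense direction
  substr(s, 201, 202) <- "CT"; substr(s, 299, 300) <- "AC"
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  expect_equal(canonical_status("chr1", 200, 300, "-", g), "canonical")
  expect_equal(canonical_status("chr1", 200, 300, "+", g), "noncanonical")
  substr(s, 201, 202) <- "GT"; substr(s, 299, 300) <- "TG"
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  expect_equal(canonical_status("chr1", 200, 300, "+", g), "noncanonical")
  expect_error(canonical_status("chr1", -5, 300, "+", g), "contig")
})

test_that("RT-switch detection finds planted direct repeats only", {
  set.seed(21)
  lcs_len <- function(a, b) {
    best <- 0L
    for (i in seq_len(nchar(a))) for (j in i:nchar(a)) {
      if (grepl(substr(a, i, j), b, fixed = TRUE))
        best <- max(best, j - i + 1L)
    }
    best
  }
  hits <- 0L
  for (rep_i in 1:20) {
    w1 <- paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")
    w2 <- paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    substr(s, 13, 28) <- w1    # donor window [12, 28)
    substr(s, 33, 48) <- w2    # acceptor window [32, 48)
    g <- Biostrings::DNAStringSet(c(chr1 = s))
    expected <- lcs_len(w1, w2) >= 8L
    expect_equal(detect_rt_switch("chr1", 20, 40, "+", g, k = 8),
                 expected)
    # strand symmetry: a direct repeat is detected on either strand
    expect_equal(detect_rt_switch("chr1", 20, 40, "-", g, k = 8),
                 expected)
    hits <- hits + expected
  }
  # planted exact repeat, flanked so it cannot extend to 9 bases
  s <- strrep("C", 60)
  substr(s, 13, 20) <- "ACGTTGCA"; substr(s, 41, 48) <- "ACGTTGCA"
  substr(s, 12, 12) <- "G"; substr(s, 21, 21) <- "T"
  substr(s, 40, 40) <- "T"; substr(s, 49, 49) <- "G"
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  expect_true(detect_rt_switch("chr1", 20, 40, "+", g, k = 8))
  # monotone in k: k=1 flags nearly everything
  expect_true(detect_rt_switch("chr1", 20, 40, "+", g, k = 1))
  expect_false(detect_rt_switch("chr1", 20, 40, "+", g, k = 9))
})

test_that("intron-retention codes follow the class-code semantics", {
  r <- transcript_model("r", "g", "chr1", "+",
                        cbind(c(100, 300, 500), c(200, 400, 600)))
  ref <- build_reference_index(list(r))
  # exon spanning one intron, other introns matched -> m
  q_m <- transcript_model("q", "", "chr1", "+",
                          cbind(c(100, 500), c(400, 600)))
  expect_equal(detect_intron_retention(q_m, ref), "m")
  # intron 1 retained, no junction shared, intron 2 unaccounted -> y
  q_y <- transcript_model("q", "", "chr1", "+", cbind(100, 450))
  expect_equal(detect_intron_retention(q_y, ref), "y")
  # mono-exon retaining every intron is still all-intron retention -> m
  q_all <- transcript_model("q", "", "chr1", "+", cbind(100, 600))
  expect_equal(detect_intron_retention(q_all, ref), "m")
  # mono-exon inside a reference intron -> i
  q_i <- transcript_model("q", "", "chr1", "+", cbind(220, 280))
  expect_equal(detect_intron_retention(q_i, ref), "i")
  # identical structure -> no retention
  expect_null(detect_intron_retention(r, ref))
  # retention plus an unmatched junction -> n
  r2 <- transcript_model("r2", "g2", "chr2", "+",
                         cbind(c(100, 300, 500, 700),
                               c(200, 400, 600, 800)))
  ref2 <- build_reference_index(list(r2))
  q_n <- transcript_model("q", "", "chr2", "+",
                          cbind(c(100, 500), c(400, 620)))
  expect_equal(detect_intron_retention(q_n, ref2), "n")
  # a 4-bp exon extension into an intron is not retention
  q_ext <- transcript_model("q", "", "chr1", "+",
                            cbind(c(100, 300, 500), c(204, 400, 600)))
  expect_null(detect_intron_retention(q_ext, ref))
})

test_that("the per-category filter policy matches the policy table", {
  mk_flags <- function(...) {
    f <- list(transcript_id = "q", unreliable_3prime = FALSE,
              noncanonical_junctions = character(0),
              rt_switch_junctions = character(0),
              junction_pass = TRUE, intron_retention_code = NULL)
    utils::modifyList(f, list(...))
  }
  call_of <- function(cat) list(transcript_id = "q", category = cat)
  # FSM: no filtering, even with every flag raised
  worst <- mk_flags(unreliable_3prime = TRUE, junction_pass = FALSE,
                    noncanonical_junctions = "j", rt_switch_junctions = "j",
                    intron_retention_code = "m")
  expect_true(apply_filter_policy(call_of("FSM"), worst)$keep)
  # ISM: only the 3' end matters
  expect_true(apply_filter_policy(
    call_of("ISM"), mk_flags(junction_pass = FALSE,
                             noncanonical_junctions = "j"))$keep)
  d <- apply_filter_policy(call_of("ISM"),
                           mk_flags(unreliable_3prime = TRUE))
  expect_false(d$keep)
  expect_equal(d$reasons, "intrapriming")
  # NIC: 3' end + coverage + intron retention, but not RT/canonical
  expect_true(apply_filter_policy(
    call_of("NIC"), mk_flags(rt_switch_junctions = "j",
                             noncanonical_junctions = "j"))$keep)
  d <- apply_filter_policy(call_of("NIC"),
                           mk_flags(intron_retention_code = "m"))
  expect_equal(d$reasons, "intron_retention")
  # NNC: all five filters
  d <- apply_filter_policy(call_of("NNC"),
                           mk_flags(noncanonical_junctions = "j"))
  expect_false(d$keep)
  expect_equal(d$reasons, "noncanonical")
  # other categories: no 3'-end filter, everything else applies
  expect_true(apply_filter_policy(
    call_of("INTERGENIC"), mk_flags(unreliable_3prime = TRUE))$keep)
  d <- apply_filter_policy(call_of("ANTISENSE"),
                           mk_flags(junction_pass = FALSE,
                                    rt_switch_junctions = "j"))
  expect_setequal(d$reasons, c("coverage", "rt_switch"))
  expect_error(apply_filter_policy(call_of("WAT"), mk_flags()), "unknown")
})

test_that("filter policy is idempotent and monotone in thresholds", {
  cat <- default_catalog()
  flags <- default_qc_flags()
  calls <- classify_catalog(cat$queries, cat$ref_index)$calls
  dec <- lapply(names(calls), function(id)
    apply_filter_policy(calls[[id]], flags[[id]]))
  keep1 <- vapply(dec, function(d) d$keep, TRUE)
  # idempotence: re-deciding the kept subset keeps everything
  kept_ids <- names(calls)[keep1]
  dec2 <- vapply(kept_ids, function(id)
    apply_filter_policy(calls[[id]], flags[[id]])$keep, TRUE)
  expect_true(all(dec2))
  # relaxing the coverage threshold to 0 never shrinks the kept set
  flags_relaxed <- lapply(names(calls), function(id) {
    f <- flags[[id]]
    f$junction_pass <- junction_support_filter(
      cat$queries[[id]], cat$coverage,
      cat$lr_counts[[id]], min_coverage = 0)
    f
  })
  keep2 <- vapply(seq_along(calls), function(i)
    apply_filter_policy(calls[[i]], flags_relaxed[[i]])$keep, TRUE)
  expect_true(all(keep2 >= keep1))
})

test_that("end support uses peaks and the poly(A) motif", {
  s <- strrep("C", 500)
  substr(s, 351, 356) <- "AATAAA"
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  tx <- transcript_model("t", "g", "chr1", "+",
                         cbind(c(100, 300), c(200, 400)))
  cage <- peak_index(GenomicRanges::GRanges("chr1",
                                            IRanges::IRanges(90, 110)))
  sup <- validate_ends(tx, cage = cage, genome = g)
  expect_true(sup$tss_supported)
  expect_true(sup$tts_supported)   # AATAAA within the last 50 nt
  expect_true(sup$tts_motif)
  # no peaks, no motif
  substr(s, 351, 356) <- "CCCCCC"
  g2 <- Biostrings::DNAStringSet(c(chr1 = s))
  sup <- validate_ends(tx, genome = g2)
  expect_false(sup$tss_supported)
  expect_false(sup$tts_supported)
})

test_that("support rates are per category with NA for empty ones", {
  calls <- list(
    a = structure(list(transcript_id = "a", category = "NIC"),
                  class = "StructuralCall"),
    b = structure(list(transcript_id = "b", category = "NIC"),
                  class = "StructuralCall"),
    c = structure(list(transcript_id = "c", category = "FSM"),
                  class = "StructuralCall"))
  sup <- list(a = list(tss_supported = TRUE, tts_supported = FALSE),
              b = list(tss_supported = FALSE, tts_supported = FALSE),
              c = list(tss_supported = TRUE, tts_supported = TRUE))
  rep <- support_rate_report(calls, sup)
  expect_equal(rep$tss_rate[rep$category == "NIC"], 0.5)
  expect_equal(rep$both_rate[rep$category == "FSM"], 1)
  expect_true(is.na(rep$tss_rate[rep$category == "NNC"]))
  expect_equal(rep$n[rep$category == "NNC"], 0L)
})
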