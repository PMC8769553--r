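# expected event sets below are hand-derived from the exon chains
test_that("each local event type is extracted with its defining sets", {
  se <- extract_events(list(
    transcript_model("t1", "g1", "chr1", "+",
                     cbind(c(100, 300, 500), c(200, 400, 600))),
    transcript_model("t2", "g1", "chr1", "+",
                     cbind(c(100, 500), c(200, 600)))))
  expect_length(se, 1L)
  expect_equal(se[[1]]$event_type, "SE")
  expect_equal(se[[1]]$event_id, "g1;SE:chr1:200-300-400-500:+")
  expect_equal(se[[1]]$inclusion_transcripts, "t1")
  expect_equal(se[[1]]$exclusion_transcripts, "t2")

  # shared acceptor, donors 20 bp apart: A5SS on '+', A3SS on '-'
  mk <- function(strand) list(
    transcript_model("t1", "g2", "chr1", strand,
                     cbind(c(100, 500), c(200, 600))),
    transcript_model("t2", "g2", "chr1", strand,
                     cbind(c(100, 500), c(220, 600))))
  a5 <- extract_events(mk("+"))
  expect_length(a5, 1L)
  expect_equal(a5[[1]]$event_type, "A5SS")
  expect_equal(a5[[1]]$inclusion_transcripts, "t2")   # longer exon
  a3 <- extract_events(mk("-"))
  expect_equal(a3[[1]]$event_type, "A3SS")

  ri <- extract_events(list(
    transcript_model("t1", "g3", "chr1", "+",
                     cbind(c(100, 300), c(200, 400))),
    transcript_model("t2", "g3", "chr1", "+", cbind(100, 400))))
  expect_length(ri, 1L)
  expect_equal(ri[[1]]$event_type, "RI")
  expect_equal(ri[[1]]$inclusion_transcripts, "t2")   # retaining form

  af <- extract_events(list(
    transcript_model("t1", "g4", "chr1", "+",
                     cbind(c(100, 900), c(200, 1000))),
    transcript_model("t2", "g4", "chr1", "+",
                     cbind(c(500, 900), c(600, 1000)))))
  expect_length(af, 1L)
  expect_equal(af[[1]]$event_type, "AF")
  expect_equal(af[[1]]$inclusion_transcripts, "t1")   # distal first exon
  # the same structure on '-' is an alternative *last* exon
  al <- extract_events(list(
    transcript_model("t1", "g5", "chr1", "-",
                     cbind(c(100, 900), c(200, 1000))),
    transcript_model("t2", "g5", "chr1", "-",
                     cbind(c(500, 900), c(600, 1000)))))
  expect_equal(al[[1]]$event_type, "AL")
  expect_equal(al[[1]]$inclusion_transcripts, "t1")

  mx <- extract_events(list(
    transcript_model("t1", "g6", "chr1", "+",
                     cbind(c(100, 300, 900), c(200, 400, 1000))),
    transcript_model("t2", "g6", "chr1", "+",
                     cbind(c(100, 600, 900), c(200, 700, 1000)))))
  expect_length(mx, 1L)
  expect_equal(mx[[1]]$event_type, "MX")
  expect_equal(mx[[1]]$inclusion_transcripts, "t1")
  expect_equal(mx[[1]]$exclusion_transcripts, "t2")
})

test_that("overlap thresholds merge near-identical variants", {
  # donors 8 bp apart fall inside the 10-bp local threshold: no event
  close_a5 <- extract_events(list(
    transcript_model("t1", "g", "chr1", "+",
                     cbind(c(100, 500), c(200, 600))),
    transcript_model("t2", "g", "chr1", "+",
                     cbind(c(100, 500), c(208, 600)))))
  expect_length(close_a5, 0L)
  # first exons overlapping by > 250 bp are one AF variant
  merged_af <- extract_events(list(
    transcript_model("t1", "g", "chr1", "+",
                     cbind(c(100, 900), c(500, 1000))),
    transcript_model("t2", "g", "chr1", "+",
                     cbind(c(140, 900), c(500, 1000)))))
  expect_length(merged_af, 0L)
  # single-transcript genes yield nothing
  expect_length(extract_events(list(
    transcript_model("t1", "g", "chr1", "+",
                     cbind(c(100, 300), c(200, 400))))), 0L)
})

test_that("extraction is order-invariant and deduplicated", {
  ann <- default_annotation()
  ev1 <- extract_events(ann$transcripts)
  set.seed(2)
  ev2 <- extract_events(ann$transcripts[sample(length(ann$transcripts))])
  expect_identical(vapply(ev1, function(e) e$event_id, ""),
                   vapply(ev2, function(e) e$event_id, ""))
  ids <- vapply(ev1, function(e) e$event_id, "")
  expect_false(anyDuplicated(ids) > 0L)
  # the synthetic annotation plants exactly one skipped exon per gene
  expect_equal(unname(table(vapply(ev1, function(e) e$event_type, ""))[["SE"]]),
               sum(ann$genes$n_exons >= 4L))
  for (e in ev1) {
    expect_length(intersect(e$inclusion_transcripts,
                            e$exclusion_transcripts), 0L)
    expect_gt(length(e$inclusion_transcripts), 0L)
    expect_gt(length(e$exclusion_transcripts), 0L)
  }
})

test_that("PSI is the inclusion share with masking below the floor", {
  ev <- extract_events(list(
    transcript_model("t1", "g1", "chr1", "+",
                     cbind(c(100, 300, 500), c(200, 400, 600))),
    transcript_model("t2", "g1", "chr1", "+",
                     cbind(c(100, 500), c(200, 600)))))
  tpm <- matrix(c(8, 2, 0.4, 0.4, 0, 0), 2, 3,
                dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
  p <- compute_psi(ev, tpm, min_total_tpm = 1)
  expect_equal(p$psi[1, "s1"], 0.8)
  expect_true(is.na(p$psi[1, "s2"]))     # total 0.8 < 1
  expect_true(is.na(p$psi[1, "s3"]))     # total 0
  p0 <- compute_psi(ev, tpm, min_total_tpm = 0)
  expect_equal(p0$psi[1, "s2"], 0.5)
  expect_error(compute_psi(ev, -tpm), "negative")
  expect_error(compute_psi(ev, tpm[1, , drop = FALSE]), "absent")
})

test_that("PSI conservation and scale invariance hold on random instances", {
  set.seed(13)
  for (i in 1:1000) {
    inc <- runif(1, 0, 50); exc <- runif(1, 0, 50)
    if (inc + exc < 1) next
    psi <- inc / (inc + exc)
    mirror <- exc / (inc + exc)
    expect_equal(psi + mirror, 1)
    s <- runif(1, 0.1, 10)
    expect_equal((s * inc) / (s * inc + s * exc), psi, tolerance = 1e-12)
    expect_true(psi >= 0 && psi <= 1)
  }
  # the same properties through the public interface
  ev <- extract_events(list(
    transcript_model("t1", "g1", "chr1", "+",
                     cbind(c(100, 300, 500), c(200, 400, 600))),
    transcript_model("t2", "g1", "chr1", "+",
                     cbind(c(100, 500), c(200, 600)))))
  mirror_ev <- ev[[1]]
  tmp <- mirror_ev$inclusion_transcripts
  mirror_ev$inclusion_transcripts <- mirror_ev$exclusion_transcripts
  mirror_ev$exclusion_transcripts <- tmp
  set.seed(14)
  tpm <- matrix(runif(20, 1, 30), 2, 10,
                dimnames = list(c("t1", "t2"), paste0("s", 1:10)))
  p <- compute_psi(list(ev[[1]], mirror_ev), tpm)
  expect_equal(unname(p$psi[1, ] + p$psi[2, ]), rep(1, 10))
  p_scaled <- compute_psi(list(ev[[1]], mirror_ev), tpm * 7)
  expect_equal(p$psi, p_scaled$psi)
})
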