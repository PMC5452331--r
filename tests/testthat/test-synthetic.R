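test_that("transcript generation is deterministic under a fixed seed", {
  a <- make_transcript(80, 300, 400, plants = list(list(position = 500)),
                       seed = 77)
  b <- make_transcript(80, 300, 400, plants = list(list(position = 500)),
                       seed = 77)
  expect_identical(a$transcript$sequence, b$transcript$sequence)
  expect_identical(a$manifest, b$manifest)
  c <- make_transcript(80, 300, 400, plants = list(list(position = 500)),
                       seed = 78)
  expect_false(identical(a$transcript$sequence, c$transcript$sequence))
})

test_that("plant validation rejects overlaps, boundary-spanning and bad sizes", {
  expect_error(make_transcript(50, 100, 100), "multiple of 3")
  expect_error(make_transcript(50, 99, 100,
                               plants = list(list(position = 60),
                                             list(position = 70)),
               seed = 1), "overlapping")
  expect_error(make_transcript(50, 99, 100,
                               plants = list(list(position = 45)),
               seed = 1), "boundary")
  expect_error(make_transcript(50, 99, 100,
                               plants = list(list(position = 240)),
               seed = 1), "outside")
  expect_error(make_transcript(50, 99, 100,
                               plants = list(list(position = 60,
                                                  substitutions = 25)),
               seed = 1), "1..22")
})

test_that("the manifest is the complete truth of a threshold-100 scan", {
  set.seed(123)
  for (i in 1:60) {
    n_plants <- sample(0:3, 1)
    utr3 <- sample(200:400, 1)
    positions <- if (n_plants > 0) {
      sort(sample(seq(160, 160 + utr3 - 60, by = 30), n_plants))
    } else integer()
    out <- make_transcript(50, 99, utr3,
                           plants = lapply(positions, function(p)
                             list(position = p)),
                           seed = sample.int(1e6, 1))
    hits <- scan_transcript(mir619(), out$transcript)
    exp <- expected_hits(out$manifest)
    expect_equal(hits$start, exp$start)
    expect_equal(hits$region, exp$region)
  }
})

test_that("substituted plants fall below threshold 100 but are found at their own ratio", {
  out <- make_transcript(50, 99, 300,
                         plants = list(list(position = 200,
                                            substitutions = c(5, 12))),
                         seed = 321)
  expect_equal(nrow(scan_transcript(mir619(), out$transcript)), 0L)
  ratio <- out$manifest$plants[[1]]$ratio
  expect_lt(ratio, 100)
  hits <- scan_transcript(mir619(), out$transcript, threshold = ratio)
  expect_true(200L %in% hits$start)
})

test_that("cohorts honor the multiplicity map and write consistent files", {
  coh <- make_cohort(10, multiplicity = c("1" = 5, "2" = 3, "4" = 2),
                     seed = 11)
  expect_length(coh$transcripts, 10L)
  hits <- scan_transcripts(mir619(), coh$transcripts)
  s <- summarize_targets(hits)
  expect_equal(s$total, 5L + 6L + 8L)
  counts <- vapply(s$multiplicity, length, integer(1))
  expect_equal(counts, c(`1` = 5L, `2` = 3L, `4` = 2L))

  dir <- withr::local_tempdir()
  coh2 <- make_cohort(4, seed = 12, out_dir = dir)
  recs <- read_transcript_table(file.path(dir, "transcripts.fa"),
                                file.path(dir, "transcripts.tsv"))
  expect_length(recs, 4L)
  expect_identical(recs$tx0001$sequence, coh2$transcripts$tx0001$sequence)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(man$transcripts, 4L)

  empty <- make_cohort(0)
  expect_length(empty$transcripts, 0L)
  expect_error(make_cohort(5, multiplicity = c("1" = 3)), "exactly n_genes")
})

test_that("family generation is deterministic and respects s_site = 0", {
  f1 <- make_family("G", n_species = 6, f_flank = 0.2, s_site = 0,
                    seed = 9)
  f2 <- make_family("G", n_species = 6, f_flank = 0.2, s_site = 0,
                    seed = 9)
  expect_identical(f1$family$members$fragment, f2$family$members$fragment)
  al <- anchor_align(f1$family, mir619())
  prof <- substitution_profile(al, "Hsa")
  expect_equal(prof$totals[["in_site"]], 0L)
  expect_error(make_family(f_flank = 0.1, s_site = 0.2), "s_site")
})
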