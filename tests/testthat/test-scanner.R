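test_that("the printed 5'UTR fragment yields exactly one hit at its bold offset", {
  hits <- scan_sequence(mir619(), "CUGGCCAGGCUCAUGCCUGUAAUCCCAGCACUUUGG")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 8L)
  expect_equal(hits$site_seq, PERFECT_SITE_RNA)
  expect_equal(hits$ratio_percent, 100)
})

test_that("threshold-100 scanning equals naive exact search for the reverse complement", {
  m <- mir619()
  set.seed(31)
  for (i in 1:40) {
    n <- sample(60:400, 1)
    seq <- rand_rna(n)
    # sometimes plant the perfect site to make matches likely
    if (i %% 2 == 0) {
      p <- sample(n - 21L, 1)
      substr(seq, p, p + 21L) <- PERFECT_SITE_RNA
    }
    expect_equal(scan_sequence(m, seq)$start,
                 naive_find(seq, PERFECT_SITE_RNA))
  }
})

test_that("lowering the threshold never removes a hit", {
  m <- mir619()
  set.seed(17)
  seq <- paste0(rand_rna(100), PERFECT_SITE_RNA, rand_rna(100))
  prev <- integer()
  for (thr in c(100, 95, 90, 80, 70, 60)) {
    cur <- scan_sequence(m, seq, threshold = thr)$start
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("sequences shorter than the miRNA give an empty result with a warning", {
  expect_warning(hits <- scan_sequence(mir619(), "ACGUACGU"), "shorter")
  expect_equal(nrow(hits), 0L)
})

test_that("region annotation assigns by start and flags junction-spanning hits", {
  set.seed(41)
  tx <- transcript_record("t", "USP29", "Hsa", rand_rna(300), 100, 249)
  expect_equal(annotate_region(tx, 2, 23),
               list(region = "5UTR", boundary_flag = FALSE))
  expect_equal(annotate_region(tx, 120, 141),
               list(region = "CDS", boundary_flag = FALSE))
  # start 10 nt before cds_end: still CDS, but flagged
  expect_equal(annotate_region(tx, 240, 261),
               list(region = "CDS", boundary_flag = TRUE))
  expect_equal(annotate_region(tx, 90, 111),
               list(region = "5UTR", boundary_flag = TRUE))
})

test_that("transcript scanning annotates hits with gene, region and energies", {
  out <- make_transcript(100, 300, 500,
                         plants = list(list(position = 30),
                                       list(position = 150),
                                       list(position = 700)),
                         seed = 99, gene = "GX", species = "Hsa", id = "tx9")
  hits <- scan_transcript(mir619(), out$transcript)
  expect_equal(hits$start, c(30L, 150L, 700L))
  expect_equal(hits$region, c("5UTR", "CDS", "3UTR"))
  expect_equal(hits$gene, rep("GX", 3))
  expect_equal(hits$dg_kj_mol, rep(-121, 3), tolerance = 1e-9)
  expect_false(any(hits$boundary_flag))
})

test_that("target summaries tally regions and gene multiplicities", {
  hits <- data.frame(
    transcript_id = c("a", "b", "b", "c", "c", "c"),
    gene = c("g1", "g2", "g2", "g3", "g3", "g3"),
    region = c("3UTR", "3UTR", "CDS", "3UTR", "3UTR", "5UTR"),
    stringsAsFactors = FALSE)
  s <- summarize_targets(hits)
  expect_equal(s$total, 6L)
  expect_equal(unname(s$region_tally), c(1L, 1L, 4L))
  expect_equal(s$multiplicity, list(`1` = "g1", `2` = "g2", `3` = "g3"))
  expect_equal(sum(s$region_tally), s$total)

  empty <- summarize_targets(hits[0, ])
  expect_equal(empty$total, 0L)
  expect_equal(unname(empty$region_tally), c(0L, 0L, 0L))
  expect_equal(length(empty$multiplicity), 0L)
})

test_that("hit TSV and BED exports round-trip coordinates", {
  out <- make_transcript(50, 99, 100, plants = list(list(position = 160)),
                         seed = 5)
  hits <- scan_transcript(mir619(), out$transcript)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "hits.tsv")
  bed <- file.path(dir, "hits.bed")
  write_hits_tsv(hits, tsv)
  back <- read.delim(tsv)
  expect_equal(back$start, hits$start)
  expect_equal(back$dg_kj_mol, -121)
  write_hits_bed(hits, bed)
  bedtab <- read.delim(bed, comment.char = "#", header = FALSE)
  expect_equal(bedtab$V2, hits$start - 1L)  # 0-based start
  expect_equal(bedtab$V3, hits$end)         # half-open end
})
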