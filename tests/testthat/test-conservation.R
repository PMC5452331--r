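test_that("all printed 5'UTR family fragments anchor with the site at columns 1..22", {
  t2 <- table2()
  fams <- split(t2, t2$gene)
  for (g in names(fams)) {
    if (nrow(fams[[g]]) < 2) next
    fam <- ortholog_family(g, data.frame(species = fams[[g]]$species,
                                         fragment = fams[[g]]$fragment))
    al <- anchor_align(fam, mir619())
    expect_equal(nrow(al$members), nrow(fams[[g]]))
    expect_equal(al$members$site_start, fams[[g]]$site_offset)
    expect_equal(sum(al$in_site), 22L)
  }
})

test_that("members below the anchor threshold are excluded with a message", {
  fam <- ortholog_family("X", data.frame(
    species = c("Hsa", "Zzz"),
    fragment = c(paste0("AAAAA", PERFECT_SITE_RNA, "AAAAA"),
                 strrep("AC", 20))))
  expect_message(al <- anchor_align(fam, mir619()), "excluded")
  expect_equal(al$members$species, "Hsa")
})

test_that("the USP29 ortholog family shows the printed substitution pattern", {
  t2 <- table2()
  usp <- t2[t2$gene == "USP29", ]
  fam <- ortholog_family("USP29", data.frame(species = usp$species,
                                             fragment = usp$fragment))
  al <- anchor_align(fam, mir619())
  prof <- substitution_profile(al, "Hsa")
  expect_equal(prof$per_member[["Pab"]], integer(0))
  expect_equal(prof$per_member[["Nle"]], integer(0))
  expect_equal(prof$per_member[["Mle"]], integer(0))
  expect_equal(prof$per_member[["Ggo"]], 17L)   # in-site C->U
  expect_equal(prof$per_member[["Rro"]], 18L)   # in-site C->G
  expect_equal(prof$per_member[["Can"]], 24L)   # downstream flank only
  expect_equal(unname(prof$totals), c(2L, 1L))
})

test_that("identical members give an all-zero profile and reference swap is symmetric", {
  set.seed(61)
  frag <- paste0(rand_rna(8), PERFECT_SITE_RNA, rand_rna(8))
  fam <- ortholog_family("Y", data.frame(species = c("Hsa", "Ptr"),
                                         fragment = c(frag, frag)))
  al <- anchor_align(fam, mir619())
  expect_equal(sum(substitution_profile(al, "Hsa")$per_column$mismatches), 0L)

  out <- make_family("Z", n_species = 2, f_flank = 0.3, s_site = 0.1,
                     seed = 8)
  al2 <- anchor_align(out$family, mir619())
  a <- substitution_profile(al2, al2$members$species[1])
  b <- substitution_profile(al2, al2$members$species[2])
  expect_equal(a$per_member[[1]], b$per_member[[1]])
  expect_error(substitution_profile(al2, "Nope"), "absent")
})

test_that("the pooled 3'UTR families have the perfect site as consensus (DNA view)", {
  t5 <- table5()
  aligned <- lapply(split(t5, t5$gene), function(g) {
    anchor_align(ortholog_family(g$gene[1],
                                 data.frame(species = g$species,
                                            fragment = g$fragment)),
                 mir619())
  })
  vm <- frequency_matrix(aligned, alphabet = "DNA")
  expect_equal(consensus_string(vm), PERFECT_SITE_DNA)
  # column frequencies are proper distributions where covered
  covered <- colSums(vm$counts) > 0
  expect_true(all(abs(colSums(vm$freqs)[covered] - 1) < 1e-12))
})

test_that("single-member frequencies are 1 at its own letters; 50/50 ties use IUPAC", {
  frag1 <- paste0("AAAA", PERFECT_SITE_RNA, "GGGG")
  frag2 <- paste0("AAAA", PERFECT_SITE_RNA, "GGGC")  # last flank col splits G/C
  fam <- ortholog_family("T", data.frame(species = c("s1", "s2"),
                                         fragment = c(frag1, frag2)))
  vm <- frequency_matrix(anchor_align(fam, mir619()))
  last <- length(vm$columns)
  expect_equal(vm$consensus[last], "S")  # {C,G} ambiguity
  expect_equal(consensus_string(vm), PERFECT_SITE_RNA)
  expect_true(all(vm$freqs[, 1] %in% c(0, 1)))
})

test_that("synthetic families recover the planted substitution rates within 3 SE", {
  out <- make_family("R", n_species = 20, f_flank = 0.1, s_site = 0.01,
                     flank_len = 10, seed = 4242)
  al <- anchor_align(out$family, mir619())
  expect_equal(nrow(al$members), 20L)
  prof <- substitution_profile(al, "Hsa")
  n_members <- 19
  n_flank <- n_members * 20
  n_site <- n_members * 22
  f_hat <- prof$totals[["flank"]] / n_flank
  s_hat <- prof$totals[["in_site"]] / n_site
  expect_lt(abs(f_hat - 0.1), 3 * sqrt(0.1 * 0.9 / n_flank))
  expect_lt(abs(s_hat - 0.01), 3 * sqrt(0.01 * 0.99 / n_site))
  # mismatch positions equal the generator's realized mutations
  for (sp in names(prof$per_member)) {
    expected <- out$manifest$mutations[[sp]] - out$manifest$flank_len
    expect_equal(prof$per_member[[sp]], sort(expected))
  }
})

test_that("gene grouping is an alphabetical partition of near-equal sizes", {
  genes <- sprintf("G%02d", 1:10)
  gr <- group_genes(sample(genes), n_groups = 4)
  expect_equal(length(gr), 4L)
  expect_equal(sort(unlist(gr, use.names = FALSE)), genes)
  expect_true(all(vapply(gr, length, integer(1)) %in% 2:3))
  expect_equal(unlist(gr, use.names = FALSE), genes)  # order preserved
})
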