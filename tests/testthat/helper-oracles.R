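# Shared constants and independent oracles. The oracles are deliberately
# naive (position loops, substring comparison) and share no code with the
# package's vectorized implementations.

MIR619_SEQ <- "GCUGGGAUUACAGGCAUGAGCC"
PERFECT_SITE_RNA <- "GGCUCAUGCCUGUAAUCCCAGC"
PERFECT_SITE_DNA <- "GGCTCATGCCTGTAATCCCAGC"

# antiparallel bond count by explicit position loop
oracle_bonds <- function(mirna_seq, site_seq, gc = 3, au = 2, gu = 1, ac = 0) {
  m <- strsplit(mirna_seq, "")[[1L]]
  s <- strsplit(site_seq, "")[[1L]]
  stopifnot(length(m) == length(s))
  L <- length(m)
  total <- 0
  for (i in seq_len(L)) {
    key <- paste(sort(c(m[i], s[L - i + 1L])), collapse = "")
    total <- total + switch(key, CG = gc, AU = au, GU = gu, AC = ac, 0)
  }
  total
}

# exact substring search allowing overlapping occurrences
naive_find <- function(seq, motif) {
  n <- nchar(seq)
  L <- nchar(motif)
  if (n < L) return(integer())
  which(vapply(seq_len(n - L + 1L), function(p) {
    substr(seq, p, p + L - 1L) == motif
  }, logical(1L)))
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")

# fixed codon choices for reverse-translating test peptides
REV_CODON <- c(H = "CAU", W = "UGG", K = "AAA", G = "GGU", R = "CGU",
               A = "GCU", L = "CUG", E = "GAA", M = "AUG", P = "CCU",
               V = "GUU", I = "AUU", S = "AGU", N = "AAU", Q = "CAA")

rev_translate <- function(pep) {
  paste(REV_CODON[strsplit(pep, "")[[1L]]], collapse = "")
}

# Transcript whose CDS encodes HWKGRAR-WLMPVIP-ALWEAKA with the perfect
# site embedded so that the site's W codon borrows one upstream U
# (site grid offset 2 relative to the CDS frame). Returns the record and
# the site start.
make_wlmpvip_transcript <- function(utr5 = "CCCCCACCCC", utr3 = "CCCCCCCCCC") {
  up <- rev_translate("HWKGRAR")          # 21 nt, ends on a codon boundary
  core <- paste0("U", substr(PERFECT_SITE_RNA, 1L, 20L))  # UGG CUC ... CCA
  after <- paste0(substr(PERFECT_SITE_RNA, 21L, 22L), "A")  # GCA = A
  down <- rev_translate("LWEAKA")
  cds <- paste0(up, core, after, down)
  tx <- transcript_record("txW", "C8orf44", "Hsa",
                          paste0(utr5, cds, utr3),
                          nchar(utr5) + 1L, nchar(utr5) + nchar(cds))
  list(transcript = tx, site_start = nchar(utr5) + nchar(up) + 2L)
}

table2 <- function() site_fragment_tables()$utr5
table5 <- function() site_fragment_tables()$utr3
table6 <- function() site_fragment_tables()$utr3_two_sites
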