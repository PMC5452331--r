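#' Scan a bare sequence for miRNA binding sites
#'
#' Slides a window of the miRNA's length over the sequence, scores each
#' window with the hydrogen-bond energy model, and reports every window
#' whose dG/dGm ratio reaches the threshold. Overlapping hits are all
#' reported; no suppression is applied. At the default threshold of 100%
#' this is exactly an exact-substring search for the miRNA's reverse
#' complement.
#'
#' @param mirna A `mature_mirna` or RNA string.
#' @param seq Nucleotide string (normalized to RNA internally).
#' @param scheme An [energy_scheme()].
#' @param threshold Minimum dG/dGm ratio in percent, in (0, 100];
#'   default 100.
#' @return Data frame with columns `start`, `end` (1-based inclusive),
#'   `site_seq`, `bonds`, `dg_kj_mol`, `ratio_percent`, ordered by
#'   `start`. Empty (with a warning) if the sequence is shorter than the
#'   miRNA.
#' @export
scan_sequence <- function(mirna, seq, scheme = energy_scheme(),
                          threshold = 100) {
  mirna <- as_mirna(mirna)
  stopifnot(threshold > 0, threshold <= 100)
  s <- normalize_seq(seq, "RNA")
  L <- mirna$length
  n <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(),
                      site_seq = character(), bonds = integer(),
                      dg_kj_mol = numeric(), ratio_percent = numeric(),
                      stringsAsFactors = FALSE)
  if (n < L) {
    warning(sprintf("sequence (%d nt) shorter than miRNA (%d nt); no windows",
                    n, L))
    return(empty)
  }
  b <- bond_matrix(scheme)
  mcode <- rev(seq_codes(mirna$sequence))
  scode <- seq_codes(s)
  nwin <- n - L + 1L
  score <- numeric(nwin)
  for (k in seq_len(L)) {
    score <- score + b[mcode[k], scode[k:(k + nwin - 1L)]]
  }
  bonds_max <- hydrogen_bonds(mirna, reverse_complement(mirna$sequence), scheme)
  keep <- which(100 * score / bonds_max >= threshold - 1e-9)
  if (!length(keep)) return(empty)
  data.frame(
    start = keep,
    end = keep + L - 1L,
    site_seq = substring(s, keep, keep + L - 1L),
    bonds = as.integer(score[keep]),
    dg_kj_mol = -scheme$e_bond * score[keep],
    ratio_percent = 100 * score[keep] / bonds_max,
    stringsAsFactors = FALSE
  )
}

#' Best-scoring window of a sequence for a miRNA
#'
#' @inheritParams scan_sequence
#' @return One-row data frame as in [scan_sequence()], for the maximal
#'   bond-count window; ties broken by the leftmost window.
#' @export
best_site <- function(mirna, seq, scheme = energy_scheme()) {
  hits <- scan_sequence(mirna, seq, scheme, threshold = 1e-6)
  if (!nrow(hits)) return(hits)
  hits[which.max(hits$bonds), , drop = FALSE]
}

#' Annotate the region of a candidate site on a transcript
#'
#' The site is assigned to the region containing its start position; the
#' boundary flag is set when the end position falls in a different region
#' (junction-spanning site).
#'
#' @param transcript A `transcript_record`.
#' @param start,end 1-based inclusive site coordinates.
#' @return List with `region` and `boundary_flag`.
#' @export
annotate_region <- function(transcript, start, end) {
  r_start <- region_of(transcript, start)
  r_end <- region_of(transcript, end)
  list(region = r_start, boundary_flag = !identical(r_start, r_end))
}

#' Scan a transcript and annotate hits with their region
#'
#' @inheritParams scan_sequence
#' @param transcript A `transcript_record`.
#' @return Data frame with columns `transcript_id`, `gene`, `species`,
#'   `start`, `end`, `region`, `boundary_flag`, `site_seq`, `bonds`,
#'   `dg_kj_mol`, `ratio_percent`. Coordinates are 1-based inclusive on
#'   the mRNA 5'->3'.
#' @examples
#' tx <- transcript_record("tx1", "DEMO", "Hsa",
#'   paste0(strrep("A", 30), reverse_complement(mir619()$sequence),
#'          strrep("A", 30)), 10, 75, complete_cds = FALSE)
#' scan_transcript(mir619(), tx)
#' @export
scan_transcript <- function(mirna, transcript, scheme = energy_scheme(),
                            threshold = 100) {
  stopifnot(inherits(transcript, "transcript_record"))
  hits <- scan_sequence(mirna, transcript$sequence, scheme, threshold)
  ann <- if (nrow(hits)) {
    lapply(seq_len(nrow(hits)), function(i) {
      annotate_region(transcript, hits$start[i], hits$end[i])
    })
  } else list()
  data.frame(
    transcript_id = rep(transcript$id, nrow(hits)),
    gene = rep(transcript$gene, nrow(hits)),
    species = rep(transcript$species, nrow(hits)),
    start = hits$start, end = hits$end,
    region = vapply(ann, `[[`, character(1L), "region"),
    boundary_flag = vapply(ann, `[[`, logical(1L), "boundary_flag"),
    site_seq = hits$site_seq, bonds = hits$bonds,
    dg_kj_mol = hits$dg_kj_mol, ratio_percent = hits$ratio_percent,
    stringsAsFactors = FALSE
  )
}

#' Scan a set of transcripts
#'
#' @inheritParams scan_transcript
#' @param transcripts List of `transcript_record` objects.
#' @return Row-bound hit table over all transcripts (see
#'   [scan_transcript()]).
#' @export
scan_transcripts <- function(mirna, transcripts, scheme = energy_scheme(),
                             threshold = 100) {
  do.call(rbind, c(lapply(transcripts, function(tx) {
    scan_transcript(mirna, tx, scheme, threshold)
  }), list(make.row.names = FALSE)))
}

#' Summarize a hit table into per-gene and per-region tallies
#'
#' @param hits Hit table from [scan_transcript()]/[scan_transcripts()]
#'   (possibly empty).
#' @return An object of class `target_summary`: list with `total` (hit
#'   count), `region_tally` (named counts over 5UTR/CDS/3UTR, summing to
#'   `total`), `per_gene` (data frame `gene`, `n_sites`, genes sorted
#'   lexicographically), and `multiplicity` (list mapping site count to
#'   the sorted genes with that many sites).
#' @export
summarize_targets <- function(hits) {
  regions <- c("5UTR", "CDS", "3UTR")
  tally <- setNames(integer(3L), regions)
  if (!is.null(hits) && nrow(hits)) {
    tb <- table(factor(hits$region, levels = regions))
    tally[] <- as.integer(tb)
    per_gene <- as.data.frame(table(hits$gene), stringsAsFactors = FALSE)
    names(per_gene) <- c("gene", "n_sites")
    per_gene <- per_gene[order(per_gene$gene), , drop = FALSE]
    rownames(per_gene) <- NULL
    mult <- split(per_gene$gene, per_gene$n_sites)
    mult <- lapply(mult, sort)
  } else {
    per_gene <- data.frame(gene = character(), n_sites = integer(),
                           stringsAsFactors = FALSE)
    mult <- list()
  }
  structure(
    list(total = sum(tally), region_tally = tally,
         per_gene = per_gene, multiplicity = mult),
    class = "target_summary"
  )
}

#' @export
print.target_summary <- function(x, ...) {
  cat(sprintf("<target_summary> %d sites in %d genes (3'UTR %d, CDS %d, 5'UTR %d)\n",
              x$total, nrow(x$per_gene), x$region_tally[["3UTR"]],
              x$region_tally[["CDS"]], x$region_tally[["5UTR"]]))
  for (k in names(x$multiplicity)) {
    genes <- x$multiplicity[[k]]
    cat(sprintf("  %s site(s): %d gene(s)%s\n", k, length(genes),
                if (length(genes) <= 8)
                  paste0(" [", paste(genes, collapse = ", "), "]") else ""))
  }
  invisible(x)
}

#' Write a hit table as TSV
#'
#' Energies are written with 2 decimals; coordinates are 1-based
#' inclusive.
#'
#' @param hits Hit table.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits
  out$dg_kj_mol <- sprintf("%.2f", out$dg_kj_mol)
  out$ratio_percent <- sprintf("%.2f", out$ratio_percent)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a hit table as BED6
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention; the conversion is stated in a header comment
#' line. Scores are the dG/dGm ratio.
#'
#' @param hits Hit table.
#' @param path Output BED path.
#' @export
write_hits_bed <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# BED6; chromStart = start - 1, chromEnd = end",
                   "(0-based half-open from 1-based inclusive)"), con)
  if (nrow(hits)) {
    bed <- data.frame(
      chrom = hits$transcript_id,
      chromStart = hits$start - 1L,
      chromEnd = hits$end,
      name = paste(hits$gene, hits$region, sep = "|"),
      score = sprintf("%.1f", hits$ratio_percent),
      strand = "+",
      stringsAsFactors = FALSE
    )
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
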