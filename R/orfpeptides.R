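# Codon arithmetic for CDS-overlapping binding sites.
#
# Frames are indexed 0/1/2 relative to the site's first nucleotide: frame f
# places codon boundaries at site positions f+1, f+4, ... Edge codons are
# completed with real transcript nucleotides (never padding), so a frame
# whose first codon starts one or two nucleotides upstream of the site
# translates those upstream bases too.

codon_index <- function(transcript, pos) {
  (pos - transcript$cds_start) %/% 3L + 1L
}

#' Translate a CDS-located binding site in all three reading frames
#'
#' For each frame the site is translated together with the minimal
#' flanking transcript nucleotides needed to complete the edge codons
#' (codons are dropped, not padded, where the transcript runs out). The
#' frame matching the transcript's own CDS phase is reported as
#' `annotated_frame`. A site of 22 nt always has exactly one frame
#' containing a stop codon when the site is the perfect miR-619-5p
#' complement: the frame reading `UAA` at site positions 13-15.
#'
#' @param transcript A `transcript_record`.
#' @param start 1-based start of the site; must lie in the CDS.
#' @param end 1-based inclusive end of the site (default a 22-nt site).
#' @return An object of class `frame_report`: list with `site_start`,
#'   `site_end`, `annotated_frame` (0/1/2) and `frames`, a list of three
#'   entries each holding `frame`, `codon_start` (transcript position of
#'   the first translated codon), `peptide`, and `has_stop` (`*` among
#'   the site-overlapping codons of that frame).
#' @export
frame_report <- function(transcript, start, end = start + 21L) {
  stopifnot(inherits(transcript, "transcript_record"))
  if (region_of(transcript, start) != "CDS") stop("site not in CDS")
  s <- as.integer(start); e <- as.integer(end)
  len <- transcript$length
  frames <- lapply(0:2, function(f) {
    a0 <- if (f == 0L) s else s + f - 3L
    a1 <- e - ((e - (s + f)) %% 3L)
    # clip codons falling off the transcript
    while (a0 < 1L) a0 <- a0 + 3L
    while (a1 + 2L > len) a1 <- a1 - 3L
    pep <- if (a1 >= a0) {
      translate_rna(substr(transcript$sequence, a0, a1 + 2L), 0L)
    } else ""
    list(frame = f, codon_start = a0, peptide = pep,
         has_stop = grepl("*", pep, fixed = TRUE))
  })
  ann <- (transcript$cds_start - s) %% 3L
  if (frames[[ann + 1L]]$has_stop) {
    message(sprintf("site at %d-%d: stop codon in the annotated reading frame",
                    s, e))
  }
  structure(
    list(site_start = s, site_end = e, annotated_frame = ann,
         frames = frames),
    class = "frame_report"
  )
}

#' @export
print.frame_report <- function(x, ...) {
  cat(sprintf("<frame_report> site %d-%d, annotated frame %d\n",
              x$site_start, x$site_end, x$annotated_frame))
  for (fr in x$frames) {
    cat(sprintf("  frame %d%s: %s%s\n", fr$frame,
                if (fr$frame == x$annotated_frame) " (annotated)" else "",
                fr$peptide, if (fr$has_stop) "  [stop]" else ""))
  }
  invisible(x)
}

#' Oligopeptide context of a CDS binding site in the annotated frame
#'
#' Translates the whole CDS in its own reading frame and slices out the
#' residues encoded by the site plus flanking residues on either side.
#' The core spans from the first codon containing at least two site
#' nucleotides through the last codon lying entirely inside the site --
#' the convention that matches how site-encoded oligopeptides are
#' conventionally printed with their flanks. Flanks are truncated (never
#' padded) at the CDS ends.
#'
#' @param transcript A `transcript_record`.
#' @param start 1-based site start; must lie in the CDS.
#' @param end 1-based inclusive site end.
#' @param flank_aa Flanking residues on each side (default 7).
#' @return An object of class `peptide_context`: list with `upstream`,
#'   `core`, `downstream` residue strings and `frame` (the annotated
#'   frame, as in [frame_report()]). `paste0(upstream, core, downstream)`
#'   is a contiguous slice of the CDS translation.
#' @export
peptide_context <- function(transcript, start, end = start + 21L,
                            flank_aa = 7L) {
  stopifnot(inherits(transcript, "transcript_record"), flank_aa >= 0L)
  if (region_of(transcript, start) != "CDS") stop("site not in CDS")
  s <- as.integer(start); e <- as.integer(end)
  cds_pep <- translate_rna(
    substr(transcript$sequence, transcript$cds_start, transcript$cds_end), 0L)
  n_codon <- nchar(cds_pep)
  phi <- (s - transcript$cds_start) %% 3L
  psi <- (e - transcript$cds_start) %% 3L
  i0 <- codon_index(transcript, s) + (phi == 2L)
  i1 <- codon_index(transcript, e) - (psi != 2L)
  i0 <- max(i0, 1L)
  i1 <- min(i1, n_codon)
  if (i1 < i0) stop("site does not cover a full codon of the CDS")
  up0 <- max(1L, i0 - flank_aa)
  dn1 <- min(n_codon, i1 + flank_aa)
  structure(
    list(upstream = substr(cds_pep, up0, i0 - 1L),
         core = substr(cds_pep, i0, i1),
         downstream = substr(cds_pep, i1 + 1L, dn1),
         frame = (transcript$cds_start - s) %% 3L,
         codon_range = c(i0, i1)),
    class = "peptide_context"
  )
}

#' @export
print.peptide_context <- function(x, ...) {
  cat(sprintf("<peptide_context> %s[%s]%s (frame %d)\n",
              x$upstream, x$core, x$downstream, x$frame))
  invisible(x)
}

#' Frame and peptide table for all CDS hits of a scan
#'
#' Convenience wrapper applying [frame_report()] and [peptide_context()]
#' to every CDS-region hit in a hit table.
#'
#' @param hits Hit table from [scan_transcripts()].
#' @param transcripts Named list of `transcript_record`s keyed by id.
#' @param flank_aa Flank width for the context columns.
#' @return Data frame with one row per CDS hit and frame (three rows per
#'   hit): `transcript_id`, `gene`, `start`, `frame`, `annotated`,
#'   `peptide`, `has_stop`, plus `upstream`, `core`, `downstream` filled
#'   on the annotated-frame row.
#' @export
peptide_table <- function(hits, transcripts, flank_aa = 7L) {
  cds_hits <- hits[hits$region == "CDS" & !hits$boundary_flag, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cds_hits)), function(i) {
    h <- cds_hits[i, ]
    tx <- transcripts[[h$transcript_id]]
    fr <- frame_report(tx, h$start, h$end)
    ctx <- peptide_context(tx, h$start, h$end, flank_aa = flank_aa)
    do.call(rbind, lapply(fr$frames, function(f) {
      ann <- f$frame == fr$annotated_frame
      data.frame(transcript_id = h$transcript_id, gene = h$gene,
                 start = h$start, frame = f$frame, annotated = ann,
                 peptide = f$peptide, has_stop = f$has_stop,
                 upstream = if (ann) ctx$upstream else "",
                 core = if (ann) ctx$core else "",
                 downstream = if (ann) ctx$downstream else "",
                 stringsAsFactors = FALSE)
    }))
  })
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), gene = character(),
                      start = integer(), frame = integer(),
                      annotated = logical(), peptide = character(),
                      has_stop = logical(), upstream = character(),
                      core = character(), downstream = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
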