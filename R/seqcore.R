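#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet
#' @importFrom Biostrings GENETIC_CODE IUPAC_CODE_MAP
#' @importFrom utils read.delim write.table
#' @importFrom stats setNames runif
NULL

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide sequence to a canonical alphabet
#'
#' Uppercases the sequence, interconverts T and U according to the target
#' alphabet, and collapses every other letter (IUPAC ambiguity codes,
#' X, gaps, ...) to `N`. The internal canonical alphabet of the package is
#' RNA; DNA-written input (as is common for 3'UTR fragments in the
#' literature) is converted on read.
#'
#' @param seq Single nucleotide string. Lowercase accepted.
#' @param alphabet `"RNA"` (default) or `"DNA"`.
#' @return Normalized sequence string over `{A,C,G,U,N}` (or `{A,C,G,T,N}`).
#' @examples
#' normalize_seq("GGCTCATGCCTGTAATCCCAGC")  # -> RNA letters
#' normalize_seq("acgu")
#' @export
normalize_seq <- function(seq, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("empty sequence")
  }
  s <- toupper(seq)
  s <- if (alphabet == "RNA") chartr("T", "U", s) else chartr("U", "T", s)
  keep <- if (alphabet == "RNA") RNA_BASES else DNA_BASES
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  chars[!chars %in% keep] <- "N"
  paste(chars, collapse = "")
}

#' Reverse complement of a nucleotide sequence
#'
#' Antiparallel complement, returned 5'->3'. The alphabet is detected from
#' the sequence itself: a sequence containing T (and no U) is complemented
#' as DNA, anything else as RNA. `N` maps to `N`.
#'
#' @param seq Normalized nucleotide string.
#' @return The reverse complement, same length and alphabet.
#' @examples
#' reverse_complement("GCUGGGAUUACAGGCAUGAGCC")
#' @export
reverse_complement <- function(seq) {
  s <- normalize_seq(seq, if (grepl("T", seq, fixed = TRUE) &&
                              !grepl("U", seq, fixed = TRUE)) "DNA" else "RNA")
  comp <- if (grepl("T", s, fixed = TRUE)) chartr("ACGTN", "TGCAN", s)
          else chartr("ACGUN", "UGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Translate an RNA sequence in a given frame
#'
#' Standard genetic code only. Stop codons are emitted as `*` and
#' translation continues past them (the presence of an in-frame stop is a
#' reported feature, not a truncation point). Codons containing `N` give
#' `X`. A trailing partial codon is dropped; fewer than 3 usable
#' nucleotides give the empty peptide.
#'
#' @param seq Normalized RNA string.
#' @param frame_offset 0, 1 or 2 leading nucleotides to skip.
#' @return Amino-acid string over the 20 standard letters plus `X` and `*`.
#' @examples
#' translate_rna("UGGCUCAUGCCUGUAAUCCCA")   # "WLMPVIP"
#' translate_rna("GGCUCAUGCCUGUAAUCCCAGC")  # contains a stop
#' @export
translate_rna <- function(seq, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  s <- normalize_seq(seq, "RNA")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (frame_offset > 0L) chars <- chars[-seq_len(frame_offset)]
  n_codon <- length(chars) %/% 3L
  if (n_codon == 0L) return("")
  idx <- seq_len(3L * n_codon)
  codons <- apply(matrix(chars[idx], nrow = 3L), 2L, paste, collapse = "")
  aa <- unname(Biostrings::GENETIC_CODE[chartr("U", "T", codons)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Read a FASTA file
#'
#' @param path FASTA file (multi-record, wrapped or unwrapped).
#' @param alphabet Canonical alphabet to normalize records into.
#' @return Named character vector of normalized sequences; names are the
#'   first whitespace-delimited token of each FASTA header.
#' @export
read_fasta <- function(path, alphabet = "RNA") {
  set <- Biostrings::readBStringSet(path)
  seqs <- vapply(as.character(set), normalize_seq, character(1L),
                 alphabet = alphabet)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Construct a transcript record
#'
#' An mRNA sequence together with its 1-based, inclusive CDS interval. The
#' CDS interval partitions the transcript into a 5'UTR `[1, cds_start-1]`,
#' a CDS `[cds_start, cds_end]`, and a 3'UTR `[cds_end+1, length]`; either
#' UTR may be empty.
#'
#' @param id Transcript identifier (FASTA id).
#' @param gene Gene symbol.
#' @param species Short species code (e.g. `"Hsa"`).
#' @param sequence Nucleotide string; normalized to RNA on construction.
#' @param cds_start,cds_end 1-based inclusive CDS bounds.
#' @param complete_cds If `TRUE` (default) the CDS length must be a
#'   multiple of 3.
#' @return An object of class `transcript_record`.
#' @export
transcript_record <- function(id, gene, species, sequence,
                              cds_start, cds_end, complete_cds = TRUE) {
  seq <- normalize_seq(sequence, "RNA")
  len <- nchar(seq)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (is.na(cds_start) || is.na(cds_end) ||
      cds_start < 1L || cds_start > cds_end || cds_end > len) {
    stop(sprintf("record '%s': CDS bounds [%s, %s] violate 1 <= cds_start <= cds_end <= %d",
                 id, cds_start, cds_end, len))
  }
  if (complete_cds && (cds_end - cds_start + 1L) %% 3L != 0L) {
    stop(sprintf("record '%s': complete CDS length %d is not a multiple of 3",
                 id, cds_end - cds_start + 1L))
  }
  structure(
    list(id = id, gene = gene, species = species, sequence = seq,
         length = len, cds_start = cds_start, cds_end = cds_end),
    class = "transcript_record"
  )
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript_record> %s (%s, %s): %d nt, CDS %d-%d\n",
              x$id, x$gene, x$species, x$length, x$cds_start, x$cds_end))
  invisible(x)
}

#' Region boundaries of a transcript
#'
#' @param transcript A `transcript_record`.
#' @return Data frame with columns `region`, `start`, `end`; empty UTRs are
#'   omitted. The three regions tile `[1, length]` exactly once.
#' @export
transcript_regions <- function(transcript) {
  stopifnot(inherits(transcript, "transcript_record"))
  out <- data.frame(
    region = c("5UTR", "CDS", "3UTR"),
    start = c(1L, transcript$cds_start, transcript$cds_end + 1L),
    end = c(transcript$cds_start - 1L, transcript$cds_end, transcript$length),
    stringsAsFactors = FALSE
  )
  out[out$end >= out$start, , drop = FALSE]
}

#' Region containing each of a set of transcript positions
#'
#' @param transcript A `transcript_record`.
#' @param pos Integer vector of 1-based positions.
#' @return Character vector over `{"5UTR","CDS","3UTR"}`.
#' @export
region_of <- function(transcript, pos) {
  stopifnot(all(pos >= 1L), all(pos <= transcript$length))
  ifelse(pos < transcript$cds_start, "5UTR",
         ifelse(pos <= transcript$cds_end, "CDS", "3UTR"))
}

#' Read transcripts from a FASTA file plus an annotation table
#'
#' The annotation table is a TSV with header columns `id`, `gene`,
#' `species`, `cds_start`, `cds_end`, keyed to the FASTA ids. Every row
#' must resolve to a FASTA record and satisfy the CDS invariants.
#'
#' @param fasta_path FASTA of transcript sequences.
#' @param table_path TSV annotation table.
#' @param complete_cds Passed through to [transcript_record()].
#' @return Named list of `transcript_record` objects, keyed by id.
#' @export
read_transcript_table <- function(fasta_path, table_path, complete_cds = TRUE) {
  seqs <- read_fasta(fasta_path, alphabet = "RNA")
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  need <- c("id", "gene", "species", "cds_start", "cds_end")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(tab$id, names(seqs))
  if (length(missing)) {
    stop("annotation rows reference ids absent from FASTA: ",
         paste(missing, collapse = ", "))
  }
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    transcript_record(tab$id[i], tab$gene[i], tab$species[i],
                      seqs[[tab$id[i]]], tab$cds_start[i], tab$cds_end[i],
                      complete_cds = complete_cds)
  })
  setNames(recs, tab$id)
}

#' Write the annotation table companion for a set of transcript records
#'
#' @param transcripts List of `transcript_record` objects.
#' @param path Output TSV path.
#' @export
write_transcript_table <- function(transcripts, path) {
  tab <- data.frame(
    id = vapply(transcripts, `[[`, character(1L), "id"),
    gene = vapply(transcripts, `[[`, character(1L), "gene"),
    species = vapply(transcripts, `[[`, character(1L), "species"),
    cds_start = vapply(transcripts, `[[`, integer(1L), "cds_start"),
    cds_end = vapply(transcripts, `[[`, integer(1L), "cds_end"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The mature miR-619-5p query
#'
#' The packaged 22-nt mature miRNA sequence used throughout the worked
#' examples, written 5'->3' in RNA letters.
#'
#' @return A `mature_mirna` object.
#' @examples
#' mir619()
#' @export
mir619 <- function() {
  mature_mirna("hsa-miR-619-5p", "GCUGGGAUUACAGGCAUGAGCC")
}

#' Construct a mature miRNA
#'
#' @param id Short text label.
#' @param sequence RNA string 5'->3'; normalized on construction.
#' @return An object of class `mature_mirna` with fields `id`, `sequence`,
#'   `length`.
#' @export
mature_mirna <- function(id, sequence) {
  seq <- normalize_seq(sequence, "RNA")
  structure(list(id = id, sequence = seq, length = nchar(seq)),
            class = "mature_mirna")
}

#' @export
print.mature_mirna <- function(x, ...) {
  cat(sprintf("<mature_mirna> %s: %s (%d nt)\n", x$id, x$sequence, x$length))
  invisible(x)
}

# Accept either a mature_mirna or a bare string wherever a miRNA is needed.
as_mirna <- function(x) {
  if (inherits(x, "mature_mirna")) return(x)
  mature_mirna("miRNA", x)
}
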