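#' Bundled example inputs
#'
#' The package ships the mature miR-619-5p query and three TSV tables of
#' published ortholog site fragments (5'UTR sites, 3'UTR sites of three
#' genes, and two-site 3'UTR genes), usable as ready-made inputs for the
#' conservation workflow.
#'
#' @return Named list of three data frames (`utr5`, `utr3`, `utr3_two_sites`),
#'   each with columns `species`, `gene`, `position` (printed full-mRNA
#'   site position), `site_offset` (1-based site start within the
#'   fragment) and `fragment`.
#' @export
site_fragment_tables <- function() {
  rd <- function(f) utils::read.delim(
    system.file("extdata", f, package = "mirsite"), stringsAsFactors = FALSE)
  list(utr5 = rd("table2_utr5_sites.tsv"),
       utr3 = rd("table5_utr3_sites.tsv"),
       utr3_two_sites = rd("table6_utr3_two_sites.tsv"))
}

fragment_families <- function(tab) {
  fams <- lapply(split(tab, tab$gene), function(g) {
    if (nrow(g) < 2L) return(NULL)
    ortholog_family(g$gene[1L],
                    data.frame(species = g$species, fragment = g$fragment,
                               position = g$site_offset,
                               stringsAsFactors = FALSE))
  })
  Filter(Negate(is.null), fams)
}

#' Assemble a run configuration
#'
#' @param mirna_fa FASTA with the (single) mature miRNA query.
#' @param transcripts_fa FASTA of mRNA sequences.
#' @param annot_tsv Companion annotation TSV (`id`, `gene`, `species`,
#'   `cds_start`, `cds_end`).
#' @param out_dir Output directory (created if absent).
#' @param family_tsv Optional ortholog-family TSV (`gene`, `species`,
#'   `fragment`) for the conservation stage.
#' @param threshold dG/dGm threshold in percent, in (0, 100].
#' @param scheme An [energy_scheme()] or path to a YAML scheme override.
#' @param anchor_threshold Anchor threshold for family alignment.
#' @param flank_aa Peptide context flank width, residues.
#' @param n_groups Gene groups for the pooled frequency matrices.
#' @param seed Seed recorded in the run log (the scan itself is
#'   deterministic; the seed matters when inputs are generated).
#' @return A validated `run_config` list.
#' @export
run_config <- function(mirna_fa, transcripts_fa, annot_tsv, out_dir,
                       family_tsv = NULL, threshold = 100,
                       scheme = energy_scheme(), anchor_threshold = 80,
                       flank_aa = 7L, n_groups = 4L, seed = 1L) {
  for (p in c(mirna_fa, transcripts_fa, annot_tsv, family_tsv)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (!(threshold > 0 && threshold <= 100)) stop("threshold must be in (0, 100]")
  if (is.character(scheme)) scheme <- read_energy_scheme(scheme)
  stopifnot(inherits(scheme, "energy_scheme"))
  structure(list(mirna_fa = mirna_fa, transcripts_fa = transcripts_fa,
                 annot_tsv = annot_tsv, family_tsv = family_tsv,
                 out_dir = out_dir, threshold = threshold, scheme = scheme,
                 anchor_threshold = anchor_threshold, flank_aa = flank_aa,
                 n_groups = n_groups, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full scan -> localize -> summarize -> peptides -> conservation
#' pipeline
#'
#' Deterministic for fixed inputs and config: reruns produce
#' byte-identical TSVs. A run log (stage counts and a config hash) is
#' written alongside the outputs and echoed to `stderr`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the hit table, target summary, peptide
#'   table and (if a family TSV was given) the per-gene alignments and
#'   grouped variation matrices.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    message(msg)
  }
  cfg_hash <- sum(utf8ToInt(paste(
    vapply(config[c("threshold", "anchor_threshold", "flank_aa",
                    "n_groups", "seed")], as.character, character(1L)),
    collapse = "|")))
  say("mirsite %s | config hash %d | seed %d",
      as.character(utils::packageVersion("mirsite")), cfg_hash, config$seed)

  mirna_seqs <- read_fasta(config$mirna_fa)
  if (length(mirna_seqs) != 1L) stop("stage mirna: expected exactly one query")
  mirna <- mature_mirna(names(mirna_seqs), mirna_seqs[[1L]])
  say("stage mirna: %s (%d nt)", mirna$id, mirna$length)

  transcripts <- tryCatch(
    read_transcript_table(config$transcripts_fa, config$annot_tsv,
                          complete_cds = FALSE),
    error = function(e) stop("stage input: ", conditionMessage(e)))
  say("stage input: %d transcripts", length(transcripts))

  hits <- scan_transcripts(mirna, transcripts, config$scheme,
                           config$threshold)
  write_hits_tsv(hits, file.path(config$out_dir, "hits.tsv"))
  write_hits_bed(hits, file.path(config$out_dir, "hits.bed"))
  say("stage scan: %d hits at threshold %.1f%%", nrow(hits), config$threshold)

  summ <- summarize_targets(hits)
  tally_tab <- data.frame(region = names(summ$region_tally),
                          n_sites = as.integer(summ$region_tally))
  utils::write.table(tally_tab, file.path(config$out_dir, "region_tally.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summ$per_gene, file.path(config$out_dir, "per_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("stage summarize: %d sites / %d genes", summ$total, nrow(summ$per_gene))

  peps <- peptide_table(hits, transcripts, flank_aa = config$flank_aa)
  utils::write.table(peps, file.path(config$out_dir, "peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("stage orf: %d CDS-hit frame rows", nrow(peps))

  aligned <- NULL
  matrices <- NULL
  if (!is.null(config$family_tsv)) {
    fams <- read_family_tsv(config$family_tsv)
    aligned <- lapply(fams, anchor_align, mirna = mirna,
                      scheme = config$scheme,
                      anchor_threshold = config$anchor_threshold)
    groups <- group_genes(names(aligned), config$n_groups)
    matrices <- lapply(groups, function(genes) {
      frequency_matrix(aligned[genes])
    })
    for (g in names(matrices)) {
      write_variation_tsv(matrices[[g]],
                          file.path(config$out_dir,
                                    sprintf("variation_%s.tsv", g)))
    }
    say("stage conserve: %d families in %d groups",
        length(aligned), length(matrices))
  }
  invisible(list(mirna = mirna, hits = hits, summary = summ,
                 peptides = peps, aligned = aligned, matrices = matrices))
}
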