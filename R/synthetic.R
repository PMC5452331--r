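# Seedable generators for transcripts, cohorts and ortholog families with
# a plant manifest recording the complete ground truth, so scans and
# summaries can be checked against a known answer.

SPECIES_POOL <- c("Hsa", "Ptr", "Ggo", "Ppa", "Pab", "Nle", "Mle", "Can",
                  "Rro", "Mfa", "Mmu", "Mne", "Csa", "Pan", "Cja", "Bmu",
                  "Cdr", "Cfe", "Eca", "Oar")

random_rna <- function(n) {
  paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")
}

mutate_base <- function(base) {
  sample(setdiff(RNA_BASES, base), 1L)
}

# all (possibly overlapping) start positions of `motif` in `chars`
motif_occurrences <- function(chars, motif_chars) {
  n <- length(chars); L <- length(motif_chars)
  if (n < L) return(integer())
  hits <- integer()
  cand <- which(chars == motif_chars[1L])
  cand <- cand[cand <= n - L + 1L]
  for (p in cand) {
    if (all(chars[p:(p + L - 1L)] == motif_chars)) hits <- c(hits, p)
  }
  hits
}

#' Generate a synthetic transcript with planted miRNA binding sites
#'
#' Background nucleotides are i.i.d. uniform over `{A,C,G,U}`; plants are
#' then written at their exact positions, either as the perfect site
#' (reverse complement of the miRNA) or with substitutions at the listed
#' site positions. Any accidental background occurrence of the perfect
#' site is re-randomized away, so the returned manifest is the complete
#' truth: a scan at threshold 100 finds exactly the exact plants.
#'
#' @param utr5_len,cds_len,utr3_len Region lengths in nt; `cds_len` must
#'   be a positive multiple of 3.
#' @param plants List of plant specs, each a list with `position`
#'   (1-based transcript start) and optional `substitutions` (integer
#'   site positions 1..22 to mutate). Plants must fit entirely inside one
#'   region and must not overlap each other.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param mirna A `mature_mirna` (default [mir619()]).
#' @param id,gene,species Record labels.
#' @return List with `transcript` (a `transcript_record`) and `manifest`
#'   (plant positions, regions, variant site sequences and their dG/dGm
#'   ratios, plus the generator parameters and seed).
#' @examples
#' out <- make_transcript(100, 300, 500,
#'                        plants = list(list(position = 450)), seed = 1)
#' scan_transcript(mir619(), out$transcript)$start  # 450
#' @export
make_transcript <- function(utr5_len, cds_len, utr3_len, plants = list(),
                            seed = NULL, mirna = mir619(), id = "tx1",
                            gene = "GENE1", species = "Hsa") {
  mirna <- as_mirna(mirna)
  L <- mirna$length
  stopifnot(utr5_len >= 0L, utr3_len >= 0L, cds_len >= 3L)
  if (cds_len %% 3L != 0L) stop("cds_len must be a multiple of 3")
  if (!is.null(seed)) set.seed(seed)
  n <- utr5_len + cds_len + utr3_len
  cds_start <- utr5_len + 1L
  cds_end <- utr5_len + cds_len
  region_at <- function(pos) {
    ifelse(pos < cds_start, "5UTR", ifelse(pos <= cds_end, "CDS", "3UTR"))
  }
  perfect <- reverse_complement(mirna$sequence)
  perfect_chars <- strsplit(perfect, "", fixed = TRUE)[[1L]]

  # validate plants: in-bounds, single-region, pairwise disjoint
  starts <- vapply(plants, function(p) as.integer(p$position), integer(1L))
  if (length(starts)) {
    if (any(starts < 1L | starts + L - 1L > n)) stop("plant outside transcript")
    if (any(region_at(starts) != region_at(starts + L - 1L))) {
      stop("plant spans a region boundary")
    }
    o <- order(starts)
    if (any(diff(starts[o]) < L)) stop("overlapping plants")
  }

  chars <- sample(RNA_BASES, n, replace = TRUE)
  plant_info <- vector("list", length(plants))
  for (i in seq_along(plants)) {
    p <- plants[[i]]
    subs <- sort(unique(as.integer(p$substitutions %||% integer())))
    if (length(subs) && (min(subs) < 1L || max(subs) > L)) {
      stop("substitution positions must lie in 1..", L)
    }
    site <- perfect_chars
    for (j in subs) site[j] <- mutate_base(site[j])
    chars[starts[i]:(starts[i] + L - 1L)] <- site
    plant_info[[i]] <- list(position = starts[i],
                            region = region_at(starts[i]),
                            substitutions = subs,
                            site_seq = paste(site, collapse = ""))
  }

  # scrub accidental perfect-site occurrences not declared in the manifest
  exact_positions <- starts[vapply(plant_info, function(p)
    length(p$substitutions) == 0L, logical(1L))]
  protected <- unlist(lapply(starts, function(s) s:(s + L - 1L)))
  for (iter in seq_len(100L)) {
    occ <- setdiff(motif_occurrences(chars, perfect_chars), exact_positions)
    if (!length(occ)) break
    for (p in occ) {
      idx <- setdiff(p:(p + L - 1L), protected)
      if (!length(idx)) stop("cannot scrub occurrence overlapping plants")
      k <- idx[1L]
      chars[k] <- mutate_base(chars[k])
    }
  }

  tx <- transcript_record(id, gene, species, paste(chars, collapse = ""),
                          cds_start, cds_end)
  for (i in seq_along(plant_info)) {
    plant_info[[i]]$ratio <-
      delta_g(mirna, plant_info[[i]]$site_seq)$ratio
  }
  list(transcript = tx,
       manifest = list(id = id, gene = gene, species = species,
                       seed = seed, utr5_len = utr5_len, cds_len = cds_len,
                       utr3_len = utr3_len, plants = plant_info))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected exact-site hits implied by a manifest
#'
#' The exact plants (no substitutions) of one or more transcript
#' manifests, i.e. the complete expected result of a threshold-100 scan.
#'
#' @param manifest A single transcript manifest or a cohort manifest
#'   (with a `transcripts` element).
#' @return Data frame `transcript_id`, `gene`, `start`, `region`, sorted
#'   by transcript then start.
#' @export
expected_hits <- function(manifest) {
  mlist <- if (!is.null(manifest$transcripts)) manifest$transcripts
           else list(manifest)
  rows <- do.call(rbind, lapply(mlist, function(m) {
    exact <- Filter(function(p) length(p$substitutions) == 0L, m$plants)
    if (!length(exact)) return(NULL)
    data.frame(transcript_id = m$id, gene = m$gene,
               start = vapply(exact, `[[`, integer(1L), "position"),
               region = vapply(exact, `[[`, character(1L), "region"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(transcript_id = character(), gene = character(),
                       start = integer(), region = character(),
                       stringsAsFactors = FALSE)
  }
  rows[order(rows$transcript_id, rows$start), , drop = FALSE]
}

#' Generate a cohort of synthetic target transcripts
#'
#' Builds `n_genes` transcripts whose per-gene site counts follow the
#' given multiplicity map. Site regions are drawn from `region_probs`,
#' which defaults to the empirical proportions of a large complete-
#' complementarity target set (214 3'UTR : 3 CDS : 4 5'UTR sites);
#' positions are uniform within the chosen region.
#'
#' @param n_genes Number of genes (one transcript each).
#' @param multiplicity Named integer vector mapping site count to the
#'   number of genes with that many sites (e.g. `c("4" = 27, "5" = 7)`);
#'   must sum to `n_genes`. Default: one site per gene.
#' @param region_probs Named sampling weights over `5UTR`, `CDS`, `3UTR`.
#' @param utr5_len,cds_len,utr3_len Region lengths for every transcript.
#' @param seed Master seed; per-transcript seeds are derived from it.
#' @param mirna A `mature_mirna`.
#' @param out_dir Optional directory: writes `transcripts.fa`,
#'   `transcripts.tsv` and `manifest.json` there.
#' @return List with `transcripts` (named list of records) and `manifest`
#'   (cohort-level, with a `transcripts` list of per-record manifests).
#' @export
make_cohort <- function(n_genes,
                        multiplicity = setNames(n_genes, "1"),
                        region_probs = c("5UTR" = 4, "CDS" = 3, "3UTR" = 214),
                        utr5_len = 150L, cds_len = 999L, utr3_len = 1500L,
                        seed = NULL, mirna = mir619(), out_dir = NULL) {
  mirna <- as_mirna(mirna)
  L <- mirna$length
  if (n_genes == 0L) {
    return(list(transcripts = list(),
                manifest = list(seed = seed, transcripts = list())))
  }
  multiplicity <- multiplicity[multiplicity > 0]
  if (sum(multiplicity) != n_genes) {
    stop("multiplicity map must account for exactly n_genes genes")
  }
  if (!is.null(seed)) set.seed(seed)
  site_counts <- sample(rep(as.integer(names(multiplicity)), multiplicity))
  tx_seeds <- sample.int(.Machine$integer.max, n_genes)
  cds_start <- utr5_len + 1L
  cds_end <- utr5_len + cds_len
  bounds <- list("5UTR" = c(1L, utr5_len), "CDS" = c(cds_start, cds_end),
                 "3UTR" = c(cds_end + 1L, utr5_len + cds_len + utr3_len))
  usable <- names(region_probs)[vapply(names(region_probs), function(r)
    bounds[[r]][2L] - bounds[[r]][1L] + 1L >= L, logical(1L))]
  probs <- region_probs[usable] / sum(region_probs[usable])

  plans <- lapply(seq_len(n_genes), function(i) {
    k <- site_counts[i]
    for (try in seq_len(1000L)) {
      regions <- sample(usable, k, replace = TRUE, prob = probs)
      pos <- vapply(regions, function(r) {
        lo <- bounds[[r]][1L]; hi <- bounds[[r]][2L] - L + 1L
        lo + sample.int(hi - lo + 1L, 1L) - 1L
      }, integer(1L))
      o <- order(pos)
      if (k <= 1L || all(diff(pos[o]) >= L)) {
        return(lapply(pos, function(p) list(position = p)))
      }
    }
    stop("could not place ", k, " non-overlapping sites")
  })

  out <- lapply(seq_len(n_genes), function(i) {
    make_transcript(utr5_len, cds_len, utr3_len, plants = plans[[i]],
                    seed = tx_seeds[i], mirna = mirna,
                    id = sprintf("tx%04d", i), gene = sprintf("G%04d", i))
  })
  transcripts <- setNames(lapply(out, `[[`, "transcript"),
                          vapply(out, function(x) x$transcript$id,
                                 character(1L)))
  manifest <- list(seed = seed, transcripts = lapply(out, `[[`, "manifest"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(vapply(transcripts, `[[`, character(1L), "sequence"),
                file.path(out_dir, "transcripts.fa"))
    write_transcript_table(transcripts, file.path(out_dir, "transcripts.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  list(transcripts = transcripts, manifest = manifest)
}

#' Generate a synthetic ortholog family with known substitution rates
#'
#' The reference member carries the perfect site with random flanks; each
#' other member is derived from it by independent per-position
#' substitutions at rate `s_site` inside the site and `f_flank` in the
#' flanks (a substitution always changes the base).
#'
#' @param gene Gene symbol.
#' @param n_species Number of members including the reference.
#' @param f_flank,s_site Per-position substitution rates; require
#'   `0 <= s_site <= f_flank <= 0.5`. Defaults emulate families whose
#'   site is much more conserved than its flanks.
#' @param flank_len Flank length on each side of the site, nt.
#' @param seed Integer seed.
#' @param mirna A `mature_mirna`.
#' @return List with `family` (an `ortholog_family`, reference species
#'   first) and `manifest` (rates, seed, site offset, and per-member
#'   realized substitution positions, fragment-relative).
#' @export
make_family <- function(gene = "GENE1", n_species = 10L, f_flank = 0.1,
                        s_site = 0.01, flank_len = 10L, seed = NULL,
                        mirna = mir619()) {
  mirna <- as_mirna(mirna)
  L <- mirna$length
  stopifnot(n_species >= 2L, flank_len >= 0L)
  if (!(s_site >= 0 && s_site <= f_flank && f_flank <= 0.5)) {
    stop("need 0 <= s_site <= f_flank <= 0.5")
  }
  if (!is.null(seed)) set.seed(seed)
  species <- c(SPECIES_POOL, sprintf("Sp%02d", seq_len(max(0L, n_species - length(SPECIES_POOL)))))[seq_len(n_species)]
  ref <- c(strsplit(random_rna(flank_len), "")[[1L]],
           strsplit(reverse_complement(mirna$sequence), "")[[1L]],
           strsplit(random_rna(flank_len), "")[[1L]])
  frag_len <- length(ref)
  in_site <- seq_len(frag_len) > flank_len & seq_len(frag_len) <= flank_len + L
  rates <- ifelse(in_site, s_site, f_flank)
  fragments <- character(n_species)
  fragments[1L] <- paste(ref, collapse = "")
  mutations <- vector("list", n_species)
  mutations[[1L]] <- integer()
  for (i in seq_len(n_species)[-1L]) {
    hit <- which(runif(frag_len) < rates)
    row <- ref
    for (j in hit) row[j] <- mutate_base(row[j])
    fragments[i] <- paste(row, collapse = "")
    mutations[[i]] <- hit
  }
  names(mutations) <- species
  fam <- ortholog_family(gene, data.frame(
    species = species, fragment = fragments,
    position = flank_len + 1L, stringsAsFactors = FALSE))
  list(family = fam,
       manifest = list(gene = gene, seed = seed, n_species = n_species,
                       f_flank = f_flank, s_site = s_site,
                       flank_len = flank_len, site_start = flank_len + 1L,
                       site_len = L, mutations = mutations))
}
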