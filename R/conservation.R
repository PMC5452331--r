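#' Construct an ortholog family of site-bearing fragments
#'
#' A family is a gene together with per-species sequence fragments, each
#' expected to carry one miRNA binding site (possibly with a small number
#' of substitutions).
#'
#' @param gene Gene symbol.
#' @param members Data frame with columns `species`, `fragment` and
#'   optionally `position` (declared site offset within the fragment,
#'   1-based, `NA` when unknown). At least 2 members.
#' @return An object of class `ortholog_family`.
#' @export
ortholog_family <- function(gene, members) {
  stopifnot(is.data.frame(members),
            all(c("species", "fragment") %in% names(members)))
  if (nrow(members) < 2L) stop("an ortholog family needs at least 2 members")
  members$fragment <- vapply(members$fragment, normalize_seq, character(1L),
                             alphabet = "RNA")
  if (is.null(members$position)) members$position <- NA_integer_
  structure(list(gene = gene, members = members), class = "ortholog_family")
}

#' Read ortholog families from a TSV
#'
#' Expected columns: `gene`, `species`, `fragment`, optional `position`.
#'
#' @param path TSV path.
#' @return Named list of `ortholog_family` objects, one per gene.
#' @export
read_family_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "species", "fragment") %in% names(tab)))
  fams <- lapply(split(tab, tab$gene), function(g) {
    ortholog_family(g$gene[1L], g[, setdiff(names(g), "gene"), drop = FALSE])
  })
  fams[sort(names(fams))]
}

#' Anchor-align family fragments on their best-scoring site window
#'
#' Each member's fragment is scanned and its best dG/dGm window (leftmost
#' on ties) is placed at site columns 1..22; flanking nucleotides hang at
#' columns <= 0 (upstream) and >= 23 (downstream). Members whose best
#' window falls below the anchor threshold are excluded with a message.
#' No gaps are introduced: the site anchor plus fixed flank columns
#' suffice for gap-free fragments.
#'
#' @param family An `ortholog_family`.
#' @param mirna A `mature_mirna` or RNA string.
#' @param scheme An [energy_scheme()].
#' @param anchor_threshold Minimum dG/dGm ratio (%) for a member to
#'   anchor; default 80.
#' @return An object of class `aligned_family`: list with `gene`,
#'   `members` (data frame `species`, `fragment`, `site_start`, `ratio`),
#'   `columns` (integer column labels; site = 1..22), `in_site` (logical
#'   mask over columns) and `matrix` (character matrix members x columns,
#'   `NA` where a fragment has no coverage).
#' @export
anchor_align <- function(family, mirna, scheme = energy_scheme(),
                         anchor_threshold = 80) {
  stopifnot(inherits(family, "ortholog_family"))
  mirna <- as_mirna(mirna)
  L <- mirna$length
  mem <- family$members
  best <- lapply(seq_len(nrow(mem)), function(i) {
    if (nchar(mem$fragment[i]) < L) return(NULL)
    best_site(mirna, mem$fragment[i], scheme)
  })
  keep <- logical(nrow(mem))
  starts <- integer(nrow(mem))
  ratios <- numeric(nrow(mem))
  for (i in seq_len(nrow(mem))) {
    b <- best[[i]]
    if (is.null(b) || !nrow(b) || b$ratio_percent < anchor_threshold - 1e-9) {
      message(sprintf("family %s: member %s excluded (best ratio %s < %.1f%%)",
                      family$gene, mem$species[i],
                      if (is.null(b) || !nrow(b)) "none"
                      else sprintf("%.1f%%", b$ratio_percent),
                      anchor_threshold))
      next
    }
    keep[i] <- TRUE
    starts[i] <- b$start
    ratios[i] <- b$ratio_percent
  }
  mem <- mem[keep, , drop = FALSE]
  starts <- starts[keep]
  ratios <- ratios[keep]
  if (!nrow(mem)) stop(sprintf("family %s: no member anchored", family$gene))
  # column of fragment position p for member i: p - site_start + 1
  col_min <- min(1L - (starts - 1L))
  col_max <- max(nchar(mem$fragment) - starts + 1L)
  columns <- seq.int(col_min, col_max)
  mat <- matrix(NA_character_, nrow = nrow(mem), ncol = length(columns),
                dimnames = list(mem$species, NULL))
  for (i in seq_len(nrow(mem))) {
    chars <- strsplit(mem$fragment[i], "", fixed = TRUE)[[1L]]
    cols <- seq_along(chars) - starts[i] + 1L
    mat[i, match(cols, columns)] <- chars
  }
  structure(
    list(gene = family$gene,
         members = data.frame(species = mem$species,
                              fragment = mem$fragment,
                              site_start = starts, ratio = ratios,
                              stringsAsFactors = FALSE),
         columns = columns, in_site = columns >= 1L & columns <= L,
         matrix = mat),
    class = "aligned_family"
  )
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family> %s: %d members, columns %d..%d (site 1..%d)\n",
              x$gene, nrow(x$members), min(x$columns), max(x$columns),
              sum(x$in_site)))
  invisible(x)
}

#' Per-column substitution profile of an aligned family
#'
#' Compares every non-reference member to the reference species
#' position-by-position over columns where both have coverage, splitting
#' mismatch tallies into in-site and flank columns. Swapping the
#' reference between two members leaves each pairwise mismatch set
#' unchanged (mismatch is symmetric).
#'
#' @param aligned An `aligned_family`.
#' @param reference Reference species code; must be a member.
#' @return An object of class `substitution_profile`: list with
#'   `reference`, `per_column` (data frame `column`, `in_site`,
#'   `mismatches`), `per_member` (named list of mismatch column vectors)
#'   and `totals` (named counts `in_site`, `flank`).
#' @export
substitution_profile <- function(aligned, reference) {
  stopifnot(inherits(aligned, "aligned_family"))
  ref_i <- match(reference, aligned$members$species)
  if (is.na(ref_i)) stop(sprintf("reference species '%s' absent", reference))
  ref <- aligned$matrix[ref_i, ]
  others <- setdiff(seq_len(nrow(aligned$members)), ref_i)
  per_member <- list()
  mism <- integer(length(aligned$columns))
  for (i in others) {
    row <- aligned$matrix[i, ]
    diff <- which(!is.na(row) & !is.na(ref) & row != ref)
    per_member[[aligned$members$species[i]]] <- aligned$columns[diff]
    mism[diff] <- mism[diff] + 1L
  }
  per_column <- data.frame(column = aligned$columns,
                           in_site = aligned$in_site,
                           mismatches = mism)
  structure(
    list(reference = reference, per_column = per_column,
         per_member = per_member,
         totals = c(in_site = sum(mism[aligned$in_site]),
                    flank = sum(mism[!aligned$in_site]))),
    class = "substitution_profile"
  )
}

#' @export
print.substitution_profile <- function(x, ...) {
  cat(sprintf("<substitution_profile> vs %s: %d in-site, %d flank substitutions\n",
              x$reference, x$totals[["in_site"]], x$totals[["flank"]]))
  invisible(x)
}

# sorted-DNA-letter-set -> IUPAC ambiguity letter (e.g. "AG" -> "R")
iupac_lookup <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  setNames(names(map),
           vapply(map, function(s)
             paste(sort(strsplit(s, "")[[1L]]), collapse = ""), character(1L)))
})

#' Position frequency matrix over one or more aligned families
#'
#' Pools per-column nucleotide counts over the members of the given
#' aligned families (a gene group). The consensus at each column is the
#' most frequent base, with ties rendered as the IUPAC ambiguity letter
#' for the tied set; `N` counts toward coverage but never toward the
#' consensus.
#'
#' @param aligned_sets One `aligned_family` or a list of them.
#' @param alphabet `"RNA"` (default) or `"DNA"` for the output letters.
#' @return An object of class `variation_matrix`: list with `columns`,
#'   `in_site`, `counts` (5 x k matrix over A,C,G,U,N), `freqs`
#'   (column-normalized over covered members) and `consensus` (character
#'   vector).
#' @export
frequency_matrix <- function(aligned_sets, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (inherits(aligned_sets, "aligned_family")) {
    aligned_sets <- list(aligned_sets)
  }
  stopifnot(length(aligned_sets) >= 1L,
            all(vapply(aligned_sets, inherits, logical(1L), "aligned_family")))
  columns <- sort(unique(unlist(lapply(aligned_sets, `[[`, "columns"))))
  letters5 <- c(RNA_BASES, "N")
  counts <- matrix(0L, nrow = 5L, ncol = length(columns),
                   dimnames = list(letters5, columns))
  for (af in aligned_sets) {
    for (i in seq_len(nrow(af$matrix))) {
      row <- af$matrix[i, ]
      ok <- !is.na(row)
      j <- match(af$columns[ok], columns)
      k <- match(row[ok], letters5)
      for (t in seq_along(j)) counts[k[t], j[t]] <- counts[k[t], j[t]] + 1L
    }
  }
  cov <- colSums(counts)
  freqs <- sweep(counts, 2L, pmax(cov, 1L), "/")
  consensus <- vapply(seq_along(columns), function(j) {
    base_counts <- counts[RNA_BASES, j]
    if (sum(base_counts) == 0L) return("N")
    top <- RNA_BASES[base_counts == max(base_counts)]
    if (length(top) == 1L) {
      if (alphabet == "DNA") chartr("U", "T", top) else top
    } else {
      code <- iupac_lookup[[paste(sort(chartr("U", "T", top)), collapse = "")]]
      if (alphabet == "DNA") code else chartr("T", "U", code)
    }
  }, character(1L))
  if (alphabet == "DNA") {
    rn <- rownames(counts); rn[rn == "U"] <- "T"
    rownames(counts) <- rn; rownames(freqs) <- rn
  }
  structure(
    list(columns = columns, in_site = columns >= 1L & columns <= 22L,
         counts = counts, freqs = freqs, consensus = consensus,
         alphabet = alphabet),
    class = "variation_matrix"
  )
}

#' @export
print.variation_matrix <- function(x, ...) {
  cat(sprintf("<variation_matrix> %d columns (%s); site consensus: %s\n",
              length(x$columns), x$alphabet,
              paste(x$consensus[x$in_site], collapse = "")))
  invisible(x)
}

#' Consensus string of a variation matrix
#'
#' @param vm A `variation_matrix`.
#' @param site_only Restrict to the site columns 1..22 (default).
#' @return Consensus string.
#' @export
consensus_string <- function(vm, site_only = TRUE) {
  stopifnot(inherits(vm, "variation_matrix"))
  sel <- if (site_only) vm$in_site else rep(TRUE, length(vm$columns))
  paste(vm$consensus[sel], collapse = "")
}

#' Split genes into alphabetical groups
#'
#' Genes are sorted lexicographically and divided into contiguous groups
#' of near-equal size, the convention used for grouped conservation
#' summaries.
#'
#' @param genes Character vector of gene symbols.
#' @param n_groups Number of groups (default 4).
#' @return Named list of sorted gene vectors (`group1`, `group2`, ...).
#' @export
group_genes <- function(genes, n_groups = 4L) {
  g <- sort(unique(genes))
  if (!length(g)) return(setNames(list(), character()))
  n_groups <- min(n_groups, length(g))
  idx <- ceiling(seq_along(g) / (length(g) / n_groups))
  idx <- pmin(idx, n_groups)
  setNames(split(g, idx), paste0("group", seq_len(n_groups)))
}

#' Write a variation matrix as TSV
#'
#' Columns: `column`, `in_site`, one count column per base, `consensus`.
#'
#' @param vm A `variation_matrix`.
#' @param path Output path.
#' @export
write_variation_tsv <- function(vm, path) {
  out <- data.frame(column = vm$columns, in_site = vm$in_site,
                    t(vm$counts), consensus = vm$consensus,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a logo-ready frequency matrix (position x 4 base frequencies)
#'
#' @param vm A `variation_matrix`.
#' @param path Output path.
#' @export
write_logo_matrix <- function(vm, path) {
  bases <- rownames(vm$freqs)[1:4]
  out <- data.frame(position = vm$columns,
                    t(vm$freqs[bases, , drop = FALSE]),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
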