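GAPCHARS <- c("-", "N")  # ambiguous bases are treated as gaps throughout

.ng86 <- new.env(parent = emptyenv())

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# Synonymous site count of one codon: at each position, the fraction of the
# three possible changes that preserve the amino acid. Changes to stop codons
# count as nonsynonymous (denominator stays 3).
ng86_syn_sites <- function() {
  if (!is.null(.ng86$sites)) return(.ng86$sites)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  sites <- vapply(codons, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    s <- 0
    for (p in 1:3) for (b in setdiff(BASES, ch[p])) {
      alt <- ch; alt[p] <- b
      altc <- paste(alt, collapse = "")
      if (code[altc] != "*" && code[altc] == code[cd]) s <- s + 1 / 3
    }
    s
  }, 0)
  names(sites) <- codons
  .ng86$sites <- sites
  sites
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all minimal mutational pathways with equal weights; pathways passing
# through a stop codon are dropped (all-blocked pairs fall back to counting
# over every pathway, stop steps scored nonsynonymous).
ng86_pair_diff <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (!is.null(.ng86$pairs[[key]])) return(.ng86$pairs[[key]])
  code <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dpos <- which(a != b)
  k <- length(dpos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(dpos) else {
    pp <- list()
    perm <- function(v, acc = integer()) {
      if (!length(v)) pp[[length(pp) + 1L]] <<- acc
      else for (i in seq_along(v)) perm(v[-i], c(acc, v[i]))
    }
    perm(dpos)
    pp
  }
  score_path <- function(ord, allow_stop) {
    cur <- a; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      cfrom <- paste(cur, collapse = ""); cto <- paste(nxt, collapse = "")
      if (code[cto] == "*" && !identical(nxt, b)) {
        if (!allow_stop) return(NULL)
      }
      if (code[cfrom] != "*" && code[cto] != "*" &&
          code[cfrom] == code[cto]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  paths <- Filter(Negate(is.null), lapply(perms, score_path, allow_stop = FALSE))
  if (!length(paths)) paths <- lapply(perms, score_path, allow_stop = TRUE)
  res <- colMeans(do.call(rbind, paths))
  if (is.null(.ng86$pairs)) .ng86$pairs <- new.env(parent = emptyenv())
  assign(key, res, envir = .ng86$pairs)
  res
}

split_codons <- function(s) {
  n <- nchar(s)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Pairwise synonymous and nonsynonymous divergence (NG86)
#'
#' Nei-Gojobori (1986) counting on an in-frame codon pair: synonymous and
#' nonsynonymous site counts are averaged over the two sequences, differences
#' at multiply-substituted codons are averaged over all minimal mutational
#' pathways with equal weights, and raw proportions are corrected for
#' multiple hits with the Jukes-Cantor formula
#' dS = -(3/4) log(1 - (4/3) pS). Codons containing gaps, ambiguous bases or
#' stops in either sequence are skipped pairwise.
#'
#' @param seq1,seq2 equal-length in-frame nucleotide strings.
#' @return object of class `ds_estimate` with fields dS, dN, pS, pN, S, N,
#'   Sd, Nd, n_codons and a `saturated` flag (pS >= 3/4, dS undefined).
#' @export
ng86_ds <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) stop("invalid-input: length mismatch")
  if (nchar(seq1) %% 3L != 0L) stop("invalid-input: length not a multiple of 3")
  code <- Biostrings::GENETIC_CODE
  c1 <- split_codons(toupper(seq1)); c2 <- split_codons(toupper(seq2))
  clean <- function(x) !grepl("[^ACGT]", x) & code[x] != "*"
  use <- clean(c1) & clean(c2)
  sites <- ng86_syn_sites()
  n_use <- sum(use)
  S <- if (n_use) (sum(sites[c1[use]]) + sum(sites[c2[use]])) / 2 else 0
  N <- 3 * n_use - S
  Sd <- Nd <- 0
  for (i in which(use & c1 != c2)) {
    d <- ng86_pair_diff(c1[i], c2[i])
    Sd <- Sd + unname(d["sd"]); Nd <- Nd + unname(d["nd"])
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  structure(list(dS = jc(pS), dN = jc(pN), pS = unname(pS), pN = unname(pN),
                 S = S, N = N, Sd = unname(Sd), Nd = unname(Nd),
                 n_codons = n_use, saturated = pS >= 3 / 4),
            class = "ds_estimate")
}

#' @export
print.ds_estimate <- function(x, ...) {
  cat(sprintf("NG86 divergence over %d codons: dS = %s, dN = %s%s\n",
              x$n_codons,
              if (is.na(x$dS)) "saturated" else sprintf("%.4f", x$dS),
              if (is.na(x$dN)) "saturated" else sprintf("%.4f", x$dN),
              if (x$saturated) " [pS saturated]" else ""))
  invisible(x)
}

#' Map a protein alignment back onto unaligned coding sequences
#'
#' Each amino-acid column expands to one codon column; protein gaps become
#' codon gaps. Every CDS must translate exactly to its (ungapped) protein
#' row under the standard genetic code.
#'
#' @param protein_aln named character vector of aligned protein sequences.
#' @param cds named character vector of unaligned coding sequences.
#' @return named character vector: the codon-aware nucleotide alignment.
#' @export
map_to_codon_alignment <- function(protein_aln, cds) {
  taxa <- names(protein_aln)
  if (!all(taxa %in% names(cds))) stop("CDS missing for some taxa")
  code <- Biostrings::GENETIC_CODE
  out <- vapply(taxa, function(tx) {
    prot <- strsplit(protein_aln[[tx]], "")[[1]]
    res <- prot[prot != "-"]
    codons <- split_codons(toupper(cds[[tx]]))
    if (length(codons) != length(res) || nchar(cds[[tx]]) %% 3L != 0L)
      stop("frame error for taxon ", tx, ": CDS length != 3 x residue count")
    aa <- code[codons]
    bad <- which(is.na(aa) | aa != res)
    if (length(bad))
      stop("translation mismatch for taxon ", tx, " at residue ", bad[1])
    j <- 0L
    paste(vapply(prot, function(p) {
      if (p == "-") "---" else { j <<- j + 1L; codons[j] }
    }, ""), collapse = "")
  }, "")
  names(out) <- taxa
  out
}

#' Mask gappy columns and short conserved blocks from an alignment
#'
#' Two-rule filter: drop columns whose gap fraction exceeds
#' `max_gap_fraction`, then drop runs of kept columns shorter than
#' `min_block`. Kept columns are returned in original order.
#'
#' @param alignment named character vector of equal-length sequences.
#' @param max_gap_fraction maximum tolerated gap fraction per column
#'   (study setting: gaps in at most half of the taxa).
#' @param min_block minimum run length of kept columns.
#' @return list with `alignment` (masked strings) and `kept`
#'   (original column indices).
#' @export
mask_blocks <- function(alignment, max_gap_fraction = 0.5, min_block = 10L) {
  m <- aln_matrix(alignment)
  gapfrac <- colMeans(matrix(m %in% GAPCHARS, nrow(m)))
  keep <- gapfrac <= max_gap_fraction
  r <- rle(keep)
  r$values <- r$values & r$lengths >= min_block
  keep <- inverse.rle(r)
  if (!any(keep)) {
    warning("all columns masked; empty alignment returned")
    return(list(alignment = setNames(rep("", nrow(m)), rownames(m)),
                kept = integer()))
  }
  list(alignment = aln_strings(m[, keep, drop = FALSE]), kept = which(keep))
}

#' Majority-rule consensus of aligned sequences
#'
#' Per column, the majority base among non-gap characters; ties go to the
#' lexicographically smallest base; all-gap columns yield a gap.
#'
#' @param seqs named character vector (>= 2 aligned members).
#' @return consensus string.
#' @export
consensus_sequence <- function(seqs) {
  if (length(seqs) < 2L) stop("need >= 2 member sequences")
  m <- aln_matrix(seqs)
  cnt <- vapply(BASES, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) cnt <- matrix(cnt, nrow = 1L,
                                   dimnames = list(NULL, BASES))
  tot <- rowSums(cnt)
  best <- max.col(cnt, ties.method = "first")  # first = lexicographic smallest
  out <- ifelse(tot == 0, "-", BASES[best])
  paste(out, collapse = "")
}

#' SNP rate of a sequence against a consensus, per kilobase
#'
#' Counts columns where both carry an unambiguous base and the bases differ,
#' normalized by compared kilobases.
#'
#' @param seq,consensus equal-length aligned strings.
#' @return list with `snps`, `compared_bp`, `per_kb`.
#' @export
snp_rate_vs_consensus <- function(seq, consensus) {
  if (nchar(seq) != nchar(consensus)) stop("length mismatch")
  a <- strsplit(toupper(seq), "")[[1]]
  b <- strsplit(toupper(consensus), "")[[1]]
  ok <- a %in% BASES & b %in% BASES
  if (!any(ok)) stop("undefined-rate: zero compared columns")
  n <- sum(a[ok] != b[ok])
  list(snps = n, compared_bp = sum(ok), per_kb = n / (sum(ok) / 1000))
}

#' Count flank-anchored ("global") SNPs in a pairwise alignment
#'
#' A mismatch column is a global SNP iff the `flank` columns on each side
#' exist and are all identical matches; the statistic estimates assembly
#' error rates robustly against local misalignment. Rates are normalized per
#' assembled (non-gap query) megabase.
#'
#' @param query,ref equal-length aligned strings (assembly vs reference).
#' @param flank required clean flank width in columns (study value 20).
#' @return list with `global`, `total`, `assembled_bp`, `per_mb_global`,
#'   `per_mb_total`.
#' @export
count_global_snps <- function(query, ref, flank = 20L) {
  if (nchar(query) != nchar(ref)) stop("length mismatch")
  q <- strsplit(toupper(query), "")[[1]]
  r <- strsplit(toupper(ref), "")[[1]]
  L <- length(q)
  both <- q %in% BASES & r %in% BASES
  mism <- both & q != r
  ident <- both & q == r
  assembled <- sum(q %in% BASES)
  total <- sum(mism)
  if (L < 2L * flank + 1L) {
    warning("alignment shorter than 2*flank+1; zero global SNPs")
    return(list(global = 0L, total = total, assembled_bp = assembled,
                per_mb_global = 0, per_mb_total = total / (assembled / 1e6)))
  }
  cs0 <- c(0L, cumsum(ident))  # cs0[i + 1] = identical matches in 1..i
  idx <- which(mism)
  idx <- idx[idx > flank & idx + flank <= L]
  glob <- sum(vapply(idx, function(i)
    cs0[i] - cs0[i - flank] == flank &&
      cs0[i + flank + 1L] - cs0[i + 1L] == flank, NA))
  list(global = as.integer(glob), total = as.integer(total),
       assembled_bp = assembled,
       per_mb_global = glob / (assembled / 1e6),
       per_mb_total = total / (assembled / 1e6))
}

#' Pairwise dS table over gene clusters with coverage filters
#'
#' For each gene alignment: members whose non-gap span covers less than
#' `min_seq_coverage` of the alignment are removed; for each remaining pair,
#' the gene is excluded when the columns actually used by the NG86
#' calculation (both members ungapped, codon unskipped) cover less than
#' `min_aln_used` of the alignment. Per-pair medians are computed over
#' retained genes with a defined (unsaturated) dS.
#'
#' @param gene_alns named list of per-gene named character vectors (in-frame
#'   alignments).
#' @param min_seq_coverage,min_aln_used filter fractions (study values 0.7).
#' @return list with `table` (long-format per-gene per-pair data.frame) and
#'   `medians` (per-pair data.frame with median dS and gene counts).
#' @export
pairwise_ds_table <- function(gene_alns, min_seq_coverage = 0.7,
                              min_aln_used = 0.7) {
  rows <- list()
  for (g in names(gene_alns)) {
    aln <- gene_alns[[g]]
    if (length(aln) < 2L) next
    len <- nchar(aln[[1]])
    span <- vapply(aln, function(s)
      sum(!(strsplit(toupper(s), "")[[1]] %in% GAPCHARS)), 0L)
    aln <- aln[span >= min_seq_coverage * len]
    if (length(aln) < 2L) next
    taxa <- sort(names(aln))
    for (i in seq_along(taxa)[-length(taxa)]) for (j in (i + 1L):length(taxa)) {
      est <- ng86_ds(aln[[taxa[i]]], aln[[taxa[j]]])
      used <- 3 * est$n_codons / len
      if (used < min_aln_used) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, taxon_a = taxa[i], taxon_b = taxa[j],
        dS = est$dS, dN = est$dN, pS = est$pS,
        saturated = est$saturated, used_fraction = used)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), taxon_a = character(),
               taxon_b = character(), dS = numeric(), dN = numeric(),
               pS = numeric(), saturated = logical(),
               used_fraction = numeric())
  med <- if (nrow(tab)) {
    key <- paste(tab$taxon_a, tab$taxon_b, sep = "|")
    do.call(rbind, lapply(split(tab, key), function(d) data.frame(
      taxon_a = d$taxon_a[1], taxon_b = d$taxon_b[1],
      median_dS = stats::median(d$dS[!d$saturated], na.rm = TRUE),
      n_genes = nrow(d), n_saturated = sum(d$saturated))))
  } else data.frame(taxon_a = character(), taxon_b = character(),
                    median_dS = numeric(), n_genes = integer(),
                    n_saturated = integer())
  rownames(med) <- NULL
  list(table = tab, medians = med)
}
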