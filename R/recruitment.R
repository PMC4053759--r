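sub_mat <- function()
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)

# Longest end-overlap (>= min_overlap, identity >= min_identity) between the
# reference's right end and the candidate's left end (side = "right"), or the
# reference's left end and the candidate's right end (side = "left").
# Anchored by a probe match, then verified base-by-base over the full overlap.
find_end_overlap <- function(ref, cand, side, min_overlap, min_identity) {
  rl <- nchar(ref); cl <- nchar(cand)
  probe_len <- min(500L, cl, min_overlap)
  mm <- floor((1 - min_identity) * probe_len)
  if (side == "right") {
    probe <- substr(cand, 1L, probe_len)
    region_start <- max(1L, rl - cl + 1L)
    region <- substr(ref, region_start, rl)
  } else {
    probe <- substr(cand, cl - probe_len + 1L, cl)
    region <- substr(ref, 1L, min(rl, cl))
  }
  hits <- tryCatch(Biostrings::matchPattern(
    Biostrings::DNAString(probe), Biostrings::DNAString(region),
    max.mismatch = mm), error = function(e) NULL)
  if (is.null(hits) || !length(hits)) return(0L)
  best <- 0L
  for (p in Biostrings::start(hits)) {
    olen <- if (side == "right") rl - (region_start + p - 1L) + 1L
            else p + probe_len - 1L
    if (olen < min_overlap || olen > cl || olen > rl) next
    if (side == "right") {
      a <- substr(ref, rl - olen + 1L, rl); b <- substr(cand, 1L, olen)
    } else {
      a <- substr(ref, 1L, olen); b <- substr(cand, cl - olen + 1L, cl)
    }
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    if (mean(av == bv) >= min_identity && olen > best) best <- olen
  }
  as.integer(best)
}

#' Join overlapping scaffolds into a patchwork reference
#'
#' Seeds with the largest scaffold of the first taxon, then repeatedly
#' extends either end with the unused scaffold having the longest
#' end-overlap of at least `min_overlap` bp (at >= `min_identity` over the
#' overlap); ties are resolved by taxon order then input order. Scaffolds
#' with no substantial overlap are appended at the end, taxon by taxon.
#' Segment provenance is recorded; reference intervals tile the patchwork
#' without overlap and every scaffold contributes at most once.
#'
#' @param scaffolds named list (one element per taxon, in phylogenetic
#'   order) of named character vectors of scaffold sequences.
#' @param min_overlap minimum usable overlap in bp (study value 10 kb).
#' @param min_identity identity required over the overlap.
#' @return object of class `patchwork`: `sequence`, `segments` data.frame
#'   (taxon, scaffold, src_start, src_end, ref_start, ref_end; 0-based
#'   half-open) and `length`.
#' @export
build_patchwork <- function(scaffolds, min_overlap = 10000L,
                            min_identity = 0.95) {
  stopifnot(is.list(scaffolds), length(scaffolds) >= 1L,
            !is.null(names(scaffolds)))
  pool <- do.call(rbind, lapply(names(scaffolds), function(tx)
    data.frame(taxon = tx, scaffold = names(scaffolds[[tx]]),
               seq = unname(scaffolds[[tx]]))))
  pool$len <- nchar(pool$seq)
  first <- which(pool$taxon == names(scaffolds)[1])
  seed <- first[which.max(pool$len[first])]
  ref <- pool$seq[seed]
  seg <- data.frame(taxon = pool$taxon[seed], scaffold = pool$scaffold[seed],
                    src_start = 0L, src_end = pool$len[seed],
                    ref_start = 0L, ref_end = pool$len[seed])
  used <- rep(FALSE, nrow(pool)); used[seed] <- TRUE
  repeat {
    cand <- which(!used)
    if (!length(cand)) break
    ov <- data.frame(i = integer(), side = character(), olen = integer())
    for (i in cand) for (side in c("right", "left")) {
      o <- find_end_overlap(ref, pool$seq[i], side, min_overlap, min_identity)
      if (o >= min_overlap)
        ov <- rbind(ov, data.frame(i = i, side = side, olen = o))
    }
    if (!nrow(ov)) break
    b <- ov[which.max(ov$olen), ]  # longest, then first-found (taxon/input order)
    i <- b$i; olen <- b$olen; cl <- pool$len[i]
    if (b$side == "right") {
      add <- substr(pool$seq[i], olen + 1L, cl)
      seg <- rbind(seg, data.frame(
        taxon = pool$taxon[i], scaffold = pool$scaffold[i],
        src_start = olen, src_end = cl,
        ref_start = nchar(ref), ref_end = nchar(ref) + cl - olen))
      ref <- paste0(ref, add)
    } else {
      shift <- cl - olen
      seg$ref_start <- seg$ref_start + shift
      seg$ref_end <- seg$ref_end + shift
      seg <- rbind(data.frame(
        taxon = pool$taxon[i], scaffold = pool$scaffold[i],
        src_start = 0L, src_end = shift, ref_start = 0L, ref_end = shift),
        seg)
      ref <- paste0(substr(pool$seq[i], 1L, shift), ref)
    }
    used[i] <- TRUE
  }
  for (i in which(!used)) {  # pool is already in taxon order
    seg <- rbind(seg, data.frame(
      taxon = pool$taxon[i], scaffold = pool$scaffold[i],
      src_start = 0L, src_end = pool$len[i],
      ref_start = nchar(ref), ref_end = nchar(ref) + pool$len[i]))
    ref <- paste0(ref, pool$seq[i])
  }
  o <- order(seg$ref_start)  # tiling invariant: segments partition [0, total)
  stopifnot(seg$ref_start[o][1] == 0L,
            all(seg$ref_start[o][-1] == seg$ref_end[o][-length(o)]),
            seg$ref_end[o][length(o)] == nchar(ref))
  structure(list(sequence = ref, segments = seg, length = nchar(ref)),
            class = "patchwork")
}

#' @export
print.patchwork <- function(x, ...) {
  cat(sprintf("Patchwork reference: %d bp from %d segments (%d taxa)\n",
              x$length, nrow(x$segments), length(unique(x$segments$taxon))))
  invisible(x)
}

build_kmer_index <- function(ref, k) {
  L <- nchar(ref)
  kmers <- substring(ref, seq_len(L - k + 1L), k:L)
  split(seq_len(L - k + 1L), kmers)
}

#' Recruit metagenome reads to a reference
#'
#' Seed-and-extend alignment: exact k-mer seeds locate the best diagonal on
#' each strand, a local affine-gap alignment (match 1, mismatch -2, gap open
#' 4, extend 1) is computed in a band around it, and the best-scoring
#' location per read is kept (ties to the leftmost reference coordinate). A
#' read is recruited iff identity > `min_id` AND aligned length >
#' `min_alnlen` AND aligned fraction of the read > `min_fraction` (strict
#' inequalities).
#'
#' @param reads named character vector of read sequences.
#' @param reference a `patchwork` or a single reference string.
#' @param min_id,min_alnlen,min_fraction recruitment filters (study values
#'   0.75, 150 bp, 0.5).
#' @param k seed k-mer size.
#' @param band extension band half-width in bp.
#' @return data.frame with one row per aligned read: `read`, `ref_start`,
#'   `ref_end` (0-based half-open), `strand`, `identity`, `aligned_len`,
#'   `aligned_fraction`, `score`, `recruited`.
#' @export
recruit_reads <- function(reads, reference, min_id = 0.75,
                          min_alnlen = 150L, min_fraction = 0.5,
                          k = 15L, band = 32L) {
  if (!length(reads)) stop("reads nonempty required")
  ref <- if (inherits(reference, "patchwork")) reference$sequence
         else as.character(reference)
  L <- nchar(ref)
  idx <- build_kmer_index(ref, k)
  # fallback index with shorter seeds, built on first use: near the 75%
  # identity boundary an exact k-mer seed can be absent even where a valid
  # local alignment exists
  k2 <- max(9L, k - 4L)
  idx2 <- NULL
  seed_diagonals <- function(s, rl) {
    offs <- seq(1L, max(1L, rl - k + 1L), by = max(1L, k %/% 2L))
    hit <- idx[substring(s, offs, offs + k - 1L)]
    diags <- unlist(lapply(seq_along(hit), function(j)
      if (is.null(hit[[j]])) integer() else hit[[j]] - offs[j]))
    if (length(diags)) return(diags)
    if (is.null(idx2)) idx2 <<- build_kmer_index(ref, k2)
    offs <- seq(1L, max(1L, rl - k2 + 1L), by = max(1L, k2 %/% 2L))
    hit <- idx2[substring(s, offs, offs + k2 - 1L)]
    unlist(lapply(seq_along(hit), function(j)
      if (is.null(hit[[j]])) integer() else hit[[j]] - offs[j]))
  }
  mat <- sub_mat()
  rows <- vector("list", length(reads))
  for (ri in seq_along(reads)) {
    rd <- reads[[ri]]
    rl <- nchar(rd)
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") rd else as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(rd)))
      diags <- seed_diagonals(s, rl)
      if (!length(diags)) next
      d <- as.integer(names(sort(table(diags), decreasing = TRUE))[1])
      ws <- max(1L, d + 1L - band)
      we <- min(L, d + rl + band)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(s),
        Biostrings::DNAString(substr(ref, ws, we)),
        type = "local", substitutionMatrix = mat,
        gapOpening = 4, gapExtension = 1)
      alen <- Biostrings::nchar(pa)  # alignment columns
      if (alen == 0L) next
      ident <- Biostrings::nmatch(pa) / alen
      rs <- ws - 1L + Biostrings::start(Biostrings::subject(pa)) - 1L
      re <- ws - 1L + Biostrings::end(Biostrings::subject(pa))
      cand <- list(score = Biostrings::score(pa), ref_start = rs,
                   ref_end = re, strand = strand, identity = ident,
                   aligned_len = alen,
                   aligned_fraction =
                     Biostrings::width(Biostrings::pattern(pa)) / rl)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$ref_start < best$ref_start))
        best <- cand
    }
    if (!is.null(best))
      rows[[ri]] <- data.frame(
        read = names(reads)[ri], ref_start = best$ref_start,
        ref_end = best$ref_end, strand = best$strand,
        identity = best$identity, aligned_len = best$aligned_len,
        aligned_fraction = best$aligned_fraction, score = best$score)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, NA)])
  if (is.null(out))
    out <- data.frame(read = character(), ref_start = integer(),
                      ref_end = integer(), strand = character(),
                      identity = numeric(), aligned_len = integer(),
                      aligned_fraction = numeric(), score = numeric())
  out$recruited <- out$identity > min_id & out$aligned_len > min_alnlen &
    out$aligned_fraction > min_fraction
  out
}

#' Recruitment summary row (counts, percent, fold coverage)
#'
#' Percent of reads recruited and the implied fold coverage
#' (recruited fraction x dataset Mb / reference Mb), with one-decimal
#' report-style rounding alongside the exact values.
#'
#' @param recruited recruited read count (or a [recruit_reads()] data.frame,
#'   in which case its `recruited` rows are counted).
#' @param total_reads,total_mb dataset totals.
#' @param reference_mb reference length in Mb.
#' @return one-row data.frame: recruited, percent, coverage,
#'   percent_report, coverage_report.
#' @export
summarize_recruitment <- function(recruited, total_reads, total_mb,
                                  reference_mb) {
  if (is.data.frame(recruited)) recruited <- sum(recruited$recruited)
  if (total_reads <= 0 || total_mb <= 0 || reference_mb <= 0)
    stop("invalid-argument: totals must be > 0")
  pct <- 100 * recruited / total_reads
  cov <- (recruited / total_reads) * total_mb / reference_mb
  data.frame(recruited = recruited, percent = pct, coverage = cov,
             percent_report = round(pct, 1), coverage_report = round(cov, 1))
}

#' Trim recruited reads to gene boundaries
#'
#' Intersects each recruited read interval with each gene interval, keeping
#' slices overlapping a gene by at least `min_overlap` bp; slice sequences
#' are extracted in gene orientation (assuming near-collinear alignments).
#'
#' @param rec data.frame from [recruit_reads()] (recruited rows are used).
#' @param reads the read sequences (named character vector).
#' @param genes gene coordinate data.frame (gene, start, end, strand;
#'   0-based half-open on the reference).
#' @param reference_length reference length (for bounds checking).
#' @param min_overlap minimum read-gene overlap in bp (study value 150).
#' @return data.frame: read, gene, ref_start, ref_end, gene_start, gene_end,
#'   seq.
#' @export
trim_reads_to_genes <- function(rec, reads, genes, reference_length,
                                min_overlap = 150L) {
  if (any(genes$start < 0L | genes$end > reference_length))
    stop("coordinate error: gene outside reference bounds")
  rec <- rec[rec$recruited, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rec))) {
    rd <- reads[[rec$read[i]]]
    oriented <- if (rec$strand[i] == "-") as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(rd))) else rd
    for (g in seq_len(nrow(genes))) {
      os <- max(rec$ref_start[i], genes$start[g])
      oe <- min(rec$ref_end[i], genes$end[g])
      if (oe - os < min_overlap) next
      off <- os - rec$ref_start[i]
      sl <- substr(oriented, off + 1L, off + (oe - os))
      if (genes$strand[g] == "-") sl <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(sl)))
      out[[length(out) + 1L]] <- data.frame(
        read = rec$read[i], gene = genes$gene[g], ref_start = os,
        ref_end = oe, gene_start = os - genes$start[g],
        gene_end = oe - genes$start[g], seq = sl)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(read = character(), gene = character(), ref_start = integer(),
               ref_end = integer(), gene_start = integer(),
               gene_end = integer(), seq = character())
}

#' Assign a read slice to a microcluster by nearest consensus
#'
#' The slice is compared at its gene-relative coordinates against each
#' microcluster consensus; it takes the label of the highest-identity
#' consensus provided the best identity beats the runner-up by at least
#' `margin`, otherwise it is left unassigned.
#'
#' @param slice_seq slice sequence (gene orientation).
#' @param gene_interval gene-relative 0-based half-open interval
#'   `c(start, end)`.
#' @param consensus_set named character vector of full-gene consensus
#'   sequences (one per microcluster).
#' @param margin required best-minus-second identity gap.
#' @return list with `label` ("unassigned" when ambiguous or no consensus)
#'   and the per-cluster `identities`.
#' @export
assign_microcluster <- function(slice_seq, gene_interval, consensus_set,
                                margin = 0.02) {
  if (is.null(consensus_set) || !length(consensus_set))
    return(list(label = "unassigned", identities = numeric(),
                reason = "no consensus for gene"))
  s <- strsplit(toupper(slice_seq), "")[[1]]
  ids <- vapply(consensus_set, function(cons) {
    cc <- strsplit(substr(toupper(cons), gene_interval[1] + 1L,
                          gene_interval[2]), "")[[1]]
    n <- min(length(s), length(cc))
    if (n == 0L) return(0)
    mean(s[seq_len(n)] == cc[seq_len(n)])
  }, 0)
  o <- order(ids, decreasing = TRUE)
  lab <- if (length(ids) == 1L || ids[o[1]] - ids[o[2]] >= margin)
    names(consensus_set)[o[1]] else "unassigned"
  list(label = lab, identities = ids)
}

#' Per-sample microcluster abundance profile
#'
#' Fractions over assigned slices per sample; the unassigned fraction is
#' reported separately.
#'
#' @param assignments data.frame with columns `sample` and `label`.
#' @return long-format data.frame: sample, cluster, n, fraction (fractions
#'   over assigned slices; the "unassigned" row's fraction is over all
#'   slices).
#' @export
abundance_profile <- function(assignments) {
  if (!nrow(assignments)) stop("no assigned slices")
  do.call(rbind, lapply(split(assignments, assignments$sample), function(d) {
    asg <- d[d$label != "unassigned", , drop = FALSE]
    tab <- table(asg$label)
    rows <- data.frame(sample = d$sample[1], cluster = names(tab),
                       n = as.integer(tab),
                       fraction = as.numeric(tab) / max(nrow(asg), 1L))
    rbind(rows, data.frame(sample = d$sample[1], cluster = "unassigned",
                           n = sum(d$label == "unassigned"),
                           fraction = sum(d$label == "unassigned") / nrow(d)))
  }))
}
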