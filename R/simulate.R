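BASES <- c("A", "C", "G", "T")

#' Simulation configuration for synthetic SAG populations
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the freshwater SAG study conditions: 9 partial genomes, a 25 kb core
#' alignment, clonal divergence placing within-microcluster pairs near
#' 1.5% nucleotide difference, a low-recombination regime
#' (R * delta * nu / mu = 0.14), amplification dropout recovering about 60%
#' of each genome, a 5e-6 per-base assembly error rate, and 400 bp
#' pyrosequencing-length metagenome reads.
#'
#' @param n_taxa number of sampled genomes (tree tips).
#' @param genome_len genome/alignment length in bp.
#' @param n_genes number of ortholog clusters carried on the genome.
#' @param gene_len gene length in bp; must be a multiple of 3.
#' @param mu expected clonal substitutions per site per unit branch length.
#' @param R import (recombination) initiations per site per unit branch
#'   length.
#' @param delta mean import tract length in bp (geometric tracts).
#' @param nu per-site substitution probability inside an import tract.
#' @param gain_rate,loss_rate gene gain/loss events per unit branch length.
#' @param recovery_mean,recovery_sd per-taxon fraction of genome retained
#'   after amplification dropout.
#' @param err_rate per-base sequencing/assembly error probability.
#' @param read_len metagenome read length in bp.
#' @param n_reads number of metagenome reads.
#' @param seed master integer seed; all stages derive sub-streams from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 9L, genome_len = 25000L, n_genes = 20L,
                       gene_len = 900L, mu = 0.01, R = 2.8e-5, delta = 1000,
                       nu = 0.05, gain_rate = 0.2, loss_rate = 0.4,
                       recovery_mean = 0.6, recovery_sd = 0.15,
                       err_rate = 5e-6, read_len = 400L, n_reads = 5000L,
                       seed = 1L) {
  cfg <- list(n_taxa = as.integer(n_taxa), genome_len = as.integer(genome_len),
              n_genes = as.integer(n_genes), gene_len = as.integer(gene_len),
              mu = mu, R = R, delta = delta, nu = nu,
              gain_rate = gain_rate, loss_rate = loss_rate,
              recovery_mean = recovery_mean, recovery_sd = recovery_sd,
              err_rate = err_rate, read_len = as.integer(read_len),
              n_reads = as.integer(n_reads), seed = as.integer(seed))
  rates <- c(mu = mu, R = R, gain_rate = gain_rate, loss_rate = loss_rate,
             err_rate = err_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (nu < 0 || nu > 1) stop("nu must lie in [0, 1]")
  if (delta < 1) stop("delta must be >= 1")
  if (recovery_mean <= 0 || recovery_mean > 1)
    stop("recovery_mean must lie in (0, 1]")
  if (cfg$gene_len %% 3L != 0L) stop("gene_len must be divisible by 3")
  if (cfg$n_taxa < 2L) stop("n_taxa must be >= 2")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a clonal genealogy under the Kingman coalescent
#'
#' Draws a random rooted binary genealogy with `rcoal` (pairwise coalescence
#' rate k(k-1)/2) and, by default, rescales branch lengths so the root-to-tip
#' depth equals one unit; clonal and import rates are then expressed per unit
#' branch length.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @param rescale rescale depth to 1 (TRUE) or keep coalescent units.
#' @return a rooted `phylo` with tip labels `t1..tn`.
#' @export
simulate_genealogy <- function(n_taxa, seed = 1L, rescale = TRUE) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  tr <- with_stage_seed(seed, "genealogy", ape::rcoal(n_taxa))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  if (rescale) {
    depth <- max(ape::node.depth.edgelength(tr))
    if (depth > 0) tr$edge.length <- tr$edge.length / depth
  }
  tr
}

# Edge indices in parent-before-child order.
preorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  match(paste(tr$edge[, 1], tr$edge[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
}

root_node <- function(tree) ape::Ntip(tree) + 1L

#' Simulate clonal sequence evolution along a genealogy
#'
#' Jukes-Cantor process: a uniform random root sequence accumulates, on each
#' branch, Poisson(mu * length * L) substitutions at uniform positions, each
#' to a uniform alternative base. Every event is recorded in the returned
#' truth object so imports can later be overlaid by exact replay.
#'
#' @param tree rooted `phylo` genealogy.
#' @param cfg a [sim_config()].
#' @return list with `alignment` (named character vector of tip sequences)
#'   and `truth` (class `sim_truth`).
#' @export
simulate_clonal_sequences <- function(tree, cfg) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "sim_config"))
  if (ape::Ntip(tree) < 2L) stop("tree must have >= 2 tips")
  L <- cfg$genome_len
  with_stage_seed(cfg$seed, "clonal", {
    root_seq <- sample.int(4L, L, replace = TRUE)
    nodes_seq <- vector("list", ape::Ntip(tree) + tree$Nnode)
    nodes_seq[[root_node(tree)]] <- root_seq
    ev <- vector("list", nrow(tree$edge))
    for (e in preorder_edges(tree)) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      s <- nodes_seq[[par]]
      n <- stats::rpois(1L, cfg$mu * tree$edge.length[e] * L)
      if (n > 0) {
        pos <- sample.int(L, n, replace = TRUE)
        off <- sample.int(3L, n, replace = TRUE)
        to <- integer(n)
        dup <- duplicated(pos)
        # multiple hits at one site must apply in order; the rest vectorize
        i1 <- which(!dup)
        to[i1] <- ((s[pos[i1]] - 1L + off[i1]) %% 4L) + 1L
        s[pos[i1]] <- to[i1]
        for (i in which(dup)) {
          to[i] <- ((s[pos[i]] - 1L + off[i]) %% 4L) + 1L
          s[pos[i]] <- to[i]
        }
        ev[[e]] <- data.frame(pos = pos, to = to)
      } else ev[[e]] <- data.frame(pos = integer(), to = integer())
      nodes_seq[[chl]] <- s
    }
    tips <- seq_len(ape::Ntip(tree))
    aln <- vapply(tips, function(i)
      paste(BASES[nodes_seq[[i]]], collapse = ""), "")
    names(aln) <- tree$tip.label
    truth <- structure(list(
      root_seq = root_seq, clonal_events = ev,
      import_tracts = rep(list(data.frame(start = integer(), end = integer(),
                                          n_sub = integer())),
                          nrow(tree$edge)),
      import_subs = rep(list(integer()), nrow(tree$edge)),
      n_clonal = sum(vapply(ev, nrow, 0L)), n_import_sub = 0L,
      realized_r_over_m = if (sum(vapply(ev, nrow, 0L)) > 0) 0 else NA_real_),
      class = "sim_truth")
    list(alignment = aln, truth = truth)
  })
}

#' Overlay homologous-recombination import tracts on a clonal simulation
#'
#' Replays the recorded clonal events from the root and, per branch,
#' initiates Poisson(R * length * L) import tracts with uniform starts and
#' geometric lengths (mean `delta`, truncated at the sequence end, 0-based
#' half-open). Each tract site is substituted with probability `nu` to a
#' uniform alternative base, mimicking divergent donor DNA. The realized
#' recombination-to-mutation ratio (import substitutions / clonal
#' substitutions) is recomputed.
#'
#' @param sim output of [simulate_clonal_sequences()].
#' @param tree the same genealogy.
#' @param cfg a [sim_config()].
#' @return list with updated `alignment` and `truth`.
#' @export
overlay_imports <- function(sim, tree, cfg) {
  stopifnot(inherits(sim$truth, "sim_truth"))
  L <- cfg$genome_len
  truth <- sim$truth
  with_stage_seed(cfg$seed, "imports", {
    nodes_seq <- vector("list", ape::Ntip(tree) + tree$Nnode)
    nodes_seq[[root_node(tree)]] <- truth$root_seq
    n_imp_sub <- 0L
    for (e in preorder_edges(tree)) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      s <- nodes_seq[[par]]
      ev <- truth$clonal_events[[e]]
      if (nrow(ev)) s[ev$pos] <- ev$to
      n <- stats::rpois(1L, cfg$R * tree$edge.length[e] * L)
      if (n > 0) {
        start0 <- sample.int(L, n, replace = TRUE) - 1L
        len <- 1L + stats::rgeom(n, 1 / cfg$delta)
        end0 <- pmin(start0 + len, L)
        subs <- integer(0)
        nsub <- integer(n)
        for (i in seq_len(n)) {
          tract <- seq.int(start0[i] + 1L, end0[i])   # 1-based site indices
          hit <- tract[stats::runif(length(tract)) < cfg$nu]
          nsub[i] <- length(hit)
          if (length(hit)) {
            off <- sample.int(3L, length(hit), replace = TRUE)
            s[hit] <- ((s[hit] - 1L + off) %% 4L) + 1L
            subs <- c(subs, hit)
          }
        }
        truth$import_tracts[[e]] <- data.frame(start = start0, end = end0,
                                               n_sub = nsub)
        truth$import_subs[[e]] <- subs
        n_imp_sub <- n_imp_sub + sum(nsub)
      }
      nodes_seq[[chl]] <- s
    }
    tips <- seq_len(ape::Ntip(tree))
    aln <- vapply(tips, function(i)
      paste(BASES[nodes_seq[[i]]], collapse = ""), "")
    names(aln) <- tree$tip.label
    truth$n_import_sub <- n_imp_sub
    truth$realized_r_over_m <-
      if (truth$n_clonal > 0) n_imp_sub / truth$n_clonal else NA_real_
    list(alignment = aln, truth = truth)
  })
}

#' Simulate gene gain and loss along a genealogy
#'
#' Root presence per cluster is Bernoulli(0.8); on a branch of length l an
#' absent cluster is gained with probability 1 - exp(-gain_rate * l) and a
#' present one lost with probability 1 - exp(-loss_rate * l). Leaves report
#' presence/absence disregarding copy number.
#'
#' @param tree rooted `phylo`.
#' @param cfg a [sim_config()].
#' @param root_prob root presence probability per cluster.
#' @return list with `matrix` (tips x clusters binary occurrence matrix),
#'   `node_states` (all nodes x clusters), and per-edge truth lists
#'   `edge_gains` / `edge_losses` of cluster indices.
#' @export
simulate_gene_flux <- function(tree, cfg, root_prob = 0.8) {
  stopifnot(inherits(tree, "phylo"))
  G <- cfg$n_genes
  if (G < 1L) stop("n_genes must be >= 1")
  with_stage_seed(cfg$seed, "geneflux", {
    n_node <- ape::Ntip(tree) + tree$Nnode
    st <- matrix(0L, n_node, G)
    st[root_node(tree), ] <- stats::rbinom(G, 1L, root_prob)
    gains <- losses <- vector("list", nrow(tree$edge))
    for (e in preorder_edges(tree)) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      l <- tree$edge.length[e]
      s <- st[par, ]
      u <- stats::runif(G)
      gain <- s == 0L & u < 1 - exp(-cfg$gain_rate * l)
      loss <- s == 1L & u < 1 - exp(-cfg$loss_rate * l)
      s[gain] <- 1L; s[loss] <- 0L
      st[chl, ] <- s
      gains[[e]] <- which(gain); losses[[e]] <- which(loss)
    }
    ids <- sprintf("clu%04d", seq_len(G))
    colnames(st) <- ids
    leaf <- st[seq_len(ape::Ntip(tree)), , drop = FALSE]
    rownames(leaf) <- tree$tip.label
    list(matrix = leaf, node_states = st,
         edge_gains = gains, edge_losses = losses)
  })
}

#' Degrade a complete genome into a partial single-cell assembly
#'
#' Emulates multiple-displacement-amplification dropout: a per-genome
#' recovery fraction is drawn from Normal(recovery_mean, recovery_sd)
#' (clipped to (0, 1], resampled while non-positive), and that much sequence
#' is kept as 5-100 contiguous scaffolds at random positions. Per-base
#' errors are then injected at `err_rate`, each recorded in the truth.
#'
#' @param genome a single genome sequence string.
#' @param cfg a [sim_config()].
#' @param seed integer seed (per-taxon).
#' @return list with `scaffolds` (named character vector), `retained`
#'   (0-based half-open genome intervals), `errors` (0-based positions with
#'   original and new base) and `recovery` (realized fraction).
#' @export
degrade_to_sag <- function(genome, cfg, seed = cfg$seed) {
  G <- nchar(genome)
  with_stage_seed(seed, "dropout", {
    f <- NA_real_
    for (i in 1:100) {
      f <- stats::rnorm(1L, cfg$recovery_mean, cfg$recovery_sd)
      if (f > 0) break
    }
    if (is.na(f) || f <= 0) stop("invalid-config: recovery draw not positive")
    f <- min(f, 1)
    keep <- max(1L, round(f * G))
    if (keep >= G) {
      blocks <- data.frame(start = 0L, end = G)
    } else {
      k <- sample(5:100, 1L)
      k <- min(k, keep, G - keep + 1L)
      # composition of kept length into k blocks (each >= 1)
      cuts <- sort(sample.int(keep - 1L, k - 1L))
      blens <- diff(c(0L, cuts, keep))
      # gaps: k + 1 parts of the removed length (ends may be 0)
      gap_total <- G - keep
      gcuts <- sort(sample.int(gap_total + 1L, k, replace = TRUE) - 1L)
      glens <- diff(c(0L, gcuts, gap_total))
      start <- cumsum(c(0L, blens[-k])) + cumsum(glens[-(k + 1L)])
      blocks <- data.frame(start = as.integer(start),
                           end = as.integer(start + blens))
    }
    scaf <- substring(genome, blocks$start + 1L, blocks$end)
    names(scaf) <- sprintf("scaffold_%03d", seq_len(nrow(blocks)))
    total <- sum(blocks$end - blocks$start)
    n_err <- stats::rbinom(1L, total, cfg$err_rate)
    errors <- data.frame(pos = integer(), from = character(),
                         to = character(), stringsAsFactors = FALSE)
    if (n_err > 0) {
      # choose offsets within the retained sequence, map to genome coords
      off <- sort(sample.int(total, n_err))
      cum <- cumsum(blocks$end - blocks$start)
      blk <- findInterval(off - 1L, cum) + 1L
      within <- off - c(0L, cum)[blk]
      gpos <- blocks$start[blk] + within            # 1-based genome position
      for (i in seq_len(n_err)) {
        si <- blk[i]
        local <- gpos[i] - blocks$start[si]         # 1-based within scaffold
        cur <- substr(scaf[si], local, local)
        alt <- sample(setdiff(BASES, cur), 1L)
        substr(scaf[si], local, local) <- alt
        errors <- rbind(errors, data.frame(pos = gpos[i] - 1L, from = cur,
                                           to = alt))
      }
    }
    list(scaffolds = scaf, retained = blocks, errors = errors,
         recovery = total / G)
  })
}

#' Simulate a metagenome read set from a mixed community
#'
#' Reads are drawn from taxa according to `abundances`, at uniform positions
#' and strands, with per-base errors at `err_rate`; qualities are constant.
#'
#' @param genomes named character vector of genome sequences.
#' @param abundances numeric simplex weights, one per genome.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `reads` (named character vector) and `truth`
#'   data.frame (read, taxon, 0-based half-open source interval, strand).
#' @export
simulate_metagenome <- function(genomes, abundances, cfg, seed = cfg$seed) {
  if (!length(genomes)) stop("invalid-argument: empty genome set")
  stopifnot(length(abundances) == length(genomes))
  if (abs(sum(abundances) - 1) > 1e-8) stop("abundances must sum to 1")
  rl <- cfg$read_len
  if (any(rl > nchar(genomes))) stop("read_len exceeds a genome length")
  with_stage_seed(seed, "metagenome", {
    n <- cfg$n_reads
    tx <- sample(names(genomes), n, replace = TRUE, prob = abundances)
    glen <- nchar(genomes)[tx]
    start0 <- floor(stats::runif(n) * (glen - rl + 1L))
    seqs <- substring(genomes[tx], start0 + 1L, start0 + rl)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rc <- strand == "-"
    if (any(rc)) seqs[rc] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rc])))
    n_err <- stats::rbinom(1L, n * rl, cfg$err_rate)
    if (n_err > 0) {
      ri <- sample.int(n, n_err, replace = TRUE)
      off <- sample.int(rl, n_err, replace = TRUE)
      for (i in seq_len(n_err)) {
        cur <- substr(seqs[ri[i]], off[i], off[i])
        substr(seqs[ri[i]], off[i], off[i]) <- sample(setdiff(BASES, cur), 1L)
      }
    }
    ids <- sprintf("read_%06d", seq_len(n))
    names(seqs) <- ids
    list(reads = seqs,
         truth = data.frame(read = ids, taxon = tx,
                            start = as.integer(start0),
                            end = as.integer(start0 + rl),
                            strand = strand, row.names = NULL))
  })
}

#' Gene coordinates on a simulated genome
#'
#' Tiles `n_genes` genes of `gene_len` bp evenly along the genome (0-based
#' half-open, forward strand).
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns gene, start, end, strand.
#' @export
gene_coordinates <- function(cfg) {
  spacing <- cfg$genome_len %/% cfg$n_genes
  if (cfg$gene_len > spacing)
    stop("genes do not fit: gene_len * n_genes exceeds genome_len")
  start <- (seq_len(cfg$n_genes) - 1L) * spacing
  data.frame(gene = sprintf("gene%03d", seq_len(cfg$n_genes)),
             start = as.integer(start),
             end = as.integer(start + cfg$gene_len), strand = "+")
}

#' Extract per-gene sub-alignments from a gap-free whole-genome alignment
#'
#' @param alignment named character vector of equal-length sequences.
#' @param genes gene coordinate data.frame from [gene_coordinates()].
#' @return named list of per-gene named character vectors.
#' @export
extract_gene_alignments <- function(alignment, genes) {
  out <- lapply(seq_len(nrow(genes)), function(i)
    substring(alignment, genes$start[i] + 1L, genes$end[i]))
  for (i in seq_along(out)) names(out[[i]]) <- names(alignment)
  names(out) <- genes$gene
  out
}

#' Simulate a three-microcluster SAG community
#'
#' Builds the divergence structure of the study population: three tight
#' microclusters (A, B, C) whose members sit at `within_depth` expected
#' substitutions per site from their cluster ancestor (within-cluster
#' pairwise divergence 2 * within_depth, i.e. dS well under 0.05 at the
#' default 0.015) while clusters are separated by `between` expected
#' substitutions per site pairwise (about 0.5). Branch lengths are in
#' substitutions per site (mu = 1).
#'
#' @param n_per_cluster genomes per microcluster.
#' @param genome_len,n_genes,gene_len genome layout (see [sim_config()]).
#' @param within_depth tip depth within a cluster (substitutions/site).
#' @param between expected pairwise divergence between clusters.
#' @param seed integer seed.
#' @return list with `tree`, `alignment` (gap-free genome alignment),
#'   `clusters` (named taxon -> cluster vector), `genes`
#'   (gene coordinates), and `cfg`.
#' @export
simulate_microcluster_community <- function(n_per_cluster = 3L,
                                            genome_len = 20000L,
                                            n_genes = 20L, gene_len = 900L,
                                            within_depth = 0.015,
                                            between = 0.5, seed = 1L) {
  stopifnot(between / 2 > within_depth)
  stem <- between / 2 - within_depth
  clade <- function(cl) sprintf("(%s):%g", paste(
    sprintf("%s%d:%g", cl, seq_len(n_per_cluster), within_depth),
    collapse = ","), stem)
  tree <- ape::read.tree(text = sprintf("(%s,%s,%s);",
                                        clade("A"), clade("B"), clade("C")))
  cfg <- sim_config(n_taxa = 3L * n_per_cluster, genome_len = genome_len,
                    n_genes = n_genes, gene_len = gene_len, mu = 1,
                    R = 0, seed = seed)
  sim <- simulate_clonal_sequences(tree, cfg)
  clusters <- substr(tree$tip.label, 1L, 1L)
  names(clusters) <- tree$tip.label
  list(tree = tree, alignment = sim$alignment, clusters = clusters,
       genes = gene_coordinates(cfg), cfg = cfg, truth = sim$truth)
}
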