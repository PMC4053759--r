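BIG_COST <- 1e12

#' Build an ortholog-cluster occurrence matrix from membership rows
#'
#' Presence/absence disregarding copy number: a cell is 1 iff the taxon has
#' at least one gene in the cluster.
#'
#' @param membership data.frame with columns `taxon`, `gene`, `cluster`.
#' @return binary integer matrix, rows = taxa, columns = clusters (both in
#'   first-appearance order).
#' @export
build_occurrence_matrix <- function(membership) {
  req <- c("taxon", "gene", "cluster")
  if (!is.data.frame(membership) || !all(req %in% names(membership)))
    stop("membership must be a data.frame with taxon, gene, cluster columns")
  if (!nrow(membership)) stop("membership table is empty")
  bad <- which(is.na(membership$taxon) | is.na(membership$cluster) |
                 membership$taxon == "" | membership$cluster == "")
  if (length(bad)) stop("malformed membership row at line ", bad[1])
  taxa <- unique(as.character(membership$taxon))
  clus <- unique(as.character(membership$cluster))
  m <- matrix(0L, length(taxa), length(clus), dimnames = list(taxa, clus))
  m[cbind(match(membership$taxon, taxa), match(membership$cluster, clus))] <- 1L
  m
}

#' Read a (taxon, gene, cluster) membership TSV
#'
#' @param path TSV file with a header line.
#' @return data.frame with columns taxon, gene, cluster.
#' @export
read_membership_tsv <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 2L) stop("membership table is empty")
  f <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 3L)
  if (length(bad)) stop("malformed membership row at line ", bad[1])
  data.frame(taxon = vapply(f[-1], `[[`, "", 1L),
             gene = vapply(f[-1], `[[`, "", 2L),
             cluster = vapply(f[-1], `[[`, "", 3L))
}

#' Collapse partial genomes into a composite taxon row
#'
#' A cluster is attributed to the composite iff it occurs in at least two of
#' the partial genomes, or in exactly one of them while also having a hit in
#' at least one external genome; clusters seen in a single partial genome
#' with no external support are excluded (and reported for audit).
#'
#' @param mat occurrence matrix of the partial taxa (>= 2 rows).
#' @param external_hits character vector of cluster ids with at least one
#'   external-genome hit.
#' @return list with `row` (named 0/1 vector over the matrix clusters) and
#'   `excluded` (cluster ids dropped by the single-genome rule).
#' @export
build_composite_taxon <- function(mat, external_hits = character()) {
  if (nrow(mat) < 2L) stop("need >= 2 partial taxa")
  cnt <- colSums(mat)
  keep <- cnt >= 2L | (cnt == 1L & colnames(mat) %in% external_hits)
  row <- as.integer(keep)
  names(row) <- colnames(mat)
  list(row = row, excluded = colnames(mat)[cnt == 1L & !keep])
}

focal_edge_index <- function(tree, focal) {
  if (is.numeric(focal)) {
    e <- as.integer(focal)
    if (e < 1L || e > nrow(tree$edge)) stop("focal branch does not exist")
    return(e)
  }
  stopifnot(is.character(focal))
  miss <- setdiff(focal, tree$tip.label)
  if (length(miss)) stop("unknown tip in focal set: ", miss[1])
  node <- if (length(focal) == 1L) match(focal, tree$tip.label)
          else ape::getMRCA(tree, focal)
  e <- which(tree$edge[, 2] == node)
  if (!length(e)) stop("focal branch does not exist (clade spans the root)")
  e
}

#' Weighted-parsimony reconstruction of ancestral gene content
#'
#' Per cluster, a bottom-up Sankoff dynamic program over presence states
#' {0, 1} with asymmetric transition costs (gain = 0 to 1, loss = 1 to 0),
#' followed by a top-down traceback. There is no root-state prior: the root
#' takes its minimum-cost state (ties broken toward presence unless
#' `root_state` fixes it). During traceback, cost-equivalent child states
#' are resolved by accelerated transformation: the state implying a change
#' on the current (rootward) branch is preferred, so changes sit as close to
#' the root as possible.
#'
#' @param tree rooted `phylo`; every tip must appear in `mat`.
#' @param mat binary occurrence matrix (taxa x clusters).
#' @param gain_cost,loss_cost positive transition costs (study defaults:
#'   gain 2, loss 1).
#' @param root_state optional fixed root state (0 or 1) applied to every
#'   cluster, overriding the minimum-cost choice.
#' @return object of class `flux_reconstruction`: per-node states, per-branch
#'   gain/loss counts and cluster lists, per-node presence totals, and the
#'   total weighted cost.
#' @export
sankoff_reconstruct <- function(tree, mat, gain_cost = 2, loss_cost = 1,
                                root_state = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (gain_cost <= 0 || loss_cost <= 0) stop("costs must be > 0")
  miss <- setdiff(tree$tip.label, rownames(mat))
  if (length(miss)) stop("missing-taxon: ", miss[1], " not in matrix")
  mat <- mat[, , drop = FALSE]
  if (!all(mat %in% c(0L, 1L))) mat <- (mat > 0) + 0L  # binarize copy counts
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  G <- ncol(mat)
  leaf <- mat[tree$tip.label, , drop = FALSE]

  cost0 <- matrix(0, nnode, G)
  cost1 <- matrix(0, nnode, G)
  cost0[seq_len(ntip), ] <- ifelse(leaf == 0L, 0, BIG_COST)
  cost1[seq_len(ntip), ] <- ifelse(leaf == 1L, 0, BIG_COST)

  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(post))) {
    par <- post[i, 1]; chl <- post[i, 2]
    cost0[par, ] <- cost0[par, ] + pmin(cost0[chl, ], cost1[chl, ] + gain_cost)
    cost1[par, ] <- cost1[par, ] + pmin(cost0[chl, ] + loss_cost, cost1[chl, ])
  }

  rt <- root_node(tree)
  state <- matrix(NA_integer_, nnode, G)
  # root ties resolve to absence: a cluster confined to one clade then
  # surfaces as a gain on that clade's stem rather than as repeated losses
  state[rt, ] <- if (!is.null(root_state)) {
    stopifnot(root_state %in% c(0L, 1L))
    rep(as.integer(root_state), G)
  } else as.integer(cost1[rt, ] < cost0[rt, ])

  ne <- nrow(tree$edge)
  gains <- losses <- integer(ne)
  gain_cl <- loss_cl <- vector("list", ne)
  pre <- preorder_edges(tree)
  for (e in pre) {
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    p <- state[par, ]
    c0 <- cost0[chl, ] + ifelse(p == 1L, loss_cost, 0)
    c1 <- cost1[chl, ] + ifelse(p == 0L, gain_cost, 0)
    s <- ifelse(c1 < c0, 1L, ifelse(c0 < c1, 0L, 1L - p))  # tie -> change
    state[chl, ] <- s
    gain_cl[[e]] <- colnames(mat)[p == 0L & s == 1L]
    loss_cl[[e]] <- colnames(mat)[p == 1L & s == 0L]
    gains[e] <- length(gain_cl[[e]])
    losses[e] <- length(loss_cl[[e]])
  }
  dimnames(state) <- list(c(tree$tip.label,
                            paste0("node", (ntip + 1L):nnode)),
                          colnames(mat))
  structure(list(
    node_states = state, gains = gains, losses = losses,
    gain_clusters = gain_cl, loss_clusters = loss_cl,
    node_presence = rowSums(state),
    total_cost = sum(gains) * gain_cost + sum(losses) * loss_cost,
    min_cost = sum(pmin(cost0[rt, ], cost1[rt, ])),
    gain_cost = gain_cost, loss_cost = loss_cost, tree = tree),
    class = "flux_reconstruction")
}

#' @export
print.flux_reconstruction <- function(x, ...) {
  cat("Gene-flux reconstruction (Sankoff/ACCTRAN)\n")
  cat(sprintf("  clusters: %d   tips: %d\n", ncol(x$node_states),
              ape::Ntip(x$tree)))
  cat(sprintf("  costs: gain %g, loss %g   total cost: %g\n",
              x$gain_cost, x$loss_cost, x$total_cost))
  cat(sprintf("  events: %d gains, %d losses\n", sum(x$gains), sum(x$losses)))
  invisible(x)
}

#' Gain-penalty sweep on a focal branch
#'
#' Re-runs the reconstruction over a ladder of gain costs and reports how
#' many clusters are inferred as gained on the focal branch at each cost;
#' under the study design the count shrinks as gains get more expensive,
#' separating near-certain gains from gain-or-repeated-loss ambiguities.
#'
#' @param tree rooted `phylo`.
#' @param mat occurrence matrix.
#' @param gain_costs numeric vector of gain costs (study sweep: 2 to 5).
#' @param loss_cost loss cost (study value 1).
#' @param focal focal branch: an edge index, a tip label, or a character
#'   vector of tips whose MRCA stem is the branch.
#' @param root_state passed to [sankoff_reconstruct()].
#' @return data.frame with columns gain_cost, gained, and the gained cluster
#'   ids as a list column `clusters`.
#' @export
penalty_sweep <- function(tree, mat, gain_costs = 2:5, loss_cost = 1,
                          focal, root_state = NULL) {
  e <- focal_edge_index(tree, focal)
  rows <- lapply(gain_costs, function(g) {
    rec <- sankoff_reconstruct(tree, mat, gain_cost = g,
                               loss_cost = loss_cost, root_state = root_state)
    list(gain_cost = g, gained = rec$gains[e], clusters = rec$gain_clusters[[e]])
  })
  out <- data.frame(gain_cost = vapply(rows, `[[`, 0, "gain_cost"),
                    gained = vapply(rows, `[[`, 0L, "gained"))
  out$clusters <- lapply(rows, `[[`, "clusters")
  out
}

#' Fallback single-linkage ortholog clustering
#'
#' A simple stand-in clusterer for when external ortholog clustering output
#' is unavailable: genes are linked when their global pairwise identity
#' reaches `min_identity`, and connected components become clusters. Output
#' matches the membership-table input of [build_occurrence_matrix()].
#'
#' @param genes data.frame with columns taxon, gene, seq.
#' @param min_identity identity cutoff in [0, 1].
#' @return data.frame with columns taxon, gene, cluster.
#' @export
cluster_genes <- function(genes, min_identity = 0.7) {
  stopifnot(all(c("taxon", "gene", "seq") %in% names(genes)))
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    ss <- Biostrings::DNAStringSet(genes$seq)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      pa <- Biostrings::pairwiseAlignment(ss[i], ss[j], type = "global")
      if (Biostrings::pid(pa) / 100 >= min_identity) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  ids <- sprintf("clu%04d", match(root, unique(root)))
  data.frame(taxon = genes$taxon, gene = genes$gene, cluster = ids)
}
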