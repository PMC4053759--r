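# Independent oracles used to cross-check the package implementations.
# Each is written as a direct, brute-force computation that shares no code
# path with the functions it checks.

# Exhaustive weighted parsimony: minimum cost over all 2^k internal-node
# labelings of a rooted tree (k internal nodes). Patterns are named 0/1
# vectors over tips.
exhaustive_parsimony_cost <- function(tree, pattern, gain_cost, loss_cost) {
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  states <- c(pattern[tree$tip.label], rep(NA_integer_, tree$Nnode))
  best <- Inf
  k <- length(internal)
  for (mask in 0:(2^k - 1L)) {
    states[internal] <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- states[tree$edge[e, 1]]; ch <- states[tree$edge[e, 2]]
      if (p == 0L && ch == 1L) cost <- cost + gain_cost
      if (p == 1L && ch == 0L) cost <- cost + loss_cost
    }
    if (cost < best) best <- cost
  }
  best
}

# Minimum gained-count consistent with minimum cost on a focal edge: over all
# optimal labelings, does any place a gain on the focal edge / do all?
exhaustive_focal_gains <- function(tree, pattern, gain_cost, loss_cost,
                                   focal_edge) {
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  states <- c(pattern[tree$tip.label], rep(NA_integer_, tree$Nnode))
  k <- length(internal)
  best <- Inf; gains_at_best <- integer()
  for (mask in 0:(2^k - 1L)) {
    states[internal] <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
    cost <- 0; g <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- states[tree$edge[e, 1]]; ch <- states[tree$edge[e, 2]]
      if (p == 0L && ch == 1L) { cost <- cost + gain_cost
                                 if (e == focal_edge) g <- 1L }
      if (p == 1L && ch == 0L) cost <- cost + loss_cost
    }
    if (cost < best) { best <- cost; gains_at_best <- g }
    else if (cost == best) gains_at_best <- union(gains_at_best, g)
  }
  list(cost = best, focal_gain_possible = gains_at_best)
}

# NG86 pathway oracle: recursive enumeration of mutation orderings between
# two codons, scoring each step as synonymous/nonsynonymous via the standard
# code; paths through intermediate stop codons are excluded.
ng86_pair_oracle <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dpos <- which(a != b)
  if (!length(dpos)) return(c(sd = 0, nd = 0))
  acc <- list()
  recurse <- function(cur, remaining, sd, nd) {
    if (!length(remaining)) { acc[[length(acc) + 1L]] <<- c(sd, nd); return() }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- b[p]
      to <- paste(nxt, collapse = "")
      if (code[to] == "*" && length(remaining) > 1L) next  # blocked path
      syn <- code[paste(cur, collapse = "")] == code[to] && code[to] != "*"
      recurse(nxt, setdiff(remaining, p), sd + syn, nd + !syn)
    }
  }
  recurse(a, dpos, 0, 0)
  if (!length(acc)) return(NULL)  # all paths blocked
  m <- do.call(rbind, acc)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# Oracle for synonymous sites of one codon (independent loop).
ng86_sites_oracle <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) for (bb in setdiff(c("A", "C", "G", "T"), ch[p])) {
    alt <- ch; alt[p] <- bb
    ac <- paste(alt, collapse = "")
    if (code[ac] != "*" && code[ac] == code[codon]) s <- s + 1 / 3
  }
  s
}

# Brute-force two-state HMM likelihood by summation over all state paths
# (for short observation vectors only).
hmm_loglik_brute <- function(x, pC, pI, a, b) {
  L <- length(x)
  pi0 <- c(0.5, 0.5)  # uniform initial distribution, as in the implementation
  Tm <- matrix(c(1 - a, a, b, 1 - b), 2, byrow = TRUE)
  emit <- function(t, s) {
    if (is.na(x[t])) return(1)
    p <- if (s == 1L) pC else pI
    if (x[t] == 1) p else 1 - p
  }
  total <- 0
  for (mask in 0:(2^L - 1L)) {
    path <- bitwAnd(bitwShiftR(mask, seq_len(L) - 1L), 1L) + 1L
    pr <- pi0[path[1]] * emit(1, path[1])
    if (L > 1) for (t in 2:L)
      pr <- pr * Tm[path[t - 1], path[t]] * emit(t, path[t])
    total <- total + pr
  }
  log(total)
}

# Brute-force posterior P(state = import at t) by path summation.
hmm_posterior_brute <- function(x, pC, pI, a, b) {
  L <- length(x)
  pi0 <- c(0.5, 0.5)
  Tm <- matrix(c(1 - a, a, b, 1 - b), 2, byrow = TRUE)
  emit <- function(t, s) {
    if (is.na(x[t])) return(1)
    p <- if (s == 1L) pC else pI
    if (x[t] == 1) p else 1 - p
  }
  num <- numeric(L); total <- 0
  for (mask in 0:(2^L - 1L)) {
    path <- bitwAnd(bitwShiftR(mask, seq_len(L) - 1L), 1L) + 1L
    pr <- pi0[path[1]] * emit(1, path[1])
    if (L > 1) for (t in 2:L)
      pr <- pr * Tm[path[t - 1], path[t]] * emit(t, path[t])
    total <- total + pr
    num[path == 2L] <- num[path == 2L] + pr
  }
  num / total
}

# Naive recruitment oracle: full local Smith-Waterman of each read (both
# strands) against the whole reference, then the three strict filters.
recruit_oracle <- function(reads, ref, min_id = 0.75, min_alnlen = 150L,
                           min_fraction = 0.5) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  vapply(reads, function(rd) {
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") rd else as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(rd)))
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(s), Biostrings::DNAString(ref), type = "local",
        substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
      if (is.null(best) || Biostrings::score(pa) > best$score)
        best <- list(score = Biostrings::score(pa),
                     alen = Biostrings::nchar(pa),
                     ident = Biostrings::nmatch(pa) / Biostrings::nchar(pa),
                     frac = Biostrings::width(Biostrings::pattern(pa)) /
                       nchar(rd))
    }
    best$ident > min_id && best$alen > min_alnlen && best$frac > min_fraction
  }, NA)
}

random_codon_seq <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Random rooted binary tree with unit branch lengths and labelled tips.
random_rooted_tree <- function(ntip) {
  tr <- ape::rtree(ntip, rooted = TRUE, br = NULL)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(ntip))
  tr
}

# Pairwise raw p-distance matrix from equal-length sequence strings.
aln_strings_to_pdist <- function(seqs) {
  n <- length(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- mean(chars[[i]] != chars[[j]])
  m
}
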