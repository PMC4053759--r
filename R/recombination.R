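#' Infer a clonal tree from an alignment by neighbor joining
#'
#' Jukes-Cantor-corrected pairwise distances (pairwise deletion of gap or
#' ambiguous columns), neighbor joining, midpoint rooting; negative branch
#' lengths are clamped to zero.
#'
#' @param alignment named character vector (>= 3 taxa, equal lengths).
#' @return rooted `phylo` with branch lengths in expected substitutions per
#'   site.
#' @export
infer_clonal_tree <- function(alignment) {
  if (length(alignment) < 3L) stop("need >= 3 taxa")
  m <- aln_matrix(alignment)
  n <- nrow(m)
  ok <- matrix(m %in% BASES, n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- ok[i, ] & ok[j, ]
    p <- if (any(use)) mean(m[i, use] != m[j, use]) else 0
    if (p >= 0.75)
      stop("saturation error: ", rownames(m)[i], " vs ", rownames(m)[j],
           " (p-distance ", round(p, 3), " >= 3/4)")
    d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 / 3 * p)
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- tryCatch(phangorn::midpoint(tr),
                 error = function(e) ape::root(tr, outgroup = 1L,
                                               resolve.root = TRUE))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

lowest_bit <- function(x)
  ifelse(bitwAnd(x, 1L) > 0L, 1L,
         ifelse(bitwAnd(x, 2L) > 0L, 2L,
                ifelse(bitwAnd(x, 4L) > 0L, 4L, 8L)))

#' Assign substitutions to branches by column-wise parsimony
#'
#' Fitch parsimony per alignment column; each state change is assigned to a
#' branch in a deterministic top-down refinement (the parent state is kept
#' wherever it is compatible, otherwise the lexicographically smallest
#' compatible base is chosen, placing ambiguous changes rootward). Columns
#' containing a gap or ambiguous base in any taxon are marked missing for
#' every branch.
#'
#' @param alignment named character vector of equal-length sequences.
#' @param tree rooted `phylo`; tips must match alignment names.
#' @return integer matrix (branches x columns) of event indicators with NA
#'   at missing columns; row order follows `tree$edge`.
#' @export
assign_substitutions <- function(alignment, tree) {
  stopifnot(setequal(names(alignment), tree$tip.label))
  m <- aln_matrix(alignment)[tree$tip.label, , drop = FALSE]
  L <- ncol(m)
  ntip <- nrow(m)
  nnode <- ntip + tree$Nnode
  missing <- colSums(!matrix(m %in% BASES, ntip)) > 0L
  bits <- matrix(0L, nnode, L)
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  for (i in seq_len(ntip))
    bits[i, !missing] <- code[m[i, !missing]]
  post <- ape::reorder.phylo(tree, "postorder")$edge
  # bottom-up: intersect child sets, union on empty intersection
  first_seen <- rep(FALSE, nnode)
  for (i in seq_len(nrow(post))) {
    par <- post[i, 1]; chl <- post[i, 2]
    if (!first_seen[par]) { bits[par, ] <- bits[chl, ]; first_seen[par] <- TRUE }
    else {
      inter <- bitwAnd(bits[par, ], bits[chl, ])
      uni <- bitwOr(bits[par, ], bits[chl, ])
      bits[par, ] <- ifelse(inter > 0L, inter, uni)
    }
  }
  state <- matrix(0L, nnode, L)
  rt <- root_node(tree)
  state[rt, !missing] <- lowest_bit(bits[rt, !missing])
  ne <- nrow(tree$edge)
  tracks <- matrix(NA_integer_, ne, L)
  obs <- which(!missing)
  for (e in preorder_edges(tree)) {
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    p <- state[par, obs]
    compat <- bitwAnd(p, bits[chl, obs]) > 0L
    s <- ifelse(compat, p, lowest_bit(bits[chl, obs]))
    state[chl, obs] <- s
    tracks[e, obs] <- as.integer(!compat)
  }
  tracks
}

#' Fit the per-branch two-state import HMM by EM
#'
#' Along each branch, alignment columns alternate between a clonal state
#' (substitution probability 1 - exp(-l_b)) and an import state
#' (substitution probability nu); transitions clonal-to-import occur at rate
#' 1 - exp(-R l_b) and import-to-clonal at 1/delta, with R, delta and nu
#' shared across branches and the clonal length l_b branch-specific.
#' Baum-Welch EM with multiple jittered restarts maximizes the likelihood;
#' the recombination-to-mutation ratio r/m is the ratio of
#' posterior-expected substitution counts in the import versus clonal state
#' (the plug-in R * delta * nu is also reported).
#'
#' @param tracks branch x column event matrix from [assign_substitutions()].
#' @param branch_lengths initial per-branch clonal lengths (expected
#'   substitutions per site), e.g. `tree$edge.length`.
#' @param init optional named list overriding initial `R`, `delta`, `nu`.
#' @param n_restarts number of jittered EM restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @param fix_R_zero fit the clonal-only model (R = 0).
#' @param seed seed for the restart jitter.
#' @return object of class `recomb_fit`.
#' @export
fit_import_hmm <- function(tracks, branch_lengths, init = NULL,
                           n_restarts = 3L, tol = 1e-6, max_iter = 500L,
                           fix_R_zero = FALSE, seed = 1L) {
  stopifnot(is.matrix(tracks), nrow(tracks) == length(branch_lengths))
  nb <- nrow(tracks)
  n_obs <- rowSums(!is.na(tracks))
  if (all(n_obs == 0)) stop("no observed columns on any branch")
  n_ev <- rowSums(tracks == 1L, na.rm = TRUE)
  p_hat <- ifelse(n_obs > 0, n_ev / n_obs, 0)
  # saturated clonal log-likelihood of the R = 0 model (closed form)
  ll_clonal <- sum(ifelse(n_ev > 0 & n_ev < n_obs,
                          n_ev * log(p_hat) + (n_obs - n_ev) * log(1 - p_hat),
                          0))
  degenerate <- sum(n_ev) == 0

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  run_em <- function(R0, delta0, nu0) {
    l_b <- clamp(-log(1 - clamp(p_hat, 0, 0.99)), 1e-8, 10)
    l_b[l_b == 0] <- 1e-8
    R <- R0; delta <- delta0; nu <- nu0
    ll_prev <- -Inf; ll_trace <- numeric()
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      pC <- clamp(1 - exp(-l_b), 1e-10, 1 - 1e-10)
      a <- clamp(1 - exp(-R * l_b), 1e-12, 1 - 1e-6)
      b <- clamp(1 / delta, 1e-12, 1)
      ll <- 0
      s <- list(gC = numeric(nb), gI = numeric(nb), gCx = numeric(nb),
                gIx = numeric(nb), xCC = numeric(nb), xCI = numeric(nb),
                xIC = numeric(nb), xII = numeric(nb))
      gammaI <- matrix(0, nb, ncol(tracks))
      for (bi in seq_len(nb)) {
        fb <- .hmm_forward_backward(tracks[bi, ], pC[bi], nu, a[bi], b)
        ll <- ll + fb$loglik
        s$gC[bi] <- fb$gC_obs; s$gI[bi] <- fb$gI_obs
        s$gCx[bi] <- fb$gCx; s$gIx[bi] <- fb$gIx
        s$xCC[bi] <- fb$xCC; s$xCI[bi] <- fb$xCI
        s$xIC[bi] <- fb$xIC; s$xII[bi] <- fb$xII
        gammaI[bi, ] <- fb$gammaI
      }
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_prev) && ll < ll_prev - 1e-6 * (abs(ll_prev) + 1))
        warning("EM log-likelihood decreased; numerical instability")
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
      # M-step: nu and delta have closed forms; l_b couples the clonal
      # emission and the clonal->import transition, so (l_b, R) are updated
      # by coordinate ascent on the expected complete log-likelihood
      # (generalized EM keeps the likelihood non-decreasing)
      nu <- clamp(sum(s$gIx) / max(sum(s$gI), 1e-12), 1e-8, 0.999)
      if (sum(s$xIC) > 1e-12)
        delta <- clamp((sum(s$xII) + sum(s$xIC)) / sum(s$xIC), 1, 1e8)
      q_branch <- function(l, bi, R) {
        p <- clamp(1 - exp(-l), 1e-12, 1 - 1e-12)
        q <- s$gCx[bi] * log(p) - (s$gC[bi] - s$gCx[bi]) * l
        if (!fix_R_zero && R > 0) {
          ab <- clamp(1 - exp(-R * l), 1e-300, 1 - 1e-12)
          q <- q + s$xCI[bi] * log(ab) - s$xCC[bi] * R * l
        }
        q
      }
      for (sweep in 1:2) {
        for (bi in seq_len(nb)) {
          cand <- stats::optimize(q_branch, c(1e-8, 10), bi = bi, R = R,
                                  maximum = TRUE, tol = 1e-9)$maximum
          # optimize() is inexact: keep the incumbent unless Q improves,
          # preserving the generalized-EM monotonicity guarantee
          if (q_branch(cand, bi, R) > q_branch(l_b[bi], bi, R))
            l_b[bi] <- cand
        }
        if (!fix_R_zero) {
          if (sum(s$xCI) > 1e-12) {
            f <- function(u) {
              Ru <- exp(u)
              au <- clamp(1 - exp(-Ru * l_b), 1e-300, 1 - 1e-12)
              sum(s$xCI * log(au) - s$xCC * Ru * l_b)
            }
            cand <- exp(stats::optimize(f, c(log(1e-12), log(10)),
                                        maximum = TRUE, tol = 1e-10)$maximum)
            if (f(log(cand)) > f(log(max(R, 1e-12)))) R <- cand
          } else R <- 1e-12
        } else R <- 0
      }
    }
    list(R = R, delta = delta, nu = nu, l_b = l_b, loglik = ll_trace[length(ll_trace)],
         ll_trace = ll_trace, converged = converged, stats = s,
         gammaI = gammaI, n_iter = length(ll_trace))
  }

  mean_rate <- max(mean(p_hat), 1e-6)
  R0 <- if (!is.null(init$R)) init$R else 1e-4
  delta0 <- if (!is.null(init$delta)) init$delta else 500
  nu0 <- if (!is.null(init$nu)) init$nu else min(10 * mean_rate, 0.5)
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    jit <- if (r == 1L) c(1, 1, 1) else
      with_stage_seed(seed, "em-restart", stats::runif(3, 0.5, 1.5),
                      counter = r)
    fit <- run_em(R0 * jit[1], delta0 * jit[2], min(nu0 * jit[3], 0.95))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  s <- best$stats
  r_over_m <- if (degenerate) 0 else sum(s$gIx) / max(sum(s$gCx), 1e-12)
  if (degenerate)
    warning("degenerate fit: no substitution events observed; r/m = 0")
  tracts <- called_tracts(best$gammaI)
  structure(list(
    R = best$R, delta = best$delta, nu = best$nu,
    branch_lengths = best$l_b, r_over_m = r_over_m,
    r_over_m_plugin = best$R * best$delta * best$nu,
    loglik = best$loglik, ll_trace = best$ll_trace,
    loglik_clonal = ll_clonal, flat = (best$loglik - ll_clonal) < 2,
    converged = best$converged, n_restarts = n_restarts,
    n_iter = best$n_iter, posterior = best$gammaI, tracts = tracts,
    tracks = tracks, n_events = n_ev, n_obs = n_obs),
    class = "recomb_fit")
}

# Call import tracts as maximal runs of posterior >= 0.5 (0-based half-open).
called_tracts <- function(gammaI, threshold = 0.5) {
  out <- list()
  for (b in seq_len(nrow(gammaI))) {
    r <- rle(gammaI[b, ] >= threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    w <- which(r$values)
    if (length(w))
      out[[length(out) + 1L]] <- data.frame(
        branch = b, start = starts[w], end = ends[w],
        mean_posterior = vapply(w, function(i)
          mean(gammaI[b, (starts[i] + 1L):ends[i]]), 0))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(branch = integer(), start = integer(), end = integer(),
               mean_posterior = numeric())
}

#' Estimate recombination-to-mutation ratio from an alignment
#'
#' The main model-fitting entry point: infers (or accepts) a rooted clonal
#' tree, assigns substitutions to branches by parsimony, and fits the
#' two-state import HMM by EM, yielding the r/m ratio, import parameters
#' (R, delta, nu) and per-column import posteriors.
#'
#' @param alignment named character vector of equal-length sequences
#'   (concatenated well-aligned blocks; see [mask_blocks()]).
#' @param tree optional rooted `phylo` clonal tree; inferred by
#'   [infer_clonal_tree()] when NULL.
#' @param ... passed to [fit_import_hmm()].
#' @return object of class `recomb_fit` (adds `tree` and `call`).
#' @export
fit_recombination <- function(alignment, tree = NULL, ...) {
  if (is.null(tree)) tree <- infer_clonal_tree(alignment)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tracks <- assign_substitutions(alignment, tree)
  fit <- fit_import_hmm(tracks, tree$edge.length, ...)
  fit$tree <- tree
  fit$call <- match.call()
  fit
}

#' Ground-truth r/m from a simulation truth object
#'
#' Substitutions inside import tracts divided by clonal substitutions,
#' summed over branches; undefined (NA with a warning) when no clonal
#' substitutions occurred.
#'
#' @param truth `sim_truth` from the simulator.
#' @return numeric r/m.
#' @export
realized_rm_oracle <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if (truth$n_clonal == 0L) {
    warning("undefined: zero clonal substitutions")
    return(NA_real_)
  }
  truth$n_import_sub / truth$n_clonal
}

#' @export
print.recomb_fit <- function(x, ...) {
  cat("Two-state import HMM fit (EM)\n")
  cat(sprintf("  r/m (posterior counts): %.4g   r/m (plug-in R*delta*nu): %.4g\n",
              x$r_over_m, x$r_over_m_plugin))
  cat(sprintf("  R = %.3g per site per unit branch, delta = %.1f bp, nu = %.4f\n",
              x$R, x$delta, x$nu))
  cat(sprintf("  log-likelihood %.2f after %d iterations (%sconverged)%s\n",
              x$loglik, x$n_iter, if (x$converged) "" else "NOT ",
              if (x$flat) " [flat: barely better than clonal-only]" else ""))
  invisible(x)
}

#' @export
summary.recomb_fit <- function(object, ...) {
  expd <- object$n_obs * ((1 - exp(-object$branch_lengths)) *
                            (1 - colMeans(t(object$posterior), na.rm = TRUE)) +
                            object$nu * colMeans(t(object$posterior), na.rm = TRUE))
  br <- data.frame(branch = seq_along(object$branch_lengths),
                   clonal_length = object$branch_lengths,
                   observed_events = object$n_events,
                   expected_events = expd,
                   import_occupancy = rowMeans(object$posterior))
  out <- list(fit = object, branches = br,
              n_tracts = nrow(object$tracts))
  class(out) <- "summary.recomb_fit"
  out
}

#' @export
print.summary.recomb_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  called import tracts (posterior >= 0.5): %d\n", x$n_tracts))
  cat("\nPer-branch diagnostics:\n")
  print(format(x$branches, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.recomb_fit <- function(object, ...)
  c(R = object$R, delta = object$delta, nu = object$nu,
    r_over_m = object$r_over_m)

#' @export
logLik.recomb_fit <- function(object, ...)
  structure(object$loglik, df = 3L + length(object$branch_lengths),
            class = "logLik")

#' @export
residuals.recomb_fit <- function(object, ...) {
  occ <- rowMeans(object$posterior)
  p_mix <- (1 - exp(-object$branch_lengths)) * (1 - occ) + object$nu * occ
  expd <- object$n_obs * p_mix
  (object$n_events - expd) / sqrt(pmax(expd * (1 - p_mix), 1e-12))
}

#' @export
plot.recomb_fit <- function(x, branches = NULL, ...) {
  g <- x$posterior
  if (is.null(branches)) branches <- seq_len(nrow(g))
  graphics::matplot(t(g[branches, , drop = FALSE]), type = "l", lty = 1,
                    xlab = "alignment column",
                    ylab = "P(import state)", ylim = c(0, 1), ...)
  invisible(x)
}

#' Simulate alignments from a fitted import model
#'
#' Draws new tip alignments on the fitted clonal tree (branch lengths set to
#' the fitted per-branch clonal rates) with the fitted import parameters.
#'
#' @param object a `recomb_fit` from [fit_recombination()].
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param genome_len alignment length; defaults to the fitted data's.
#' @param ... unused.
#' @return list of named character vectors (one alignment per replicate).
#' @export
simulate.recomb_fit <- function(object, nsim = 1, seed = 1L,
                                genome_len = NULL, ...) {
  if (is.null(object$tree)) stop("fit carries no tree; use fit_recombination")
  tr <- object$tree
  tr$edge.length <- object$branch_lengths
  L <- if (is.null(genome_len)) ncol(object$posterior) else genome_len
  lapply(seq_len(nsim), function(i) {
    cfg <- sim_config(n_taxa = ape::Ntip(tr), genome_len = L, mu = 1,
                      R = object$R, delta = object$delta, nu = object$nu,
                      seed = stage_seed(seed, "fit-sim", i))
    sim <- simulate_clonal_sequences(tr, cfg)
    overlay_imports(sim, tr, cfg)$alignment
  })
}
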