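test_that("NJ clonal tree solves the three-point formulas on 3 taxa", {
  # build sequences with controlled pairwise differences
  L <- 6000L
  base <- paste(rep("A", L), collapse = "")
  flip <- function(s, idx) {
    for (i in idx) substr(s, i, i) <- "G"
    s
  }
  # x gets sites 1..60, y sites 61..150, z sites 151..270 mutated:
  # p_xy = (60+90)/L, p_xz = (60+120)/L, p_yz = (90+120)/L (additive)
  x <- flip(base, 1:60); y <- flip(base, 61:150); z <- flip(base, 151:270)
  aln <- c(x = x, y = y, z = z)
  tr <- infer_clonal_tree(aln)
  jc <- function(p) -0.75 * log(1 - 4 / 3 * p)
  dxy <- jc(150 / L); dxz <- jc(180 / L); dyz <- jc(210 / L)
  expected <- c(x = (dxy + dxz - dyz) / 2, y = (dxy + dyz - dxz) / 2,
                z = (dxz + dyz - dxy) / 2)
  tip_edge <- function(lbl)
    tr$edge.length[tr$edge[, 2] == which(tr$tip.label == lbl)]
  # pendant branch lengths solve the three-point formulas (up to the
  # midpoint root splitting one pendant edge)
  depths <- ape::node.depth.edgelength(tr)
  for (lbl in c("x", "y", "z")) {
    others <- setdiff(c("x", "y", "z"), lbl)
    dsum <- function(a, b) {
      i <- which(tr$tip.label == a); j <- which(tr$tip.label == b)
      ape::dist.nodes(tr)[i, j]
    }
    expect_equal(unname((dsum(lbl, others[1]) + dsum(lbl, others[2]) -
                           dsum(others[1], others[2])) / 2),
                 unname(expected[lbl]), tolerance = 1e-9)
  }
  expect_error(infer_clonal_tree(aln[1:2]), ">= 3")

  same <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  tr0 <- infer_clonal_tree(same)
  expect_true(all(tr0$edge.length == 0))

  sat <- c(a = strrep("ACGT", 100), b = strrep("CATG", 100),
           c = strrep("GTAC", 100))
  expect_error(infer_clonal_tree(sat), "saturation")
})

test_that("NJ recovers the simulated topology at study-scale divergence", {
  # recovery is claimed for resolvable genealogies: every internal edge
  # must carry at least ~3 expected substitutions at mu * L
  L <- 100000L
  ok <- vapply(1:30, function(s) {
    tr <- simulate_genealogy(9, seed = s)
    internal <- tr$edge[, 2] > 9L
    if (min(tr$edge.length[internal]) * 0.01 * L < 3) return(NA)
    cfg <- sim_config(genome_len = L, seed = s, R = 0)
    aln <- simulate_clonal_sequences(tr, cfg)$alignment
    est <- infer_clonal_tree(aln)
    phangorn::RF.dist(ape::unroot(tr), ape::unroot(est)) == 0
  }, NA)
  expect_gt(sum(!is.na(ok)), 15L)
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("parsimony substitution tracks are assigned sensibly", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  aln <- c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAGA")
  tracks <- assign_substitutions(aln, tr)
  expect_equal(sum(tracks[, 3], na.rm = TRUE), 1L)       # one event
  pend_d <- which(tr$edge[, 2] == which(tr$tip.label == "d"))
  expect_equal(tracks[pend_d, 3], 1L)                    # on d's branch
  expect_true(all(tracks[, c(1, 2, 4)] == 0L))           # invariant columns
  aln2 <- c(a = "AA-A", b = "AAAA", c = "AAAA", d = "AANA")
  tracks2 <- assign_substitutions(aln2, tr)
  expect_true(all(is.na(tracks2[, 3])))                  # gap/N -> missing
})

test_that("clonal event totals track branch lengths (r^2 >= 0.9)", {
  tr <- simulate_genealogy(9, seed = 13)
  cfg <- sim_config(R = 0, seed = 13)
  aln <- simulate_clonal_sequences(tr, cfg)$alignment
  tracks <- assign_substitutions(aln, tr)
  ev <- rowSums(tracks == 1L, na.rm = TRUE)
  # the two root-child edges cannot be polarized by parsimony on a rooted
  # tree (no outgroup), so they are pooled into one point
  re <- which(tr$edge[, 1] == 10L)
  len <- c(tr$edge.length[-re], sum(tr$edge.length[re]))
  evp <- c(ev[-re], sum(ev[re]))
  expect_gte(summary(stats::lm(evp ~ len))$r.squared, 0.9)
})

test_that("forward-backward matches brute-force path summation", {
  set.seed(31)
  for (rep in 1:20) {
    L <- 8L
    x <- sample(c(0L, 1L, NA), L, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    pC <- runif(1, 0.001, 0.2); pI <- runif(1, 0.05, 0.8)
    a <- runif(1, 0.001, 0.3); b <- runif(1, 0.01, 0.5)
    fb <- sagpop:::.hmm_forward_backward(x, pC, pI, a, b)
    expect_equal(fb$loglik, hmm_loglik_brute(x, pC, pI, a, b),
                 tolerance = 1e-10)
    expect_equal(fb$gammaI, hmm_posterior_brute(x, pC, pI, a, b),
                 tolerance = 1e-10)
    expect_true(all(fb$gammaI >= 0 & fb$gammaI <= 1))
  }
})

test_that("EM log-likelihood is non-decreasing and converges", {
  tr <- simulate_genealogy(9, seed = 17)
  cfg <- sim_config(seed = 17, R = 2.8e-5)
  sim <- overlay_imports(simulate_clonal_sequences(tr, cfg), tr, cfg)
  fit <- expect_no_warning(
    fit_recombination(sim$alignment, n_restarts = 2, seed = 17))
  expect_true(all(diff(fit$ll_trace) > -1e-6 * (abs(fit$loglik) + 1)))
  expect_true(fit$converged)
  expect_equal(sum(fit$posterior < 0 | fit$posterior > 1), 0L)
})

test_that("low-recombination regime estimates r/m below 1", {
  ests <- vapply(1:10, function(s) {
    tr <- simulate_genealogy(9, seed = s)
    cfg <- sim_config(seed = s)
    sim <- overlay_imports(simulate_clonal_sequences(tr, cfg), tr, cfg)
    fit_recombination(sim$alignment, n_restarts = 2, seed = s)$r_over_m
  }, 0)
  expect_gte(mean(ests < 1), 0.9)
})

test_that("high-recombination regime estimates r/m above 10", {
  res <- vapply(1:8, function(s) {
    tr <- simulate_genealogy(9, seed = s)
    cfg <- sim_config(mu = 8e-4, nu = 0.1, delta = 1000,
                      R = 60 * 8e-4 / (1000 * 0.1), seed = s)
    sim <- overlay_imports(simulate_clonal_sequences(tr, cfg), tr, cfg)
    fit <- fit_recombination(sim$alignment, n_restarts = 2, seed = s)
    c(est = fit$r_over_m, real = sim$truth$realized_r_over_m)
  }, c(est = 0, real = 0))
  expect_gte(mean(res["est", ] > 10), 0.9)
  expect_lt(abs(log2(stats::median(res["est", ]) /
                       stats::median(res["real", ]))), 1)  # factor 2
})

test_that("non-identifiable emissions return a flat diagnostic, no crash", {
  set.seed(3)
  tracks <- matrix(rbinom(4 * 2000, 1, 0.02), 4, 2000)
  fit <- fit_import_hmm(tracks, branch_lengths = rep(0.02, 4),
                        init = list(nu = 0.02), n_restarts = 1)
  expect_s3_class(fit, "recomb_fit")
  expect_true(fit$flat)
})

test_that("clonal-only model reproduces per-branch event counts", {
  tr <- simulate_genealogy(9, seed = 23)
  cfg <- sim_config(R = 0, seed = 23)
  aln <- simulate_clonal_sequences(tr, cfg)$alignment
  tracks <- assign_substitutions(aln, tr)
  fit <- fit_import_hmm(tracks, tr$edge.length, fix_R_zero = TRUE,
                        n_restarts = 1)
  n_obs <- rowSums(!is.na(tracks))
  obs <- rowSums(tracks == 1L, na.rm = TRUE)
  expd <- n_obs * (1 - exp(-fit$branch_lengths))
  keep <- expd > 1
  x2 <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  expect_lt(x2, stats::qchisq(0.99, df = sum(keep)))
  expect_equal(fit$r_over_m, 0, tolerance = 1e-6)
})

test_that("called import tracts overlap the truth (precision/recall >= 0.7)", {
  prec <- num_t <- rec_hit <- 0
  tp <- fp <- fn <- 0
  for (s in 1:5) {
    tr <- simulate_genealogy(9, seed = 300 + s)
    cfg <- sim_config(mu = 0.002, nu = 0.1, delta = 1000, R = 2e-4,
                      seed = 300 + s)
    sim <- overlay_imports(simulate_clonal_sequences(tr, cfg), tr, cfg)
    fit <- fit_recombination(sim$alignment, tree = tr, n_restarts = 2,
                             seed = s)
    for (e in seq_len(nrow(tr$edge))) {
      truth_cols <- rep(FALSE, cfg$genome_len)
      tw <- sim$truth$import_tracts[[e]]
      if (nrow(tw)) for (k in seq_len(nrow(tw)))
        truth_cols[(tw$start[k] + 1L):tw$end[k]] <- TRUE
      called <- fit$posterior[e, ] >= 0.5
      tp <- tp + sum(called & truth_cols)
      fp <- fp + sum(called & !truth_cols)
      fn <- fn + sum(!called & truth_cols)
    }
  }
  expect_gte(tp / (tp + fp), 0.7)  # precision
  expect_gte(tp / (tp + fn), 0.7)  # recall
})

test_that("realized r/m oracle follows its definition", {
  tr <- simulate_genealogy(4, seed = 2)
  cfg <- sim_config(n_taxa = 4, genome_len = 4000L, R = 0, seed = 2)
  sim <- overlay_imports(simulate_clonal_sequences(tr, cfg), tr, cfg)
  expect_equal(realized_rm_oracle(sim$truth), 0)
  fake <- sim$truth
  fake$n_clonal <- 30L; fake$n_import_sub <- 3L
  expect_equal(realized_rm_oracle(fake), 0.1)
  fake$n_clonal <- 0L
  expect_warning(expect_true(is.na(realized_rm_oracle(fake))), "undefined")
})

test_that("recomb_fit methods behave like a model object", {
  tr <- simulate_genealogy(6, seed = 41)
  cfg <- sim_config(n_taxa = 6, genome_len = 8000L, seed = 41)
  sim <- overlay_imports(simulate_clonal_sequences(tr, cfg), tr, cfg)
  fit <- fit_recombination(sim$alignment, n_restarts = 1, seed = 41)
  expect_named(coef(fit), c("R", "delta", "nu", "r_over_m"))
  expect_s3_class(logLik(fit), "logLik")
  expect_output(print(fit), "r/m")
  expect_output(print(summary(fit)), "Per-branch")
  expect_length(residuals(fit), nrow(fit$tracks))
  pdf(NULL); plot(fit); dev.off()
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2L)
  expect_equal(nchar(sims[[1]][[1]]), ncol(fit$posterior))
  expect_false(identical(sims[[1]], sims[[2]]))
})
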