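test_that("config validation enforces the generator invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(mu = -1), "rates")
  expect_error(sim_config(nu = 1.5), "nu")
  expect_error(sim_config(delta = 0.5), "delta")
  expect_error(sim_config(recovery_mean = 0), "recovery_mean")
  expect_error(sim_config(gene_len = 100), "divisible")
  expect_error(sim_config(n_taxa = 1), "n_taxa")
})

test_that("coalescent genealogy has the right shape and scaling", {
  expect_error(simulate_genealogy(1), "n_taxa")
  cherry <- simulate_genealogy(2, seed = 3)
  expect_equal(ape::Ntip(cherry), 2L)
  expect_equal(cherry$edge.length[1], cherry$edge.length[2])
  tr <- simulate_genealogy(9, seed = 7)
  expect_equal(ape::Ntip(tr), 9L)
  expect_equal(tr$Nnode, 8L)
  expect_equal(nrow(tr$edge), 16L)
  depths <- ape::node.depth.edgelength(tr)[1:9]
  expect_equal(max(depths), 1)  # rescaled to unit depth
})

test_that("coalescent TMRCA matches the closed-form expectation", {
  n <- 50L
  reps <- 400L
  tm <- vapply(seq_len(reps), function(i)
    max(ape::node.depth.edgelength(
      simulate_genealogy(n, seed = i, rescale = FALSE))), 0)
  expected <- 2 * (1 - 1 / n)   # E[TMRCA] for the Kingman coalescent
  se <- stats::sd(tm) / sqrt(reps)
  expect_lt(abs(mean(tm) - expected), 3 * se)
})

test_that("clonal simulation respects zero rate and Jukes-Cantor expectation", {
  tr <- simulate_genealogy(5, seed = 1)
  cfg0 <- sim_config(n_taxa = 5, genome_len = 2000L, mu = 0, seed = 4)
  sim0 <- simulate_clonal_sequences(tr, cfg0)
  expect_equal(length(unique(sim0$alignment)), 1L)
  expect_equal(sim0$truth$n_clonal, 0L)

  # cherry with tip length 1 each, mu*l = 0.01 per tip
  cherry <- ape::read.tree(text = "(a:1,b:1);")
  L <- 20000L
  reps <- 60L
  pdiff <- vapply(seq_len(reps), function(i) {
    cfg <- sim_config(n_taxa = 2, genome_len = L, mu = 0.01, seed = 1000 + i)
    a <- aln_mat <- simulate_clonal_sequences(cherry, cfg)$alignment
    mean(strsplit(a[[1]], "")[[1]] != strsplit(a[[2]], "")[[1]])
  }, 0)
  d <- 0.02                                     # total path divergence
  expected_p <- 3 / 4 * (1 - exp(-4 / 3 * d))   # JC multiple-hit oracle
  se <- stats::sd(pdiff) / sqrt(reps)
  expect_lt(abs(mean(pdiff) - expected_p), 3 * se)
})

test_that("import overlay is a no-op at R = 0 and updates the truth", {
  tr <- simulate_genealogy(6, seed = 2)
  cfg <- sim_config(n_taxa = 6, genome_len = 5000L, R = 0, seed = 9)
  sim <- simulate_clonal_sequences(tr, cfg)
  out <- overlay_imports(sim, tr, cfg)
  expect_identical(out$alignment, sim$alignment)
  expect_equal(out$truth$realized_r_over_m, 0)

  cfg2 <- sim_config(n_taxa = 6, genome_len = 5000L, R = 1e-3, nu = 0.1,
                     delta = 500, seed = 9)
  out2 <- overlay_imports(simulate_clonal_sequences(tr, cfg2), tr, cfg2)
  tw <- do.call(rbind, out2$truth$import_tracts)
  expect_true(all(tw$start >= 0 & tw$end <= cfg2$genome_len))
  expect_equal(out2$truth$realized_r_over_m,
               out2$truth$n_import_sub / out2$truth$n_clonal)
})

test_that("realized r/m hits the high and low regimes", {
  n_seed <- 40L
  ratios <- vapply(seq_len(n_seed), function(s) {
    tr <- simulate_genealogy(9, seed = s)
    cfg <- sim_config(mu = 8e-4, nu = 0.1, delta = 1000,
                      R = 60 * 8e-4 / (1000 * 0.1), seed = s)
    overlay_imports(simulate_clonal_sequences(tr, cfg), tr,
                    cfg)$truth$realized_r_over_m
  }, 0)
  expect_gte(mean(ratios > 40 & ratios < 90), 0.9)  # within factor 1.5 of 60

  low <- vapply(seq_len(n_seed), function(s) {
    tr <- simulate_genealogy(9, seed = s)
    cfg <- sim_config(seed = s)  # defaults: R*delta*nu/mu = 0.14
    overlay_imports(simulate_clonal_sequences(tr, cfg), tr,
                    cfg)$truth$realized_r_over_m
  }, 0)
  expect_true(all(low < 1))
})

test_that("realized r/m is consistent for the generative ratio at large L", {
  target <- 0.14
  ratios <- vapply(1:8, function(s) {
    tr <- simulate_genealogy(4, seed = s)
    cfg <- sim_config(n_taxa = 4, genome_len = 1000000L, seed = s)
    overlay_imports(simulate_clonal_sequences(tr, cfg), tr,
                    cfg)$truth$realized_r_over_m
  }, 0)
  expect_lt(abs(mean(ratios) - target) / target, 0.1)
})

test_that("gene flux respects zero rates and loss-dominated reduction", {
  tr <- simulate_genealogy(6, seed = 5)
  cfg0 <- sim_config(n_taxa = 6, n_genes = 50L, gain_rate = 0, loss_rate = 0,
                     seed = 3)
  fx <- simulate_gene_flux(tr, cfg0)
  root_set <- fx$node_states[7L, ]
  for (i in 1:6) expect_equal(unname(fx$matrix[i, ]), unname(root_set))

  # long ingroup stem with loss >> gain erodes the ingroup core
  tr2 <- ape::read.tree(text = "((a:0.1,b:0.1):2,(c:0.1,d:0.1):0.1);")
  smaller <- vapply(1:30, function(s) {
    cfg <- sim_config(n_taxa = 4, n_genes = 300L, gain_rate = 0.01,
                      loss_rate = 1, seed = s)
    fx <- simulate_gene_flux(tr2, cfg)
    core_in <- sum(fx$matrix["a", ] & fx$matrix["b", ])
    core_out <- sum(fx$matrix["c", ] & fx$matrix["d", ])
    core_in < core_out
  }, NA)
  expect_gte(mean(smaller), 0.9)
})

test_that("SAG degradation retains blocks, injects traceable errors", {
  cfg <- sim_config(genome_len = 30000L, recovery_mean = 1, recovery_sd = 0,
                    err_rate = 0)
  g <- simulate_clonal_sequences(simulate_genealogy(2, seed = 1),
                                 cfg)$alignment[[1]]
  sag <- degrade_to_sag(g, cfg, seed = 11)
  expect_equal(length(sag$scaffolds), 1L)
  expect_identical(unname(sag$scaffolds[[1]]), g)
  expect_equal(sag$recovery, 1)

  cfg2 <- sim_config(genome_len = 30000L, recovery_mean = 0.6,
                     recovery_sd = 0.1, err_rate = 2e-4)
  sag2 <- degrade_to_sag(g, cfg2, seed = 12)
  lens <- sag2$retained$end - sag2$retained$start
  expect_true(all(lens > 0))
  expect_true(all(sag2$retained$start >= 0 &
                    sag2$retained$end <= nchar(g)))
  expect_equal(sum(lens), round(sag2$recovery * nchar(g)))
  expect_equal(sum(nchar(sag2$scaffolds)), sum(lens))
  # every recorded error is a real difference at its genome position
  for (i in seq_len(nrow(sag2$errors))) {
    gp <- sag2$errors$pos[i]
    blk <- which(sag2$retained$start <= gp & gp < sag2$retained$end)
    local <- gp - sag2$retained$start[blk] + 1L
    expect_equal(substr(sag2$scaffolds[[blk]], local, local),
                 sag2$errors$to[i])
    expect_equal(substr(g, gp + 1L, gp + 1L), sag2$errors$from[i])
  }
})

test_that("gene recovery after dropout matches the binomial expectation", {
  cfg <- sim_config(genome_len = 30000L, n_genes = 30L, gene_len = 300L,
                    recovery_mean = 0.5, recovery_sd = 0.02, err_rate = 0)
  g <- simulate_clonal_sequences(simulate_genealogy(2, seed = 2),
                                 cfg)$alignment[[1]]
  genes <- gene_coordinates(cfg)
  n_sag <- 10L
  present <- matrix(FALSE, n_sag, nrow(genes))
  for (s in seq_len(n_sag)) {
    sag <- degrade_to_sag(g, cfg, seed = 100 + s)
    for (gi in seq_len(nrow(genes))) {
      cov <- sum(pmax(0L, pmin(sag$retained$end, genes$end[gi]) -
                        pmax(sag$retained$start, genes$start[gi])))
      present[s, gi] <- cov >= genes$end[gi] - genes$start[gi] - cov
    }
  }
  # majority-covered genes track the 50% recovery fraction: ~5 of 10 SAGs
  expect_gt(mean(colSums(present)), 3.5)
  expect_lt(mean(colSums(present)), 6.5)
})

test_that("metagenome simulation follows the abundance simplex", {
  cfg <- sim_config(genome_len = 10000L, read_len = 200L, n_reads = 400L,
                    err_rate = 0)
  g2 <- simulate_clonal_sequences(simulate_genealogy(2, seed = 6),
                                  cfg)$alignment
  mg1 <- simulate_metagenome(g2, c(1, 0), cfg, seed = 3)
  expect_true(all(mg1$truth$taxon == names(g2)[1]))
  expect_true(all(mg1$truth$end <= nchar(g2[[1]])))
  expect_error(simulate_metagenome(character(), numeric(), cfg), "empty")
  expect_error(simulate_metagenome(g2, c(0.7, 0.2), cfg), "sum to 1")

  cfg2 <- sim_config(genome_len = 10000L, read_len = 100L, n_reads = 20000L,
                     err_rate = 0)
  mg <- simulate_metagenome(g2, c(0.05, 0.95), cfg2, seed = 4)
  n1 <- sum(mg$truth$taxon == names(g2)[1])
  expect_lt(abs(n1 - 1000), 3 * sqrt(20000 * 0.05 * 0.95))
})

test_that("same seed reproduces bit-identical output, new seeds differ", {
  tr <- simulate_genealogy(5, seed = 8)
  cfg <- sim_config(n_taxa = 5, genome_len = 3000L, seed = 21)
  a <- overlay_imports(simulate_clonal_sequences(tr, cfg), tr, cfg)
  b <- overlay_imports(simulate_clonal_sequences(tr, cfg), tr, cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(n_taxa = 5, genome_len = 3000L, seed = 22)
  c2 <- simulate_clonal_sequences(tr, cfg2)
  expect_false(identical(a$alignment, c2$alignment))
})

test_that("microcluster community reproduces the study divergence structure", {
  com <- simulate_microcluster_community(seed = 2)
  expect_equal(length(com$alignment), 9L)
  m <- aln_strings_to_pdist(com$alignment)
  within <- m[outer(com$clusters, com$clusters, `==`) & upper.tri(m)]
  between <- m[outer(com$clusters, com$clusters, `!=`) & upper.tri(m)]
  expect_true(all(within < 0.05))
  expect_true(all(between > 0.25))  # raw p-distance at JC distance ~0.5
})

test_that("sequence and gene table round-trip through FASTA/GFF3", {
  com <- simulate_microcluster_community(genome_len = 3000L, n_genes = 3L,
                                         gene_len = 300L, seed = 5)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(com$alignment, fa)
  expect_identical(read_fasta(fa), com$alignment)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(com$alignment, fq)
  expect_identical(read_fastq(fq), com$alignment)
  gff <- tempfile(fileext = ".gff3")
  write_gff_genes(com$genes, gff)
  rt <- read_gff_genes(gff)
  expect_equal(rt, com$genes)
})
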