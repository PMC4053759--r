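PIPELINE_DEFAULTS <- list(
  seed = 1L,
  # community / simulator
  n_per_cluster = 3L, genome_len = 20000L, n_genes = 20L, gene_len = 900L,
  within_depth = 0.015, between_divergence = 0.5,
  gain_rate = 0.2, loss_rate = 0.4, recovery_mean = 0.6, recovery_sd = 0.15,
  err_rate = 5e-6, read_len = 400L, n_reads = 1500L,
  abundances = c(A = 0.2, B = 0.1, C = 0.7),
  # recombination regimes and model fit; the high (marine-like) regime has
  # lower clonal divergence, its diversity coming almost entirely from imports
  rm_low = 0.14, rm_high = 60, rm_delta = 1000,
  rm_mu_low = 0.01, rm_nu_low = 0.05, rm_mu_high = 8e-4, rm_nu_high = 0.1,
  rm_taxa = 9L, rm_len = 25000L, n_restarts = 3L,
  # study-default thresholds
  min_id = 0.75, min_alnlen = 150L, min_fraction = 0.5,
  min_seq_coverage = 0.7, min_aln_used = 0.7,
  patchwork_min_overlap = 10000L, snp_flank = 20L,
  gain_cost = 2, loss_cost = 1, trim_min_overlap = 150L,
  assign_margin = 0.02)

#' Pipeline configuration
#'
#' Flat, typed configuration for [run_pipeline()]. Every threshold defaults
#' to the study value (recruitment identity 0.75, alignment length 150 bp,
#' read fraction 0.5, dS coverage filters 0.7/0.7, patchwork overlap 10 kb,
#' SNP flank 20 bp, gain cost 2, loss cost 1). Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  structure(cfg, class = "pipeline_config")
}

# FNV-1a hash of a deparsed object; used for parameter fingerprints in the
# run manifest so reruns are comparable without hashing whole files.
param_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 131 + cc) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full synthetic-analysis pipeline
#'
#' Executes the stages in dependency order on synthetic data: community
#' simulation, divergence (pairwise dS, consensus SNP rates), recombination
#' (two r/m regimes fitted with the import HMM), gene flux
#' (Sankoff/ACCTRAN + penalty sweep), and recruitment (patchwork, read
#' recruitment, gene trimming, microcluster assignment, abundance profile).
#' All outputs are plain text (TSV/FASTA/JSON); a JSON manifest records the
#' seed, parameter hash and per-stage outputs. Reruns with the same config
#' and seed are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "sagpop",
                   version = as.character(utils::packageVersion("sagpop")),
                   seed = config$seed, param_hash = param_hash(unclass(config)),
                   config = unclass(config), stages = list(), failed = NULL)
  seed <- config$seed
  finish <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed <<- list(stage = name, message = conditionMessage(res))
      finish()
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    manifest$stages[[name]] <<- res
    res
  }

  com <- NULL
  run_stage("community", function() {
    com <<- simulate_microcluster_community(
      n_per_cluster = config$n_per_cluster, genome_len = config$genome_len,
      n_genes = config$n_genes, gene_len = config$gene_len,
      within_depth = config$within_depth,
      between = config$between_divergence, seed = seed)
    write_fasta(com$alignment, file.path(outdir, "community.fasta"))
    write_gff_genes(com$genes, file.path(outdir, "genes.gff3"))
    list(taxa = length(com$alignment), files = c("community.fasta", "genes.gff3"))
  })

  ds <- NULL
  run_stage("divergence", function() {
    galn <- extract_gene_alignments(com$alignment, com$genes)
    ds <<- pairwise_ds_table(galn, config$min_seq_coverage,
                             config$min_aln_used)
    write_tsv(ds$table[, setdiff(names(ds$table), "clusters")],
              file.path(outdir, "ds_pairs.tsv"))
    write_tsv(ds$medians, file.path(outdir, "ds_medians.tsv"))
    # SNPs/kb vs microcluster consensus over concatenated genes
    snp <- do.call(rbind, lapply(unique(com$clusters), function(cl) {
      mem <- names(com$clusters)[com$clusters == cl]
      cons <- consensus_sequence(com$alignment[mem])
      do.call(rbind, lapply(mem, function(tx) {
        r <- snp_rate_vs_consensus(com$alignment[[tx]], cons)
        data.frame(cluster = cl, taxon = tx, snps = r$snps,
                   per_kb = r$per_kb)
      }))
    }))
    write_tsv(snp, file.path(outdir, "snp_vs_consensus.tsv"))
    list(n_pairs = nrow(ds$medians), snp_per_kb_median = stats::median(snp$per_kb),
         files = c("ds_pairs.tsv", "ds_medians.tsv", "snp_vs_consensus.tsv"))
  })

  run_stage("recombination", function() {
    tr <- simulate_genealogy(config$rm_taxa, seed = stage_seed(seed, "rm-tree"))
    fit_regime <- function(rm_target, mu, nu, tag) {
      R <- rm_target * mu / (config$rm_delta * nu)
      cfg <- sim_config(n_taxa = config$rm_taxa, genome_len = config$rm_len,
                        mu = mu, R = R, delta = config$rm_delta, nu = nu,
                        seed = stage_seed(seed, paste0("rm-", tag)))
      sim <- overlay_imports(simulate_clonal_sequences(tr, cfg), tr, cfg)
      fit <- fit_recombination(sim$alignment, tree = NULL,
                               n_restarts = config$n_restarts, seed = seed)
      list(regime = tag, target = rm_target,
           realized = realized_rm_oracle(sim$truth),
           estimate = fit$r_over_m, plugin = fit$r_over_m_plugin,
           loglik = fit$loglik, converged = fit$converged)
    }
    lo <- fit_regime(config$rm_low, config$rm_mu_low, config$rm_nu_low, "low")
    hi <- fit_regime(config$rm_high, config$rm_mu_high, config$rm_nu_high,
                     "high")
    tab <- data.frame(regime = c(lo$regime, hi$regime),
                      target = c(lo$target, hi$target),
                      realized = c(lo$realized, hi$realized),
                      estimate = c(lo$estimate, hi$estimate),
                      plugin = c(lo$plugin, hi$plugin),
                      converged = c(lo$converged, hi$converged))
    write_tsv(tab, file.path(outdir, "rm_estimates.tsv"))
    list(low = lo, high = hi,
         separation_orders = log10(hi$estimate / lo$estimate),
         files = "rm_estimates.tsv")
  })

  run_stage("geneflux", function() {
    tr <- simulate_genealogy(config$rm_taxa, seed = stage_seed(seed, "flux-tree"))
    cfg <- sim_config(n_taxa = config$rm_taxa, n_genes = 200L,
                      gain_rate = config$gain_rate,
                      loss_rate = config$loss_rate,
                      seed = stage_seed(seed, "flux"))
    flux <- simulate_gene_flux(tr, cfg)
    rec <- sankoff_reconstruct(tr, flux$matrix, config$gain_cost,
                               config$loss_cost)
    ev <- data.frame(edge = seq_along(rec$gains),
                     parent = tr$edge[, 1], child = tr$edge[, 2],
                     gains = rec$gains, losses = rec$losses)
    write_tsv(ev, file.path(outdir, "flux_events.tsv"))
    write_occurrence_tsv(flux$matrix, file.path(outdir, "occurrence.tsv"))
    # focal branch: stem of the largest clade not adjacent to the root
    # (root-child polarity is unresolvable without outgroups)
    rt <- root_node(tr)
    cand <- which(tr$edge[, 2] > ape::Ntip(tr) & tr$edge[, 1] != rt)
    sizes <- vapply(tr$edge[cand, 2], function(n)
      length(ape::extract.clade(tr, n)$tip.label), 0L)
    focal <- cand[which.max(sizes)]
    sweep <- penalty_sweep(tr, flux$matrix, gain_costs = 2:5,
                           loss_cost = config$loss_cost, focal = focal)
    write_tsv(sweep[, c("gain_cost", "gained")],
              file.path(outdir, "penalty_sweep.tsv"))
    list(total_gains = sum(rec$gains), total_losses = sum(rec$losses),
         total_cost = rec$total_cost,
         sweep = stats::setNames(sweep$gained, sweep$gain_cost),
         files = c("flux_events.tsv", "occurrence.tsv", "penalty_sweep.tsv"))
  })

  run_stage("recruitment", function() {
    # patchwork: two overlapping scaffolds of the first representative
    # genome are joined; a non-overlapping scaffold from a second genome is
    # placed at the end, as small/non-overlapping scaffolds were in the study
    reps <- vapply(c("A", "B", "C"), function(cl)
      names(com$clusters)[com$clusters == cl][1], "")
    g <- com$alignment[[reps[1]]]
    G <- nchar(g)
    eff <- min(config$patchwork_min_overlap, G %/% 4L)
    mid <- G %/% 2L
    scafs <- list(
      stats::setNames(c(substr(g, 1L, mid + eff %/% 2L),
                        substr(g, mid - eff %/% 2L + 1L, G)),
                      c("scf1", "scf2")),
      stats::setNames(substr(com$alignment[[reps[2]]], 1L, 4000L), "scf3"))
    names(scafs) <- reps[1:2]
    pw <- build_patchwork(scafs, min_overlap = eff)
    genomes <- stats::setNames(com$alignment[reps], c("A", "B", "C"))
    ab <- config$abundances[c("A", "B", "C")]
    mcfg <- sim_config(n_taxa = 3L, genome_len = G, err_rate = config$err_rate,
                       read_len = config$read_len, n_reads = config$n_reads,
                       seed = stage_seed(seed, "metagenome"))
    mg <- simulate_metagenome(genomes, ab, mcfg)
    write_fastq(mg$reads, file.path(outdir, "reads.fastq"))
    rec <- recruit_reads(mg$reads, pw, config$min_id, config$min_alnlen,
                         config$min_fraction)
    summ <- summarize_recruitment(rec, length(mg$reads),
                                  length(mg$reads) * config$read_len / 1e6,
                                  pw$length / 1e6)
    write_tsv(summ, file.path(outdir, "recruitment_summary.tsv"))
    slices <- trim_reads_to_genes(rec, mg$reads, com$genes, pw$length,
                                  config$trim_min_overlap)
    cons <- lapply(stats::setNames(seq_len(nrow(com$genes)), com$genes$gene),
                   function(i) {
      galn <- substring(com$alignment, com$genes$start[i] + 1L,
                        com$genes$end[i])
      names(galn) <- names(com$alignment)
      vapply(c("A", "B", "C"), function(cl) consensus_sequence(
        galn[names(com$clusters)[com$clusters == cl]]), "")
    })
    labels <- vapply(seq_len(nrow(slices)), function(i) assign_microcluster(
      slices$seq[i], c(slices$gene_start[i], slices$gene_end[i]),
      cons[[slices$gene[i]]], config$assign_margin)$label, "")
    asg <- data.frame(sample = "demo", label = labels)
    prof <- if (nrow(asg)) abundance_profile(asg) else
      data.frame(sample = character(), cluster = character(),
                 n = integer(), fraction = numeric())
    write_tsv(prof, file.path(outdir, "abundance_profile.tsv"))
    list(patchwork_bp = pw$length, recruited = summ$recruited,
         percent = summ$percent, coverage = summ$coverage,
         n_slices = nrow(slices),
         profile = stats::setNames(prof$fraction, prof$cluster),
         files = c("reads.fastq", "recruitment_summary.tsv",
                   "abundance_profile.tsv"))
  })

  finish()
  invisible(manifest)
}

#' Generate a run report from pipeline outputs
#'
#' Collects the stage outputs present in a run directory into one
#' machine-readable JSON and a short human-readable text summary; missing
#' stages are listed as skipped and the report is still produced.
#' Regeneration is idempotent.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return the report list, invisibly.
#' @export
make_report <- function(run_dir) {
  mf_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", run_dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  rep <- list(seed = mf$seed, param_hash = mf$param_hash, skipped = character())
  grab <- function(file) {
    p <- file.path(run_dir, file)
    if (file.exists(p)) utils::read.table(p, sep = "\t", header = TRUE) else NULL
  }
  ds <- grab("ds_medians.tsv")
  if (is.null(ds)) rep$skipped <- c(rep$skipped, "divergence") else
    rep$ds_medians <- ds
  rm <- grab("rm_estimates.tsv")
  if (is.null(rm)) rep$skipped <- c(rep$skipped, "recombination") else {
    rep$rm <- rm
    rep$rm_separation_orders <-
      log10(rm$estimate[rm$regime == "high"] / rm$estimate[rm$regime == "low"])
  }
  sw <- grab("penalty_sweep.tsv")
  if (is.null(sw)) rep$skipped <- c(rep$skipped, "geneflux") else
    rep$penalty_sweep <- sw
  rc <- grab("recruitment_summary.tsv")
  if (is.null(rc)) rep$skipped <- c(rep$skipped, "recruitment") else
    rep$recruitment <- rc
  ab <- grab("abundance_profile.tsv")
  if (!is.null(ab)) rep$abundance <- ab
  jsonlite::write_json(rep, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  txt <- c("sagpop pipeline report",
           sprintf("seed %s  params %s", mf$seed, mf$param_hash))
  if (!is.null(rep$rm))
    txt <- c(txt, sprintf(
      "r/m: low regime est %.3g (target %.3g), high est %.3g (target %.3g), separation %.1f orders",
      rep$rm$estimate[rep$rm$regime == "low"], rep$rm$target[rep$rm$regime == "low"],
      rep$rm$estimate[rep$rm$regime == "high"], rep$rm$target[rep$rm$regime == "high"],
      rep$rm_separation_orders))
  if (!is.null(rep$recruitment))
    txt <- c(txt, sprintf("recruitment: %d reads (%.1f%%), %.1fx coverage",
                          rep$recruitment$recruited, rep$recruitment$percent,
                          rep$recruitment$coverage))
  if (length(rep$skipped))
    txt <- c(txt, paste("skipped stages:", paste(rep$skipped, collapse = ", ")))
  writeLines(txt, file.path(run_dir, "report.txt"))
  invisible(rep)
}
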