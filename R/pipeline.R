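#' Default pipeline configuration
#'
#' Returns the full configuration of the end-to-end analysis with the
#' package defaults: QC at SNP call rate 0.95, animal call rate 0.90 and
#' HWE alpha 1e-6; GBC with a 1% nullification filter, a 0.94 purity
#' cut-off and a 5% two-breed cross threshold; the five-criteria ROH scan;
#' a top-1% island threshold. The `simulate` block describes the synthetic
#' study: an indigenous-like and a western-like breed cluster, a focal
#' breed with planted autozygosity, and two-breed crosses with known
#' origin. Every entry may be overridden (overrides are echoed in the run
#' manifest).
#'
#' @param seed integer seed driving every stochastic stage.
#' @return nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    input = NULL,  # list(genotypes = <plink prefix>, dialect, freqs = <tsv>) to skip simulation
    simulate = list(
      n_chrom = 18L, snps_per_chrom = 2450L, chrom_length = 125e6,
      tree = list(c("NX", "SZL", "BM", "EH", "RC"), c("DC", "LR", "YK")),
      fst = c(0.18, 0.04),
      focal_breed = "NX",
      n_focal = 40L, target_F = 0.09, mean_seg_len_mb = 6.3,
      crosses = list(
        list(breedA = "DC", breedB = "NX", type = "F1", n = 8L),
        list(breedA = "DC", breedB = "NX", type = "F2", n = 4L),
        list(breedA = "DC", breedB = "NX", type = "BC_B", n = 4L),
        list(breedA = "SZL", breedB = "NX", type = "F1", n = 4L)),
      n_other = 4L, other_breed = "DC",
      missing_rate = 0.01),
    qc = list(snp_call_rate = 0.95, ind_call_rate = 0.90, hwe_alpha = 1e-6),
    gbc = list(nullify = 0.01, cutoff = 0.94, cross_threshold = 0.05,
               prune_tol = 1e-3),
    roh = roh_params(),
    islands = list(top_fraction = 0.01),
    pca_k = 2L
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override the defaults of
#' [pipeline_config]; everything else keeps its default.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = user$seed %||% 1L)
  for (nm in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

#' Run the full breed-composition / ROH pipeline
#'
#' Stages: simulate (or ingest) genotypes, QC, GBC estimation and
#' purebred/cross classification, ROH detection on the classified
#' purebreds of the focal breed, ROH summary statistics and inbreeding,
#' ROH islands, and population structure. All stage outputs are written as
#' tab-separated text under `outdir`, together with a JSON manifest of the
#' configuration, seed and per-file MD5 checksums; rerunning with the same
#' configuration reproduces identical checksums.
#'
#' @param config a `pipeline_config`.
#' @param outdir output directory (created if absent).
#' @return the manifest, invisibly (list).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_msg <- function(...) message("[pipeline] ", ...)
  stage <- function(name, expr) {
    log_msg("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  truth <- NULL; origin <- NULL
  if (is.null(config$input)) {
    sim <- config$simulate
    dat <- stage("simulate", {
      map <- gen_marker_map(sim$n_chrom, sim$snps_per_chrom, sim$chrom_length,
                            seed = seed)
      freqs <- gen_breed_frequencies(map, sim$tree, fst = sim$fst,
                                     seed = seed + 1L)
      foc <- gen_autozygous_genomes(map, freqs[sim$focal_breed, ], sim$n_focal,
                                    target_F = sim$target_F,
                                    mean_seg_len_mb = sim$mean_seg_len_mb,
                                    missing_rate = sim$missing_rate,
                                    seed = seed + 2L)
      geno <- foc$gm$geno
      ids <- paste0("focal", seq_len(nrow(geno)))
      origin <- NULL
      ci <- 0L
      for (cr in sim$crosses) {
        ci <- ci + 1L
        d <- cross_design(cr$breedA, cr$breedB, cr$type)
        cg <- gen_cross_genotypes(freqs[cr$breedA, ], freqs[cr$breedB, ], map,
                                  d, cr$n, seed = seed + 10L + ci)
        cid <- sprintf("%s_%sx%s_%d", cr$type, cr$breedA, cr$breedB,
                       seq_len(cr$n))
        geno <- rbind(geno, cg$gm$geno)
        ids <- c(ids, cid)
        origin <- rbind(origin, data.frame(animal = cid, breedA = cr$breedA,
                                           fracA = cg$origin$fracA))
      }
      if (sim$n_other > 0) {
        og <- gen_purebred_genotypes(freqs[sim$other_breed, ], map, sim$n_other,
                                     missing_rate = sim$missing_rate,
                                     seed = seed + 30L)
        geno <- rbind(geno, og$geno)
        ids <- c(ids, paste0("other", seq_len(sim$n_other)))
      }
      gm <- genotype_matrix(geno, map, ids)
      truth <- foc$truth
      truth$animal <- ids[match(truth$animal, foc$gm$ids)]
      list(gm = gm, freqs = freqs, truth = truth, origin = origin)
    })
    write_freq_table(dat$freqs, file.path(outdir, "breed_frequencies.tsv"))
    data.table::fwrite(dat$truth, file.path(outdir, "planted_segments.tsv"), sep = "\t")
    if (!is.null(dat$origin))
      data.table::fwrite(dat$origin, file.path(outdir, "cross_truth.tsv"), sep = "\t")
    gm <- dat$gm; freqs <- dat$freqs
    focal <- sim$focal_breed
  } else {
    gm <- stage("ingest", read_plink(config$input$genotypes,
                                     dialect = config$input$dialect %||% "text"))
    freqs <- stage("ingest", read_freq_table(config$input$freqs))
    focal <- config$input$focal_breed
  }

  qc <- stage("qc", qc_filter(gm, config$qc$snp_call_rate,
                              config$qc$ind_call_rate, config$qc$hwe_alpha))
  gm_qc <- qc$gm
  freqs_qc <- freqs[, match(gm_qc$map$snp_id, colnames(freqs)), drop = FALSE]
  qr <- qc$report
  data.table::fwrite(data.frame(
    rule = c("animal_call_rate", "snp_call_rate", "snp_hwe"),
    threshold = unname(qr$thresholds[c("ind_call_rate", "snp_call_rate", "hwe_alpha")]),
    removed = c(qr$animals_removed_call_rate, qr$snps_removed_call_rate,
                qr$snps_removed_hwe)),
    file.path(outdir, "qc_report.tsv"), sep = "\t")

  gbc <- stage("gbc", {
    res <- estimate_gbc_all(gm_qc, freqs_qc,
                            nullify_threshold = config$gbc$nullify,
                            prune_tol = config$gbc$prune_tol)
    res$label <- vapply(seq_len(nrow(res)), function(i)
      classify_purebred(unlist(res[i, rownames(freqs_qc)]), focal,
                        config$gbc$cutoff), character(1))
    res
  })
  data.table::fwrite(gbc, file.path(outdir, "gbc_report.tsv"), sep = "\t")

  purebred_ids <- gbc$animal[gbc$label == "purebred"]
  gm_pure <- if (length(purebred_ids)) {
    keep <- gm_qc$ids %in% purebred_ids
    genotype_matrix(gm_qc$geno[keep, , drop = FALSE], gm_qc$map,
                    gm_qc$ids[keep])
  } else NULL

  segs <- stage("roh", {
    if (is.null(gm_pure)) stop("no purebred animals to scan")
    detect_roh(gm_pure, config$roh)
  })
  write_roh(segs, file.path(outdir, "roh_segments.tsv"))

  stats_out <- stage("stats", {
    summ <- summarize_roh(segs, n_animals = length(purebred_ids))
    inb <- inbreeding_table(segs, purebred_ids, gm_pure$map)
    cov <- chromosome_coverage(segs, gm_pure$map)
    gen <- generations_from_length(summ$table$mean_length_mb[
      summ$table$class != "All" & summ$table$N > 0])
    list(summ = summ, inb = inb, cov = cov, gen = gen)
  })
  data.table::fwrite(stats_out$summ$table, file.path(outdir, "roh_class_table.tsv"), sep = "\t")
  data.table::fwrite(stats_out$inb$overall, file.path(outdir, "inbreeding.tsv"), sep = "\t")
  data.table::fwrite(stats_out$cov, file.path(outdir, "chromosome_coverage.tsv"), sep = "\t")

  isl <- stage("islands", detect_islands(segs, gm_pure$map,
                                         length(purebred_ids),
                                         config$islands$top_fraction))
  data.table::fwrite(isl$incidence, file.path(outdir, "snp_incidence.tsv"), sep = "\t")
  data.table::fwrite(isl$islands, file.path(outdir, "roh_islands.tsv"), sep = "\t")

  stage("structure", {
    corr <- breed_frequency_correlation(freqs_qc)
    utils::write.table(round(corr, 4), file.path(outdir, "breed_correlation.tsv"),
                       sep = "\t", quote = FALSE)
    write_dendrogram(cluster_breeds(corr), file.path(outdir, "breed_dendrogram.nwk"))
    pca <- pca_genotypes(gm_qc, k = config$pca_k)
    data.table::fwrite(data.frame(animal = rownames(pca$scores),
                                  round(pca$scores, 4)),
                       file.path(outdir, "pca_scores.tsv"), sep = "\t")
  })

  files <- sort(list.files(outdir, pattern = "\\.(tsv|nwk)$"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("gbcroh")),
    seed = seed,
    config_hash = config_hash(config),
    n_animals_in = nrow(gm$geno),
    n_purebred = length(purebred_ids),
    f_roh_mean = mean(stats_out$inb$overall$f_roh),
    checksums = as.list(tools::md5sum(file.path(outdir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("done: ", length(files), " outputs in ", outdir)
  invisible(manifest)
}

# order-stable hash of the configuration
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile(); on.exit(unlink(f))
  writeLines(as.character(s), f)
  unname(tools::md5sum(f))
}
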