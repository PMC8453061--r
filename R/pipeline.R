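#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> select-probes -> estimate -> genotype QC ->
#' association on a synthetic cohort, writing each stage's outputs and
#' a manifest (file hashes, row counts, seed) under `out_dir`. With
#' `resume = TRUE`, stages whose output files still match the recorded
#' manifest hashes are skipped.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param min_mm probe-selection nuclear mismatch threshold.
#' @param est_config an [estimator_config()].
#' @param qc_cfg a [qc_config()].
#' @param resume reuse stage outputs whose hashes match the manifest.
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         min_mm = 2L,
                         est_config = estimator_config(),
                         qc_cfg = qc_config(),
                         resume = FALSE, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest_path <- file.path(out_dir, "manifest.json")
  old_manifest <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL

  paths <- list(
    references = file.path(out_dir, "references.fasta"),
    probes_fa = file.path(out_dir, "probes.fasta"),
    probes_tsv = file.path(out_dir, "probes.tsv"),
    intensities = file.path(out_dir, "intensities.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    genotypes = file.path(out_dir, "genotypes.vcf"),
    truth = file.path(out_dir, "truth.json"),
    selection = file.path(out_dir, "probe_selection.tsv"),
    estimates = file.path(out_dir, "estimates.tsv"),
    probe_qc = file.path(out_dir, "probe_qc.tsv"),
    qc_samples = file.path(out_dir, "qc_removed_samples.tsv"),
    qc_snps = file.path(out_dir, "qc_removed_snps.tsv"),
    pcs = file.path(out_dir, "pc_scores.tsv"),
    association = file.path(out_dir, "association.tsv"),
    km = file.path(out_dir, "km_curves.tsv"),
    roc = file.path(out_dir, "roc_summary.tsv"),
    summary = file.path(out_dir, "summary.json"))

  stage_done <- function(stage, files) {
    if (is.null(old_manifest) || is.null(old_manifest$stages[[stage]])) {
      return(FALSE)
    }
    rec <- old_manifest$stages[[stage]]$files
    if (!all(file.exists(files))) return(FALSE)
    all(unname(tools::md5sum(files)) == unlist(rec[basename(files)]))
  }
  manifest <- list(seed = config$seed, n_samples = config$n_samples,
                   stages = list())
  record <- function(stage, files, info = list()) {
    manifest$stages[[stage]] <<- c(
      list(files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                           basename(files)))), info)
  }

  # -- simulate ------------------------------------------------------
  sim_files <- unlist(paths[c("references", "probes_fa", "probes_tsv",
                              "intensities", "phenotypes", "genotypes",
                              "truth")])
  sim <- simulate_dataset(config)
  if (stage_done("simulate", sim_files)) {
    say("simulate: outputs up to date, reusing")
  } else {
    say("simulate: n=%d samples, %d probes, %d SNPs", config$n_samples,
        nrow(sim$probes), config$n_snps)
    write_fasta(c(mito = sim$ref$refs$mito, sim$ref$refs$nuclear),
                paths$references)
    write_fasta(stats::setNames(sim$probes$sequence, sim$probes$probe_id),
                paths$probes_fa)
    write_tsv(sim$probes[c("probe_id", "gc_fraction", "source")],
              paths$probes_tsv)
    write_matrix_tsv(round(sim$intensities$intensity, 4), paths$intensities)
    write_tsv(sim$cohort$cohort, paths$phenotypes)
    write_vcf(sim$genotypes$genotypes, paths$genotypes)
    truth <- list(numts = sim$ref$numts,
                  outlier_probes = sim$probes$probe_id[sim$probes$is_outlier],
                  cn = as.list(sim$cn),
                  h0 = as.list(sim$cohort$h0),
                  genotype_truth = sim$genotypes$truth[
                    c("low_maf_snps", "monomorphic_snps", "all_het_snps",
                      "bad_sample", "bad_snps")])
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = 10)
  }
  record("simulate", sim_files)

  # -- probe selection ----------------------------------------------
  probes_df <- sim$probes[c("probe_id", "sequence")]
  sel <- select_mtdna_probes(probes_df, sim$ref$refs, min_mm = min_mm)
  write_tsv(sel$report, paths$selection)
  record("select_probes", paths$selection,
         list(n_selected = nrow(sel$selected)))
  say("select-probes: %d of %d probes selected", nrow(sel$selected),
      nrow(sel$report))

  # -- estimation ----------------------------------------------------
  ints <- sim$intensities$intensity[sel$selected$probe_id, , drop = FALSE]
  gc <- stats::setNames(sel$selected$gc_fraction, sel$selected$probe_id)
  est <- estimate_mtdna_pipeline(ints, gc, est_config)
  write_tsv(est$estimates, paths$estimates)
  write_tsv(data.frame(probe_id = names(est$outlier_distances),
                       sd_distance = unname(est$outlier_distances),
                       removed = names(est$outlier_distances) %in% est$removed,
                       stringsAsFactors = FALSE), paths$probe_qc)
  record("estimate", c(paths$estimates, paths$probe_qc),
         list(n_retained = length(est$retained)))
  say("estimate: %d probes retained, %d removed as outliers",
      length(est$retained), length(est$removed))

  # -- genotype QC ---------------------------------------------------
  qc <- run_genotype_qc(sim$genotypes$genotypes, qc_cfg)
  write_tsv(qc$removed_samples, paths$qc_samples)
  write_tsv(qc$removed_snps, paths$qc_snps)
  pcs_df <- data.frame(sample_id = rownames(qc$pcs), qc$pcs,
                       stringsAsFactors = FALSE)
  write_tsv(pcs_df, paths$pcs)
  record("qc", unlist(paths[c("qc_samples", "qc_snps", "pcs")]),
         list(n_samples = ncol(qc$genotypes), n_snps = nrow(qc$genotypes)))
  say("qc: removed %d samples, %d SNPs; %d PCs on %d pruned SNPs",
      nrow(qc$removed_samples), nrow(qc$removed_snps), ncol(qc$pcs),
      length(qc$pruned_snps))

  # -- association ---------------------------------------------------
  pheno <- merge(sim$cohort$cohort, pcs_df, by = "sample_id", all.x = TRUE)
  assoc <- run_association_suite(est$estimates, pheno)
  write_tsv(assoc, paths$association)

  merged <- merge(est$estimates, sim$cohort$cohort, by = "sample_id")
  ards <- merged[merged$ards == 1, ]
  km <- km_logrank(ards, median_split(ards$standardized_estimate))
  write_tsv(km$curves, paths$km)
  roc_mt <- roc_delong(ards$standardized_estimate, ards$event)
  roc_rows <- data.frame(score = "wb_mtdna", auc = roc_mt$auc,
                         lo95 = roc_mt$ci[1], hi95 = roc_mt$ci[2],
                         stringsAsFactors = FALSE)
  cc <- !is.na(ards$apache2)
  if (sum(ards$event[cc]) >= 2) {
    roc_ap <- roc_delong(ards$apache2[cc], ards$event[cc])
    lp <- stats::glm(event ~ standardized_estimate + apache2,
                     family = stats::binomial(), data = ards[cc, ])
    roc_both <- roc_delong(stats::fitted(lp), ards$event[cc])
    cmp <- compare_rocs(ards$standardized_estimate[cc],
                        stats::fitted(lp), ards$event[cc])
    roc_rows <- rbind(
      roc_rows,
      data.frame(score = "apache2", auc = roc_ap$auc, lo95 = roc_ap$ci[1],
                 hi95 = roc_ap$ci[2], stringsAsFactors = FALSE),
      data.frame(score = "wb_mtdna_plus_apache2", auc = roc_both$auc,
                 lo95 = roc_both$ci[1], hi95 = roc_both$ci[2],
                 stringsAsFactors = FALSE))
    delong_p <- cmp$p
  } else {
    delong_p <- NA_real_
  }
  write_tsv(roc_rows, paths$roc)
  summary <- list(
    n_samples = config$n_samples,
    n_probes_selected = nrow(sel$selected),
    n_probes_retained = length(est$retained),
    ards_crude_hr = assoc$hr[assoc$model == "crude" & assoc$stratum == "ards"],
    logrank_p = km$p, auc_wb_mtdna = roc_mt$auc, delong_p = delong_p,
    events_needed_hr2 = events_needed(0.05, 0.90, 2))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = 10)
  record("associate",
         unlist(paths[c("association", "km", "roc", "summary")]),
         list(logrank_p = km$p))
  say("associate: ARDS crude HR %.2f, log-rank p %.3g, AUC %.3f",
      summary$ards_crude_hr, km$p, roc_mt$auc)

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(manifest)
}

#' Render a human-readable pipeline report
#'
#' Assembles the stage outputs under `out_dir` into a Markdown summary:
#' probe selection counts, estimator QC, genotype QC removals, the
#' stratified crude association table and the adjusted-model ladder.
#' Missing stage outputs produce a partial report with warnings.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param path output Markdown file (default `report.md` in `out_dir`).
#' @return invisibly, the report path.
#' @export
render_report <- function(out_dir, path = file.path(out_dir, "report.md")) {
  lines <- c("# Synthetic wb-mtDNA survival pipeline report", "")
  fmt_tab <- function(df) {
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i) {
        paste("|", paste(vapply(df[i, ], function(v) {
          if (is.numeric(v)) format(signif(v, 4)) else as.character(v)
        }, character(1)), collapse = " | "), "|")
      }, character(1)))
  }
  add_stage <- function(lines, file, title, fn) {
    p <- file.path(out_dir, file)
    if (!file.exists(p)) {
      warning("missing stage output: ", file)
      return(c(lines, sprintf("## %s", title), "", "*missing*", ""))
    }
    c(lines, sprintf("## %s", title), "", fn(p), "")
  }
  lines <- add_stage(lines, "probe_selection.tsv", "Probe selection",
                     function(p) {
    d <- read_tsv(p)
    sprintf("%d of %d probes selected (exact mito match, nuclear mismatch screen).",
            sum(d$selected), nrow(d))
  })
  lines <- add_stage(lines, "probe_qc.tsv", "Probe outlier removal",
                     function(p) {
    d <- read_tsv(p)
    sprintf("%d of %d probes removed as intensity outliers.",
            sum(d$removed), nrow(d))
  })
  lines <- add_stage(lines, "qc_removed_samples.tsv", "Genotype QC",
                     function(p) {
    ds <- read_tsv(p)
    dp <- read_tsv(file.path(out_dir, "qc_removed_snps.tsv"))
    c(sprintf("Removed %d sample(s) and %d SNP(s).", nrow(ds), nrow(dp)),
      if (nrow(ds)) fmt_tab(ds))
  })
  lines <- add_stage(lines, "association.tsv", "Association models",
                     function(p) {
    d <- read_tsv(p)
    crude <- d[d$model == "crude", ]
    ladder <- d[d$model != "crude", ]
    out <- c("### Crude (per stratum)", "", fmt_tab(crude), "")
    if (nrow(ladder)) {
      out <- c(out, "### Adjusted and sensitivity models (ARDS)", "",
               fmt_tab(ladder))
    }
    out
  })
  lines <- add_stage(lines, "roc_summary.tsv", "ROC", function(p) {
    fmt_tab(read_tsv(p))
  })
  writeLines(lines, path)
  invisible(path)
}
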