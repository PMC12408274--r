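#' Run the full within-population analysis pipeline
#'
#' Orchestrates the complete analysis in the canonical order: call-rate QC,
#' ROH detection and inbreeding coefficients, pairwise FST, LD-decay Ne per
#' population, the five per-population selection scans, DCMS composition
#' with FDR calling, and candidate BED export. Every output lands in one
#' results directory together with an echoed configuration and a run log,
#' and every number in the summary is re-derivable by calling the
#' corresponding function with the echoed parameters.
#'
#' The configuration is a nested list (or path to a YAML file with the
#' same structure):
#' \preformatted{
#' input:    prefix: <plink prefix>     # or
#' simulate: <arguments for wf_config(), including seed>
#' phased_vcf: <path>                   # optional, enables iHS/H12
#' outdir:   <results directory>
#' seed:     <integer>
#' stages:   [qc, roh, fst, ne, scan, dcms]   # optional subset
#' qc:   {sample_max_missing: 0.10, variant_max_missing: 0.05}
#' roh:  {min_length_kb: 1000, ...}     # roh_params() fields; min_snps
#'                                      # defaults to the L parameter
#' ne:   {dist_min_bp: 50000, dist_max_bp: 4000000, bin_bp: 50000,
#'        alpha: 2, mapping: sved_feldman}
#' scan: {maf_min: 0.05, h12_window_snps: 25, zhp_window_bp: 200000,
#'        freq_window_bp: 300000, min_snps: 10}
#' dcms: {grid_bp: 500000, fdr_q: 0.05, min_components: 3}
#' }
#' Unknown top-level keys are rejected. Haplotype-based scans (iHS, H12)
#' run only when phased haplotypes are available (simulated truth phase or
#' `phased_vcf`); otherwise the composite uses the three genotype-based
#' statistics.
#'
#' @param config nested list or YAML file path
#' @return invisibly, the summary list (also written as `summary.json`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("input", "simulate", "phased_vcf", "outdir", "seed", "stages",
             "qc", "roh", "ne", "scan", "dcms", "kinship")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$outdir)) stop("configuration needs an 'outdir'")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  stages <- config$stages %||% c("qc", "roh", "fst", "ne", "scan", "dcms")
  log_path <- file.path(outdir, "run_log.txt")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ..., "\n",
                            sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("flockscan ", as.character(utils::packageVersion("flockscan")),
       "; seed ", seed)
  yaml::write_yaml(config, file.path(outdir, "config_echo.yaml"))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  summary <- list(seed = seed)
  hsets <- NULL

  # ---- input ----
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim <- run_stage("input", simulate_wf(do.call(wf_config, sim_args)))
    g <- sim$genotypes
    hsets <- sim$haplotypes
    jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logf("simulated input: ", n_samples(g), " samples x ", n_variants(g),
         " variants")
  } else if (!is.null(config$input$prefix)) {
    g <- run_stage("input", load_plink(config$input$prefix))
    logf("loaded ", config$input$prefix, ": ", n_samples(g), " x ",
         n_variants(g))
  } else stop("configuration needs either 'input: prefix:' or 'simulate:'")
  if (!is.null(config$phased_vcf))
    hsets <- run_stage("input", read_phased_vcf(config$phased_vcf))

  # ---- qc ----
  if ("qc" %in% stages) {
    qc_args <- config$qc %||% list()
    qc <- run_stage("qc", do.call(apply_qc, c(list(g), qc_args)))
    g <- qc$genotypes
    write_qc_report(qc$report, file.path(outdir, "qc_report.tsv"))
    summary$qc <- list(n_samples_in = qc$report$n_samples_in,
                       n_samples_out = qc$report$n_samples_out,
                       n_variants_in = qc$report$n_variants_in,
                       n_variants_out = qc$report$n_variants_out,
                       removed_samples = qc$report$removed_samples$sample_id,
                       removed_variants = qc$report$removed_variants$id)
    logf("qc: ", qc$report$n_samples_out, " samples, ",
         qc$report$n_variants_out, " variants retained")
    if (!is.null(hsets))
      hsets <- lapply(hsets, subset_haplotypes,
                      sample_ids = intersect(hsets[[1]]$sample_ids,
                                             g$samples$sample_id))
  }
  pops <- unique(g$samples$population)

  # ---- roh + inbreeding ----
  if ("roh" %in% stages) {
    summary$roh <- run_stage("roh", {
      roh_args <- config$roh %||% list()
      inb_all <- NULL; seg_all <- NULL
      for (pop in pops) {
        gp <- subset_genotypes(g, samples = g$samples$population == pop)
        if (is.null(roh_args$min_snps)) {
          mh <- mean(colMeans(gp$calls == 1, na.rm = TRUE), na.rm = TRUE)
          mh <- min(max(mh, 1e-3), 1 - 1e-3)
          roh_args$min_snps <- l_parameter(n_variants(gp), n_samples(gp),
                                           mean_het = mh)
        }
        params <- do.call(roh_params, roh_args)
        segs <- detect_roh(gp, params)
        seg_all <- rbind(seg_all, segs)
        inb_all <- rbind(inb_all,
                         suppressWarnings(inbreeding_coefficients(gp, segs)))
        roh_args$min_snps <- NULL
      }
      write_roh(seg_all, file.path(outdir, "roh_segments.tsv"))
      utils::write.table(inb_all, file.path(outdir, "inbreeding.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logf("roh: ", nrow(seg_all), " segments")
      list(n_segments = nrow(seg_all),
           mean_f_roh = as.list(tapply(inb_all$F_ROH, inb_all$population,
                                       mean)))
    })
  }

  # ---- fst ----
  if ("fst" %in% stages && length(pops) >= 2) {
    M <- run_stage("fst", fst_matrix(g))
    utils::write.table(M, file.path(outdir, "fst_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    summary$fst <- list(max = max(M), min_offdiag = min(M[upper.tri(M)]))
    logf("fst matrix over ", length(pops), " populations")
  }

  # ---- ne ----
  if ("ne" %in% stages) {
    ne_args <- config$ne %||% list()
    summary$ne <- run_stage("ne", {
      out <- list()
      for (pop in pops) {
        gp <- subset_genotypes(g, samples = g$samples$population == pop)
        keep <- ld_prune(gp, window_snps = 100, step_snps = 50,
                         r2_threshold = 0.1)
        tr <- do.call(ne_trajectory, c(list(subset_genotypes(gp,
                                                variants = keep)), ne_args))
        utils::write.table(tr, file.path(outdir, paste0("ne_", pop, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        v <- tr[tr$valid, ]
        out[[pop]] <- if (nrow(v)) stats::median(v$Ne) else NA
      }
      logf("ne trajectories written")
      out
    })
  }

  # ---- scan + dcms ----
  if (any(c("scan", "dcms") %in% stages)) {
    scan_args <- config$scan %||% list()
    dcms_args <- config$dcms %||% list()
    sig_counts <- list()
    for (pop in pops) {
      res <- run_stage("scan", {
        gp <- subset_genotypes(g, samples = g$samples$population == pop)
        ihs <- NULL; h12 <- NULL
        if (!is.null(hsets)) {
          keep_ids <- intersect(hsets[[1]]$sample_ids,
                                gp$samples$sample_id)
          hp <- lapply(hsets, subset_haplotypes, sample_ids = keep_ids)
          hp <- lapply(hp, function(h) polarize_to_major(h)$haplotypes)
          ihs <- ihs_scan(hp, maf_min = scan_args$maf_min %||% 0.05)
          h12 <- h12_scan(hp,
                          window_snps = scan_args$h12_window_snps %||% 25L)
        }
        zhp <- zhp_scan(gp, window_bp = scan_args$zhp_window_bp %||% 200000,
                        min_snps = scan_args$min_snps %||% 10L)
        freq <- window_frequency_stats(
          gp, window_bp = scan_args$freq_window_bp %||% 300000,
          min_snps = scan_args$min_snps %||% 10L)
        for (nm in c("ihs", "h12", "zhp", "freq")) {
          obj <- get(nm)
          if (!is.null(obj))
            utils::write.table(obj,
              file.path(outdir, paste0("scan_", pop, "_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
        }
        list(ihs = ihs, h12 = h12, zhp = zhp, freq = freq)
      })
      if ("dcms" %in% stages) {
        dc <- run_stage("dcms", do.call(dcms_pipeline,
          c(res, list(grid_bp = dcms_args$grid_bp %||% 500000,
                      fdr_q = dcms_args$fdr_q %||% 0.05,
                      min_components = dcms_args$min_components %||% 3L))))
        utils::write.table(dc, file.path(outdir, paste0("dcms_", pop, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        export_candidates(dc,
                          path = file.path(outdir,
                                           paste0("candidates_", pop, ".bed")))
        sig_counts[[pop]] <- sum(dc$significant)
        logf("dcms ", pop, ": ", sum(dc$significant), " significant windows")
      }
    }
    if (length(sig_counts)) summary$dcms_significant_windows <- sig_counts
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
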