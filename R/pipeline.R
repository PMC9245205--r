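# Pipeline orchestration: simulate -> DE -> dominance -> ASE -> patterns ->
# overlap -> enrichment -> variant analysis, behind a single seeded
# configuration. Every stage writes TSV outputs; rerunning with the same
# configuration and seed reproduces the result tables byte for byte
# (run_report.tsv, which carries wall times, is the only exception).

#' Pipeline configuration
#'
#' All thresholds of the analysis surface here with their default values:
#' DEG calling at `deg_fdr` 0.01 and `deg_lfc` 1, ASEG calling at
#' `ase_padj` 0.05, the activity rule (`active_min_reads` 2 reads in
#' `active_min_reps` 2 replicates), the allelic depth floor `ase_min_depth`
#' 10, and `n_sim` 1000 resampling draws.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed; stage seeds are derived from it so that
#'   enabling or disabling one stage does not perturb the others.
#' @param simulate generate inputs with the simdata module (TRUE) or read
#'   them from the given paths (FALSE).
#' @param sim list of [sim_config] arguments (seed comes from `seed`).
#' @param counts_path,sheet_path,allelic_path,gff_path,vcf_path,genome_path,term_map_path
#'   input files when `simulate = FALSE` (counts/sheet/allelic are required;
#'   the variant stage runs only when gff/vcf/genome are all given).
#' @param deg_fdr,deg_lfc,ase_padj,active_min_reads,active_min_reps,ase_min_depth,n_sim
#'   analysis thresholds (see description).
#' @param dghp_union classify the union (TRUE) or intersection (FALSE) of
#'   the two hybrid-vs-parent DEG sets.
#' @param pseudocount_reporting add the reporting-only pseudocount log2
#'   fold change column to DE tables.
#' @param rank_sum_sign_fix apply variant rank-sum filters with negative
#'   thresholds (see [filter_variants]).
#' @param stages character vector of stages to run, or `"all"`. Stages:
#'   simulate, de, dominance, ase, patterns, overlap, enrich, varannot.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, simulate = TRUE,
                            sim = list(),
                            counts_path = NULL, sheet_path = NULL,
                            allelic_path = NULL, gff_path = NULL,
                            vcf_path = NULL, genome_path = NULL,
                            term_map_path = NULL,
                            deg_fdr = 0.01, deg_lfc = 1, ase_padj = 0.05,
                            active_min_reads = 2L, active_min_reps = 2L,
                            ase_min_depth = 10L, n_sim = 1000L,
                            dghp_union = TRUE,
                            pseudocount_reporting = FALSE,
                            rank_sum_sign_fix = TRUE,
                            stages = "all") {
  all_stages <- c("simulate", "de", "dominance", "ase", "patterns",
                  "overlap", "enrich", "varannot")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages))
    config_error("unknown stage(s): ",
                 paste(setdiff(stages, all_stages), collapse = ", "))
  if (!simulate) stages <- setdiff(stages, "simulate")
  cfg <- list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
              sim = sim, counts_path = counts_path,
              sheet_path = sheet_path, allelic_path = allelic_path,
              gff_path = gff_path, vcf_path = vcf_path,
              genome_path = genome_path, term_map_path = term_map_path,
              deg_fdr = deg_fdr, deg_lfc = deg_lfc, ase_padj = ase_padj,
              active_min_reads = as.integer(active_min_reads),
              active_min_reps = as.integer(active_min_reps),
              ase_min_depth = as.integer(ase_min_depth),
              n_sim = as.integer(n_sim), dghp_union = dghp_union,
              pseudocount_reporting = pseudocount_reporting,
              rank_sum_sign_fix = rank_sum_sign_fix, stages = stages)
  for (th in c("deg_fdr", "deg_lfc", "ase_padj", "active_min_reads",
               "active_min_reps", "ase_min_depth", "n_sim"))
    if (!(cfg[[th]] > 0)) config_error(th, " must be positive")
  if (!simulate) {
    for (pp in c("counts_path", "sheet_path", "allelic_path")) {
      if (is.null(cfg[[pp]]))
        config_error(pp, " is required when simulate = FALSE")
      if (!file.exists(cfg[[pp]]))
        config_error(pp, " does not exist: ", cfg[[pp]])
    }
    for (pp in c("gff_path", "vcf_path", "genome_path", "term_map_path"))
      if (!is.null(cfg[[pp]]) && !file.exists(cfg[[pp]]))
        config_error(pp, " does not exist: ", cfg[[pp]])
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror the [pipeline_config] arguments.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order, writing one TSV per
#' result table under `outdir` plus a `MANIFEST` of the files produced and
#' a `run_report.tsv` (seed, gene counts per stage, wall time). A stage
#' failure leaves the partial outputs in place with the MANIFEST marked
#' incomplete, then signals the error.
#'
#' @param config a [pipeline_config] (or a YAML path understood by
#'   [read_pipeline_config]).
#' @return invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  produced <- character(0)
  emit <- function(df, name) {
    write_tsv(df, out(name))
    produced <<- c(produced, name)
  }
  report <- list(seed = config$seed)
  res <- list()
  manifest <- function(status) {
    writeLines(c(paste0("status\t", status),
                 paste0("file\t", sort(produced))), out("MANIFEST"))
  }
  run <- function() {
    stages <- config$stages
    # ---- inputs ----
    if ("simulate" %in% stages) {
      scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
      trio <- simulate_trio_counts(scfg)
      allelic <- simulate_allelic_counts(scfg, trio$truth)
      ann <- simulate_genome_annotation(scfg, trio$truth)
      terms <- simulate_term_map(scfg,
                                 rownames(SummarizedExperiment::assay(trio$counts)))
      write_counts(trio$counts, out("counts.tsv"), out("samples.tsv"))
      write_allelic_counts(allelic, out("allelic.tsv"))
      write_gff(ann$models, out("genes.gff3"))
      write_vcf(ann$variants, out("variants.vcf"))
      write_genome(ann$genome, out("genome.fa"))
      write_tsv(terms, out("terms.tsv"))
      write_truth(trio$truth, out("truth.tsv"))
      write_truth(ann$variant_truth, out("variant_truth.tsv"))
      produced <- c(produced, "counts.tsv", "samples.tsv", "allelic.tsv",
                    "genes.gff3", "variants.vcf", "genome.fa", "terms.tsv")
      produced <<- produced
      paths <- list(counts = out("counts.tsv"), sheet = out("samples.tsv"),
                    allelic = out("allelic.tsv"), gff = out("genes.gff3"),
                    vcf = out("variants.vcf"), genome = out("genome.fa"),
                    terms = out("terms.tsv"))
    } else {
      paths <- list(counts = config$counts_path, sheet = config$sheet_path,
                    allelic = config$allelic_path, gff = config$gff_path,
                    vcf = config$vcf_path, genome = config$genome_path,
                    terms = config$term_map_path)
    }
    se <- read_counts(paths$counts, paths$sheet)
    allelic <- read_allelic_counts(paths$allelic)
    cd <- SummarizedExperiment::colData(se)
    tissues <- unique(cd$tissue)
    sf <- size_factors(se)
    res$size_factors <<- sf
    report$n_genes <<- nrow(se)

    cols_of <- function(role, tissue)
      rownames(cd)[cd$role == role & cd$tissue == tissue]
    active <- list()
    de <- list()
    if ("de" %in% stages) {
      for (ts in tissues) {
        act <- unique(c(
          call_active_genes(se, cols_of("maternal", ts),
                            config$active_min_reads, config$active_min_reps),
          call_active_genes(se, cols_of("paternal", ts),
                            config$active_min_reads, config$active_min_reps),
          call_active_genes(se, cols_of("hybrid", ts),
                            config$active_min_reads, config$active_min_reps)))
        active[[ts]] <- act
        sub <- se[act, ]
        contrasts <- list(
          hybrid_vs_mother = c("maternal", "hybrid"),
          hybrid_vs_father = c("paternal", "hybrid"),
          mother_vs_father = c("maternal", "paternal"))
        for (cn in names(contrasts)) {
          ga <- cols_of(contrasts[[cn]][1], ts)
          gb <- cols_of(contrasts[[cn]][2], ts)
          tab <- nb_wald_test(sub, ga, gb, sf = sf,
                              fdr_cutoff = config$deg_fdr,
                              lfc_cutoff = config$deg_lfc,
                              pseudocount_lfc = config$pseudocount_reporting)
          de[[ts]][[cn]] <- tab
          emit(tab, sprintf("de_%s_%s.tsv", ts, cn))
        }
        report[[paste0("n_active_", ts)]] <<- length(act)
      }
      res$active <<- active
      res$de <<- de
      r2 <- sample_correlation(se, sf = sf,
                               min_reads = config$active_min_reads)
      emit(data.frame(sample = rownames(r2), r2, check.names = FALSE),
           "sample_correlation.tsv")
      res$sample_correlation <<- r2
    }
    if ("dominance" %in% stages) {
      if (!"de" %in% stages)
        config_error("dominance stage requires the de stage")
      summaries <- NULL
      dom <- list()
      for (ts in tissues) {
        cl <- classify_dghp(se, de[[ts]]$hybrid_vs_mother,
                            de[[ts]]$hybrid_vs_father, ts, sf = sf,
                            membership = if (config$dghp_union) "union"
                                         else "intersection")
        dom[[ts]] <- cl
        emit(cl$records, sprintf("dominance_%s.tsv", ts))
        summaries <- rbind(summaries,
                           data.frame(tissue = ts, cl$summary))
        report[[paste0("n_dghp_", ts)]] <<- nrow(cl$records)
      }
      emit(summaries, "dominance_summary.tsv")
      res$dominance <<- dom
    }
    ase <- list()
    if ("ase" %in% stages) {
      for (ts in tissues) {
        tab <- ase_test(allelic, ts, min_depth = config$ase_min_depth,
                        padj_cutoff = config$ase_padj)
        ase[[ts]] <- tab
        emit(tab, sprintf("ase_%s.tsv", ts))
        report[[paste0("n_aseg_", ts)]] <<- sum(tab$is_aseg)
      }
      res$ase <<- ase
    }
    if ("patterns" %in% stages && length(tissues) >= 2) {
      if (!"ase" %in% stages)
        config_error("patterns stage requires the ase stage")
      pat <- classify_aseg_patterns(ase[[tissues[1]]], ase[[tissues[2]]])
      emit(pat$patterns, "aseg_patterns.tsv")
      emit(pat$counts, "aseg_pattern_counts.tsv")
      res$patterns <<- pat
    }
    if ("overlap" %in% stages) {
      if (!all(c("de", "ase") %in% stages))
        config_error("overlap stage requires the de and ase stages")
      rows <- NULL
      ov <- list()
      for (ts in tissues) {
        parental <- de[[ts]]$mother_vs_father
        degs <- parental$gene_id[parental$is_deg]
        asegs <- ase[[ts]]$gene_id[ase[[ts]]$is_aseg]
        universe <- active[[ts]]
        degs <- intersect(degs, universe)
        asegs <- intersect(asegs, universe)
        if (length(asegs) == 0) next
        t <- overlap_resampling_test(degs, asegs, universe,
                                     n_sim = config$n_sim,
                                     seed = config$seed + 10L)
        ov[[ts]] <- t
        rows <- rbind(rows, data.frame(
          tissue = ts, n_parental_degs = length(degs),
          n_asegs = length(asegs), observed_overlap = t$observed_overlap,
          percent_asegs_deg = 100 * t$observed_overlap / length(asegs),
          null_mean = t$null_mean, null_sd = t$null_sd, t_stat = t$t_stat,
          p_t = t$p_t, p_empirical = t$p_empirical))
      }
      if (!is.null(rows)) emit(rows, "overlap.tsv")
      res$overlap <<- ov
    }
    if ("enrich" %in% stages && !is.null(paths$terms)) {
      if (!"ase" %in% stages)
        config_error("enrich stage requires the ase stage")
      terms <- read_tsv(paths$terms)
      for (ts in tissues) {
        asegs <- ase[[ts]]$gene_id[ase[[ts]]$is_aseg]
        universe <- unique(ase[[ts]]$gene_id)
        if (length(asegs) == 0) next
        enr <- hypergeom_enrichment(asegs, terms, universe)
        emit(enr, sprintf("enrichment_%s.tsv", ts))
        res$enrichment[[ts]] <<- enr
      }
    }
    if ("varannot" %in% stages &&
        !is.null(paths$gff) && !is.null(paths$vcf) &&
        !is.null(paths$genome)) {
      models <- read_gff(paths$gff)
      variants <- read_variants(paths$vcf)
      genome <- read_genome(paths$genome)
      verdicts <- filter_variants(variants,
                                  rank_sum_sign_fix = config$rank_sum_sign_fix)
      emit(verdicts, "variant_filters.tsv")
      passing <- variants[verdicts$passed, , drop = FALSE]
      effects <- classify_variant_effects(passing, models, genome)
      emit(effects, "variant_effects.tsv")
      res$effects <<- effects
      if ("ase" %in% stages) {
        asegs <- unique(unlist(lapply(ase, function(x)
          x$gene_id[x$is_aseg])))
        if (length(asegs) > 0) {
          dens <- variant_density_comparison(
            effects, asegs, models$genes$gene_id, n_sim = config$n_sim,
            seed = config$seed + 11L)
          emit(dens, "variant_density.tsv")
          res$variant_density <<- dens
        }
      }
      report$n_variants_pass <<- sum(verdicts$passed)
    }
  }
  ok <- tryCatch({ run(); TRUE },
                 error = function(e) { manifest("incomplete"); stop(e) })
  report$wall_time_sec <- round(as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")), 2)
  report$package_version <- as.character(utils::packageVersion("heteroseq"))
  write_tsv(data.frame(key = names(report),
                       value = vapply(report, function(x)
                         paste(format(x), collapse = ","), character(1))),
            out("run_report.tsv"))
  manifest("complete")
  invisible(c(res, list(outdir = config$outdir, files = sort(produced))))
}
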