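# Synthetic data with known truth: NB counts for a hybrid/parent trio in one
# or more tissues, gene-level allelic counts, and a small genome with gene
# models and variants whose consequence categories hold by construction.
# The truth table is written separately and is never read by the analysis
# pipeline itself.

HP_CATEGORIES <- c("over_dominance", "dominance", "partial_dominance",
                   "additive")
IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Counts are negative binomial
#' with `Var = mu + dispersion * mu^2` (dispersion shared across genes).
#' Genes planted in an inheritance-mode category get parent and hybrid means
#' whose noiseless Hp lies strictly inside that category's interval, at
#' distance at least 0.1 from both endpoints, and with hybrid-vs-at-least-one
#' -parent fold change of at least `2^lfc_magnitude`. Non-DE genes have equal
#' means in all three accessions.
#'
#' @param seed integer master seed; a fixed seed gives bit-identical output.
#' @param n_genes number of genes.
#' @param n_replicates biological replicates per accession and tissue.
#' @param tissues character vector of tissue labels.
#' @param mean_log_expression log-scale location of baseline gene means.
#' @param mean_log_sd log-scale spread of baseline gene means.
#' @param dispersion NB dispersion alpha (> 0), `Var = mu + alpha mu^2`.
#' @param frac_de fraction of genes planted as differentially expressed.
#' @param lfc_magnitude planted minimum |log2 fold change| of the hybrid
#'   against at least one parent; must lie in (0, 2] (the planted negative
#'   over-dominance tail requires hybrid means near zero otherwise).
#' @param hp_category_fractions named weights over the four Hp categories
#'   used to assign planted DE genes; raw values must not sum above 1.
#' @param frac_ase fraction of genes planted with allelic imbalance.
#' @param ase_fold planted allelic fold (> 1); the biased-allele read
#'   fraction is `ase_fold / (1 + ase_fold)`.
#' @param frac_ase_shift fraction of planted ASE genes whose bias direction
#'   flips in tissues after the first (the "shift direction" pattern).
#' @param allelic_depth_mean mean total allelic depth per gene and replicate
#'   (Poisson).
#' @param n_variants_per_gene mean number of variants planted per gene
#'   (Poisson).
#' @param impact_category_probs named probabilities over
#'   HIGH/MODERATE/LOW/MODIFIER; must sum to 1.
#' @param aseg_variant_multiplier variant-rate multiplier for genes planted
#'   as ASE (used to emulate variant enrichment on ASEGs).
#' @param depth_factor_sd log-scale spread of per-sample depth factors.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_replicates = 3L,
                       tissues = c("leaf", "panicle"),
                       mean_log_expression = log(200),
                       mean_log_sd = 1,
                       dispersion = 0.05,
                       frac_de = 0.3,
                       lfc_magnitude = 2,
                       hp_category_fractions = c(over_dominance = 0.70,
                                                 dominance = 0.10,
                                                 partial_dominance = 0.12,
                                                 additive = 0.08),
                       frac_ase = 0.1,
                       ase_fold = 4,
                       frac_ase_shift = 0.05,
                       allelic_depth_mean = 100,
                       n_variants_per_gene = 3,
                       impact_category_probs = c(HIGH = 0.15, MODERATE = 0.35,
                                                 LOW = 0.25, MODIFIER = 0.25),
                       aseg_variant_multiplier = 1,
                       depth_factor_sd = 0.1) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates), tissues = tissues,
              mean_log_expression = mean_log_expression,
              mean_log_sd = mean_log_sd, dispersion = dispersion,
              frac_de = frac_de, lfc_magnitude = lfc_magnitude,
              hp_category_fractions = hp_category_fractions,
              frac_ase = frac_ase, ase_fold = ase_fold,
              frac_ase_shift = frac_ase_shift,
              allelic_depth_mean = allelic_depth_mean,
              n_variants_per_gene = n_variants_per_gene,
              impact_category_probs = impact_category_probs,
              aseg_variant_multiplier = aseg_variant_multiplier,
              depth_factor_sd = depth_factor_sd)
  frac_in_01 <- function(x) is.numeric(x) && all(x >= 0) && all(x <= 1)
  if (is.na(cfg$seed) || abs(seed) >= 2^31 - 10)
    config_error("seed must be a 32-bit integer")
  if (cfg$n_genes < 1) config_error("n_genes must be positive")
  if (cfg$n_replicates < 1) config_error("n_replicates must be positive")
  if (length(cfg$tissues) < 1 || anyDuplicated(cfg$tissues))
    config_error("tissues must be distinct labels")
  if (!(cfg$dispersion > 0)) config_error("dispersion must be > 0")
  if (!frac_in_01(c(cfg$frac_de, cfg$frac_ase, cfg$frac_ase_shift)))
    config_error("fractions must lie in [0, 1]")
  if (!(cfg$lfc_magnitude > 0 && cfg$lfc_magnitude <= 2))
    config_error("lfc_magnitude must lie in (0, 2]")
  fr <- cfg$hp_category_fractions
  if (!all(names(fr) %in% HP_CATEGORIES) || is.null(names(fr)))
    config_error("hp_category_fractions must be named by: ",
                 paste(HP_CATEGORIES, collapse = ", "))
  if (!frac_in_01(fr)) config_error("hp_category_fractions must lie in [0,1]")
  if (sum(fr) > 1 + 1e-9)
    config_error("hp_category_fractions sum above 1")
  ip <- cfg$impact_category_probs
  if (!setequal(names(ip), IMPACT_LEVELS))
    config_error("impact_category_probs must be named HIGH/MODERATE/LOW/MODIFIER")
  if (abs(sum(ip) - 1) > 1e-9)
    config_error("impact_category_probs must sum to 1")
  if (!(cfg$ase_fold > 1)) config_error("ase_fold must be > 1")
  if (cfg$allelic_depth_mean < 0)
    config_error("allelic_depth_mean must be >= 0")
  if (cfg$aseg_variant_multiplier <= 0)
    config_error("aseg_variant_multiplier must be > 0")
  structure(cfg, class = "sim_config")
}

# Planted Hp bands: strictly inside the category interval, margin 0.1 from
# every finite endpoint; the unbounded over-dominance tails are truncated at
# |Hp| = 3 (positive side) / -1.55 (negative side keeps the hybrid mean
# positive under the planted parent separation).
hp_band <- function(category, positive) {
  switch(category,
         additive = c(-0.1, 0.1),
         partial_dominance = if (positive) c(0.3, 0.7) else c(-0.7, -0.3),
         dominance = if (positive) c(0.9, 1.1) else c(-1.1, -0.9),
         over_dominance = if (positive) c(1.3, 3) else c(-1.55, -1.3),
         config_error("unknown Hp category: ", category))
}

#' Simulate a hybrid/parent trio counts matrix with planted truth
#'
#' Draws NB counts for the maternal parent, paternal parent and hybrid in
#' each tissue. DE genes are planted in an Hp category (see [sim_config]);
#' the noiseless means recorded in the truth table reproduce the planted
#' category exactly under [hp_statistic] + [classify_dominance].
#'
#' @param config a [sim_config].
#' @return list with `counts` (a SummarizedExperiment, assay `"counts"`,
#'   column data sample sheet) and `truth` (data.frame keyed by gene and
#'   tissue, with planted DE status, Hp category and value, the noiseless
#'   normalized means `mu_maternal`/`mu_paternal`/`mu_hybrid`, and the
#'   planted allelic-bias direction).
#' @export
simulate_trio_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  nr <- config$n_replicates
  tissues <- config$tissues
  gene_id <- sprintf("g%05d", seq_len(ng))

  base <- rlnorm(ng, config$mean_log_expression, config$mean_log_sd)
  # exact planted fractions (rounded counts) so truth-table tallies are
  # reproducible for any seed
  de <- rep(FALSE, ng)
  de[sample.int(ng, round(config$frac_de * ng))] <- TRUE
  fr <- config$hp_category_fractions
  fr <- fr[fr > 0]
  if (length(fr) == 0) de[] <- FALSE
  category <- rep(NA_character_, ng)
  h <- rep(NA_real_, ng)
  if (any(de)) {
    category[de] <- sample(names(fr), sum(de), replace = TRUE,
                           prob = fr / sum(fr))
    p_pos <- ifelse(category[de] == "over_dominance", 0.75, 0.5)
    positive <- runif(sum(de)) < p_pos
    band <- t(mapply(hp_band, category[de], positive))
    h[de] <- runif(sum(de), band[, 1], band[, 2])
  }
  # parent separation keeping the hybrid at least 2^lfc-fold from one
  # parent across every planted band: 2F for h >= 0 (hybrid at or above
  # mid-parent), F^2 for -1 <= h < 0 (the fold conditions f1/p_low >= F and
  # p_high/f1 >= F meet exactly at h = -(F-1)/(F+1) when r = F^2), and 4
  # for the deep negative tail (where f1 >= 0 forces a small separation)
  Fc <- 2^config$lfc_magnitude
  r_sep <- ifelse(!de, 1,
           ifelse(h >= 0, 2 * Fc,
           ifelse(h >= -1, max(Fc^2, 2), 4)))
  hi_is_maternal <- runif(ng) < 0.5

  # planted allelic-bias direction (independent of DE planting)
  is_ase <- rep(FALSE, ng)
  is_ase[sample.int(ng, round(config$frac_ase * ng))] <- TRUE
  dir1 <- rep("none", ng)
  dir1[is_ase] <- sample(c("maternal", "paternal"), sum(is_ase),
                         replace = TRUE)
  flip <- function(d) ifelse(d == "maternal", "paternal",
                             ifelse(d == "paternal", "maternal", d))

  accs <- c(maternal = "mother", paternal = "father", hybrid = "hybrid")
  samples <- expand.grid(replicate = seq_len(nr), tissue = tissues,
                         role = names(accs), stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)[, c("role", "tissue",
                                                     "replicate")]
  samples$accession <- accs[samples$role]
  samples$sample_id <- sprintf("%s_%s_rep%d", samples$accession,
                               samples$tissue, samples$replicate)
  depth <- exp(rnorm(nrow(samples), 0, config$depth_factor_sd))

  truth <- NULL
  counts <- matrix(0L, ng, nrow(samples),
                   dimnames = list(gene_id, samples$sample_id))
  for (ti in seq_along(tissues)) {
    tf <- if (ti == 1) rep(1, ng) else rlnorm(ng, 0, 0.3)
    mu_lo <- base * tf
    mu_hi <- mu_lo * r_sep
    a_eff <- (mu_hi - mu_lo) / 2
    mid <- (mu_hi + mu_lo) / 2
    mu_hybrid <- ifelse(de, mid + h * a_eff, mu_lo)
    mu_mat <- ifelse(hi_is_maternal, mu_hi, mu_lo)
    mu_pat <- ifelse(hi_is_maternal, mu_lo, mu_hi)
    dir_t <- if (ti == 1) dir1 else {
      shift <- is_ase & runif(ng) < config$frac_ase_shift
      ifelse(shift, flip(dir1), dir1)
    }
    truth <- rbind(truth, data.frame(
      gene_id = gene_id, tissue = tissues[ti], de_status = de,
      hp_category = category, hp_planted = h,
      mu_maternal = mu_mat, mu_paternal = mu_pat, mu_hybrid = mu_hybrid,
      ase_direction = dir_t, stringsAsFactors = FALSE))
    for (j in which(samples$tissue == tissues[ti])) {
      mu <- switch(samples$role[j], maternal = mu_mat, paternal = mu_pat,
                   hybrid = mu_hybrid)
      counts[, j] <- rnbinom(ng, mu = mu * depth[j],
                             size = 1 / config$dispersion)
    }
  }
  storage.mode(counts) <- "integer"
  sheet <- samples[, c("sample_id", "accession", "role", "tissue",
                       "replicate")]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sheet, row.names = sheet$sample_id))
  list(counts = se, truth = truth)
}

#' Simulate gene-level allelic counts in the hybrid
#'
#' Per gene, tissue and replicate the total allelic depth is Poisson with
#' mean `allelic_depth_mean` and the maternal count is binomial with success
#' probability `ase_fold/(1+ase_fold)` for maternally biased genes,
#' `1/(1+ase_fold)` for paternally biased genes and 0.5 otherwise, following
#' the planted direction in `truth`.
#'
#' @param config a [sim_config].
#' @param truth truth table from [simulate_trio_counts].
#' @return data.frame with columns `gene_id`, `tissue`, `replicate`,
#'   `maternal_count`, `paternal_count`. If `allelic_depth_mean` is zero all
#'   counts are zero and the result carries attribute
#'   `uninformative = TRUE` with a warning.
#' @export
simulate_allelic_counts <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (!(config$ase_fold > 1)) config_error("ase_fold must be > 1")
  need <- c("gene_id", "tissue", "ase_direction")
  if (!all(need %in% names(truth)))
    schema_error("truth table missing column(s): ",
                 paste(setdiff(need, names(truth)), collapse = ", "))
  set.seed(config$seed + 1L)
  nr <- config$n_replicates
  f <- config$ase_fold
  pi_of <- c(maternal = f / (1 + f), paternal = 1 / (1 + f), none = 0.5)
  out <- truth[rep(seq_len(nrow(truth)), each = nr),
               c("gene_id", "tissue", "ase_direction")]
  out$replicate <- rep(seq_len(nr), nrow(truth))
  total <- rpois(nrow(out), config$allelic_depth_mean)
  out$maternal_count <- rbinom(nrow(out), total,
                               pi_of[out$ase_direction])
  out$paternal_count <- total - out$maternal_count
  out$ase_direction <- NULL
  rownames(out) <- NULL
  out <- out[, c("gene_id", "tissue", "replicate", "maternal_count",
                 "paternal_count")]
  if (config$allelic_depth_mean == 0) {
    warning("allelic_depth_mean is 0: all allelic counts are zero ",
            "(uninformative)")
    attr(out, "uninformative") <- TRUE
  }
  out
}

# ---- genome / variants -----------------------------------------------------

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

aa_of <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# one random gene structure in transcript-local coordinates (always 5'->3')
random_gene_structure <- function() {
  utr5 <- sample(30:80, 1)
  utr3 <- sample(30:80, 1)
  n_codons <- sample(60:180, 1)
  body <- sample(setdiff(names(Biostrings::GENETIC_CODE), STOPS),
                 n_codons - 2, replace = TRUE)
  cds_seq <- paste0("ATG", paste(body, collapse = ""), "TAA")
  cds_len <- 3L * n_codons
  has_intron <- runif(1) < 0.5
  if (has_intron) {
    ilen <- sample(120:400, 1)
    b <- sample(10:(cds_len - 10), 1)     # CDS bases before the intron
    intron <- paste0("GT", rand_dna(ilen - 4), "AG")
    seq_local <- paste0(rand_dna(utr5), substr(cds_seq, 1, b), intron,
                        substr(cds_seq, b + 1, cds_len), rand_dna(utr3))
    cds_local <- data.frame(
      start = c(utr5 + 1, utr5 + b + ilen + 1),
      end = c(utr5 + b, utr5 + b + ilen + (cds_len - b)),
      phase = c(0L, (3L - b %% 3L) %% 3L))
    exon_local <- data.frame(start = c(1, utr5 + b + ilen + 1),
                             end = c(utr5 + b, utr5 + cds_len + ilen + utr3))
    intron_local <- c(utr5 + b + 1, utr5 + b + ilen)
  } else {
    seq_local <- paste0(rand_dna(utr5), cds_seq, rand_dna(utr3))
    cds_local <- data.frame(start = utr5 + 1, end = utr5 + cds_len,
                            phase = 0L)
    exon_local <- data.frame(start = 1, end = utr5 + cds_len + utr3)
    intron_local <- NULL
  }
  list(seq = seq_local, len = nchar(seq_local), cds = cds_local,
       exons = exon_local, intron = intron_local, cds_seq = cds_seq,
       n_codons = n_codons, utr5 = utr5)
}

# map a transcript-local position to a genomic position
local_to_genomic <- function(pos, seg_start, seg_len, strand) {
  if (strand == "+") seg_start - 1L + pos else seg_start - 1L + (seg_len - pos + 1L)
}

# search the coding sequence for a single-base substitution realizing the
# requested effect; returns list(local_pos, ref, alt) in transcript coords
# (local_pos relative to CDS start = 1) or NULL
find_cds_snv <- function(cds_seq, effect) {
  n_codons <- nchar(cds_seq) / 3
  for (ci in sample(2:(n_codons - 1))) {
    codon <- substr(cds_seq, 3 * ci - 2, 3 * ci)
    aa0 <- aa_of(codon)
    pos_order <- if (effect == "synonymous") 3L else sample(1:3)
    for (p in pos_order) {
      ref <- substr(codon, p, p)
      for (alt in sample(setdiff(BASES, ref))) {
        new <- codon
        substr(new, p, p) <- alt
        aa1 <- aa_of(new)
        hit <- switch(effect,
                      synonymous = aa1 == aa0 && aa0 != "*",
                      missense = aa1 != aa0 && aa0 != "*" && aa1 != "*",
                      stop_gained = aa1 == "*" && aa0 != "*")
        if (hit) return(list(cds_pos = 3L * (ci - 1L) + p, ref = ref,
                             alt = alt))
      }
    }
  }
  NULL
}

#' Simulate a genome, gene models and variants with planted impact classes
#'
#' Emits non-overlapping gene models (each with a single CDS, optionally
#' split by one intron, on either strand) on synthetic chromosomes named
#' `chrSim1..k`, plus variants constructed so that each planted impact
#' category is realized by construction: a stop-creating or frameshifting
#' or splice-site change for HIGH, a codon-changing CDS SNP for MODERATE, a
#' synonymous CDS SNP for LOW, and an intronic/upstream/intergenic SNP for
#' MODIFIER. Genes are separated by gaps above 10 kb so "intergenic"
#' (beyond the 5 kb upstream/downstream windows) is unambiguous.
#'
#' @param config a [sim_config].
#' @param truth optional truth table from [simulate_trio_counts]; when given,
#'   genes planted with allelic bias receive `aseg_variant_multiplier` times
#'   the baseline variant rate.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `models`
#'   ([gene_models]), `variants` (data.frame in [read_variants] layout) and
#'   `variant_truth` (data.frame: variant id, gene, planted consequence and
#'   impact).
#' @export
simulate_genome_annotation <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 1) config_error("n_genes must be positive")
  set.seed(config$seed + 2L)
  ng <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(ng))
  genes_per_chrom <- 100L
  ase_genes <- character(0)
  if (!is.null(truth))
    ase_genes <- unique(truth$gene_id[truth$ase_direction != "none"])

  genes <- exons <- cds <- NULL
  seqs <- list()          # per-chromosome character segments
  chrom_of <- character(ng)
  structures <- vector("list", ng)
  seg_start <- integer(ng)
  gap_before <- integer(ng)

  cur_chrom <- 0L
  cur_pos <- 0L
  for (i in seq_len(ng)) {
    if ((i - 1L) %% genes_per_chrom == 0L) {
      cur_chrom <- cur_chrom + 1L
      seqs[[cur_chrom]] <- character(0)
      cur_pos <- 0L
    }
    chrom <- sprintf("chrSim%d", cur_chrom)
    gap <- sample(10500:12500, 1)
    st <- random_gene_structure()
    strand <- sample(c("+", "-"), 1)
    seg <- if (strand == "+") st$seq else revcomp_str(st$seq)
    seqs[[cur_chrom]] <- c(seqs[[cur_chrom]], rand_dna(gap), seg)
    s0 <- cur_pos + gap + 1L
    cur_pos <- cur_pos + gap + st$len
    chrom_of[i] <- chrom
    structures[[i]] <- c(st, list(strand = strand))
    seg_start[i] <- s0
    gap_before[i] <- gap

    map_iv <- function(iv) {
      if (strand == "+") {
        data.frame(start = s0 - 1L + iv$start, end = s0 - 1L + iv$end)
      } else {
        data.frame(start = s0 - 1L + (st$len - iv$end + 1L),
                   end = s0 - 1L + (st$len - iv$start + 1L))
      }
    }
    ex_g <- map_iv(st$exons)
    cd_g <- map_iv(st$cds)
    cd_g$phase <- st$cds$phase
    ex_g <- ex_g[order(ex_g$start), , drop = FALSE]
    cd_g <- cd_g[order(cd_g$start), , drop = FALSE]
    genes <- rbind(genes, data.frame(
      gene_id = gene_id[i], chrom = chrom, strand = strand,
      start = min(ex_g$start), end = max(ex_g$end),
      stringsAsFactors = FALSE))
    exons <- rbind(exons, data.frame(gene_id = gene_id[i], chrom = chrom,
                                     start = ex_g$start, end = ex_g$end,
                                     stringsAsFactors = FALSE))
    cds <- rbind(cds, data.frame(gene_id = gene_id[i], chrom = chrom,
                                 start = cd_g$start, end = cd_g$end,
                                 phase = cd_g$phase,
                                 stringsAsFactors = FALSE))
  }
  # tail gap so downstream windows stay on-chromosome
  for (k in seq_along(seqs)) seqs[[k]] <- c(seqs[[k]], rand_dna(7000))
  genome <- Biostrings::DNAStringSet(
    setNames(vapply(seqs, paste, character(1), collapse = ""),
             sprintf("chrSim%d", seq_along(seqs))))
  models <- gene_models(genes, exons, cds)

  # ---- plant variants ----
  chrom_seq <- setNames(as.character(genome), names(genome))
  used <- new.env(parent = emptyenv())
  is_free <- function(chrom, p1, p2) {
    key <- paste0(chrom, ":", p1:p2)
    if (any(vapply(key, function(k) !is.null(used[[k]]), logical(1))))
      return(FALSE)
    for (k in key) used[[k]] <- TRUE
    TRUE
  }
  vrows <- list()
  trows <- list()
  mult <- ifelse(gene_id %in% ase_genes, config$aseg_variant_multiplier, 1)
  n_var <- rpois(ng, config$n_variants_per_gene * mult)
  for (i in seq_len(ng)) {
    if (n_var[i] == 0) next
    st <- structures[[i]]
    strand <- st$strand
    chrom <- chrom_of[i]
    s0 <- seg_start[i]
    cats <- sample(names(config$impact_category_probs), n_var[i],
                   replace = TRUE, prob = config$impact_category_probs)
    for (cat in cats) {
      v <- plant_variant(cat, st, strand, chrom, s0, chrom_seq[[chrom]],
                         gene_id[i], gap_before[i], is_free)
      if (is.null(v)) next
      vrows[[length(vrows) + 1L]] <- v$rec
      trows[[length(trows) + 1L]] <- v$truth
    }
  }
  variants <- do.call(rbind, vrows)
  variant_truth <- do.call(rbind, trows)
  if (!is.null(variants)) {
    ord <- order(variants$chrom, variants$pos)
    variants <- variants[ord, , drop = FALSE]
    variant_truth <- variant_truth[ord, , drop = FALSE]
    variants$id <- sprintf("var%06d", seq_len(nrow(variants)))
    variant_truth$variant_id <- variants$id
    rownames(variants) <- rownames(variant_truth) <- NULL
  }
  list(genome = genome, models = models, variants = variants,
       variant_truth = variant_truth)
}

# realize one variant of the requested impact category for one gene;
# returns list(rec = VCF-layout row, truth = truth row) or NULL
plant_variant <- function(cat, st, strand, chrom, s0, chr_seq, gene_id,
                          gap_before, is_free) {
  L <- st$len
  cds_start_local <- st$utr5 + 1L
  # local transcript position -> genomic, accounting for strand
  g_of <- function(p) local_to_genomic(p, s0, L, strand)
  # transcript-local CDS position (1..cds_len) -> local construct position,
  # skipping the intron if present
  local_of_cds <- function(cp) {
    b <- if (!is.null(st$intron)) st$cds$end[1] - st$cds$start[1] + 1L else Inf
    if (cp <= b) st$utr5 + cp
    else st$utr5 + (st$intron[2] - st$intron[1] + 1L) + cp
  }
  snv_rec <- function(gpos, ref_t, alt_t, consequence, impact) {
    ref_g <- if (strand == "+") ref_t else comp_base(ref_t)
    alt_g <- if (strand == "+") alt_t else comp_base(alt_t)
    if (!is_free(chrom, gpos, gpos)) return(NULL)
    stopifnot(substr(chr_seq, gpos, gpos) == ref_g)
    list(rec = data.frame(chrom = chrom, pos = gpos, id = ".", ref = ref_g,
                          alt = alt_g, qual = 100, QD = 25, SOR = 1, FS = 3,
                          MQ = 60, MQRankSum = 0, ReadPosRankSum = 0,
                          stringsAsFactors = FALSE),
         truth = data.frame(variant_id = ".", chrom = chrom, pos = gpos,
                            gene_id = gene_id, consequence = consequence,
                            impact = impact, stringsAsFactors = FALSE))
  }
  intergenic_snv <- function(consequence, gpos) {
    ref <- substr(chr_seq, gpos, gpos)
    alt <- sample(setdiff(BASES, ref), 1)
    if (!is_free(chrom, gpos, gpos)) return(NULL)
    gid <- if (consequence %in% c("upstream", "intron")) gene_id
           else NA_character_
    list(rec = data.frame(chrom = chrom, pos = gpos, id = ".", ref = ref,
                          alt = alt, qual = 100, QD = 25, SOR = 1, FS = 3,
                          MQ = 60, MQRankSum = 0, ReadPosRankSum = 0,
                          stringsAsFactors = FALSE),
         truth = data.frame(variant_id = ".", chrom = chrom, pos = gpos,
                            gene_id = gid, consequence = consequence,
                            impact = "MODIFIER", stringsAsFactors = FALSE))
  }

  if (cat == "MODIFIER") {
    choices <- c("upstream", "intergenic")
    if (!is.null(st$intron)) choices <- c(choices, "intron")
    sub <- sample(choices, 1)
    if (sub == "intron") {
      lp <- sample((st$intron[1] + 3L):(st$intron[2] - 3L), 1)
      return(intergenic_snv("intron", g_of(lp)))
    }
    if (sub == "upstream") {
      u <- sample(200:3000, 1)   # within the 5 kb window, 5' of the TSS
      gpos <- if (strand == "+") s0 - u else s0 + L - 1L + u
      if (gpos < 1 || gpos > nchar(chr_seq)) return(NULL)
      return(intergenic_snv("upstream", gpos))
    }
    # intergenic: in the gap 5' of this gene's segment, > 5 kb from both
    # flanking genes (gaps are always > 10.2 kb)
    gpos <- s0 - 5001L - sample(0:200, 1)
    if (gpos < 1) return(NULL)
    return(intergenic_snv("intergenic", gpos))
  }

  if (cat == "LOW") {
    hit <- find_cds_snv(st$cds_seq, "synonymous")
    if (is.null(hit)) return(NULL)
    return(snv_rec(g_of(local_of_cds(hit$cds_pos)), hit$ref, hit$alt,
                   "synonymous", "LOW"))
  }
  if (cat == "MODERATE") {
    hit <- find_cds_snv(st$cds_seq, "missense")
    if (is.null(hit)) return(NULL)
    return(snv_rec(g_of(local_of_cds(hit$cds_pos)), hit$ref, hit$alt,
                   "missense", "MODERATE"))
  }
  # HIGH
  subtypes <- c("stop_gained", "frameshift")
  if (!is.null(st$intron)) subtypes <- c(subtypes, "splice_donor")
  sub <- sample(subtypes, 1)
  if (sub == "splice_donor") {
    lp <- st$intron[1]                       # first intron base, 5' side
    ref_t <- substr(st$seq, lp, lp)
    alt_t <- sample(setdiff(BASES, ref_t), 1)
    return(snv_rec(g_of(lp), ref_t, alt_t, "splice_donor", "HIGH"))
  }
  if (sub == "stop_gained") {
    hit <- find_cds_snv(st$cds_seq, "stop_gained")
    if (!is.null(hit))
      return(snv_rec(g_of(local_of_cds(hit$cds_pos)), hit$ref, hit$alt,
                     "stop_gained", "HIGH"))
    # fall through to a frameshift
  }
  # frameshift: delete 1 or 2 bases wholly inside one CDS interval (genomic
  # coordinates, left-anchored VCF representation)
  nd <- sample(1:2, 1)
  cd_g <- st$cds
  # genomic CDS intervals for this gene
  ivs <- if (strand == "+") {
    data.frame(start = s0 - 1L + cd_g$start, end = s0 - 1L + cd_g$end)
  } else {
    data.frame(start = s0 - 1L + (L - cd_g$end + 1L),
               end = s0 - 1L + (L - cd_g$start + 1L))
  }
  iv <- ivs[sample(nrow(ivs), 1), ]
  if (iv$end - iv$start < nd + 8) iv <- ivs[which.max(ivs$end - ivs$start), ]
  anchor <- sample((iv$start + 3L):(iv$end - 3L - nd), 1)
  if (!is_free(chrom, anchor, anchor + nd)) return(NULL)
  ref <- substr(chr_seq, anchor, anchor + nd)
  alt <- substr(chr_seq, anchor, anchor)
  list(rec = data.frame(chrom = chrom, pos = anchor, id = ".", ref = ref,
                        alt = alt, qual = 100, QD = 25, SOR = 1, FS = 3,
                        MQ = 60, MQRankSum = 0, ReadPosRankSum = 0,
                        stringsAsFactors = FALSE),
       truth = data.frame(variant_id = ".", chrom = chrom, pos = anchor,
                          gene_id = gene_id, consequence = "frameshift",
                          impact = "HIGH", stringsAsFactors = FALSE))
}

#' Simulate a random gene-to-term annotation map
#'
#' Plumbing so the over-representation stage is exercisable end to end: each
#' gene is annotated to one to three of `n_terms` terms uniformly at random
#' (no planted enrichment).
#'
#' @param config a [sim_config].
#' @param gene_ids character vector of gene identifiers.
#' @param n_terms number of terms.
#' @return data.frame with columns `term_id`, `gene_id`.
#' @export
simulate_term_map <- function(config, gene_ids, n_terms = 50L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  terms <- sprintf("T%04d", seq_len(n_terms))
  k <- sample(1:3, length(gene_ids), replace = TRUE)
  df <- data.frame(
    term_id = unlist(lapply(k, function(n) sample(terms, n))),
    gene_id = rep(gene_ids, k), stringsAsFactors = FALSE)
  df[order(df$term_id, df$gene_id), , drop = FALSE]
}
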