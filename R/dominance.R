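# Inheritance-mode classification of hybrid expression: additive and
# dominance effects and the dominance-to-additivity ratio Hp, computed from
# mean normalized counts of the two parents (p1, p2) and the hybrid (f1).

DOMINANCE_CATEGORIES <- c("over_dominance", "dominance", "partial_dominance",
                          "additive", "degenerate")

#' Additive effect, dominance effect and the Hp statistic
#'
#' `a = |p1 - p2| / 2` is the additive effect, `d = f1 - (p1 + p2)/2` the
#' dominance effect (deviation of the hybrid from the mid-parent value) and
#' `Hp = d / a` their ratio. When the parents are equal (`a = 0`), Hp is
#' `+Inf`/`-Inf` with the sign of `d`, and 0 when `d` is also 0.
#'
#' @param p1,p2,f1 mean normalized counts of the maternal parent, paternal
#'   parent and hybrid (non-negative, vectorized).
#' @return data.frame with columns `a_effect`, `d_effect`, `hp`.
#' @export
hp_statistic <- function(p1, p2, f1) {
  if (any(c(p1, p2, f1) < 0, na.rm = TRUE))
    schema_error("p1, p2, f1 must be non-negative")
  a <- abs(p1 - p2) / 2
  d <- f1 - (p1 + p2) / 2
  hp <- ifelse(a > 0, d / a,
               ifelse(d > 0, Inf, ifelse(d < 0, -Inf, 0)))
  data.frame(a_effect = a, d_effect = d, hp = hp)
}

#' Classify inheritance mode from Hp
#'
#' The half-open intervals partition the extended real line exactly:
#' additive `(-0.2, 0.2]`, partial dominance `(-0.8, -0.2]` or `(0.2, 0.8]`,
#' dominance `(-1.2, -0.8]` or `(0.8, 1.2]`, over-dominance `<= -1.2` or
#' `> 1.2` (the boundary asymmetry is deliberate and kept as stated);
#' `+Inf`/`-Inf` fall in over-dominance.
#'
#' @param hp numeric vector (may contain `Inf`/`-Inf`); NaN is an error.
#' @return character vector of categories.
#' @export
classify_dominance <- function(hp) {
  if (any(is.nan(hp))) schema_error("Hp is NaN")
  if (any(is.na(hp))) schema_error("Hp is NA")
  ifelse(hp <= -1.2, "over_dominance",
  ifelse(hp <= -0.8, "dominance",
  ifelse(hp <= -0.2, "partial_dominance",
  ifelse(hp <= 0.2, "additive",
  ifelse(hp <= 0.8, "partial_dominance",
  ifelse(hp <= 1.2, "dominance", "over_dominance"))))))
}

#' Classify the hybrid-vs-parent DEGs of a tissue by inheritance mode
#'
#' The classified set (DGhp) contains the genes that are DEGs in at least
#' one hybrid-vs-parent contrast (`union`, the default) or in both
#' (`intersection`). For each such gene, p1/p2/f1 are the replicate means of
#' size-factor-normalized counts in the tissue, and the Hp category follows
#' [hp_statistic] and [classify_dominance]. Genes with all three means zero
#' are reported as `degenerate` and excluded from the category percentages.
#'
#' @param counts SummarizedExperiment with assay `"counts"` and column data
#'   columns `role` (maternal/paternal/hybrid) and `tissue`.
#' @param de_hybrid_mother,de_hybrid_father DE tables from [nb_wald_test]
#'   for the hybrid-vs-mother and hybrid-vs-father contrasts of this tissue.
#' @param tissue tissue label to classify.
#' @param sf size factors (computed on the full matrix when `NULL`).
#' @param membership `"union"` or `"intersection"` of the two DEG sets.
#' @return list with `records` (data.frame: gene_id, tissue, p1, p2, f1,
#'   a_effect, d_effect, hp, category) and `summary` (per-category counts
#'   and percentages over the non-degenerate records).
#' @export
classify_dghp <- function(counts, de_hybrid_mother, de_hybrid_father, tissue,
                          sf = NULL, membership = c("union", "intersection")) {
  membership <- match.arg(membership)
  if (!methods::is(counts, "SummarizedExperiment"))
    schema_error("counts must be a SummarizedExperiment with sample metadata")
  cd <- SummarizedExperiment::colData(counts)
  if (!all(c("role", "tissue") %in% names(cd)))
    schema_error("column data must carry 'role' and 'tissue'")
  degs_m <- de_hybrid_mother$gene_id[de_hybrid_mother$is_deg]
  degs_f <- de_hybrid_father$gene_id[de_hybrid_father$is_deg]
  dghp <- if (membership == "union") union(degs_m, degs_f)
          else intersect(degs_m, degs_f)
  if (length(dghp) == 0) {
    warning("empty DGhp set for tissue ", tissue)
    rec <- data.frame(gene_id = character(0), tissue = character(0),
                      p1 = numeric(0), p2 = numeric(0), f1 = numeric(0),
                      a_effect = numeric(0), d_effect = numeric(0),
                      hp = numeric(0), category = character(0))
    return(list(records = rec, summary = dominance_summary(rec)))
  }
  q <- normalized_counts(counts, sf)
  grp <- function(role) {
    cols <- rownames(cd)[cd$role == role & cd$tissue == tissue]
    if (length(cols) == 0) schema_error("no ", role, " samples in tissue ",
                                        tissue)
    rowMeans(q[dghp, cols, drop = FALSE])
  }
  p1 <- grp("maternal"); p2 <- grp("paternal"); f1 <- grp("hybrid")
  st <- hp_statistic(p1, p2, f1)
  degenerate <- p1 == 0 & p2 == 0 & f1 == 0
  category <- ifelse(degenerate, "degenerate", classify_dominance(st$hp))
  rec <- data.frame(gene_id = dghp, tissue = tissue, p1 = p1, p2 = p2,
                    f1 = f1, a_effect = st$a_effect, d_effect = st$d_effect,
                    hp = st$hp, category = category,
                    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  list(records = rec, summary = dominance_summary(rec))
}

dominance_summary <- function(records) {
  cats <- setdiff(DOMINANCE_CATEGORIES, "degenerate")
  n <- vapply(cats, function(k) sum(records$category == k), integer(1))
  data.frame(category = cats, n = n,
             percent = if (sum(n) > 0) 100 * n / sum(n) else rep(NA_real_, length(n)),
             stringsAsFactors = FALSE)
}
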