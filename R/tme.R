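# Tumor-microenvironment profiling: hierarchical clustering of patients on
# immune gene-set expression with bootstrap stability, and single/combined
# marker-gene strata (GZMA, FOXP3, PD-L1/CD274) feeding the survival
# module.

GENE_ALIASES <- c(PDL1 = "CD274", `PD-L1` = "CD274", FoxP3 = "FOXP3")

resolve_gene <- function(gene, expression) {
  mapped <- unname(GENE_ALIASES[gene])
  gene <- ifelse(is.na(mapped), gene, mapped)
  missing <- setdiff(gene, rownames(expression))
  if (length(missing)) {
    rlang::abort(paste0("gene(s) absent from expression matrix: ",
                        paste(missing, collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  gene
}

#' Illustrative immune gene sets
#'
#' Small marker-gene lists for the four immune populations used in the
#' microenvironment analysis.  These are deliberately minimal
#' illustrations for synthetic data; analyses of real cohorts should
#' supply curated lists.
#'
#' @return Named list of character vectors (`CD8_T`, `CD4_T`, `Treg`,
#'   `MDSC`).
#' @export
default_gene_sets <- function() {
  list(
    CD8_T = c("CD8A", "CD8B", "GZMA", "GZMB", "PRF1"),
    CD4_T = c("CD4", "IL7R", "CD40LG"),
    Treg = c("FOXP3", "IL2RA", "CTLA4"),
    MDSC = c("ITGAM", "CD33", "ARG1")
  )
}

# Cluster patients into 2 groups on a patients x genes submatrix with
# average-linkage agglomeration.  Euclidean distance is the default: the
# HIGH/LOW contrast is a difference in overall expression level, which
# correlation distance is blind to (it compares profiles up to shift and
# scale).  Correlation distance remains available for pattern-driven
# clustering; it falls back to Euclidean when a patient has zero variance
# across the (resampled) genes.
cut2_clusters <- function(sub, distance = "euclidean") {
  d <- if (distance == "correlation") {
    vars <- apply(sub, 1, stats::var)
    if (ncol(sub) >= 2 && all(vars > 0)) {
      stats::as.dist(1 - stats::cor(t(sub)))
    } else {
      stats::dist(sub)
    }
  } else {
    stats::dist(sub)
  }
  stats::cutree(stats::hclust(d, method = "average"), k = 2)
}

#' Cluster patients on an immune gene set with bootstrap stability
#'
#' Hierarchically clusters patients (average linkage) over the gene-set
#' expression submatrix, cuts the dendrogram into two clusters, and labels
#' the cluster with the higher mean expression `HIGH`.  Stability is the
#' fraction of `n_boot` gene-resampled re-clusterings in which the patient
#' lands in the same cluster as the majority of its original cluster
#' mates.  Genes (not patients) are resampled so that the clustered
#' objects stay fixed.
#'
#' The default distance is Euclidean, because infiltration contrasts are
#' differences in overall expression level; `"correlation"` distance
#' (shift/scale-invariant, pattern-driven) is available as an alternative.
#'
#' @param expression Gene-by-patient matrix.
#' @param genes Character vector (length >= 2) of gene-set members.
#' @param n_boot Number of bootstrap resamples; default 100.
#' @param seed Integer seed; fixed seed gives identical assignments.
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @return Tibble `patient`, `cluster` (factor LOW/HIGH), `stability`
#'   (in [0, 1]).
#' @export
cluster_gene_set <- function(expression, genes, n_boot = 100L, seed = 1L,
                             distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  genes <- resolve_gene(genes, expression)
  if (length(genes) < 2) {
    rlang::abort("gene set must contain at least 2 genes for the bootstrap",
                 class = "neosurv_validation_error")
  }
  if (ncol(expression) < 4) {
    rlang::abort("clustering requires at least 4 patients",
                 class = "neosurv_validation_error")
  }
  sub <- t(expression[genes, , drop = FALSE])  # patients x genes
  base <- cut2_clusters(sub, distance)
  means <- tapply(rowMeans(sub), base, mean)
  high_id <- as.integer(names(means)[which.max(means)])
  cluster <- factor(unname(ifelse(base == high_id, "HIGH", "LOW")),
                    levels = c("LOW", "HIGH"))

  same_as_majority <- matrix(FALSE, nrow = nrow(sub), ncol = n_boot)
  with_local_seed(component_seed(seed, "tme_bootstrap"), {
    for (b in seq_len(n_boot)) {
      gsel <- sample.int(length(genes), replace = TRUE)
      boot <- cut2_clusters(sub[, gsel, drop = FALSE], distance)
      for (i in seq_len(nrow(sub))) {
        mates <- setdiff(which(base == base[i]), i)
        if (!length(mates)) {
          same_as_majority[i, b] <- TRUE  # singleton cluster: trivially stable
        } else {
          same_as_majority[i, b] <-
            mean(boot[mates] == boot[i]) >= 0.5
        }
      }
    }
  })
  tibble::tibble(patient = rownames(sub), cluster = cluster,
                 stability = rowMeans(same_as_majority))
}

#' Stratify patients by a single gene's expression
#'
#' Delegates to [dichotomize()] on the gene's expression vector.  PD-L1
#' aliases (`PDL1`, `PD-L1`) resolve to `CD274`; `FoxP3` to `FOXP3`.
#'
#' @param expression Gene-by-patient matrix.
#' @param gene Gene symbol.
#' @param mode `"mean"` (default) or `"quartile"`.
#' @return Tibble `patient`, `score`, `group` as from [dichotomize()].
#' @export
gene_stratum <- function(expression, gene, mode = c("mean", "quartile")) {
  mode <- match.arg(mode)
  gene <- resolve_gene(gene, expression)
  scores <- tibble::tibble(patient = colnames(expression),
                           score = expression[gene, ])
  dichotomize(scores, mode = mode)
}

#' Stratify by one gene within an expression subset of another
#'
#' Restricts the cohort to the patients falling on `secondary_side` of the
#' secondary gene's mean split (or the whole cohort for
#' `secondary_side = "all"`), then stratifies the restricted patients by
#' the primary gene.
#'
#' @param expression Gene-by-patient matrix.
#' @param primary_gene Gene defining the reported strata (e.g. `GZMA`).
#' @param secondary_gene Restricting gene (e.g. `FOXP3` or `PDL1`).
#' @param secondary_side `"low"` (default), `"high"`, or `"all"`.
#' @param mode Split mode for the primary gene.
#' @return Tibble `patient`, `score`, `group` restricted to the secondary
#'   subset; attribute `n_restricted` carries the subset size.
#' @export
combined_stratum <- function(expression, primary_gene, secondary_gene,
                             secondary_side = c("low", "high", "all"),
                             mode = c("mean", "quartile")) {
  secondary_side <- match.arg(secondary_side)
  mode <- match.arg(mode)
  if (secondary_side == "all") {
    out <- gene_stratum(expression, primary_gene, mode = mode)
    attr(out, "n_restricted") <- ncol(expression)
    return(out)
  }
  sec <- gene_stratum(expression, secondary_gene, mode = "mean")
  keep <- sec$patient[!is.na(sec$group) & sec$group == secondary_side]
  if (!length(keep)) {
    rlang::abort("secondary restriction leaves no patients",
                 class = "neosurv_validation_error")
  }
  out <- gene_stratum(expression[, keep, drop = FALSE], primary_gene,
                      mode = mode)
  attr(out, "n_restricted") <- length(keep)
  out
}

#' Compare neoantigen counts between infiltration clusters
#'
#' Two-sided Wilcoxon rank-sum comparison of a per-patient neoantigen
#' count between the HIGH and LOW infiltration clusters.
#'
#' @param assignments Output of [cluster_gene_set()].
#' @param patient_summaries Output of `call_neoantigens()$summary`.
#' @param count_col Which count to compare; default `"n_candidates"`.
#' @return List: `high` and `low` count vectors, `p_value`, `statistic`.
#' @export
neoantigens_vs_infiltration <- function(assignments, patient_summaries,
                                        count_col = "n_candidates") {
  merged <- dplyr::inner_join(assignments, patient_summaries,
                              by = "patient")
  if (!nrow(merged)) {
    rlang::abort("no shared patients between assignments and summaries",
                 class = "neosurv_validation_error")
  }
  high <- merged[[count_col]][merged$cluster == "HIGH"]
  low <- merged[[count_col]][merged$cluster == "LOW"]
  wt <- suppressWarnings(stats::wilcox.test(high, low,
                                            alternative = "two.sided"))
  list(high = high, low = low, p_value = wt$p.value,
       statistic = unname(wt$statistic))
}
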