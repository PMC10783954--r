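# Pipeline orchestration: per-pathway scoring, the full score table with
# q-values and tied-average ranks, and the subsample reproducibility check.

#' Pipeline configuration
#'
#' Collects the tunable parameters of a run. `k` is the method's only
#' substantive parameter: the number of nearest neighbours, trading local
#' against global sample structure (default 25). Permutation count defaults
#' to 10 000; pathways with fewer than `min_pathway_genes` genes observed in
#' the matrix are skipped.
#'
#' @param k neighbours per sample in the kNN graph (>= 2).
#' @param n_permutations permutations for the empirical p-value; 0 disables
#'   significance testing.
#' @param min_pathway_genes minimum number of pathway genes that must be
#'   present in the expression matrix.
#' @param resolution modularity resolution (1 = classic modularity).
#' @param seed master seed; per-pathway seeds are derived from it and the
#'   pathway name, so results never depend on pathway order.
#' @param normalization `"zscore"` (per-gene standardization) or `"none"`.
#' @param neighbor_mode kNN search mode, see [build_knn()].
#' @param condition_column optional name of a confounder column in the
#'   phenotype table; scores are then conditional on it.
#' @return a list of class `mipath_config`.
#' @export
run_config <- function(k = 25L, n_permutations = 10000L,
                       min_pathway_genes = 5L, resolution = 1,
                       seed = 1L, normalization = c("zscore", "none"),
                       neighbor_mode = c("auto", "exact", "approximate"),
                       condition_column = NULL) {
  normalization <- match.arg(normalization)
  neighbor_mode <- match.arg(neighbor_mode)
  if (!is_count(k, min = 2L)) stop("k must be an integer >= 2")
  if (!is_count(n_permutations, min = 0L)) stop("n_permutations must be >= 0")
  if (!is_count(min_pathway_genes, min = 1L)) stop("min_pathway_genes must be >= 1")
  structure(
    list(k = as.integer(k), n_permutations = as.integer(n_permutations),
         min_pathway_genes = as.integer(min_pathway_genes),
         resolution = as.numeric(resolution), seed = as.integer(seed),
         normalization = normalization, neighbor_mode = neighbor_mode,
         condition_column = condition_column),
    class = "mipath_config"
  )
}

#' Standardize genes
#'
#' Centers every gene (column) to mean 0 and scales it to unit population
#' standard deviation, so that Euclidean distances weigh genes equally.
#' Zero-variance genes carry no neighbourhood information and are set to
#' all-zeros with a warning. `method = "none"` is the identity.
#'
#' @param expr expression matrix, samples x genes (dense or sparse; the
#'   result is dense for `"zscore"`).
#' @param method `"zscore"` or `"none"`.
#' @return the normalized matrix with the input's dimnames.
#' @export
normalize_genes <- function(expr, method = c("zscore", "none")) {
  method <- match.arg(method)
  if (method == "none") return(expr)
  x <- as.matrix(expr)
  mu <- colMeans(x)
  n <- nrow(x)
  sdev <- sqrt(colMeans(x^2) - mu^2) # population SD
  zero_var <- sdev < .Machine$double.eps^0.5
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance gene(s) set to all-zeros")
    sdev[zero_var] <- 1
    mu[zero_var] <- 0
  }
  x <- sweep(sweep(x, 2L, mu, "-"), 2L, sdev, "/")
  x[, zero_var] <- 0
  x
}

#' Score one pathway against a phenotype
#'
#' Runs the full per-pathway pipeline: restrict the expression matrix to the
#' pathway's genes (exact identifier intersection), standardize them, build
#' the SNN-weighted kNN graph in that subspace, detect sample modules by
#' directed-modularity optimisation, and score the module partition against
#' the phenotype with (conditional) adjusted mutual information. When
#' `config$n_permutations > 0`, an empirical p-value is computed by
#' permuting the phenotype labels with the module partition held fixed.
#'
#' @param expr expression matrix, samples x genes.
#' @param genes character vector of the pathway's gene identifiers.
#' @param phenotype phenotype partition over the samples (vector, in row
#'   order of `expr`).
#' @param config a [run_config()].
#' @param confounder optional confounder partition; scores become
#'   conditional on it and permutations are stratified.
#' @param seed seed for this pathway; defaults to `config$seed`.
#' @return a list with `status` (`"ok"` or `"skipped"`), `n_genes_used`,
#'   and, when scored, `n_modules`, `modules` (the module labels), the score
#'   list `score`, and `p_value` (`NA` when permutations are disabled).
#' @export
score_pathway <- function(expr, genes, phenotype, config = run_config(),
                          confounder = NULL, seed = config$seed) {
  present <- intersect(genes, colnames(expr))
  n_used <- length(present)
  if (n_used < config$min_pathway_genes) {
    return(list(status = "skipped",
                reason = sprintf("%d of %d pathway genes in matrix (need >= %d)",
                                 n_used, length(genes), config$min_pathway_genes),
                n_genes_used = n_used))
  }
  if (length(phenotype) != nrow(expr)) {
    stop("phenotype must have one label per expression sample")
  }
  sub <- as.matrix(expr[, present, drop = FALSE])
  sub <- suppressWarnings(normalize_genes(sub, config$normalization))
  graph <- build_snn_graph(sub, k = config$k, mode = config$neighbor_mode,
                           seed = seed)
  part <- detect_modules(graph, resolution = config$resolution, seed = seed)
  score <- if (is.null(confounder)) {
    ami(part$membership, phenotype)
  } else {
    conditional_ami(part$membership, phenotype, confounder)
  }
  p_value <- NA_real_
  if (config$n_permutations > 0L) {
    p_value <- permutation_test(part$membership, phenotype,
                                n_perm = config$n_permutations,
                                seed = seed,
                                conditional_on = confounder)$p_value
  }
  list(status = "ok", n_genes_used = n_used, n_modules = part$n_modules,
       modules = part$membership, score = score, p_value = p_value)
}

#' Score every pathway in a collection
#'
#' Applies [score_pathway()] to each pathway, then annotates the retained
#' pathways with Storey q-values and tied-average ranks on the AMI score
#' (rank 1 = highest AMI; equal scores share the average of the ranks they
#' occupy). Each pathway's seed is derived from the master seed and the
#' pathway's name, so the table is identical for any pathway ordering.
#'
#' @param expr expression matrix, samples x genes.
#' @param pathways named list of gene-identifier vectors (see [read_gmt()]).
#' @param pheno phenotype data.frame with a `sample_id` column, aligned to
#'   `expr` (see [align_inputs()]).
#' @param phenotype_col name of the phenotype column in `pheno`.
#' @param config a [run_config()]; `config$condition_column`, when set,
#'   names the confounder column in `pheno`.
#' @param verbose emit per-pathway progress messages.
#' @return a data.frame of class `mipath_scores` with columns `pathway`,
#'   `n_genes_used`, `n_modules`, `ami`, `p_value`, `q_value`, `rank`,
#'   `status`; skipped pathways carry `NA` scores and no rank.
#' @export
score_all <- function(expr, pathways, pheno, phenotype_col,
                      config = run_config(), verbose = FALSE) {
  validate_expression(expr)
  if (length(pathways) == 0L) stop("empty pathway collection")
  if (!phenotype_col %in% colnames(pheno)) {
    stop("phenotype column '", phenotype_col, "' not found")
  }
  if (nrow(pheno) != nrow(expr) ||
      !all(pheno$sample_id == rownames(expr))) {
    stop("inputs are not aligned; call align_inputs() first")
  }
  phenotype <- pheno[[phenotype_col]]
  confounder <- NULL
  if (!is.null(config$condition_column)) {
    if (!config$condition_column %in% colnames(pheno)) {
      stop("condition column '", config$condition_column, "' not found")
    }
    confounder <- pheno[[config$condition_column]]
  }
  rows <- vector("list", length(pathways))
  for (i in seq_along(pathways)) {
    name <- names(pathways)[i]
    seed_i <- derive_seed(config$seed, name)
    res <- score_pathway(expr, pathways[[i]], phenotype, config,
                         confounder = confounder, seed = seed_i)
    if (res$status == "skipped") {
      if (verbose) message(sprintf("[%d/%d] %s: skipped (%s)",
                                   i, length(pathways), name, res$reason))
      rows[[i]] <- data.frame(pathway = name, n_genes_used = res$n_genes_used,
                              n_modules = NA_integer_, ami = NA_real_,
                              p_value = NA_real_, status = "skipped")
    } else {
      if (verbose) message(sprintf("[%d/%d] %s: %d modules, AMI %.4f",
                                   i, length(pathways), name,
                                   res$n_modules, res$score$ami))
      rows[[i]] <- data.frame(pathway = name, n_genes_used = res$n_genes_used,
                              n_modules = res$n_modules, ami = res$score$ami,
                              p_value = res$p_value, status = "ok")
    }
  }
  tab <- do.call(rbind, rows)
  ok <- tab$status == "ok"
  if (!any(ok)) stop("no pathway passed the gene-count threshold")
  tab$q_value <- NA_real_
  if (config$n_permutations > 0L) {
    tab$q_value[ok] <- qvalues(tab$p_value[ok])
  }
  tab$rank <- NA_real_
  tab$rank[ok] <- rank(-tab$ami[ok], ties.method = "average")
  tab <- tab[, c("pathway", "n_genes_used", "n_modules", "ami",
                 "p_value", "q_value", "rank", "status")]
  class(tab) <- c("mipath_scores", "data.frame")
  tab
}

#' Write a pathway score table as TSV
#'
#' @param scores a table from [score_all()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Subsample reproducibility of pathway scores
#'
#' Draws `n_repeats` uniform sample subsets of size `fraction * n`, scores
#' every pathway on each subset, and reports the Pearson correlation between
#' the AMI score vectors of every pair of repeats. High mean correlation
#' indicates that the method captures a stable signal rather than sampling
#' noise.
#'
#' @param expr,pathways,pheno,phenotype_col,config as in [score_all()].
#' @param fraction subsample fraction in (0, 1].
#' @param n_repeats number of subsamples (>= 2).
#' @return a list with `mean_correlation`, the `correlations` matrix
#'   (`n_repeats` x `n_repeats`), and `scores` (pathways x repeats matrix of
#'   AMI values).
#' @export
subsample_reproducibility <- function(expr, pathways, pheno, phenotype_col,
                                      config = run_config(), fraction = 0.2,
                                      n_repeats = 10L) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (!is_count(n_repeats, min = 2L)) stop("n_repeats must be >= 2")
  n <- nrow(expr)
  size <- floor(fraction * n)
  if (size < config$k + 1L) {
    stop(sprintf("subsample size %d is too small for k = %d", size, config$k))
  }
  score_mat <- NULL
  for (r in seq_len(n_repeats)) {
    seed_r <- derive_seed(config$seed, paste0("subsample_", r))
    idx <- with_seed(seed_r, sort(sample.int(n, size)))
    cfg_r <- config
    cfg_r$seed <- seed_r
    tab <- score_all(expr[idx, , drop = FALSE],
                     pathways,
                     pheno[idx, , drop = FALSE],
                     phenotype_col, cfg_r)
    if (is.null(score_mat)) {
      score_mat <- matrix(NA_real_, nrow = nrow(tab), ncol = n_repeats,
                          dimnames = list(tab$pathway, NULL))
    }
    score_mat[tab$pathway, r] <- tab$ami
  }
  keep <- stats::complete.cases(score_mat)
  cors <- stats::cor(score_mat[keep, , drop = FALSE], method = "pearson")
  pairs <- cors[upper.tri(cors)]
  list(mean_correlation = mean(pairs), correlations = cors,
       scores = score_mat)
}
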