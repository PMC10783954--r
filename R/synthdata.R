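# Seeded synthetic expression datasets with a planted pathway-phenotype
# association, size-matched decoy pathways, optional single-cell-like dropout,
# and an optional confounder. Gaussian generative model: the pipeline consumes
# normalized values, so effect sizes are interpretable in SD units.

#' Synthetic dataset specification
#'
#' Describes a dataset with `n_groups` phenotype groups, one planted
#' "signal" pathway whose genes shift their means between groups by
#' `effect_size` standard deviations, `n_noise_genes` pure-noise genes, and
#' `n_decoy_pathways` decoy pathways of the signal pathway's size drawn from
#' the noise genes (without replacement within a pathway, with replacement
#' across pathways). Dropout zeroes each entry independently with
#' probability `dropout_rate`, mimicking transcript-capture failure in
#' single-cell assays.
#'
#' @param n_samples total number of samples.
#' @param n_groups number of phenotype groups.
#' @param group_sizes per-group sample counts; defaults to a near-even
#'   split and must sum to `n_samples`.
#' @param n_signal_genes genes in the planted pathway.
#' @param n_noise_genes background genes.
#' @param effect_size between-group mean shift on signal genes, in units of
#'   the within-group SD (>= 0; 0 plants no signal).
#' @param dropout_rate probability in [0, 1) that any entry is zeroed.
#' @param confounder_groups optional number of confounder levels.
#' @param n_decoy_pathways number of decoy pathways.
#' @param seed integer seed; generation is fully reproducible.
#' @return a list of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 1000L, n_groups = 4L, group_sizes = NULL,
                       n_signal_genes = 20L, n_noise_genes = 500L,
                       effect_size = 2, dropout_rate = 0,
                       confounder_groups = NULL, n_decoy_pathways = 50L,
                       seed = 1L) {
  if (is.null(group_sizes)) {
    base <- n_samples %/% n_groups
    group_sizes <- rep(base, n_groups)
    extra <- n_samples - sum(group_sizes)
    if (extra > 0L) group_sizes[seq_len(extra)] <- group_sizes[seq_len(extra)] + 1L
  }
  if (sum(group_sizes) != n_samples) stop("group_sizes must sum to n_samples")
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (n_signal_genes < 1L || n_noise_genes < n_signal_genes) {
    stop("need at least as many noise genes as signal genes (decoy size match)")
  }
  structure(
    list(n_samples = as.integer(n_samples), n_groups = as.integer(n_groups),
         group_sizes = as.integer(group_sizes),
         n_signal_genes = as.integer(n_signal_genes),
         n_noise_genes = as.integer(n_noise_genes),
         effect_size = as.numeric(effect_size),
         dropout_rate = as.numeric(dropout_rate),
         confounder_groups = confounder_groups,
         n_decoy_pathways = as.integer(n_decoy_pathways),
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

synth_pathways <- function(spec, signal_genes, noise_genes) {
  pathways <- list(signal = signal_genes)
  for (d in seq_len(spec$n_decoy_pathways)) {
    pathways[[sprintf("decoy_%03d", d)]] <-
      sample(noise_genes, spec$n_signal_genes, replace = FALSE)
  }
  pathways
}

apply_dropout <- function(x, rate) {
  if (rate > 0) x[matrix(stats::runif(length(x)) < rate, nrow(x))] <- 0
  x
}

#' Generate a synthetic dataset with a planted pathway signal
#'
#' Signal genes are drawn as `Normal(effect_size * mu[gene, group], 1)`
#' where the per-gene, per-group base means `mu` are standard normal draws;
#' noise genes are `Normal(0, 1)`. The phenotype column holds the group
#' labels. When `confounder_groups` is set, an additional confounder column
#' with balanced levels assigned independently of everything else is
#' included (a no-confounding control; see [generate_confounded()] for an
#' actual confounder).
#'
#' @param spec a [synth_spec()].
#' @return a list with `expr` (samples x genes matrix), `pheno` (data.frame
#'   with `sample_id`, `phenotype`, and optionally `confounder`),
#'   `pathways` (named list; `"signal"` first, then decoys), and `spec`.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    group <- rep(seq_len(spec$n_groups), spec$group_sizes)
    sample_ids <- sprintf("s%04d", seq_len(n))
    signal_genes <- sprintf("SIG%03d", seq_len(spec$n_signal_genes))
    noise_genes <- sprintf("NSE%04d", seq_len(spec$n_noise_genes))

    mu <- matrix(stats::rnorm(spec$n_signal_genes * spec$n_groups),
                 nrow = spec$n_signal_genes)
    signal <- spec$effect_size * t(mu[, group, drop = FALSE]) +
      matrix(stats::rnorm(n * spec$n_signal_genes), nrow = n)
    noise <- matrix(stats::rnorm(n * spec$n_noise_genes), nrow = n)
    expr <- cbind(signal, noise)
    dimnames(expr) <- list(sample_ids, c(signal_genes, noise_genes))
    expr <- apply_dropout(expr, spec$dropout_rate)

    pheno <- data.frame(sample_id = sample_ids,
                        phenotype = paste0("g", group))
    if (!is.null(spec$confounder_groups)) {
      z <- sample(rep_len(seq_len(spec$confounder_groups), n))
      pheno$confounder <- paste0("z", z)
    }
    pathways <- synth_pathways(spec, signal_genes, noise_genes)
    list(expr = expr, pheno = pheno, pathways = pathways, spec = spec)
  })
}

#' Generate a synthetic dataset with a confounded pathway
#'
#' Models the confounding scenario: a latent discrete variable Z drives both
#' the genes of a "confounded" pathway (mean shifts by Z only) and the
#' phenotype Y (with probability `agreement`, a sample's phenotype is a
#' deterministic function of its Z level; otherwise it is uniform), while
#' the pathway is conditionally independent of Y given Z. The unconditional
#' pathway-phenotype AMI is therefore spurious and the conditional AMI given
#' Z is near zero. Setting `agreement = 0` makes Z independent of Y, a
#' negative control under which conditional and unconditional scores agree.
#'
#' @param spec a [synth_spec()] with `confounder_groups` set; `effect_size`
#'   here is the Z-driven shift on the confounded pathway's genes.
#' @param agreement probability in [0, 1] that a sample's phenotype follows
#'   its confounder level.
#' @return as [generate()], with the planted pathway named `"confounded"`
#'   and the phenotype table carrying `phenotype` and `confounder` columns.
#' @export
generate_confounded <- function(spec, agreement = 0.9) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(spec$confounder_groups)) {
    stop("spec$confounder_groups must be set for generate_confounded()")
  }
  if (agreement < 0 || agreement > 1) stop("agreement must be in [0, 1]")
  with_seed(spec$seed, {
    n <- spec$n_samples
    nz <- spec$confounder_groups
    z <- rep_len(seq_len(nz), n)
    follows <- stats::runif(n) < agreement
    y <- ifelse(follows,
                (z - 1L) %% spec$n_groups + 1L,
                sample.int(spec$n_groups, n, replace = TRUE))
    sample_ids <- sprintf("s%04d", seq_len(n))
    conf_genes <- sprintf("CNF%03d", seq_len(spec$n_signal_genes))
    noise_genes <- sprintf("NSE%04d", seq_len(spec$n_noise_genes))

    mu <- matrix(stats::rnorm(spec$n_signal_genes * nz),
                 nrow = spec$n_signal_genes)
    confd <- spec$effect_size * t(mu[, z, drop = FALSE]) +
      matrix(stats::rnorm(n * spec$n_signal_genes), nrow = n)
    noise <- matrix(stats::rnorm(n * spec$n_noise_genes), nrow = n)
    expr <- cbind(confd, noise)
    dimnames(expr) <- list(sample_ids, c(conf_genes, noise_genes))
    expr <- apply_dropout(expr, spec$dropout_rate)

    pheno <- data.frame(sample_id = sample_ids,
                        phenotype = paste0("g", y),
                        confounder = paste0("z", z))
    pathways <- synth_pathways(spec, conf_genes, noise_genes)
    names(pathways)[1L] <- "confounded"
    list(expr = expr, pheno = pheno, pathways = pathways, spec = spec)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes `expr.csv`, `phenotype.tsv`, and `pathways.gmt` into a directory,
#' in the formats [read_expression()], [read_phenotype()], and [read_gmt()]
#' read back.
#'
#' @param dataset a list from [generate()] or [generate_confounded()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(dataset$expr, file.path(dir, "expr.csv"))
  utils::write.table(dataset$pheno, file.path(dir, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(dataset$pathways, file.path(dir, "pathways.gmt"))
  invisible(dir)
}
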