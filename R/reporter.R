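#' Raw reporter Z score of a gene set
#'
#' Aggregates member gene p-values through the standard normal quantile:
#' \deqn{Z = \frac{1}{\sqrt{k}} \sum_{g} \Phi^{-1}(1 - p_g).}
#' Smaller p-values give larger Z.
#'
#' @param pvals numeric vector of p-values in (0, 1); clipped to
#'   `[clip, 1 - clip]` before the quantile transform.
#' @param clip clipping bound away from 0 and 1 (default 1e-10).
#' @return scalar Z.
#' @export
reporter_z <- function(pvals, clip = 1e-10) {
  if (!length(pvals)) stop("empty gene set")
  p <- pmin(pmax(pvals, clip), 1 - clip)
  sum(stats::qnorm(1 - p)) / sqrt(length(p))
}

#' Metabolite-to-gene sets from a model's GPR rules
#'
#' For every metabolite, the set of genes appearing in the GPR of any
#' reaction that produces or consumes it. Sets with at least `min_size`
#' genes are retained (default 1).
#'
#' @param model a `metabolic_model`.
#' @param min_size minimum set size kept.
#' @return named list: metabolite id -> character vector of gene ids.
#' @export
metabolite_gene_sets <- function(model, min_size = 1L) {
  sets <- lapply(model$metabolites$id, function(m) character(0))
  names(sets) <- model$metabolites$id
  for (r in model$reactions) {
    if (is.na(r$gpr)) next
    genes <- gpr_genes(parse_gpr(r$gpr))
    for (met in names(r$stoich)[r$stoich != 0])
      sets[[met]] <- union(sets[[met]], genes)
  }
  sets[vapply(sets, length, 0L) >= min_size]
}

#' Reporter-metabolite enrichment with a permutation background
#'
#' Scores each metabolite's gene set in four directional classes:
#' \describe{
#' \item{non-directional}{two-sided gene p-values as given;}
#' \item{distinct-directional}{one-tailed p-values oriented by the fold
#'   change sign (`p/2` for upregulated genes, `1 - p/2` for
#'   downregulated), so coherent up-regulation drives Z positive and
#'   coherent down-regulation negative;}
#' \item{mixed-directional up / down}{the subset of member genes with the
#'   respective sign, scored with their one-tailed p-values (`p/2`)
#'   against a background drawn from same-sign genes only.}
#' }
#' The background corrects for set size: for each class and set size k,
#' `n_perm` random gene sets of size k are drawn (without replacement)
#' from the class's gene population, giving `mu_k`, `sigma_k` and a
#' permutation p-value; corrected Z is `(Z - mu_k)/sigma_k`. Adjusted
#' p-values are Benjamini-Hochberg within each class. The significance
#' flag requires the adjusted p below `alpha` and additionally caps the
#' number of flagged metabolites per class at the top `top_frac` of all
#' tested metabolites.
#'
#' @param stats data.frame with columns `gene_id`, `pvalue` and `log2fc`.
#' @param sets named list of gene sets (metabolite id -> gene ids), e.g.
#'   from [metabolite_gene_sets()].
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutation draws.
#' @param clip p-value clipping bound (default 1e-10).
#' @param alpha adjusted-p significance threshold per class (default 0.01).
#' @param top_frac cap on flagged metabolites per class, as a fraction of
#'   the tested list (default 0.05).
#' @return object of class `reporter_result`: data.frame with one row per
#'   (metabolite, class): `metabolite`, `class`, `k`, `z_raw`, `z_corrected`,
#'   `pvalue`, `padj`, `significant`; attribute `dropped` lists metabolites
#'   with no scored genes.
#' @export
reporter_analysis <- function(stats, sets, n_perm = 10000L, seed = 1L,
                              clip = 1e-10, alpha = 0.01, top_frac = 0.05) {
  stopifnot(all(c("gene_id", "pvalue", "log2fc") %in% names(stats)),
            n_perm >= 100L)
  if (anyDuplicated(stats$gene_id)) stop("duplicate gene ids in stats")
  p <- pmin(pmax(stats$pvalue, clip), 1 - clip)
  up <- stats$log2fc > 0
  score_pop <- list(
    "non-directional" = stats::setNames(stats::qnorm(1 - p), stats$gene_id),
    "distinct-directional" = stats::setNames(
      stats::qnorm(1 - pmin(pmax(ifelse(up, p / 2, 1 - p / 2), clip), 1 - clip)),
      stats$gene_id),
    "mixed-directional up" = stats::setNames(
      stats::qnorm(1 - pmin(pmax(p[up] / 2, clip), 1 - clip)), stats$gene_id[up]),
    "mixed-directional down" = stats::setNames(
      stats::qnorm(1 - pmin(pmax(p[!up] / 2, clip), 1 - clip)), stats$gene_id[!up]))

  # drop metabolites with no member gene in the stats at all
  measured <- stats$gene_id
  has_any <- vapply(sets, function(s) any(s %in% measured), logical(1))
  dropped <- names(sets)[!has_any]
  sets <- sets[has_any]
  n_tested <- length(sets)
  cap <- floor(top_frac * n_tested)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  res <- list()
  for (cls in names(score_pop)) {
    pop <- score_pop[[cls]]
    ks <- vapply(sets, function(s) sum(s %in% names(pop)), 0L)
    null_by_k <- list()
    for (k in sort(unique(ks[ks >= 1L & ks <= length(pop)]))) {
      draws <- vapply(seq_len(n_perm),
                      function(i) sum(pop[sample.int(length(pop), k)]) / sqrt(k),
                      0)
      null_by_k[[as.character(k)]] <- draws
    }
    for (m in names(sets)) {
      k <- ks[[m]]
      if (k < 1L || k > length(pop)) {
        res[[length(res) + 1L]] <- data.frame(
          metabolite = m, class = cls, k = k, z_raw = NA_real_,
          z_corrected = NA_real_, pvalue = NA_real_, padj = NA_real_,
          significant = FALSE, stringsAsFactors = FALSE)
        next
      }
      members <- intersect(sets[[m]], names(pop))
      z <- sum(pop[members]) / sqrt(k)
      draws <- null_by_k[[as.character(k)]]
      mu <- mean(draws); sdev <- stats::sd(draws)
      zc <- if (sdev > 0) (z - mu) / sdev else 0
      pv <- (1 + sum(draws >= z)) / (n_perm + 1)
      res[[length(res) + 1L]] <- data.frame(
        metabolite = m, class = cls, k = k, z_raw = z, z_corrected = zc,
        pvalue = pv, padj = NA_real_, significant = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)

  for (cls in unique(out$class)) {
    idx <- which(out$class == cls & !is.na(out$pvalue))
    if (!length(idx)) next
    out$padj[idx] <- stats::p.adjust(out$pvalue[idx], method = "BH")
    sig <- idx[out$padj[idx] < alpha]
    if (length(sig) > cap) {
      ord <- sig[order(out$pvalue[sig], -out$z_corrected[sig])]
      sig <- ord[seq_len(cap)]
    }
    out$significant[sig] <- TRUE
  }
  structure(out, class = c("reporter_result", "data.frame"), dropped = dropped,
            n_perm = n_perm, seed = seed, alpha = alpha, top_frac = top_frac)
}

#' Write reporter results as one TSV per class
#'
#' @param result a `reporter_result`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of files written, invisibly.
#' @export
write_reporter_tsv <- function(result, dir, prefix = "reporter") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (cls in unique(result$class)) {
    slug <- gsub("[^a-z]+", "_", tolower(cls))
    f <- file.path(dir, sprintf("%s_%s.tsv", prefix, slug))
    utils::write.table(result[result$class == cls, , drop = FALSE], f,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a gene statistics table for reporter analysis
#'
#' Tab-separated with columns `gene_id`, `pvalue`, `log2fc`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_gene_stats_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
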