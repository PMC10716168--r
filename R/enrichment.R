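#' Cell-type overlap enrichment by gene resampling
#'
#' Observed statistic per cell class is the overlap between the selected
#' genes and the class; the null is the overlap of size-matched random gene
#' sets drawn uniformly from the universe (all genes entering the PLS). The
#' one-sided add-one p tests enrichment. Empty selection or class gives `NA`.
#'
#' @param selected_genes character vector of selected gene ids.
#' @param annotation data.frame with columns `gene`, `class` (or a named
#'   class vector).
#' @param universe character vector of all candidate genes.
#' @param n_perm number of resamples.
#' @param seed integer seed.
#' @return data.frame: `class`, `observed`, `null_mean`, `null_sd`, `p`, `q`
#'   (Benjamini-Hochberg across classes).
#' @export
cell_type_test <- function(selected_genes, annotation, universe,
                           n_perm = 10000, seed = 1L) {
  if (is.data.frame(annotation)) {
    ann <- stats::setNames(annotation$class, annotation$gene)
  } else ann <- annotation
  if (!all(selected_genes %in% universe)) stop("selected genes must be a subset of the universe")
  set.seed(seed)
  cls <- sort(unique(stats::na.omit(unname(ann[universe]))))
  member <- factor(unname(ann[universe]), levels = cls)
  s <- length(selected_genes)
  observed <- as.numeric(table(member[match(selected_genes, universe)]))
  if (s == 0 || length(cls) == 0) {
    return(data.frame(class = cls, observed = NA_real_, null_mean = NA_real_,
                      null_sd = NA_real_, p = NA_real_, q = NA_real_))
  }
  null_counts <- matrix(0L, n_perm, length(cls))
  mi <- as.integer(member)
  for (b in seq_len(n_perm)) {
    null_counts[b, ] <- tabulate(mi[sample.int(length(universe), s)], length(cls))
  }
  p <- vapply(seq_along(cls), function(j) {
    (1 + sum(null_counts[, j] >= observed[j])) / (n_perm + 1)
  }, 0)
  class_n <- as.numeric(table(member))
  p[observed == 0 & class_n == 0] <- NA
  data.frame(class = cls, observed = observed,
             class_size = class_n,
             null_mean = colMeans(null_counts),
             null_sd = apply(null_counts, 2, stats::sd),
             p = p, q = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Category enrichment with a spatially autocorrelated null
#'
#' The observed statistic per category is the mean PLS component-1 gene
#' weight of its genes; the null distribution re-derives component-1 weights
#' against each surrogate of the slope map and recomputes the category means,
#' so both gene co-expression and spatial autocorrelation shape the null.
#' Two-sided add-one p, Benjamini-Hochberg across categories.
#'
#' @param gene_weights named numeric vector of component-1 gene weights (the
#'   universe).
#' @param categories named list of gene id vectors.
#' @param X standardised regions x genes matrix used for the PLS.
#' @param y standardised slope map.
#' @param surrogates `surrogate_ensemble` of `y` (or n x R matrix).
#' @return data.frame: `category`, `n_genes`, `observed`, `null_mean`,
#'   `null_sd`, `p`, `q`.
#' @export
category_enrichment_sa <- function(gene_weights, categories, X, y, surrogates) {
  S <- if (inherits(surrogates, "surrogate_ensemble")) surrogates$maps else surrogates
  universe <- names(gene_weights)
  idx <- lapply(categories, function(g) which(universe %in% g))
  observed <- vapply(idx, function(i) if (length(i)) mean(gene_weights[i]) else NA_real_, 0)
  n_surr <- nrow(S)
  null_means <- matrix(NA_real_, n_surr, length(categories))
  for (b in seq_len(n_surr)) {
    ys <- as.numeric(scale(S[b, ]))
    w <- drop(crossprod(X, ys))
    nw <- sqrt(sum(w^2))
    if (nw > 0) w <- w / nw
    if (stats::cor(drop(X %*% w), ys) < 0) w <- -w
    null_means[b, ] <- vapply(idx, function(i) if (length(i)) mean(w[i]) else NA_real_, 0)
  }
  p <- vapply(seq_along(categories), function(j) {
    if (is.na(observed[j])) return(NA_real_)
    (1 + sum(abs(null_means[, j]) >= abs(observed[j]))) / (n_surr + 1)
  }, 0)
  data.frame(category = names(categories),
             n_genes = lengths(idx),
             observed = observed,
             null_mean = colMeans(null_means),
             null_sd = apply(null_means, 2, stats::sd),
             p = p, q = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Read a gene-to-class annotation TSV
#' @param path TSV with columns `gene`, `class`.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "class") %in% names(tab))) stop("annotation needs gene and class columns")
  tab
}

#' Read GMT-style gene categories
#'
#' Tab-delimited lines: category name, description, then gene ids.
#'
#' @param path path to the GMT file.
#' @return named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, "", 1))
}

#' Write GMT-style gene categories
#' @param categories named list of gene id vectors.
#' @param path output path.
#' @export
write_gmt <- function(categories, path) {
  writeLines(vapply(names(categories), function(nm) {
    paste(c(nm, nm, categories[[nm]]), collapse = "\t")
  }, ""), path)
}
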