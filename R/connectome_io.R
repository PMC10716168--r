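#' Construct a connectome object
#'
#' A connectome is a symmetric, nonnegative, zero-diagonal weighted adjacency
#' matrix over brain regions, optionally paired with a matrix of mean
#' streamline lengths (mm) sharing the nonzero support of the weights.
#'
#' @param weights R x R numeric matrix of connection weights (e.g. FA x FN).
#' @param lengths optional R x R numeric matrix of mean fiber lengths (mm).
#' @param sym_tol relative tolerance above which asymmetry is an error rather
#'   than rounding noise to be symmetrised away.
#' @return an object of class `connectome` with elements `weights` and
#'   `lengths` (possibly `NULL`).
#' @export
connectome <- function(weights, lengths = NULL, sym_tol = 1e-8) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("connectome matrix must be square")
  if (!all(is.finite(weights))) stop("connectome weights must be finite")
  if (any(weights < 0)) stop("connectome weights must be nonnegative")
  asym <- max(abs(weights - t(weights)))
  scale <- max(abs(weights), 1e-300)
  if (asym / scale > sym_tol) {
    stop(sprintf("connectome asymmetry %.3g exceeds tolerance %g", asym / scale, sym_tol))
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- NULL
  if (!is.null(lengths)) {
    lengths <- as.matrix(lengths)
    if (!identical(dim(lengths), dim(weights))) stop("lengths matrix dimension mismatch")
    if (any(lengths < 0, na.rm = TRUE)) stop("lengths must be nonnegative")
    lengths <- (lengths + t(lengths)) / 2
    diag(lengths) <- 0
    dimnames(lengths) <- NULL
  }
  structure(list(weights = weights, lengths = lengths), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  R <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> %d regions, %d edges, density %.3f%s\n",
              R, ne, ne / (R * (R - 1) / 2),
              if (is.null(x$lengths)) "" else ", with lengths"))
  invisible(x)
}

n_regions <- function(x) nrow(x$weights)

#' Read a region metadata table
#'
#' Expects a tab-delimited file with header columns
#' `id,name,hemisphere,x,y,z,module,cortical`. File ids may use any unique
#' coding (e.g. 1-based atlas labels); rows are taken in file order and row
#' order defines the internal region index used throughout the package.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with columns `id`, `name`, `hemisphere`, `x`, `y`,
#'   `z`, `module`, `cortical`; one row per region.
#' @export
read_region_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("id", "name", "hemisphere", "x", "y", "z", "module", "cortical")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("region table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab <- tab[required]
  if (anyDuplicated(tab$id)) stop("duplicate region id in region table")
  if (!all(tab$hemisphere %in% c("L", "R"))) stop("hemisphere must be 'L' or 'R'")
  if (!all(is.finite(as.matrix(tab[c("x", "y", "z")])))) stop("non-finite region centroid")
  if (any(is.na(tab$module) | tab$module == "")) stop("every region needs a module label")
  tab$cortical <- as.logical(tab$cortical)
  if (anyNA(tab$cortical)) stop("cortical flag must be logical")
  rownames(tab) <- NULL
  tab
}

#' Write a region table
#' @param regions region table as returned by [read_region_table()].
#' @param path output path.
#' @export
write_region_table <- function(regions, path) {
  write_tsv_full(regions, path)
}

# tab-delimited UTF-8 writer with full float precision (repr round-trip)
write_tsv_full <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Read a dense connectivity matrix
#'
#' Reads a dense numeric TSV/CSV (delimiter inferred from the first line),
#' validates shape and nonnegativity, symmetrises rounding-level asymmetry and
#' zeroes the diagonal. A paired lengths file `<stem>.lengths.tsv` is loaded
#' automatically when present.
#'
#' @param path path to the matrix file.
#' @param n_regions expected number of regions (rows/columns).
#' @return a [connectome()] object.
#' @export
read_connectome <- function(path, n_regions) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  if (nrow(m) != n_regions || ncol(m) != n_regions) {
    stop(sprintf("connectome at '%s' is %dx%d, expected %dx%d",
                 path, nrow(m), ncol(m), n_regions, n_regions))
  }
  lengths <- NULL
  lpath <- paste0(sub("\\.[^.]+$", "", path), ".lengths.tsv")
  if (file.exists(lpath)) {
    lengths <- as.matrix(utils::read.table(lpath, sep = "\t", header = FALSE))
  }
  connectome(m, lengths)
}

#' Write a connectome to a dense TSV
#'
#' Full float precision so that write/read round-trips are exact to numeric
#' representation. Lengths, when present, go to `<stem>.lengths.tsv`.
#'
#' @param x a [connectome()].
#' @param path output path.
#' @export
write_connectome <- function(x, path) {
  write_matrix <- function(m, p) {
    txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(txt, p, useBytes = TRUE)
  }
  write_matrix(x$weights, path)
  if (!is.null(x$lengths)) {
    write_matrix(x$lengths, paste0(sub("\\.[^.]+$", "", path), ".lengths.tsv"))
  }
  invisible(path)
}

#' Load a longitudinal cohort from a manifest
#'
#' The manifest is a CSV with columns
#' `subject,wave,age,sex,tbv,centre,matrix_path`. Rows with ages outside
#' `age_bounds` are rejected with a warning (mirroring cohort inclusion
#' criteria); scans are sorted by (subject, wave).
#'
#' @param manifest_path path to the manifest CSV.
#' @param regions region table; all matrices must be `nrow(regions)` square.
#' @param age_bounds inclusive age range in years.
#' @return an object of class `cohort`: list with `scans` (data.frame of
#'   scan covariates), `connectomes` (list of [connectome()] aligned with
#'   `scans` rows) and `regions`.
#' @export
load_cohort <- function(manifest_path, regions, age_bounds = c(6, 14)) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("subject", "wave", "age", "sex", "tbv", "centre", "matrix_path")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0) stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  out_of_range <- man$age < age_bounds[1] | man$age > age_bounds[2]
  if (any(out_of_range)) {
    warning(sprintf("%d scan(s) rejected: age outside [%g, %g]",
                    sum(out_of_range), age_bounds[1], age_bounds[2]))
    man <- man[!out_of_range, , drop = FALSE]
  }
  if (nrow(man) == 0) stop("empty cohort")
  man <- man[order(man$subject, man$wave), , drop = FALSE]
  if (any(unlist(tapply(man$wave, man$subject, function(w) duplicated(w))))) {
    stop("waves must be strictly increasing within subject")
  }
  base <- dirname(manifest_path)
  R <- nrow(regions)
  conns <- lapply(man$matrix_path, function(p) {
    full <- if (file.exists(p)) p else file.path(base, p)
    read_connectome(full, R)
  })
  rownames(man) <- NULL
  coh <- structure(list(scans = man, connectomes = conns, regions = regions),
                   class = "cohort")
  message(cohort_summary(coh))
  coh
}

cohort_summary <- function(cohort) {
  counts <- table(table(cohort$scans$subject))
  sprintf("cohort: %d subjects, %d scans (scans-per-subject: %s)",
          length(unique(cohort$scans$subject)), nrow(cohort$scans),
          paste(sprintf("%sx%s", counts, names(counts)), collapse = ", "))
}

#' Assemble a cohort from in-memory pieces
#' @param scans data.frame of scan covariates (subject, wave, age, sex, tbv, centre).
#' @param connectomes list of [connectome()] aligned with `scans` rows, or `NULL`
#'   for a covariate-only design.
#' @param regions region table.
#' @return a `cohort` object.
#' @export
as_cohort <- function(scans, connectomes = NULL, regions = NULL) {
  scans <- as.data.frame(scans)
  ord <- order(scans$subject, scans$wave)
  scans <- scans[ord, , drop = FALSE]
  rownames(scans) <- NULL
  if (!is.null(connectomes)) connectomes <- connectomes[ord]
  structure(list(scans = scans, connectomes = connectomes, regions = regions),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", cohort_summary(x), "\n", sep = "")
  invisible(x)
}

#' Group-average network with a prevalence threshold
#'
#' An edge enters the group network iff the fraction of scans in which it is
#' nonzero is at least `prevalence` (the false-positive-suppression rule:
#' edges present in fewer than 75% of scans are zeroed). Kept-edge weights are
#' the mean weight across all scans (zeros included); lengths are averaged
#' over the scans where the edge is present.
#'
#' @param cohort a `cohort` with connectomes.
#' @param prevalence fraction in (0, 1].
#' @return a [connectome()].
#' @export
group_average_network <- function(cohort, prevalence = 0.75) {
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must be in (0, 1]")
  conns <- cohort$connectomes
  if (is.null(conns) || length(conns) == 0) stop("cohort has no connectomes")
  R <- n_regions(conns[[1]])
  nz <- matrix(0, R, R)
  wsum <- matrix(0, R, R)
  lsum <- matrix(0, R, R)
  lcnt <- matrix(0, R, R)
  for (cn in conns) {
    nz <- nz + (cn$weights > 0)
    wsum <- wsum + cn$weights
    if (!is.null(cn$lengths)) {
      present <- cn$weights > 0
      lsum <- lsum + cn$lengths * present
      lcnt <- lcnt + present
    }
  }
  n <- length(conns)
  keep <- (nz / n) >= prevalence
  w <- (wsum / n) * keep
  lens <- NULL
  if (any(lcnt > 0)) {
    lens <- matrix(0, R, R)
    has <- keep & lcnt > 0
    lens[has] <- lsum[has] / lcnt[has]
  }
  connectome(w, lens)
}
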