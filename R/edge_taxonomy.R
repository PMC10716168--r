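#' Identify hub regions on the group-average network
#'
#' A region is a hub if its degree strength or its betweenness centrality
#' exceeds the across-region mean plus one sample standard deviation.
#'
#' @param group_net group-average [connectome()].
#' @return logical length-R vector.
#' @export
identify_hubs <- function(group_net) {
  k <- degree_strength(group_net)
  b <- betweenness_centrality(group_net)
  (k > mean(k) + stats::sd(k)) | (b > mean(b) + stats::sd(b))
}

group_support_edges <- function(group_net) {
  W <- weights_of(group_net)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], weight = W[idx])
}

#' Classify group-network edges
#'
#' Produces the three edge taxonomies on the group-average support:
#' hub class (rich-club = hub-hub, feeder = hub-nonhub, local =
#' nonhub-nonhub), module class (within/between the 8 functional
#' subnetworks), and length class (short/long around the mean edge length;
#' ties go to short).
#'
#' @param group_net group-average [connectome()]; lengths required for the
#'   length taxonomy.
#' @param regions region table with a `module` column.
#' @return data.frame with columns `i`, `j`, `weight`, `hub_class`,
#'   `module_class`, `length_class` (the latter `NA` when lengths are absent),
#'   plus attribute `hubs` (logical vector).
#' @export
classify_edges <- function(group_net, regions) {
  ed <- group_support_edges(group_net)
  hubs <- identify_hubs(group_net)
  nh <- hubs[ed$i] + hubs[ed$j]
  ed$hub_class <- c("local", "feeder", "rich-club")[nh + 1L]
  mod <- regions$module
  ed$module_class <- ifelse(mod[ed$i] == mod[ed$j], "within", "between")
  if (!is.null(group_net$lengths)) {
    len <- group_net$lengths[cbind(ed$i, ed$j)]
    thr <- mean(len)
    ed$length_class <- ifelse(len <= thr, "short", "long")
    ed$length <- len
  } else {
    ed$length_class <- NA_character_
  }
  attr(ed, "hubs") <- hubs
  ed
}

#' Per-scan mean connection strength by edge type
#'
#' For every class of every taxonomy, the mean of the scan's weights over the
#' group-support edges of that class, zeros included where the scan lacks the
#' edge (so the quantity is comparable across scans). Empty classes are `NA`.
#'
#' @param scan a [connectome()] for one scan.
#' @param classification output of [classify_edges()].
#' @return named numeric vector (e.g. `hub.rich-club`, `module.within`,
#'   `length.short`, ...).
#' @export
edge_type_strength <- function(scan, classification) {
  W <- weights_of(scan)
  w <- W[cbind(classification$i, classification$j)]
  out <- c()
  for (tax in c("hub_class", "module_class", "length_class")) {
    cls <- classification[[tax]]
    if (all(is.na(cls))) next
    lv <- switch(tax,
                 hub_class = c("rich-club", "feeder", "local"),
                 module_class = c("within", "between"),
                 length_class = c("short", "long"))
    for (l in lv) {
      sel <- !is.na(cls) & cls == l
      out[paste0(sub("_class$", "", tax), ".", l)] <-
        if (any(sel)) mean(w[sel]) else NA_real_
    }
  }
  out
}

#' Edge-type strength table for a whole cohort
#' @param cohort a `cohort` with connectomes.
#' @param classification output of [classify_edges()].
#' @return data.frame: one row per scan, scan covariates plus one column per
#'   edge type.
#' @export
cohort_edge_type_strength <- function(cohort, classification) {
  mat <- t(vapply(cohort$connectomes,
                  function(cn) edge_type_strength(cn, classification),
                  edge_type_strength(cohort$connectomes[[1]], classification)))
  cbind(cohort$scans[setdiff(names(cohort$scans), "matrix_path")],
        as.data.frame(mat, check.names = FALSE))
}
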