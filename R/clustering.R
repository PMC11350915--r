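# Cross-site niche comparison: overlap-derived distances, deterministic
# complete-linkage clustering, and conspecific altitudinal overlap.

#' Convert an overlap matrix to a dissimilarity matrix
#'
#' `d = 1 - overlap`, zero diagonal. Note 1 - overlap is a bounded
#' dissimilarity but not necessarily a metric (the triangle inequality
#' is not guaranteed); complete linkage does not require one.
#'
#' @param m An `overlap_matrix` (see [community_overlap_matrix()]) or a
#'   symmetric numeric matrix of overlaps with unit diagonal.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
overlap_to_distance <- function(m) {
  v <- if (inherits(m, "overlap_matrix")) m$values else m
  stopifnot(is.matrix(v), nrow(v) == ncol(v))
  d <- 1 - v
  diag(d) <- 0
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Agglomerates the two clusters with the smallest inter-cluster
#' distance, where the distance between clusters is the *maximum*
#' pairwise distance between their members. Ties are broken
#' deterministically by the lexicographically smallest pair of cluster
#' leaf-label sets, so identical inputs always yield identical trees.
#' Complete-linkage merge heights are non-decreasing by construction.
#'
#' @param d Square symmetric non-negative distance matrix.
#' @param labels Leaf labels; default taken from `rownames(d)`.
#' @return A `niche_dendrogram`: `labels`, `merge` (hclust-style signed
#'   index matrix), `height` (non-decreasing merge heights).
#'   Coercible via [as.hclust()].
#' @export
complete_linkage <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || n < 2L) stopf("d must be a square matrix with >= 2 rows")
  if (max(abs(d - t(d))) > 1e-9) stopf("d must be symmetric")
  if (any(d < 0)) stopf("d must be non-negative")
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  stopifnot(length(labels) == n)

  D <- d
  id <- -seq_len(n)                 # hclust coding: negative = leaf
  leafsets <- lapply(seq_len(n), function(i) labels[i])
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  pair_key <- function(i, j) {
    a <- paste(sort(leafsets[[i]]), collapse = ",")
    b <- paste(sort(leafsets[[j]]), collapse = ",")
    paste(sort(c(a, b)), collapse = " | ")
  }

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (ai in seq_along(idx)) {
      for (aj in seq_along(idx)) {
        if (aj <= ai) next
        i <- idx[ai]; j <- idx[aj]
        dij <- D[i, j]
        if (dij < best_d - 1e-12) {
          best <- c(i, j); best_d <- dij; best_key <- pair_key(i, j)
        } else if (abs(dij - best_d) <= 1e-12) {
          key <- pair_key(i, j)
          if (key < best_key) { best <- c(i, j); best_key <- key }
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best_d
    # the merged cluster lives in slot i; complete linkage: max distance
    newd <- pmax(D[i, ], D[j, ])
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- 0
    leafsets[[i]] <- c(leafsets[[i]], leafsets[[j]])
    id[i] <- step
    active[j] <- FALSE
  }
  structure(list(labels = labels, merge = merge, height = height),
            class = "niche_dendrogram")
}

#' @export
print.niche_dendrogram <- function(x, ...) {
  cat(sprintf("Complete-linkage dendrogram, %d leaves\n", length(x$labels)))
  for (k in seq_along(x$height)) {
    nm <- function(v) if (v < 0) x$labels[-v] else sprintf("{%d}", v)
    cat(sprintf("  merge %d: %s + %s at %.4f\n", k,
                nm(x$merge[k, 1]), nm(x$merge[k, 2]), x$height[k]))
  }
  invisible(x)
}

leaf_order <- function(merge, n) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  walk(n - 1L)
}

#' @export
as.hclust.niche_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  structure(list(merge = x$merge, height = x$height,
                 order = leaf_order(x$merge, n), labels = x$labels,
                 method = "complete", call = match.call(),
                 dist.method = "1 - niche overlap"),
            class = "hclust")
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from the merge heights (ultrametric tree).
#'
#' @param x A `niche_dendrogram`.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_dendrogram_newick <- function(x, path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(x))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Total niche profiles of several sites on a shared scheme
#'
#' Builds per-species total niche profiles at each site using the
#' *shared* study months as the seasonal classes, so profiles from
#' different sites live on one resource-class scheme and can be compared
#' or clustered. Leaves are labelled `species@site`.
#'
#' @param records Validated annotation records.
#' @param design A [survey_design()].
#' @param sites Sites to include (default all in the design).
#' @param weights Passed to [total_niche_profile()].
#' @return Named list of defined total `niche_profile`s, names
#'   `species@site`.
#' @export
cross_site_profiles <- function(records, design, sites = design$sites,
                                weights = c(1, 1, 1) / 3) {
  shared_months <- Reduce(intersect, design$months[sites])
  if (length(shared_months) < 1L) stopf("sites share no study months")
  restricted <- survey_design(design$sites,
                              months = stats::setNames(
                                rep(list(shared_months), length(design$sites)),
                                design$sites),
                              altitudes = design$altitudes,
                              daylight_hours = design$daylight_hours,
                              night_hours = design$night_hours)
  keep <- records$month %in% shared_months
  recs <- records[keep, , drop = FALSE]
  out <- list()
  for (s in sites) {
    profs <- suppressWarnings(species_niche_profiles(recs, restricted, s,
                                                     weights = weights))
    for (sp in names(profs)) {
      if (!is.null(profs[[sp]]$total)) {
        out[[paste0(sp, "@", s)]] <- profs[[sp]]$total
      }
    }
  }
  out
}

#' Conspecific niche overlap across two sites
#'
#' For every species with defined total profiles at both sites, the
#' overlap of its two site-specific niches (computed on the shared-month
#' scheme), with mean and sample sd across species.
#'
#' @param records Validated annotation records.
#' @param design A [survey_design()].
#' @param site_a,site_b The two sites.
#' @param method Overlap method, see [niche_overlap()].
#' @param weights Passed to [total_niche_profile()].
#' @return List with `overlap` (named per-species vector), `mean`, `sd`.
#' @export
conspecific_cross_site_overlap <- function(records, design, site_a, site_b,
                                           method = c("schoener", "pianka"),
                                           weights = c(1, 1, 1) / 3) {
  method <- match.arg(method)
  profs <- cross_site_profiles(records, design, c(site_a, site_b), weights)
  sp_of <- sub("@.*$", "", names(profs))
  site_of <- sub("^.*@", "", names(profs))
  shared <- intersect(sp_of[site_of == site_a], sp_of[site_of == site_b])
  if (length(shared) == 0L) stopf("no species with defined profiles at both sites")
  ov <- vapply(shared, function(sp) {
    niche_overlap(profs[[paste0(sp, "@", site_a)]],
                  profs[[paste0(sp, "@", site_b)]], method)
  }, numeric(1))
  list(overlap = ov, mean = mean(ov),
       sd = if (length(ov) > 1L) stats::sd(ov) else NA_real_)
}
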