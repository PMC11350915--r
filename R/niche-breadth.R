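#' Standardized acoustic niche breadth (inverse Simpson)
#'
#' Niche breadth is the inverse of Simpson's concentration over the
#' resource-use proportions, NB = 1 / sum(p_i^2), ranging from 1 (a
#' specialist using one class) to r (a generalist spreading evenly over
#' all r classes). It is standardized to \[0, 1\] as
#' NB* = (NB - 1) / (r - 1).
#'
#' @param profile A defined `niche_profile` (see
#'   [call_structure_profile()] and friends).
#' @return A `breadth_result` list with `species`, `site`, `dimension`,
#'   `nb`, `nb_star` and the class count `r`.
#' @examples
#' p <- anuraniche:::new_niche_profile("sp", "site", "diel",
#'                                     rep(1 / 24, 24), sprintf("h%02d", 0:23))
#' niche_breadth(p)$nb_star  # uniform use of all classes -> 1
#' @export
niche_breadth <- function(profile) {
  check_defined(profile)
  p <- profile$p
  if (any(p < -1e-12)) stopf("negative proportions in profile")
  if (abs(sum(p) - 1) > 1e-6) stopf("profile proportions must sum to 1")
  r <- length(p)
  nb <- 1 / sum(p^2)
  structure(list(species = profile$species, site = profile$site,
                 dimension = profile$dimension,
                 nb = nb, nb_star = (nb - 1) / (r - 1), r = r),
            class = "breadth_result")
}

#' @export
print.breadth_result <- function(x, ...) {
  cat(sprintf("NB = %.3f, NB* = %.3f (r = %d; %s @ %s, %s)\n",
              x$nb, x$nb_star, x$r, x$species, x$site, x$dimension))
  invisible(x)
}

#' Expected breadth under equal exclusive niche partitioning
#'
#' If the standardized niche space is split exclusively and equally among
#' n species, each holds a standardized breadth of 1/n. This is the
#' reference value an observed community-average NB* is compared against
#' when asking whether niche space is partitioned.
#'
#' @param n_species Number of species in the community (>= 1).
#' @return The per-species standardized breadth, 1/n_species.
#' @examples
#' equal_partition_breadth(6)  # 0.1667, prints as 0.17
#' @export
equal_partition_breadth <- function(n_species) {
  if (!is_whole(n_species) || n_species < 1) {
    stopf("n_species must be a positive integer")
  }
  1 / as.numeric(n_species)
}

#' Breadth table for a site's community
#'
#' Computes NB and NB* for each species and dimension (plus the additive
#' total) at a site, in long format.
#'
#' @inheritParams species_niche_profiles
#' @return A data.frame with columns `species`, `site`, `dimension`,
#'   `nb`, `nb_star`, `r`.
#' @export
breadth_table <- function(records, design, site, species = NULL,
                          weights = c(1, 1, 1) / 3) {
  profs <- species_niche_profiles(records, design, site, species, weights)
  rows <- list()
  for (sp in names(profs)) {
    for (dim in c("call_structure", "diel", "seasonal", "total")) {
      pr <- profs[[sp]][[dim]]
      if (is.null(pr) || pr$undefined) next
      b <- niche_breadth(pr)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, site = site, dimension = dim,
        nb = b$nb, nb_star = b$nb_star, r = b$r)
    }
  }
  if (length(rows) == 0L) stopf("no defined niche profiles at site '%s'", site)
  do.call(rbind, rows)
}
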