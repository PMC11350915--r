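#' Pairwise niche overlap of two resource-use profiles
#'
#' The default is Schoener's proportional similarity,
#' `1 - 0.5 * sum(|p_i - q_i|)`, a bounded symmetric measure equal to 1
#' only for identical profiles and 0 for disjoint resource use. Pianka's
#' symmetric index `sum(p q) / sqrt(sum(p^2) sum(q^2))` is available as
#' an alternative.
#'
#' @param p,q Defined `niche_profile`s over the same scheme.
#' @param method `"schoener"` (default) or `"pianka"`.
#' @return A single overlap value in \[0, 1\].
#' @export
niche_overlap <- function(p, q, method = c("schoener", "pianka")) {
  method <- match.arg(method)
  check_defined(p); check_defined(q)
  if (p$dimension != q$dimension || length(p$p) != length(q$p)) {
    stopf("niche profiles use different resource-class schemes")
  }
  overlap_values(p$p, q$p, method)
}

overlap_values <- function(pv, qv, method) {
  if (method == "schoener") {
    max(0, min(1, 1 - 0.5 * sum(abs(pv - qv))))
  } else {
    denom <- sqrt(sum(pv^2) * sum(qv^2))
    if (denom == 0) stopf("degenerate profile in Pianka overlap")
    max(0, min(1, sum(pv * qv) / denom))
  }
}

#' Community overlap matrix over total niche profiles
#'
#' Builds the symmetric pairwise overlap matrix (unit diagonal) for all
#' species with defined total profiles, and summarizes the off-diagonal
#' upper triangle by its mean and sample (n-1) standard deviation.
#'
#' @param profiles A named list of defined total `niche_profile`s (one
#'   per species), e.g. the `total` elements of
#'   [species_niche_profiles()].
#' @param method Overlap method, see [niche_overlap()].
#' @return An `overlap_matrix` object: `species`, `values` (matrix),
#'   `method`, `mean`, `sd`, `n_pairs`.
#' @export
community_overlap_matrix <- function(profiles, method = c("schoener", "pianka")) {
  method <- match.arg(method)
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  if (length(profiles) < 2L) stopf("need at least two species with defined profiles")
  species <- names(profiles)
  if (is.null(species) || any(!nzchar(species))) {
    species <- vapply(profiles, function(p) p$species, character(1))
  }
  n <- length(profiles)
  v <- diag(1, n)
  dimnames(v) <- list(species, species)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      v[i, j] <- v[j, i] <- niche_overlap(profiles[[i]], profiles[[j]], method)
    }
  }
  summarize_overlap_matrix(v, method)
}

# Wrap an already-computed symmetric overlap matrix (e.g. published
# values) in the same container community_overlap_matrix() returns.
summarize_overlap_matrix <- function(values, method = "schoener") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-9) stopf("overlap matrix must be symmetric")
  upper <- values[upper.tri(values)]
  structure(list(species = rownames(values), values = values, method = method,
                 mean = mean(upper), sd = stats::sd(upper),
                 n_pairs = length(upper)),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("Pairwise niche overlap (%s), %d species, %d pairs\n",
              x$method, length(x$species), x$n_pairs))
  print(round(x$values, 3))
  cat(sprintf("  mean = %.4f, sd = %.4f\n", x$mean, x$sd))
  invisible(x)
}

#' Randomization null for niche overlap
#'
#' Under the null of no resource partitioning, each null overlap value is
#' the average of `n_draws` (default 10) independent uniform(0,1) draws.
#' Analytically such a value has mean 0.5 and standard deviation
#' sqrt(1 / (12 * n_draws)) (about 0.0913 for 10 draws). `reps` sets of
#' `n_pairs` values are generated deterministically from the seed.
#'
#' @param n_pairs Number of species pairs per replicate set.
#' @param n_draws Uniform draws averaged per null value.
#' @param reps Number of replicate sets.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A `random_overlap_null` list: `values` (length
#'   `reps * n_pairs`), `mean`, `sd`, plus the call parameters.
#' @export
random_overlap_null <- function(n_pairs, n_draws = 10, reps = 1, seed) {
  if (!is_whole(n_pairs) || n_pairs < 1) stopf("n_pairs must be >= 1")
  if (!is_whole(n_draws) || n_draws < 1) stopf("n_draws must be >= 1")
  if (!is_whole(reps) || reps < 1) stopf("reps must be >= 1")
  total <- as.integer(reps) * as.integer(n_pairs)
  values <- with_seed(seed, {
    colMeans(matrix(stats::runif(total * n_draws), nrow = n_draws))
  })
  structure(list(values = values, mean = mean(values), sd = stats::sd(values),
                 n_pairs = n_pairs, n_draws = n_draws, reps = reps,
                 seed = seed),
            class = "random_overlap_null")
}

#' Compare empirical overlap against the randomization null
#'
#' Returns the two-sample t statistic for the mean difference
#' (empirical minus null; pooled-variance by default, Welch optionally)
#' and the variance-ratio F statistic (larger sample variance over the
#' smaller), with the orientation recorded.
#'
#' @param empiric Numeric vector of empirical overlap values.
#' @param null Numeric vector of null overlap values (or a
#'   `random_overlap_null` object).
#' @param var_equal Use the pooled-variance t (default); `FALSE` gives
#'   Welch's t.
#' @return A list with `t`, `df_t`, `p_t`, `f`, `df_f`, `p_f` and
#'   `larger_variance` (`"empiric"` or `"null"`).
#' @export
empiric_vs_random_test <- function(empiric, null, var_equal = TRUE) {
  if (inherits(null, "random_overlap_null")) null <- null$values
  if (length(empiric) < 2L || length(null) < 2L) {
    stopf("both samples need at least two values")
  }
  tt <- stats::t.test(empiric, null, var.equal = var_equal)
  v1 <- stats::var(empiric); v2 <- stats::var(null)
  if (v1 == 0 && v2 == 0) stopf("degenerate samples: both variances are zero")
  if (v1 >= v2) {
    f <- v1 / v2; df_f <- c(length(empiric) - 1L, length(null) - 1L)
    larger <- "empiric"
  } else {
    f <- v2 / v1; df_f <- c(length(null) - 1L, length(empiric) - 1L)
    larger <- "null"
  }
  p_f <- 2 * stats::pf(f, df_f[1], df_f[2], lower.tail = FALSE)
  list(t = unname(tt$statistic), df_t = unname(tt$parameter),
       p_t = tt$p.value, f = f, df_f = df_f, p_f = min(1, p_f),
       larger_variance = larger)
}
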