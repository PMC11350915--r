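test_that("overlap converts to a zero-diagonal bounded dissimilarity", {
  v <- matrix(c(1, 0.74, 0.74, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  d <- overlap_to_distance(v)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_equal(d[1, 2], 0.26)
  expect_equal(d, t(d))
})

test_that("complete linkage reproduces the hand-worked three-point case", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 1
  d["A", "C"] <- d["C", "A"] <- 4
  d["B", "C"] <- d["C", "B"] <- 3
  dend <- complete_linkage(d)
  expect_equal(dend$height, c(1, 4))       # (A,B) at 1, then C at max(4,3)
  expect_equal(dend$merge[1, ], c(-2, -1)) # leaves A and B first
  expect_equal(dend$merge[2, ], c(-3, 1))
})

test_that("tied distances are resolved deterministically", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  dend1 <- complete_linkage(d)
  dend2 <- complete_linkage(d)
  expect_identical(dend1, dend2)
  expect_equal(dend1$height, rep(1, 3))
  # lexicographically smallest pair merges first
  expect_equal(sort(-dend1$merge[1, ]), c(1, 2))
})

test_that("complete linkage agrees with hclust on random instances", {
  set.seed(88)
  for (i in 1:50) {
    n <- 8
    m <- matrix(runif(n * n), n)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    rownames(d) <- colnames(d) <- paste0("L", seq_len(n))
    mine <- complete_linkage(d)
    ref <- stats::hclust(stats::as.dist(d), method = "complete")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
    # same tree topology and heights: cophenetic distances must coincide
    cm <- as.matrix(stats::cophenetic(stats::as.hclust(mine)))
    cr <- as.matrix(stats::cophenetic(ref))
    expect_equal(cm[rownames(cr), colnames(cr)], cr, tolerance = 1e-12)
    # no height inversions
    expect_true(all(diff(mine$height) >= -1e-12))
  }
})

test_that("dendrograms export to parseable Newick with merge heights", {
  d <- matrix(c(0, 0.2, 0.9, 0.8,
                0.2, 0, 0.85, 0.95,
                0.9, 0.85, 0, 0.3,
                0.8, 0.95, 0.3, 0), 4,
              dimnames = list(c("w", "x", "y", "z"), c("w", "x", "y", "z")))
  dend <- complete_linkage(d)
  nwk <- write_dendrogram_newick(dend)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("w", "x", "y", "z"))
  path <- withr::local_tempfile(fileext = ".newick")
  write_dendrogram_newick(dend, path)
  expect_true(file.exists(path))
})

test_that("incidence matrices code presence per sample unit and period", {
  design <- tiny_design()
  df <- data.frame(
    site = "siteA",
    date = as.Date(rep(c("2019-09-01", "2019-09-02", "2019-09-03"), each = 2)),
    month = "2019-09",
    hour = rep(c(20L, 21L), 3), minute_index = 1L,
    species = c("sp1", "sp2", "sp1", NA, NA, NA),
    call_rate = c(3L, 1L, 2L, 0L, 0L, 0L), calls = "",
    spl_1k = NA_real_, spl_2k = NA_real_, spl_3k = NA_real_,
    spl_4k = NA_real_, spl_5k = NA_real_, rain_index = 0L,
    stringsAsFactors = FALSE)
  recs <- validate_records(df)
  m <- build_incidence(recs, design, unit = "day", period = "night")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(unclass(m)),
               matrix(c(1L, 1L, 0L, 1L, 0L, 0L), 3),
               ignore_attr = TRUE)  # sp1: d1,d2; sp2: d1
  expect_error(build_incidence(recs, design, period = "daylight"), "no records")

  silent <- df; silent$species <- NA; silent$call_rate <- 0L
  m0 <- build_incidence(validate_records(silent), design, "day", "night",
                        species = c("sp1", "sp2"))
  expect_true(all(m0 == 0L))

  m_min <- build_incidence(recs, design, unit = "minute", period = "night")
  expect_equal(nrow(m_min), 6L)
})

test_that("rarefaction has exact endpoints and the hypergeometric mean", {
  # every species in every sample: flat curve, zero spread
  m <- matrix(1L, 5, 3)
  curve <- rarefy_incidence(m, n_randomizations = 50, seed = 2)
  expect_equal(curve$richness, rep(3, 5))
  expect_equal(curve$sd, rep(0, 5))
  expect_equal(curve$lower, curve$upper)

  # S species each in exactly one distinct sample: E[S_k] = S k / n
  n <- 12; S <- 6
  m2 <- matrix(0L, n, S)
  m2[cbind(seq_len(S) * 2, seq_len(S))] <- 1L
  curve2 <- rarefy_incidence(m2, n_randomizations = 400, seed = 7)
  for (k in c(3, 6, 9)) {
    expected <- S * k / n
    # conservative se: per-species inclusion is Bernoulli(k/n)
    se <- sqrt(S * (k / n) * (1 - k / n)) / sqrt(400)
    expect_lt(abs(curve2$richness[k] - expected), 3.5 * se + 1e-9)
  }
  # exact at k = n, in every randomization
  expect_equal(curve2$richness[n], S)
  expect_equal(curve2$sd[n], 0)
  # monotone non-decreasing for arbitrary matrices
  set.seed(14)
  m3 <- matrix(rbinom(8 * 5, 1, 0.3), 8, 5)
  c3 <- rarefy_incidence(m3, n_randomizations = 30, seed = 3)
  expect_true(all(diff(c3$richness) >= -1e-12))
  expect_true(all(c3$lower <= c3$richness + 1e-12 & c3$richness <= c3$upper + 1e-12))
  expect_equal(c3$richness[8], sum(colSums(m3) > 0))
})

test_that("conspecific niches across sites are closer than dissimilar heterospecifics", {
  # two sites, three species; site B shifts every species' diel peak by two
  # hours (small conspecific change) while species differ grossly
  months <- c("2019-09", "2019-10")
  design <- survey_design(c("A", "B"), months = months)
  mk <- function(name, fmean, peak_shifted) {
    diel <- rep(0.02, 24)
    diel[peak_shifted] <- 2
    species_params(name, fmean, 120, c(fmean - 400, fmean + 400),
                   notes_probs = c(1, 0, 0, 0, 0),
                   pulses_values = c(6L, 9L), pulses_probs = c(0.5, 0.5),
                   diel_rate = diel,
                   seasonal_mult = c("2019-09" = 1, "2019-10" = 1),
                   site_mult = c(A = 1, B = 1))
  }
  # same species list; the generator is run per design, so emulate the site
  # shift by generating two one-site datasets with shifted diel peaks
  spA <- list(mk("nightcaller", 3400, 21:23), mk("daycaller", 2600, 10:12),
              mk("lowcaller", 1300, 1:3))
  spB <- list(mk("nightcaller", 3400, 20:22), mk("daycaller", 2600, 9:11),
              mk("lowcaller", 1300, 2:4))
  gen_site <- function(site, sps, seed) {
    d <- survey_design(site, months = months)
    sps <- lapply(sps, function(s) { s$site_mult <- setNames(1, site); s })
    generate_dataset(generator_config(d, sps, days_per_month = 6, seed = seed))
  }
  recs <- rbind(gen_site("A", spA, 31), gen_site("B", spB, 32))
  profs <- cross_site_profiles(recs, design)
  expect_setequal(names(profs),
                  as.vector(outer(c("nightcaller", "daycaller", "lowcaller"),
                                  c("A", "B"), paste, sep = "@")))
  consp <- niche_overlap(profs[["nightcaller@A"]], profs[["nightcaller@B"]])
  hetero <- niche_overlap(profs[["nightcaller@A"]], profs[["daycaller@B"]])
  expect_gt(consp, hetero)

  cc <- conspecific_cross_site_overlap(recs, design, "A", "B")
  expect_length(cc$overlap, 3L)
  expect_true(all(cc$overlap > 0.5))
  expect_lt(cc$mean, 1)  # site shift keeps conspecific overlap below identity

  # clustering pairs each species' two site-leaves before joining others
  om <- community_overlap_matrix(profs)
  dend <- complete_linkage(overlap_to_distance(om))
  first3 <- dend$merge[1:3, ]
  merged_pairs <- apply(first3, 1, function(row) {
    sp <- sub("@.*", "", dend$labels[-row])
    length(unique(sp)) == 1L
  })
  expect_true(all(merged_pairs))
})
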