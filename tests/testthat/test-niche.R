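# Builds a record table whose single species has exactly the given call
# features at siteA (one call per minute row).
records_with_calls <- function(freq, notes, pulses) {
  n <- length(freq)
  df <- data.frame(
    site = "siteA",
    date = as.Date("2019-09-01") + ((seq_len(n) - 1) %/% 120),
    month = "2019-09",
    hour = ((seq_len(n) - 1) %/% 5) %% 24,
    minute_index = (seq_len(n) - 1) %% 5 + 1,
    species = "sp1",
    call_rate = 1L,
    calls = sprintf("%g:%d:%d", freq, notes, pulses),
    spl_1k = NA_real_, spl_2k = NA_real_, spl_3k = NA_real_,
    spl_4k = NA_real_, spl_5k = NA_real_,
    rain_index = 0L, stringsAsFactors = FALSE)
  validate_records(df)
}

test_that("identical calls give a three-point call-structure profile with NB = 3", {
  recs <- records_with_calls(rep(3400, 10), rep(1L, 10), rep(8L, 10))
  p <- call_structure_profile(recs, "sp1", "siteA")
  expect_equal(sum(p$p > 0), 3L)
  expect_equal(sort(unique(p$p[p$p > 0])), 1 / 3)
  expect_equal(sum(p$p), 1)
  b <- niche_breadth(p)
  expect_equal(b$nb, 3)
  expect_equal(b$nb_star, 2 / 24)
})

test_that("uniform use of every call-structure class gives the closed-form NB", {
  # 495 calls: each of 9 freq classes 55x, each of 5 note classes 99x,
  # each of 11 pulse classes 45x
  freq <- rep(seq(750, 4750, 500), each = 55)
  notes <- rep(rep(1:5, 99), length.out = 495)
  pulse_reps <- c(0L, seq(1L, 25L, 3L), 28L)  # one representative per class
  pulses <- rep(pulse_reps, each = 45)
  recs <- records_with_calls(freq, notes, pulses)
  b <- niche_breadth(call_structure_profile(recs, "sp1", "siteA"))
  nb_expected <- 1 / (9 * (1 / 27)^2 + 5 * (1 / 15)^2 + 11 * (1 / 33)^2)
  expect_equal(b$nb, nb_expected)
  expect_equal(b$nb, 22.3875, tolerance = 1e-4)
})

test_that("two equiprobable frequency classes with fixed notes/pulses give NB = 3.6", {
  recs <- records_with_calls(rep(c(3400, 2700), 20), rep(1L, 40), rep(8L, 40))
  b <- niche_breadth(call_structure_profile(recs, "sp1", "siteA"))
  expect_equal(b$nb, 1 / (2 * (1 / 6)^2 + (1 / 3)^2 + (1 / 3)^2))
  expect_equal(b$nb, 3.6)
})

test_that("diel profiles are normalized hourly mean rates over all minutes", {
  df <- data.frame(
    site = "siteA", date = as.Date("2019-09-01"), month = "2019-09",
    hour = c(0L, 1L, 2L, 3L), minute_index = 1L,
    species = c("sp1", "sp1", "sp1", NA),
    call_rate = c(2L, 1L, 1L, 0L),
    calls = "", spl_1k = NA_real_, spl_2k = NA_real_, spl_3k = NA_real_,
    spl_4k = NA_real_, spl_5k = NA_real_, rain_index = 0L,
    stringsAsFactors = FALSE)
  recs <- validate_records(df)
  p <- diel_profile(recs, "sp1", "siteA")
  expect_equal(p$p[1:4], c(0.5, 0.25, 0.25, 0))
  b <- niche_breadth(p)
  expect_equal(b$nb, 1 / 0.375, tolerance = 1e-9)
  expect_equal(b$nb_star, (1 / 0.375 - 1) / 23, tolerance = 1e-9)

  # silent minutes in an hour lower that hour's mean
  df2 <- rbind(df, within(df[1, ], { minute_index <- 2L; species <- NA; call_rate <- 0L }))
  p2 <- diel_profile(validate_records(df2), "sp1", "siteA")
  expect_equal(p2$p[1:3], c(1, 1, 1) / 3)  # hour 0 mean drops to 1
})

test_that("specialists and generalists reach the NB* limits exactly", {
  calls_one_hour <- data.frame(
    site = "siteA", date = as.Date("2019-09-01"), month = "2019-09",
    hour = 20L, minute_index = 1:3, species = "sp1", call_rate = 4L,
    calls = "", spl_1k = NA_real_, spl_2k = NA_real_, spl_3k = NA_real_,
    spl_4k = NA_real_, spl_5k = NA_real_, rain_index = 0L,
    stringsAsFactors = FALSE)
  b <- niche_breadth(diel_profile(validate_records(calls_one_hour), "sp1", "siteA"))
  expect_equal(b$nb, 1)
  expect_equal(b$nb_star, 0)

  uniform <- profile_of(rep(1 / 24, 24))
  bu <- niche_breadth(uniform)
  expect_equal(bu$nb, 24)
  expect_equal(bu$nb_star, 1)

  expect_equal(niche_breadth(profile_of(c(0.5, 0.5, rep(0, 23))[1:25]))$nb_star,
               1 / 24)
})

test_that("seasonal standardization uses the site's month count", {
  design <- survey_design(c("s7", "s6"),
                          months = list(s7 = sprintf("2019-%02d", 6:12),
                                        s6 = sprintf("2019-%02d", 6:11)))
  mk <- function(site, months) {
    validate_records(data.frame(
      site = site, date = as.Date(paste0(months, "-15")), month = months,
      hour = 20L, minute_index = 1L, species = "sp1", call_rate = 3L,
      calls = "", spl_1k = NA_real_, spl_2k = NA_real_, spl_3k = NA_real_,
      spl_4k = NA_real_, spl_5k = NA_real_, rain_index = 0L,
      stringsAsFactors = FALSE))
  }
  recs <- rbind(mk("s7", sprintf("2019-%02d", 6:12)),
                mk("s6", sprintf("2019-%02d", 6:11)))
  b7 <- niche_breadth(seasonal_profile(recs, "sp1", "s7", design))
  b6 <- niche_breadth(seasonal_profile(recs, "sp1", "s6", design))
  expect_equal(b7$r, 7L)
  expect_equal(b6$r, 6L)
  expect_equal(b7$nb_star, 1)  # uniform across the site's months
  expect_equal(b6$nb_star, 1)

  # single active month -> specialist
  one <- mk("s6", "2019-07")
  expect_equal(niche_breadth(seasonal_profile(one, "sp1", "s6", design))$nb_star, 0)
})

test_that("undefined profiles propagate as flagged errors, not zeros", {
  recs <- tiny_records()
  p <- call_structure_profile(recs, "ghost_species", "siteA")
  expect_true(p$undefined)
  expect_error(niche_breadth(p), "undefined")
  expect_error(niche_overlap(p, p), "undefined")
})

test_that("the additive total niche concatenates weighted dimension profiles", {
  mk <- function(dim, p) anuraniche:::new_niche_profile("sp", "s", dim, p,
                                                        paste0("c", seq_along(p)))
  r3 <- 7
  cs <- mk("call_structure", c(1, rep(0, 24)))
  di <- mk("diel", c(1, rep(0, 23)))
  se <- mk("seasonal", c(1, rep(0, r3 - 1)))
  tot <- total_niche_profile(cs, di, se)
  expect_equal(length(tot$p), 25 + 24 + r3)
  b <- niche_breadth(tot)
  expect_equal(b$nb, 3)  # three point masses of 1/3
  expect_equal(b$nb_star, 2 / (56 - 1))

  # all uniform: NB = 9 / (1/r1 + 1/r2 + 1/r3)
  csu <- mk("call_structure", rep(1 / 25, 25))
  diu <- mk("diel", rep(1 / 24, 24))
  seu <- mk("seasonal", rep(1 / r3, r3))
  bu <- niche_breadth(total_niche_profile(csu, diu, seu))
  expect_equal(bu$nb, 9 / (1 / 25 + 1 / 24 + 1 / r3))

  # degenerate weights reduce to the single dimension's NB,
  # restandardized by the total class count
  b_cs <- niche_breadth(total_niche_profile(csu, diu, seu, weights = c(1, 0, 0)))
  expect_equal(b_cs$nb, niche_breadth(csu)$nb)
  expect_equal(b_cs$nb_star, (25 - 1) / (56 - 1))
  expect_error(total_niche_profile(csu, diu, seu, weights = c(1, 1, 1)),
               "summing to 1")
})

test_that("overlap has identity, disjointness and the worked-example values", {
  p <- profile_of(c(1, 0)); q <- profile_of(c(0.5, 0.5))
  expect_equal(niche_overlap(p, p), 1)
  expect_equal(niche_overlap(p, profile_of(c(0, 1))), 0)
  expect_equal(niche_overlap(p, profile_of(c(0, 1)), "pianka"), 0)
  expect_equal(niche_overlap(p, q, "schoener"), 0.5)
  expect_equal(niche_overlap(p, q, "pianka"), 0.5 / sqrt(0.5), tolerance = 1e-9)
  expect_error(niche_overlap(p, profile_of(rep(1 / 3, 3))), "different")
})

test_that("overlap is symmetric, bounded, and 1 only for identical profiles", {
  set.seed(31)
  for (i in 1:25) {
    p <- random_profile(12); q <- random_profile(12)
    for (m in c("schoener", "pianka")) {
      o <- niche_overlap(p, q, m)
      expect_gte(o, 0); expect_lte(o, 1)
      expect_equal(o, niche_overlap(q, p, m))
    }
    expect_lt(niche_overlap(p, q, "schoener"), 1)
    expect_equal(niche_overlap(p, p, "schoener"), 1)
  }
})

test_that("NB stays in [1, r] and never increases when classes are merged", {
  set.seed(77)
  for (i in 1:40) {
    r <- sample(3:30, 1)
    pr <- random_profile(r)
    b <- niche_breadth(pr)
    expect_gte(b$nb, 1); expect_lte(b$nb, r)
    expect_gte(b$nb_star, 0); expect_lte(b$nb_star, 1)
    # merge two random classes: concentration rises, NB cannot increase
    ij <- sample(r, 2)
    merged <- pr$p
    merged[ij[1]] <- merged[ij[1]] + merged[ij[2]]
    merged <- merged[-ij[2]]
    expect_lte(niche_breadth(profile_of(merged))$nb, b$nb + 1e-12)
  }
})

test_that("equal partition of niche space gives 1/n per species", {
  expect_equal(equal_partition_breadth(6), 1 / 6)
  expect_equal(round(equal_partition_breadth(6), 2), 0.17)
  expect_equal(equal_partition_breadth(1), 1)
  expect_equal(equal_partition_breadth(4), 0.25)
  expect_error(equal_partition_breadth(0), "positive")
})

test_that("community overlap matrices are symmetric with unit diagonal", {
  profs <- list(a = profile_of(c(1, 0, 0)), b = profile_of(c(0.5, 0.5, 0)),
                c = profile_of(c(0, 0.2, 0.8)))
  om <- community_overlap_matrix(profs)
  expect_equal(om$values, t(om$values))
  expect_equal(diag(om$values), c(a = 1, b = 1, c = 1))
  expect_equal(om$n_pairs, 3L)
  expect_equal(om$mean, mean(om$values[upper.tri(om$values)]))
  # two identical species -> overlap 1
  om2 <- community_overlap_matrix(list(x = profile_of(c(0.3, 0.7)),
                                       y = profile_of(c(0.3, 0.7))))
  expect_equal(om2$values[1, 2], 1)
  expect_equal(om2$mean, 1)
  expect_error(community_overlap_matrix(profs[1]), "two species")
})

test_that("the randomization null has the analytic mean and spread", {
  null <- random_overlap_null(n_pairs = 15, n_draws = 10, reps = 100, seed = 3)
  expect_length(null$values, 1500L)
  expect_true(all(null$values > 0 & null$values < 1))
  # mean of a mean-of-10-uniforms is 0.5, sd sqrt(1/120); 4 sigma bounds
  se <- sqrt(1 / 120) / sqrt(1500)
  expect_lt(abs(null$mean - 0.5), 4 * se)
  expect_lt(abs(null$sd - sqrt(1 / 120)), 0.012)
  # determinism per seed, without disturbing the caller's RNG
  set.seed(99)
  before <- .Random.seed
  again <- random_overlap_null(15, 10, 100, seed = 3)
  expect_identical(again$values, null$values)
  expect_identical(.Random.seed, before)
})

test_that("empiric-vs-null statistics match textbook formulas", {
  expect_error(empiric_vs_random_test(c(1), c(1, 2)), "at least two")
  same <- c(0.2, 0.3, 0.4)
  res <- empiric_vs_random_test(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$f, 1)

  e <- c(0.2, 0.25, 0.3); n <- c(0.45, 0.5, 0.6)
  res2 <- empiric_vs_random_test(e, n)
  sp2 <- ((3 - 1) * var(e) + (3 - 1) * var(n)) / (3 + 3 - 2)
  t_hand <- (mean(e) - mean(n)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res2$t, t_hand, tolerance = 1e-12)
  expect_equal(res2$df_t, 4)
  expect_equal(res2$f, max(var(e), var(n)) / min(var(e), var(n)))
  expect_equal(res2$larger_variance, "null")
  expect_lt(res2$t, 0)  # empirical overlap below the null

  # strong separation gives a large negative t
  res3 <- empiric_vs_random_test(rep(0.2, 5) + rnorm(5, 0, 1e-4),
                                 rep(0.5, 5) + rnorm(5, 0, 1e-4))
  expect_lt(res3$t, -100)
})
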