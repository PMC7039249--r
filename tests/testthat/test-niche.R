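test_that("growth-label normalization remaps only the three tolerance labels", {
  expect_equal(normalize_growth_label("thermotolerant"), "thermophile")
  expect_equal(normalize_growth_label("Psychrotolerant"), "psychrophile")
  expect_equal(normalize_growth_label("psychrotrophic"), "psychrophile")
  expect_equal(normalize_growth_label("halotolerant"), "unbinned")
  expect_equal(normalize_growth_label(NA_character_), "unbinned")
  # idempotence on canonical labels
  canon <- c(niche_classes()$o2, niche_classes()$temperature)
  expect_equal(normalize_growth_label(canon), canon)
  expect_equal(normalize_growth_label(toupper(canon)), canon)
})

test_that("niche profiles report per-class means and family shares", {
  cen <- census_from_counts(list(c(3, 1, 0)), o2 = "aerobe")
  p <- niche_profile(cen, "o2")
  expect_equal(p$class, "aerobe")
  expect_equal(c(p$share_fd4, p$share_fd2, p$share_fld), c(75, 25, 0))

  cen2 <- fixture_census(n = 200, seed = 19)
  p2 <- niche_profile(cen2, "o2")
  expect_true(all(abs(p2$share_fd4 + p2$share_fd2 + p2$share_fld - 100) < 1e-9))
  expect_equal(sum(p2$n), nrow(cen2))  # every organism carries a canonical label
  # empty classes omitted
  cen3 <- census_from_counts(list(c(1, 0, 0)), o2 = "anaerobe")
  expect_equal(nrow(niche_profile(cen3, "o2")), 1L)
})

test_that("niche grids round for display to two significant figures with N/A cells", {
  cen <- census_from_counts(
    list(c(12, 0, 0), c(13, 0, 0), c(13, 0, 0)),
    o2 = "aerobe", temperature = "mesophile")
  g <- niche_grid(cen, "fd4")
  expect_equal(g$values["mesophile", "aerobe"], 38 / 3)
  expect_equal(g$display["mesophile", "aerobe"], "13")
  expect_equal(g$display["psychrophile", "aerobe"], "N/A")
  expect_equal(peccensus:::format_sig2(0.0456), "0.046")
  expect_equal(peccensus:::format_sig2(12.666), "13")
})

test_that("grid cells aggregated with the count grid reproduce axis-wise means", {
  cen <- fixture_census(n = 300, seed = 29)
  g <- niche_grid(cen, "fd2")
  prof <- niche_profile(cen, "o2")
  for (cl in prof$class) {
    v <- g$values[, cl]; n <- g$counts[, cl]
    expect_equal(sum(v * n, na.rm = TRUE) / sum(n),
                 prof$mean_fd2[prof$class == cl])
  }
})

test_that("7Fe fractions pool genes per oxygen class and recover the configured rate", {
  cen <- census_from_counts(list(c(2, 0, 0, 1), c(0, 1, 0, 0)),
                            o2 = c("aerobe", "anaerobe"))
  f <- seven_fe_fractions(cen)
  expect_equal(f$fraction[f$class == "aerobe"], 0.5)
  expect_true(is.na(f$fraction[f$class == "anaerobe"]))

  cen2 <- fixture_census(n = 800, seed = 47, seven_fe_rate = 0.3)
  f2 <- seven_fe_fractions(cen2)
  pooled <- sum(f2$n_7fe_genes) / sum(f2$n_fd4_genes)
  se <- sqrt(0.3 * 0.7 / sum(f2$n_fd4_genes))
  expect_lt(abs(pooled - 0.3), 3 * se)
})

test_that("pH profiles normalize by organisms per pH and conserve totals", {
  cen <- census_from_counts(list(c(3, 0, 0), c(1, 0, 0), c(5, 0, 0)),
                            ph = c(7, 7, 8))
  prof <- ph_profile(cen)
  expect_equal(prof$avg_fd4, c(2, 5))
  expect_equal(prof$n_organisms, c(2, 1))

  cen2 <- fixture_census(n = 300, seed = 37, ph_present = 0.7)
  prof2 <- ph_profile(cen2)
  annotated <- cen2[!is.na(cen2$ph), ]
  expect_lt(nrow(annotated), nrow(cen2))  # unannotated excluded here only
  for (f in c("fd4", "fd2", "fld"))
    expect_equal(sum(prof2[[paste0("avg_", f)]] * prof2$n_organisms),
                 sum(annotated[[paste0("n_", f)]]))
})

test_that("weighted pH means reduce to plain means under uniform weights", {
  cen <- census_from_counts(list(c(2, 2, 2), c(2, 2, 2)), ph = c(6, 8))
  st <- ph_weighted_comparison(ph_profile(cen))
  expect_equal(st$families$weighted_mean_ph, rep(7, 3))
  # identical profiles: degenerate all-zero differences reported as p = 1
  expect_equal(st$pairs$p, rep(1, 3))
})

test_that("the paired t-test matches the definitional formula on random profiles", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    prof <- data.frame(ph = sort(runif(n, 4, 10)), n_organisms = 1L,
                       avg_fd4 = runif(n, 0, 5), avg_fd2 = runif(n, 0, 5),
                       avg_fld = runif(n, 0, 5))
    st <- ph_weighted_comparison(prof)
    d <- prof$avg_fd4 - prof$avg_fd2
    t_ref <- mean(d) / (sd(d) / sqrt(n))
    p_ref <- 2 * pt(-abs(t_ref), n - 1)
    row <- st$pairs[st$pairs$family_a == "fd4" & st$pairs$family_b == "fd2", ]
    expect_equal(row$t, t_ref, tolerance = 1e-12)
    expect_equal(row$p, p_ref, tolerance = 1e-12)
    # weighted sd against the definitional frequency-weight form
    w <- prof$avg_fld
    m <- sum(w * prof$ph) / sum(w)
    s_ref <- sqrt(sum(w * (prof$ph - m)^2) / sum(w))
    expect_equal(st$families$weighted_sd_ph[st$families$family == "fld"],
                 s_ref, tolerance = 1e-12)
  }
})

test_that("too few shared pH bins is reported as not computable", {
  cen <- census_from_counts(list(c(1, 1, 1)), ph = 7)
  st <- ph_weighted_comparison(ph_profile(cen))
  expect_true(all(is.na(st$pairs$p)))
})
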