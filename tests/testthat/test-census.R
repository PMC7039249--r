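make_meta <- function(ids, domain = "Bacteria") {
  data.frame(organism_id = ids, domain = domain, phylum = NA_character_,
             class = NA_character_, o2 = NA_character_,
             temperature = NA_character_, ph = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("census counting is per signature, with zero rows for gene-less organisms", {
  genes <- data.frame(
    organism_id = c("o1", "o1", "o1", "o3"),
    gene_id = c("g1", "g2", "g3", "g1"),
    length = c(60L, 70L, 160L, 90L),
    signatures = c("IPR017896", "IPR017896", "IPR008254",
                   "IPR001041;IPR017896"),
    stringsAsFactors = FALSE
  )
  cen <- build_census(genes, make_meta(c("o1", "o2", "o3")))
  o1 <- cen[cen$organism_id == "o1", ]
  expect_equal(c(o1$n_fd4, o1$n_fd2, o1$n_fld, o1$total), c(2L, 0L, 1L, 3L))
  o2 <- cen[cen$organism_id == "o2", ]
  expect_equal(o2$total, 0L)
  # the dual-signature gene increments both families and contributes 2 to total
  o3 <- cen[cen$organism_id == "o3", ]
  expect_equal(c(o3$n_fd4, o3$n_fd2, o3$total), c(1L, 1L, 2L))
  expect_equal(attr(cen, "diagnostics")$n_multi_family, 1L)
})

test_that("counts are invariant to input row order and orphan genes are reported", {
  ds <- fixture_dataset(n = 50, seed = 17)
  cen1 <- build_census(ds$genes, ds$metadata)
  perm <- ds$genes[sample.int(nrow(ds$genes)), ]
  cen2 <- build_census(perm, ds$metadata)
  expect_equal(as.data.frame(cen1), as.data.frame(cen2), ignore_attr = TRUE)

  orphan <- rbind(ds$genes, data.frame(
    organism_id = "ghost", gene_id = "g1", length_aa = 60L,
    ipr_accessions = "IPR017896"))
  cen3 <- build_census(orphan, ds$metadata)
  expect_equal(as.data.frame(cen3), as.data.frame(cen1), ignore_attr = TRUE)
  expect_equal(nrow(attr(cen3, "diagnostics")$unmatched_organism_genes), 1L)
})

test_that("group summaries use sample sd, zero for singletons, sorted by mean total", {
  cen <- census_from_counts(
    list(c(2, 1, 0), c(4, 1, 0), c(0, 0, 7)),
    phylum = c("P1", "P1", "P2"))
  s <- summarize_by_group(cen, "phylum")
  expect_equal(s$group, c("P2", "P1"))  # 7 > 4: descending mean total
  p1 <- s[s$group == "P1", ]
  expect_equal(p1$mean_fd4, 3)
  expect_equal(p1$sd_fd4, sd(c(2, 4)))
  p2 <- s[s$group == "P2", ]
  expect_equal(p2$mean_total, 7)
  expect_equal(p2$sd_total, 0)
  # ties broken alphabetically
  cen2 <- census_from_counts(list(c(1, 0, 0), c(1, 0, 0)),
                             phylum = c("B", "A"))
  expect_equal(summarize_by_group(cen2, "phylum")$group, c("A", "B"))
  # missing labels fall into "unclassified"
  cen3 <- census_from_counts(list(c(1, 0, 0)), phylum = NA_character_)
  expect_equal(summarize_by_group(cen3, "phylum")$group, "unclassified")
})

test_that("summaries recover configured generator means within 3 standard errors", {
  mu_total <- 7
  cen <- fixture_census(n = 800, seed = 23,
                        means = c(fd4 = 4, fd2 = 2, fld = 1), dispersion = Inf)
  s <- summarize_by_group(cen, "domain")
  se <- sqrt(mu_total / 800)  # Poisson total
  expect_lt(abs(s$mean_total[1] - mu_total), 3 * se)
})

test_that("abundance histograms partition the census", {
  cen <- census_from_counts(list(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)))
  h <- abundance_histogram(cen, "total")
  expect_equal(h, data.frame(count = c(0L, 3L), n_organisms = c(2L, 1L)))
  cen2 <- fixture_census(n = 150, seed = 2)
  for (w in c("total", "fd4", "fd2", "fld"))
    expect_equal(sum(abundance_histogram(cen2, w)$n_organisms), nrow(cen2))
})

test_that("pairwise quadrant fractions partition and marginals match histograms", {
  cen <- census_from_counts(list(c(3, 0, 0)))
  pw <- pairwise_matrix(cen, "fld", "fd2")
  expect_equal(pw$matrix, data.frame(count_a = 0L, count_b = 0L, n = 1L))
  expect_equal(unname(pw$quadrants[["both_below"]]), 1)

  cen2 <- fixture_census(n = 300, seed = 77)
  pw2 <- pairwise_matrix(cen2, "fd4", "fld")
  expect_equal(sum(pw2$quadrants), 1)
  expect_equal(sum(pw2$matrix$n), nrow(cen2))
  # marginal over count_b reproduces the fd4 histogram
  marg <- aggregate(n ~ count_a, pw2$matrix, sum)
  h <- abundance_histogram(cen2, "fd4")
  expect_equal(marg$count_a, h$count)
  expect_equal(marg$n, h$n_organisms)
  # and over count_a, the fld histogram
  marg_b <- aggregate(n ~ count_b, pw2$matrix, sum)
  h_b <- abundance_histogram(cen2, "fld")
  expect_equal(marg_b$n, h_b$n_organisms)

  expect_error(pairwise_matrix(cen2, "fd4", "fd4"), "differ")
})

test_that("strategy classification partitions organisms by family richness", {
  cen <- census_from_counts(list(c(0, 0, 0), c(5, 0, 0), c(2, 1, 3),
                                 c(0, 0, 2), c(0, 1, 1)))
  expect_equal(classify_strategy(cen),
               c("none", "specialist", "generalist", "specialist",
                 "generalist"))
  f <- strategy_fractions(cen)
  expect_equal(sum(f), 1)
  expect_equal(unname(f), c(1, 2, 2) / 5)
})
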