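test_that("regeneration with the same seed and config is identical", {
  a <- fixture_dataset(n = 40, seed = 11)
  b <- fixture_dataset(n = 40, seed = 11)
  expect_identical(a$genes, b$genes)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$tree, b$tree)
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_dataset(a, d1)
  write_synthetic_dataset(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  c <- fixture_dataset(n = 40, seed = 12)
  expect_false(identical(a$genes, c$genes))
})

test_that("all-zero count means yield an empty gene table but full metadata", {
  ds <- fixture_dataset(n = 15, seed = 3, means = c(fd4 = 0, fd2 = 0, fld = 0))
  expect_equal(nrow(ds$genes), 0L)
  expect_equal(nrow(ds$metadata), 15L)
})

test_that("negative organism counts are rejected", {
  arch <- fixture_archetype()
  expect_error(generate_census_dataset(list(list(config = arch, n = -1)), 1),
               "non-negative")
})

test_that("per-organism family counts recover the configured means and 7Fe rate", {
  mu <- c(fd4 = 11.9, fd2 = 2, fld = 1)
  n <- 1000
  cen <- fixture_census(n = n, seed = 99, means = mu, dispersion = Inf,
                        seven_fe_rate = 0.3)
  # Poisson counts: se of the mean is sqrt(mu/n)
  for (f in names(mu)) {
    se <- sqrt(mu[[f]] / n)
    expect_lt(abs(mean(cen[[paste0("n_", f)]]) - mu[[f]]), 3 * se)
  }
  # binomial 7Fe flags among [4Fe-4S] genes
  n4 <- sum(cen$n_fd4)
  frac <- sum(cen$n_7fe) / n4
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n4))
})

test_that("negative binomial dispersion widens counts to the configured variance", {
  mu <- 8; theta <- 1
  cen <- fixture_census(n = 1500, seed = 5,
                        means = c(fd4 = mu, fd2 = 0, fld = 0),
                        dispersion = theta)
  v <- var(cen$n_fd4)
  expected <- mu + mu^2 / theta
  # sampling error of a variance estimate is wide; 4 relative-sd window
  expect_lt(abs(v - expected) / expected, 0.35)
  expect_lt(abs(mean(cen$n_fd4) - mu), 3 * sqrt(expected / 1500))
})

test_that("generated lengths stay in [40, 220] and exercise both sides of the cutoff", {
  ds <- fixture_dataset(n = 300, seed = 8,
                        means = c(fd4 = 0, fd2 = 0, fld = 5),
                        mix = list(
                          fd4 = cbind(center = 70, spread = 6, weight = 1),
                          fd2 = cbind(center = 90, spread = 6, weight = 1),
                          fld = cbind(center = 200, spread = 10, weight = 1)))
  expect_true(all(ds$genes$length_aa >= 40 & ds$genes$length_aa <= 220))
  expect_gt(sum(ds$genes$length_aa > 200), 0)
  expect_gt(sum(ds$genes$length_aa <= 200), 0)
})

test_that("length-filtered lengths recover the configured mixture modes", {
  ds <- fixture_dataset(n = 600, seed = 21, means = c(fd4 = 4, fd2 = 0, fld = 0))
  cen <- build_census(ds$genes, ds$metadata)
  genes <- read_gene_annotations(write_gene_tsv(
    sprintf("%s\t%s\t%d\t%s", ds$genes$organism_id, ds$genes$gene_id,
            ds$genes$length_aa, ds$genes$ipr_accessions)))
  lt <- gene_length_table(genes, cen)
  dens <- length_density(lt$length[lt$family == "fd4"])
  modes <- detect_modes(dens)
  expect_equal(nrow(modes), 2L)
  expect_lt(abs(modes$position[1] - 70), dens$bandwidth)
  expect_lt(abs(modes$position[2] - 170), dens$bandwidth)
})

test_that("random trees conserve and recover the requested leaf set", {
  nwk <- generate_tree(c("A", "B"), seed = 1)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("A", "B"))

  ids <- sprintf("org%03d", 1:351)
  nwk <- generate_tree(ids, seed = 2)
  tr <- ape::read.tree(text = nwk)
  expect_equal(length(tr$tip.label), 351L)
  expect_setequal(tr$tip.label, ids)

  expect_error(generate_tree(c("A", "A", "B"), 1), "duplicate")
  expect_error(generate_tree("A", 1), "at least two")
})

test_that("decoy accessions appear in gene tables but never in counts", {
  ds <- fixture_dataset(n = 120, seed = 13, means = c(fd4 = 2, fd2 = 1, fld = 1),
                        decoy_rate = 0.2, decoy_gene_rate = 0.5)
  expect_true(any(grepl("IPR999999", ds$genes$ipr_accessions)))
  cen <- build_census(ds$genes, ds$metadata)
  small <- ds$genes[ds$genes$length_aa <= 200, ]
  cls <- strsplit(small$ipr_accessions, ";", fixed = TRUE)
  n_fd4_direct <- sum(vapply(cls, function(s) "IPR017896" %in% s, logical(1)))
  expect_equal(sum(cen$n_fd4), n_fd4_direct)
})
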