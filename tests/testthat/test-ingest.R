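test_that("gene annotation parsing merges signature rows by set union", {
  path <- write_gene_tsv(c(
    "orgA\tg1\t84\tIPR017896;IPR000813",
    "orgA\tg2\t95\tIPR001041",
    "orgA\tg2\t95\tIPR017896",
    "orgB\tg1\t150\tIPR008254"
  ))
  rec <- read_gene_annotations(path)
  expect_equal(nrow(rec), 3L)
  g1 <- rec[rec$organism_id == "orgA" & rec$gene_id == "g1", ]
  expect_setequal(strsplit(g1$signatures, ";")[[1]],
                  c("IPR017896", "IPR000813"))
  g2 <- rec[rec$organism_id == "orgA" & rec$gene_id == "g2", ]
  expect_setequal(strsplit(g2$signatures, ";")[[1]],
                  c("IPR001041", "IPR017896"))
})

test_that("a header-only file parses to an empty record set", {
  rec <- read_gene_annotations(write_gene_tsv(character(0)))
  expect_equal(nrow(rec), 0L)
})

test_that("parse errors name the offending column or row", {
  path <- tempfile()
  writeLines(c("organism_id\tgene_id\tipr_accessions", "a\tg\tIPR008254"), path)
  expect_error(read_gene_annotations(path), "length_aa")
  bad <- write_gene_tsv("orgA\tg1\tlong\tIPR008254")
  expect_error(read_gene_annotations(bad), "row 1")
  expect_error(read_gene_annotations(write_gene_tsv("orgA\tg1\t84.5\tIPR008254")),
               "non-integer")
})

test_that("the size filter keeps 200-residue genes and drops 201", {
  rec <- data.frame(
    organism_id = "o", gene_id = c("g1", "g2", "g3", "g4"),
    length = c(184L, 200L, 201L, 55L),
    signatures = "IPR008254", stringsAsFactors = FALSE
  )
  kept <- apply_length_filter(rec, 200)
  expect_setequal(kept$gene_id, c("g1", "g2", "g4"))
  expect_identical(apply_length_filter(kept, 200), kept)  # idempotent
  expect_equal(kept$gene_id, c("g1", "g2", "g4"))         # order preserved
})

test_that("signature classification follows the family map and ignores unknowns", {
  expect_equal(classify_gene("IPR001041"),
               list(families = "fd2", seven_fe = FALSE))
  expect_equal(classify_gene(c("IPR017896", "IPR000813")),
               list(families = "fd4", seven_fe = TRUE))
  expect_equal(classify_gene("IPR999999"),
               list(families = character(0), seven_fe = FALSE))
  # 7Fe alone never creates a family
  expect_equal(classify_gene("IPR000813")$families, character(0))
  # multi-family gene
  expect_setequal(classify_gene("IPR001041;IPR017896")$families,
                  c("fd2", "fd4"))
})

test_that("pre-counted census tables parse with totals and error checks", {
  path <- tempfile()
  writeLines(c("organism_id\tn_fd4\tn_fd2\tn_fld\tdomain",
               "o1\t2\t1\t0\tBacteria",
               "o2\t0\t0\t0\tArchaea",
               "o3\t5\t5\t5\tEukaryota"), path)
  cen <- read_supplementary_census(path)
  expect_equal(cen$total, c(3L, 0L, 15L))
  expect_equal(nrow(cen), 3L)

  dup <- tempfile()
  writeLines(c("organism_id\tn_fd4\tn_fd2\tn_fld",
               "o1\t1\t0\t0", "o1\t2\t0\t0"), dup)
  expect_error(read_supplementary_census(dup), "o1")

  neg <- tempfile()
  writeLines(c("organism_id\tn_fd4\tn_fd2\tn_fld", "o1\t-1\t0\t0"), neg)
  expect_error(read_supplementary_census(neg), "row 1")
})

test_that("the column-mapping config binds arbitrary layouts", {
  path <- tempfile()
  writeLines(c("Organism\tFourFe\tTwoFe\tFlavo\tKingdom\tpH",
               "o1\t4\t1\t5\tBacteria\t6.5"), path)
  cen <- read_supplementary_census(path, mapping = c(
    organism_id = "Organism", n_fd4 = "FourFe", n_fd2 = "TwoFe",
    n_fld = "Flavo", domain = "Kingdom", ph = "pH"))
  expect_equal(cen$total, 10L)
  expect_equal(cen$ph, 6.5)
  expect_error(read_supplementary_census(path, mapping = c(bogus = "x")),
               "bogus")
})

test_that("a census built from genes equals one re-read from its own summary", {
  ds <- fixture_dataset(n = 80, seed = 31, decoy_rate = 0.1,
                        decoy_gene_rate = 0.2)
  cen <- build_census(ds$genes, ds$metadata)
  path <- tempfile()
  write.table(as.data.frame(cen), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  back <- read_supplementary_census(path)
  for (col in c("organism_id", "n_fd4", "n_fd2", "n_fld", "n_7fe", "total"))
    expect_equal(back[[col]], cen[[col]], ignore_attr = TRUE)
})
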