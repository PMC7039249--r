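# shared fixtures built in code

# a single-archetype recipe with tightly controlled parameters
fixture_archetype <- function(means = c(fd4 = 4, fd2 = 2, fld = 1),
                              dispersion = Inf, seven_fe_rate = 0.3,
                              decoy_rate = 0, decoy_gene_rate = 0,
                              ph_present = 1,
                              mix = NULL) {
  if (is.null(mix))
    mix <- list(
      fd4 = cbind(center = c(70, 170), spread = c(6, 6), weight = c(0.5, 0.5)),
      fd2 = cbind(center = 90, spread = 6, weight = 1),
      fld = cbind(center = 150, spread = 6, weight = 1)
    )
  pec_archetype(
    name = "test", domain = "Bacteria", family_means = means,
    dispersion = dispersion, seven_fe_rate = seven_fe_rate,
    length_mixture = mix,
    o2_probs = c("obligate anaerobe" = 0.2, anaerobe = 0.2, facultative = 0.3,
                 microaerophilic = 0, aerobe = 0.2, "obligate aerobe" = 0.1),
    temp_probs = c(psychrophile = 0.1, mesophile = 0.6, thermophile = 0.2,
                   hyperthermophile = 0.1),
    phylum_probs = c(Proteobacteria = 0.6, Firmicutes = 0.4),
    ph_mean = 7, ph_sd = 1, ph_present = ph_present,
    decoy_rate = decoy_rate, decoy_gene_rate = decoy_gene_rate
  )
}

fixture_dataset <- function(n = 200, seed = 42, ...) {
  arch <- fixture_archetype(...)
  generate_census_dataset(list(list(config = arch, n = n)), seed = seed)
}

fixture_census <- function(n = 200, seed = 42, ...) {
  ds <- fixture_dataset(n = n, seed = seed, ...)
  build_census(ds$genes, ds$metadata)
}

# write a gene annotation TSV from inline rows
write_gene_tsv <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("organism_id\tgene_id\tlength_aa\tipr_accessions", rows), path)
  path
}

write_meta_tsv <- function(rows,
                           header = "organism_id\tdomain\tphylum\to2\ttemperature\tph") {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(header, rows), path)
  path
}

# hand-built census from count triples: list of c(fd4, fd2, fld[, 7fe])
census_from_counts <- function(counts, o2 = NULL, temperature = NULL,
                               ph = NULL, domain = "Bacteria",
                               phylum = NA_character_) {
  n <- length(counts)
  m <- t(vapply(counts, function(x) {
    x <- as.integer(x)
    if (length(x) == 3L) x <- c(x, 0L)
    x
  }, integer(4)))
  as_pec_census(data.frame(
    organism_id = sprintf("org%03d", seq_len(n)),
    domain = rep_len(domain, n), phylum = rep_len(phylum, n),
    class = NA_character_,
    o2 = if (is.null(o2)) NA_character_ else rep_len(o2, n),
    temperature = if (is.null(temperature)) NA_character_ else rep_len(temperature, n),
    ph = if (is.null(ph)) NA_real_ else rep_len(ph, n),
    n_fd4 = m[, 1], n_fd2 = m[, 2], n_fld = m[, 3], n_7fe = m[, 4],
    total = m[, 1] + m[, 2] + m[, 3],
    stringsAsFactors = FALSE
  ))
}

# brute-force adjoining ternary cells by scanning every cell's closed region
brute_force_adjoining <- function(c3, total, step = 10) {
  ncell <- 100 / step
  p <- 100 * c3 / total
  out <- list()
  for (i in 0:(ncell - 1)) for (j in 0:(ncell - 1)) for (k in 0:(ncell - 1)) {
    s <- i + j + k
    idx <- c(i, j, k)
    inside <- if (s == ncell - 1) all(p >= idx * step - 1e-9)
    else if (s == ncell - 2) all(p <= (idx + 1) * step + 1e-9)
    else FALSE
    if (inside) out[[length(out) + 1L]] <- idx
  }
  do.call(rbind, out)
}
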