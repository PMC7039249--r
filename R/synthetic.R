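#' Define a synthetic organism archetype
#'
#' An archetype is a generative recipe for one kind of genome: negative
#' binomial family gene counts (reducing to Poisson when `dispersion` is
#' infinite), a per-gene probability that a [4Fe-4S] gene also carries the
#' 7Fe signature, family-specific Gaussian length mixtures truncated to
#' [40, 220] residues (so the 200-residue filter is exercised on both
#' sides), categorical niche-label distributions, and a normal external-pH
#' model. A small decoy-signature rate plants the unknown accession
#' `IPR999999` on some genes, which classification must ignore.
#'
#' @param name short label, e.g. `"archaeon-like"`.
#' @param domain `"Archaea"`, `"Bacteria"` or `"Eukaryota"`.
#' @param family_means named numeric vector `c(fd4=, fd2=, fld=)` of mean
#'   gene counts per genome; all `>= 0`.
#' @param dispersion negative binomial size parameter (variance
#'   `mu + mu^2/dispersion`); `Inf` gives Poisson counts.
#' @param seven_fe_rate probability in [0, 1] that a [4Fe-4S] gene carries
#'   the 7Fe signature.
#' @param length_mixture named list (`fd4`, `fd2`, `fld`) of matrices with
#'   columns `center`, `spread`, `weight`; weights must sum to 1 per family.
#' @param o2_probs,temp_probs named probability vectors over the canonical
#'   oxygen / temperature classes.
#' @param phylum_probs named probability vector over phylum labels.
#' @param ph_mean,ph_sd mean and spread of external pH.
#' @param ph_present probability that an organism has a pH annotation.
#' @param decoy_rate per-gene probability of an extra decoy accession.
#' @param decoy_gene_rate per-organism probability of one decoy-only gene.
#' @return object of class `pec_archetype`.
#' @export
pec_archetype <- function(name, domain, family_means, dispersion = Inf,
                          seven_fe_rate = 0.1, length_mixture,
                          o2_probs, temp_probs, phylum_probs,
                          ph_mean = 7, ph_sd = 1, ph_present = 0.5,
                          decoy_rate = 0.05, decoy_gene_rate = 0.1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!domain %in% c("Archaea", "Bacteria", "Eukaryota"))
    stop("'domain' must be Archaea, Bacteria or Eukaryota", call. = FALSE)
  fams <- names(pec_families())
  if (!all(fams %in% names(family_means)) || any(family_means < 0))
    stop("'family_means' needs non-negative fd4/fd2/fld entries", call. = FALSE)
  if (seven_fe_rate < 0 || seven_fe_rate > 1)
    stop("'seven_fe_rate' must lie in [0, 1]", call. = FALSE)
  if (!all(fams %in% names(length_mixture)))
    stop("'length_mixture' needs fd4/fd2/fld components", call. = FALSE)
  for (f in fams) {
    m <- length_mixture[[f]]
    if (!is.matrix(m) || !all(c("center", "spread", "weight") %in% colnames(m)))
      stop("each length mixture must be a matrix with center/spread/weight columns",
           call. = FALSE)
    if (abs(sum(m[, "weight"]) - 1) > 1e-8)
      stop("mixture weights for family ", f, " must sum to 1", call. = FALSE)
    if (any(m[, "center"] < 40) || any(m[, "center"] > 220))
      stop("mixture centers must lie within the [40, 220] truncation range",
           call. = FALSE)
  }
  check_probs <- function(p, what, levels) {
    if (!all(names(p) %in% levels) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("'%s' must be a probability vector over: %s", what,
                   paste(levels, collapse = ", ")), call. = FALSE)
  }
  check_probs(o2_probs, "o2_probs", niche_classes()$o2)
  check_probs(temp_probs, "temp_probs", niche_classes()$temperature)
  if (any(phylum_probs < 0) || abs(sum(phylum_probs) - 1) > 1e-8)
    stop("'phylum_probs' must be a probability vector", call. = FALSE)
  structure(
    list(name = name, domain = domain,
         family_means = family_means[fams], dispersion = dispersion,
         seven_fe_rate = seven_fe_rate, length_mixture = length_mixture[fams],
         o2_probs = o2_probs, temp_probs = temp_probs,
         phylum_probs = phylum_probs,
         ph_mean = ph_mean, ph_sd = ph_sd, ph_present = ph_present,
         decoy_rate = decoy_rate, decoy_gene_rate = decoy_gene_rate),
    class = "pec_archetype"
  )
}

mixture <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- c("center", "spread", "weight")
  m
}

#' Default archetype mix emulating a large finished-genome collection
#'
#' Three archetypes with the sample sizes and domain-level abundance
#' structure of a 7,079-genome survey: 275 archaea averaging ~12.7 PEC
#' genes/genome dominated by [4Fe-4S] Fds, 6,733 bacteria averaging ~7.9
#' with a balanced mix, and 71 eukaryotes averaging ~2.8 dominated by
#' [2Fe-2S] Fds. Negative binomial dispersions are solved from the
#' domain-level total standard deviations (5.7, 6.2, 5.3); length-mixture
#' modes sit at the family mode positions seen in genome data (~70/110/170,
#' ~90/110/160 and ~150/170/200 residues).
#'
#' @param scale multiplier on the per-archetype organism counts (use a value
#'   `< 1` for quick test-sized datasets; counts are rounded and kept
#'   `>= 1`).
#' @return list of `list(config = pec_archetype, n = integer)` entries.
#' @export
default_archetypes <- function(scale = 1) {
  stopifnot(scale > 0)
  n_of <- function(n) max(1L, as.integer(round(n * scale)))
  list(
    archaeon = list(
      config = pec_archetype(
        name = "archaeon-like", domain = "Archaea",
        family_means = c(fd4 = 10.6, fd2 = 1.0, fld = 1.1),
        dispersion = 5.8, seven_fe_rate = 0.05,
        length_mixture = list(
          fd4 = mixture(c(70, 8, 0.45), c(110, 10, 0.35), c(170, 12, 0.20)),
          fd2 = mixture(c(90, 7, 0.50), c(110, 8, 0.25), c(160, 12, 0.25)),
          fld = mixture(c(150, 8, 0.45), c(170, 8, 0.35), c(200, 10, 0.20))
        ),
        o2_probs = c("obligate anaerobe" = 0.25, anaerobe = 0.40,
                     facultative = 0.10, microaerophilic = 0.02,
                     aerobe = 0.15, "obligate aerobe" = 0.08),
        temp_probs = c(psychrophile = 0.02, mesophile = 0.38,
                       thermophile = 0.40, hyperthermophile = 0.20),
        phylum_probs = c(Euryarchaeota = 0.70, Crenarchaeota = 0.25,
                         Thaumarchaeota = 0.05),
        ph_mean = 6.5, ph_sd = 1.5
      ),
      n = n_of(275)
    ),
    bacterium = list(
      config = pec_archetype(
        name = "bacterium-like", domain = "Bacteria",
        family_means = c(fd4 = 4.2, fd2 = 2.0, fld = 1.7),
        dispersion = 0.8, seven_fe_rate = 0.12,
        length_mixture = list(
          fd4 = mixture(c(70, 8, 0.45), c(110, 10, 0.35), c(170, 12, 0.20)),
          fd2 = mixture(c(90, 7, 0.50), c(110, 8, 0.25), c(160, 12, 0.25)),
          fld = mixture(c(150, 8, 0.45), c(170, 8, 0.35), c(200, 10, 0.20))
        ),
        o2_probs = c("obligate anaerobe" = 0.08, anaerobe = 0.17,
                     facultative = 0.35, microaerophilic = 0.05,
                     aerobe = 0.25, "obligate aerobe" = 0.10),
        temp_probs = c(psychrophile = 0.05, mesophile = 0.85,
                       thermophile = 0.08, hyperthermophile = 0.02),
        phylum_probs = c(Proteobacteria = 0.40, Firmicutes = 0.25,
                         Actinobacteria = 0.15, Bacteroidetes = 0.10,
                         Cyanobacteria = 0.10),
        ph_mean = 7.0, ph_sd = 1.0
      ),
      n = n_of(6733)
    ),
    eukaryote = list(
      config = pec_archetype(
        name = "eukaryote-like", domain = "Eukaryota",
        family_means = c(fd4 = 0.3, fd2 = 2.1, fld = 0.4),
        dispersion = 0.2, seven_fe_rate = 0.10,
        length_mixture = list(
          fd4 = mixture(c(70, 8, 0.45), c(110, 10, 0.35), c(170, 12, 0.20)),
          fd2 = mixture(c(90, 7, 0.40), c(110, 8, 0.30), c(160, 12, 0.30)),
          fld = mixture(c(150, 8, 0.45), c(170, 8, 0.35), c(200, 10, 0.20))
        ),
        o2_probs = c("obligate anaerobe" = 0.02, anaerobe = 0.03,
                     facultative = 0.25, microaerophilic = 0.00,
                     aerobe = 0.55, "obligate aerobe" = 0.15),
        temp_probs = c(psychrophile = 0.05, mesophile = 0.93,
                       thermophile = 0.02, hyperthermophile = 0.00),
        phylum_probs = c(Streptophyta = 0.15, Ascomycota = 0.45,
                         Chordata = 0.20, Chlorophyta = 0.20),
        ph_mean = 7.0, ph_sd = 0.8
      ),
      n = n_of(71)
    )
  )
}

DECOY_ACCESSION <- "IPR999999"

fam_accession <- c(fd4 = "IPR017896", fd2 = "IPR001041", fld = "IPR008254")

# one truncated-Gaussian-mixture length draw batch
sample_lengths <- function(n, mix) {
  if (n == 0L) return(integer(0))
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix[, "weight"])
  out <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      v <- round(rnorm(1, mix[comp[i], "center"], mix[comp[i], "spread"]))
      if (v >= 40 && v <= 220) break
    }
    out[i] <- v
  }
  out
}

sample_cat <- function(p) {
  if (sum(p > 0) == 0L) return(NA_character_)
  names(p)[sample.int(length(p), 1L, prob = p)]
}

#' Generate a synthetic census dataset
#'
#' Draws, for each archetype, `n` organisms with seeded per-organism
#' substreams (the substream seed depends only on the dataset seed and the
#' organism's position, so regenerating with the same arguments is
#' byte-identical). Each organism gets negative binomial family gene
#' counts, per-gene lengths from the archetype's truncated mixtures
#' (including some above 200 residues), 7Fe flags on [4Fe-4S] genes,
#' occasional decoy accessions, niche labels and pH. A random binary tree
#' over the organism ids is included whenever there are at least two
#' organisms.
#'
#' @param archetypes list of `list(config = pec_archetype, n = count)`
#'   entries, e.g. from [default_archetypes()].
#' @param seed integer seed.
#' @return object of class `pec_synthetic_dataset`: list with `genes`
#'   (gene annotation table in the ingest dialect), `metadata` (organism
#'   metadata table), `tree` (Newick text or `NULL`), `seed`, `archetypes`.
#' @export
generate_census_dataset <- function(archetypes = default_archetypes(),
                                    seed = 1L) {
  seed <- check_count(seed, "seed", min = 0L)
  for (a in archetypes) {
    if (!inherits(a$config, "pec_archetype"))
      stop("each archetype entry needs a 'config' of class pec_archetype",
           call. = FALSE)
    if (length(a$n) != 1L || is.na(a$n) || a$n < 0 || a$n != floor(a$n))
      stop("archetype organism count 'n' must be a non-negative integer",
           call. = FALSE)
  }
  meta_rows <- list()
  gene_rows <- list()
  org_index <- 0L
  for (a in archetypes) {
    cfg <- a$config
    slug <- gsub("[^a-z0-9]+", "_", tolower(cfg$name))
    for (i in seq_len(a$n)) {
      org_index <- org_index + 1L
      org_id <- sprintf("%s_%05d", slug, i)
      # per-organism substream: depends only on (seed, position)
      sub_seed <- (seed + 1009L * org_index) %% 2147483647L
      drawn <- with_seed(sub_seed, draw_organism(cfg, org_id))
      meta_rows[[org_index]] <- drawn$meta
      gene_rows[[org_index]] <- drawn$genes
    }
  }
  metadata <- if (length(meta_rows)) do.call(rbind, meta_rows) else
    data.frame(organism_id = character(), domain = character(),
               phylum = character(), class = character(), o2 = character(),
               temperature = character(), ph = numeric())
  genes <- do.call(rbind, gene_rows[!vapply(gene_rows, is.null, logical(1))])
  if (is.null(genes))
    genes <- data.frame(organism_id = character(), gene_id = character(),
                        length_aa = integer(), ipr_accessions = character())
  rownames(metadata) <- rownames(genes) <- NULL
  tree <- if (nrow(metadata) >= 2L)
    generate_tree(metadata$organism_id, seed = seed) else NULL
  structure(
    list(genes = genes, metadata = metadata, tree = tree, seed = seed,
         archetypes = archetypes),
    class = "pec_synthetic_dataset"
  )
}

# draw one organism (RNG already seeded by the caller)
draw_organism <- function(cfg, org_id) {
  fams <- names(pec_families())
  counts <- vapply(fams, function(f) {
    mu <- cfg$family_means[[f]]
    if (mu == 0) return(0L)
    if (is.infinite(cfg$dispersion)) as.integer(rpois(1L, mu))
    else as.integer(rnbinom(1L, mu = mu, size = cfg$dispersion))
  }, integer(1))
  g <- 0L
  rows <- list()
  for (f in fams) {
    n <- counts[[f]]
    if (n == 0L) next
    lens <- sample_lengths(n, cfg$length_mixture[[f]])
    seven <- if (f == "fd4") runif(n) < cfg$seven_fe_rate else rep(FALSE, n)
    decoy <- runif(n) < cfg$decoy_rate
    for (j in seq_len(n)) {
      g <- g + 1L
      accs <- fam_accession[[f]]
      if (seven[j]) accs <- c(accs, "IPR000813")
      if (decoy[j]) accs <- c(accs, DECOY_ACCESSION)
      rows[[g]] <- data.frame(
        organism_id = org_id, gene_id = sprintf("%s_g%03d", org_id, g),
        length_aa = lens[j], ipr_accessions = paste(accs, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (runif(1) < cfg$decoy_gene_rate) {
    g <- g + 1L
    rows[[g]] <- data.frame(
      organism_id = org_id, gene_id = sprintf("%s_g%03d", org_id, g),
      length_aa = sample(40:220, 1L), ipr_accessions = DECOY_ACCESSION,
      stringsAsFactors = FALSE
    )
  }
  ph <- if (runif(1) < cfg$ph_present)
    min(14, max(0, round(rnorm(1, cfg$ph_mean, cfg$ph_sd), 1))) else NA_real_
  meta <- data.frame(
    organism_id = org_id, domain = cfg$domain,
    phylum = sample_cat(cfg$phylum_probs), class = NA_character_,
    o2 = sample_cat(cfg$o2_probs), temperature = sample_cat(cfg$temp_probs),
    ph = ph, stringsAsFactors = FALSE
  )
  list(meta = meta, genes = if (g > 0L) do.call(rbind, rows) else NULL)
}

#' Generate a random binary tree over organism ids
#'
#' @param organism_ids character vector of at least two distinct labels.
#' @param seed integer seed.
#' @return Newick text of a rooted binary tree whose leaf set equals
#'   `organism_ids`.
#' @export
generate_tree <- function(organism_ids, seed = 1L) {
  organism_ids <- as.character(organism_ids)
  if (length(organism_ids) < 2L)
    stop("at least two organism ids are required", call. = FALSE)
  if (anyDuplicated(organism_ids))
    stop("duplicate organism ids: ",
         organism_ids[duplicated(organism_ids)][1], call. = FALSE)
  seed <- check_count(seed, "seed", min = 0L)
  tree <- with_seed(seed,
                    ape::rtree(length(organism_ids), rooted = TRUE,
                               tip.label = organism_ids))
  ape::write.tree(tree)
}

#' @export
print.pec_synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic PEC dataset (seed %d): %d organisms, %d gene rows\n",
              x$seed, nrow(x$metadata), nrow(x$genes)))
  for (a in x$archetypes)
    cat(sprintf("  %s: %d organisms (means fd4=%.1f fd2=%.1f fld=%.1f)\n",
                a$config$name, a$n, a$config$family_means[["fd4"]],
                a$config$family_means[["fd2"]], a$config$family_means[["fld"]]))
  invisible(x)
}

#' Write a synthetic dataset to disk in the ingest dialects
#'
#' Emits `genes.tsv` and `metadata.tsv` in the tab-separated layouts the
#' ingest functions consume, the tree as `tree.nwk` (when present), and a
#' declarative `config.txt` recording the seed and every archetype
#' parameter.
#'
#' @param dataset a `pec_synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genes = file.path(dir, "genes.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             config = file.path(dir, "config.txt"))
  write.table(dataset$genes, paths[["genes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$metadata, paths[["metadata"]], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  if (!is.null(dataset$tree)) {
    paths[["tree"]] <- file.path(dir, "tree.nwk")
    writeLines(dataset$tree, paths[["tree"]])
  }
  cfg <- c(sprintf("seed = %d", dataset$seed))
  for (a in dataset$archetypes) {
    c0 <- a$config
    cfg <- c(cfg, "", sprintf("[archetype %s]", c0$name),
             sprintf("domain = %s", c0$domain),
             sprintf("n_organisms = %d", a$n),
             sprintf("mean_fd4 = %g", c0$family_means[["fd4"]]),
             sprintf("mean_fd2 = %g", c0$family_means[["fd2"]]),
             sprintf("mean_fld = %g", c0$family_means[["fld"]]),
             sprintf("dispersion = %g", c0$dispersion),
             sprintf("seven_fe_rate = %g", c0$seven_fe_rate),
             sprintf("ph_mean = %g", c0$ph_mean),
             sprintf("ph_sd = %g", c0$ph_sd),
             sprintf("ph_present = %g", c0$ph_present))
    for (f in names(c0$length_mixture)) {
      m <- c0$length_mixture[[f]]
      cfg <- c(cfg, sprintf("mixture_%s = %s", f,
                            paste(apply(m, 1, paste, collapse = ":"),
                                  collapse = "; ")))
    }
  }
  writeLines(cfg, paths[["config"]])
  invisible(paths)
}
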