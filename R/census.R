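#' @rdname build_census
#' @param x data frame with the census columns.
#' @export
as_pec_census <- function(x) {
  need <- c("organism_id", "domain", "n_fd4", "n_fd2", "n_fld", "n_7fe", "total")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("not a census table; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(x$organism_id))
    stop("census organism ids are not unique", call. = FALSE)
  counts <- x[c("n_fd4", "n_fd2", "n_fld", "n_7fe")]
  if (any(vapply(counts, function(v) any(is.na(v) | v < 0), logical(1))))
    stop("census counts must be non-negative", call. = FALSE)
  if (any(x$total != x$n_fd4 + x$n_fd2 + x$n_fld))
    stop("census total must equal n_fd4 + n_fd2 + n_fld", call. = FALSE)
  if (any(x$n_7fe > x$n_fd4))
    stop("n_7fe cannot exceed n_fd4", call. = FALSE)
  class(x) <- unique(c("pec_census", class(x)))
  x
}

#' Build the per-organism PEC census
#'
#' Counts, for every organism in `meta`, the length-filtered genes matching
#' each family signature. Counting is per signature: a gene carrying both Fd
#' cluster signatures increments both family counts. The `total` column sums
#' the three family counts; the 7Fe count is the subset of [4Fe-4S] genes
#' also carrying the 7Fe signature and is never added to the total.
#' Organisms present in `meta` with no matching genes keep all-zero counts —
#' the census must represent PEC-free genomes explicitly.
#'
#' Genes referencing organisms absent from `meta`, unknown accessions, and
#' multi-family genes are tallied in the `diagnostics` attribute rather than
#' silently dropped.
#'
#' @param genes gene data frame from [read_gene_annotations()] (or the
#'   synthetic generator).
#' @param meta organism metadata data frame from [read_organism_metadata()].
#' @param map a [pec_signature_map()].
#' @param apply_filter apply the map's length cutoff before counting
#'   (default `TRUE`; set `FALSE` if `records` were filtered already).
#' @return a `pec_census` data frame: one row per organism with taxonomy,
#'   raw niche labels, `ph`, counts `n_fd4`, `n_fd2`, `n_fld`, `n_7fe` and
#'   `total`, plus a `diagnostics` attribute.
#' @export
build_census <- function(genes, meta, map = pec_signature_map(),
                         apply_filter = TRUE) {
  genes <- as_gene_records(genes)
  if (apply_filter) genes <- apply_length_filter(genes, map$length_cutoff)
  cls <- classify_signature_table(genes$signatures, map)
  matched <- genes$organism_id %in% meta$organism_id
  unmatched <- genes[!matched, , drop = FALSE]

  tally <- function(flag) {
    v <- integer(nrow(meta))
    names(v) <- meta$organism_id
    if (any(flag & matched)) {
      t <- table(genes$organism_id[flag & matched])
      v[names(t)] <- as.integer(t)
    }
    unname(v)
  }
  n_fd4 <- tally(cls$fd4)
  n_fd2 <- tally(cls$fd2)
  n_fld <- tally(cls$fld)
  n_7fe <- tally(cls$fd4 & cls$seven_fe)

  census <- data.frame(
    organism_id = meta$organism_id,
    domain = canonical_domain(meta$domain),
    phylum = meta$phylum %||% NA_character_,
    class = meta$class %||% NA_character_,
    o2 = meta$o2 %||% NA_character_,
    temperature = meta$temperature %||% NA_character_,
    ph = meta$ph %||% NA_real_,
    n_fd4 = n_fd4, n_fd2 = n_fd2, n_fld = n_fld, n_7fe = n_7fe,
    total = n_fd4 + n_fd2 + n_fld,
    stringsAsFactors = FALSE
  )
  census <- as_pec_census(census)
  attr(census, "diagnostics") <- list(
    unmatched_organism_genes = unmatched,
    unknown_accessions = attr(cls, "unknown_accessions"),
    n_multi_family = sum(rowSums(cls[c("fd4", "fd2", "fld")]) > 1L),
    n_genes_counted = sum(matched)
  )
  census
}

#' @export
print.pec_census <- function(x, ...) {
  cat(sprintf("PEC census: %d organisms, %d PEC genes total\n",
              nrow(x), sum(x$total)))
  fams <- pec_families()
  cat(sprintf("  %s: %d | %s: %d | %s: %d | 7Fe-flagged: %d\n",
              fams[["fd4"]], sum(x$n_fd4), fams[["fd2"]], sum(x$n_fd2),
              fams[["fld"]], sum(x$n_fld), sum(x$n_7fe)))
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more organisms\n", nrow(x) - 6L))
  invisible(x)
}

#' Group-wise abundance summaries
#'
#' Mean and sample (n-1) standard deviation of the per-genome gene counts,
#' per family and for the total, within each level of a grouping column.
#' Organisms with a missing or empty group value fall into `"unclassified"`.
#' Groups are ordered by descending mean total, ties broken alphabetically —
#' the ordering used for phylum-level league tables.
#'
#' @param census a `pec_census`.
#' @param by grouping column: one of `"domain"`, `"phylum"`, `"class"`, or a
#'   vector of custom labels of length `nrow(census)`.
#' @return data frame with columns `group`, `n`, and `mean_*`/`sd_*` for
#'   `fd4`, `fd2`, `fld`, `total`. The `sd_convention` attribute records the
#'   estimator used.
#' @export
summarize_by_group <- function(census, by = "domain") {
  if (length(by) == 1L && is.character(by)) {
    if (!by %in% names(census))
      stop("no such grouping column in census: ", by, call. = FALSE)
    g <- census[[by]]
  } else {
    if (length(by) != nrow(census))
      stop("custom grouping must have one label per organism", call. = FALSE)
    g <- as.character(by)
  }
  g[is.na(g) | !nzchar(trimws2(g))] <- "unclassified"
  if (nrow(census) == 0L) {
    out <- data.frame(group = character(), n = integer())
    for (f in c("fd4", "fd2", "fld", "total")) {
      out[[paste0("mean_", f)]] <- numeric()
      out[[paste0("sd_", f)]] <- numeric()
    }
    return(out)
  }
  groups <- sort(unique(g))
  rows <- lapply(groups, function(lev) {
    sub <- census[g == lev, , drop = FALSE]
    row <- data.frame(group = lev, n = nrow(sub), stringsAsFactors = FALSE)
    for (f in c("fd4", "fd2", "fld")) {
      v <- sub[[paste0("n_", f)]]
      row[[paste0("mean_", f)]] <- mean(v)
      row[[paste0("sd_", f)]] <- sd0(v)
    }
    row$mean_total <- mean(sub$total)
    row$sd_total <- sd0(sub$total)
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_total, out$group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sd_convention") <- "sample (n-1); 0 for single-organism groups"
  out
}

#' Histogram of per-organism gene counts
#'
#' @param census a `pec_census`.
#' @param which `"total"` or a family code (`"fd4"`, `"fd2"`, `"fld"`).
#' @return data frame `count`, `n_organisms` over the observed integer
#'   counts; the `n_organisms` column sums to `nrow(census)`.
#' @export
abundance_histogram <- function(census, which = c("total", "fd4", "fd2", "fld")) {
  which <- match.arg(which)
  v <- if (which == "total") census$total else census[[paste0("n_", which)]]
  t <- table(v)
  data.frame(count = as.integer(names(t)), n_organisms = as.integer(t))
}

#' Pairwise abundance matrix for two PEC families
#'
#' Cross-tabulates per-organism counts of two families and reports the four
#' quadrant fractions at an abundance threshold: organisms with fewer than
#' `threshold` genes of both types, at least `threshold` of both, and the two
#' mixed quadrants. The fractions partition the census and sum to 1.
#'
#' @param census a `pec_census`.
#' @param fam_a,fam_b distinct family codes (`"fd4"`, `"fd2"`, `"fld"`).
#' @param threshold integer abundance threshold (default 4).
#' @return object of class `pec_pairwise`: list with `matrix` (long data
#'   frame `count_a`, `count_b`, `n`), `quadrants` (named fractions
#'   `both_below`, `a_high_b_low`, `a_low_b_high`, `both_at_or_above`),
#'   `families`, `threshold`, `n_organisms`.
#' @export
pairwise_matrix <- function(census, fam_a, fam_b, threshold = 4L) {
  fams <- names(pec_families())
  fam_a <- match.arg(fam_a, fams)
  fam_b <- match.arg(fam_b, fams)
  if (fam_a == fam_b) stop("fam_a and fam_b must differ", call. = FALSE)
  threshold <- check_count(threshold, "threshold", min = 1L)
  a <- census[[paste0("n_", fam_a)]]
  b <- census[[paste0("n_", fam_b)]]
  tab <- as.data.frame(table(count_a = a, count_b = b), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  mat <- data.frame(count_a = as.integer(tab$count_a),
                    count_b = as.integer(tab$count_b),
                    n = as.integer(tab$Freq))
  mat <- mat[order(mat$count_a, mat$count_b), , drop = FALSE]
  rownames(mat) <- NULL
  n <- length(a)
  quadrants <- c(
    both_below = sum(a < threshold & b < threshold),
    a_high_b_low = sum(a >= threshold & b < threshold),
    a_low_b_high = sum(a < threshold & b >= threshold),
    both_at_or_above = sum(a >= threshold & b >= threshold)
  ) / n
  structure(
    list(matrix = mat, quadrants = quadrants,
         families = c(a = fam_a, b = fam_b),
         threshold = threshold, n_organisms = n),
    class = "pec_pairwise"
  )
}

#' @export
print.pec_pairwise <- function(x, ...) {
  fams <- pec_families()
  cat(sprintf("Pairwise PEC abundance: %s vs %s (threshold %d, %d organisms)\n",
              fams[[x$families[["a"]]]], fams[[x$families[["b"]]]],
              x$threshold, x$n_organisms))
  q <- round(100 * x$quadrants, 1)
  cat(sprintf("  both < t: %s%% | a >= t only: %s%% | b >= t only: %s%% | both >= t: %s%%\n",
              q[["both_below"]], q[["a_high_b_low"]],
              q[["a_low_b_high"]], q[["both_at_or_above"]]))
  invisible(x)
}

#' Classify organisms as PEC specialists or generalists
#'
#' `"none"` when all three family counts are zero, `"specialist"` when
#' exactly one family is present, `"generalist"` when two or more are.
#'
#' @param census a `pec_census` (or any data frame with the three count
#'   columns).
#' @return character vector, one label per organism.
#' @export
classify_strategy <- function(census) {
  k <- (census$n_fd4 > 0L) + (census$n_fd2 > 0L) + (census$n_fld > 0L)
  c("none", "specialist", "generalist", "generalist")[k + 1L]
}

#' Fractions of PEC-free, specialist and generalist organisms
#'
#' @param census a `pec_census`.
#' @return named numeric vector of fractions (`none`, `specialist`,
#'   `generalist`) summing to 1.
#' @export
strategy_fractions <- function(census) {
  s <- factor(classify_strategy(census),
              levels = c("none", "specialist", "generalist"))
  f <- as.vector(table(s)) / nrow(census)
  names(f) <- levels(s)
  f
}
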