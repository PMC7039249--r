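#' Long table of classified, length-filtered gene lengths
#'
#' One row per (gene, family) membership — a gene matching two family
#' signatures contributes its length to both families, consistent with the
#' per-signature census counts. Each row carries the host organism's
#' normalized niche classes and its total PEC count from the census, the
#' three grouping axes of the length analyses.
#'
#' @param genes gene data frame (as from [read_gene_annotations()]).
#' @param census the `pec_census` built from the same genes and metadata.
#' @param map a [pec_signature_map()].
#' @param apply_filter apply the map's length cutoff first (default `TRUE`).
#' @return data frame `organism_id`, `gene_id`, `length`, `family`,
#'   `seven_fe`, `o2_class`, `temp_class`, `total_pec`.
#' @export
gene_length_table <- function(genes, census, map = pec_signature_map(),
                              apply_filter = TRUE) {
  genes <- as_gene_records(genes)
  if (apply_filter) genes <- apply_length_filter(genes, map$length_cutoff)
  cls <- classify_signature_table(genes$signatures, map)
  o2 <- census_niche_axis(census, "o2")
  temp <- census_niche_axis(census, "temperature")
  ridx <- match(genes$organism_id, census$organism_id)
  rows <- lapply(names(pec_families()), function(f) {
    sel <- cls[[f]] & !is.na(ridx)
    if (!any(sel)) return(NULL)
    data.frame(
      organism_id = genes$organism_id[sel],
      gene_id = genes$gene_id[sel],
      length = genes$length[sel],
      family = f,
      seven_fe = cls$seven_fe[sel],
      o2_class = o2[ridx[sel]],
      temp_class = temp[ridx[sel]],
      total_pec = census$total[ridx[sel]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(organism_id = character(), gene_id = character(),
                      length = integer(), family = character(),
                      seven_fe = logical(), o2_class = character(),
                      temp_class = character(), total_pec = integer())
  rownames(out) <- NULL
  out
}

#' Kernel-smoothed length density for one set of genes
#'
#' Gaussian-kernel density estimate evaluated on an integer residue grid
#' spanning `[min - 3*bw, max + 3*bw]` and renormalized so its trapezoidal
#' integral over the grid is exactly 1. The default bandwidth follows
#' Scott's rule, `sd(x) * n^(-1/5)`, with a floor of 1 residue so that
#' degenerate inputs (a single length value) still yield a proper density.
#'
#' @param lengths integer vector of gene lengths (residues); must be
#'   non-empty.
#' @param bandwidth numeric bandwidth in residues, or `"auto"` for Scott's
#'   rule.
#' @param family,group optional labels stored on the result.
#' @return object of class `pec_density`: list with `grid`, `density`,
#'   `n_genes`, `bandwidth`, `range` (min/max contributing length),
#'   `mean_length`, `family`, `group`.
#' @export
length_density <- function(lengths, bandwidth = "auto",
                           family = NA_character_, group = NA_character_) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L || any(is.na(lengths)))
    stop("'lengths' must be a non-empty numeric vector without NA", call. = FALSE)
  n <- length(lengths)
  bw <- if (identical(bandwidth, "auto")) {
    s <- if (n > 1L) sd(lengths) else 0
    max(1, s * n^(-1 / 5))
  } else {
    if (!is.numeric(bandwidth) || bandwidth <= 0)
      stop("'bandwidth' must be positive or \"auto\"", call. = FALSE)
    as.numeric(bandwidth)
  }
  grid <- seq(floor(min(lengths) - 3 * bw), ceiling(max(lengths) + 3 * bw))
  dens <- vapply(grid, function(g) mean(dnorm(g, mean = lengths, sd = bw)),
                 numeric(1))
  integral <- trapezoid(grid, dens)
  dens <- dens / integral
  structure(
    list(grid = grid, density = dens, n_genes = n, bandwidth = bw,
         range = c(min(lengths), max(lengths)), mean_length = mean(lengths),
         family = family, group = group),
    class = "pec_density"
  )
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.pec_density <- function(x, ...) {
  lab <- if (!is.na(x$family)) pec_families()[[x$family]] else "lengths"
  grp <- if (!is.na(x$group)) sprintf(" [group %s]", x$group) else ""
  cat(sprintf("Length density: %s%s, n = %d genes, bandwidth %.2f, range %d-%d, mean %.1f residues\n",
              lab, grp, x$n_genes, x$bandwidth, x$range[1], x$range[2],
              x$mean_length))
  invisible(x)
}

#' Length densities per family and grouping
#'
#' Splits a [gene_length_table()] by one grouping axis and computes one
#' smoothed density per (family, group). Grouping by `"total_pec"` bins the
#' host genome's total PEC count with `total_breaks` (left-closed; default
#' bins 1, 2, 3-5, 6-10, 11-20, 21+); the niche axes use the canonical
#' classes and drop unbinned organisms. Empty groups are omitted with a
#' message.
#'
#' @param length_table data frame from [gene_length_table()].
#' @param family family code to profile.
#' @param group `"total_pec"`, `"o2_class"` or `"temp_class"`.
#' @param bandwidth per-group bandwidth, or `"auto"`.
#' @param total_breaks increasing integer cut points for the total-PEC bins.
#' @return named list of `pec_density` objects, in group order.
#' @export
length_density_by <- function(length_table, family = c("fd4", "fd2", "fld"),
                              group = c("total_pec", "o2_class", "temp_class"),
                              bandwidth = "auto",
                              total_breaks = c(1, 2, 3, 6, 11, 21, Inf)) {
  family <- match.arg(family)
  group <- match.arg(group)
  sub <- length_table[length_table$family == family, , drop = FALSE]
  if (group == "total_pec") {
    labels <- total_bin_labels(total_breaks)
    key <- cut(sub$total_pec, breaks = c(total_breaks), right = FALSE,
               labels = labels)
    levels <- labels
  } else {
    key <- sub[[group]]
    levels <- niche_classes()[[if (group == "o2_class") "o2" else "temperature"]]
  }
  out <- list()
  for (lev in levels) {
    sel <- !is.na(key) & key == lev
    if (!any(sel)) {
      message(sprintf("length_density_by: no %s genes in group '%s'; omitted",
                      family, lev))
      next
    }
    out[[lev]] <- length_density(sub$length[sel], bandwidth = bandwidth,
                                 family = family, group = lev)
  }
  out
}

total_bin_labels <- function(breaks) {
  lo <- head(breaks, -1)
  hi <- breaks[-1] - 1
  ifelse(is.infinite(breaks[-1]), paste0(lo, "+"),
         ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi)))
}

#' Detect modes of a smoothed length density
#'
#' Local maxima of the density curve whose height is at least
#' `min_prominence` times the global peak, returned in increasing position
#' order. Plateaus count once (at their central grid point); a flat density
#' has no modes.
#'
#' @param density a `pec_density`.
#' @param min_prominence minimum height as a fraction of the global maximum
#'   (default 0.05).
#' @return data frame `position` (residues), `height`, `rel_height`
#'   (fraction of the global peak).
#' @export
detect_modes <- function(density, min_prominence = 0.05) {
  y <- density$density
  x <- density$grid
  n <- length(y)
  empty <- data.frame(position = numeric(), height = numeric(),
                      rel_height = numeric())
  if (n < 3L || max(y) <= 0 || diff(range(y)) == 0) return(empty)
  # collapse exact plateaus to single runs, then test run neighbours
  r <- rle(y)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(vals)
  pos <- numeric(0); ht <- numeric(0)
  for (i in seq_len(k)) {
    left <- if (i > 1L) vals[i - 1L] else -Inf
    right <- if (i < k) vals[i + 1L] else -Inf
    if (i == 1L || i == k) next  # grid extends 3 bw beyond data; edges are tails
    if (vals[i] > left && vals[i] > right) {
      centre <- x[floor((starts[i] + ends[i]) / 2)]
      pos <- c(pos, centre)
      ht <- c(ht, vals[i])
    }
  }
  keep <- ht >= min_prominence * max(y)
  out <- data.frame(position = pos[keep], height = ht[keep],
                    rel_height = ht[keep] / max(y))
  out[order(out$position), , drop = FALSE]
}
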