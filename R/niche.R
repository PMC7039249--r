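#' Canonical growth-niche classes
#'
#' Ordered oxygen-requirement and growth-temperature classes used on all
#' niche axes. The orderings are fixed: anaerobic to aerobic, and cold to
#' hot.
#'
#' @return list with character vectors `o2` and `temperature`.
#' @export
niche_classes <- function() {
  list(
    o2 = c("obligate anaerobe", "anaerobe", "facultative",
           "microaerophilic", "aerobe", "obligate aerobe"),
    temperature = c("psychrophile", "mesophile", "thermophile",
                    "hyperthermophile")
  )
}

#' Normalize a growth-niche label
#'
#' Case-insensitive mapping of raw metadata labels onto the canonical
#' classes. Exactly three tolerance labels are re-binned: `thermotolerant`
#' to `thermophile`, and `psychrotolerant`/`psychrotrophic` to
#' `psychrophile`. Every other label must already match a canonical class
#' name; anything else (including missing values) becomes `"unbinned"` —
#' labels are never guessed. Normalizing a canonical label returns it
#' unchanged (idempotence).
#'
#' @param raw character vector of raw labels.
#' @return character vector of canonical class names or `"unbinned"`.
#' @export
#' @examples
#' normalize_growth_label(c("Thermotolerant", "aerobe", "halotolerant"))
normalize_growth_label <- function(raw) {
  canon <- c(niche_classes()$o2, niche_classes()$temperature)
  extra <- c(thermotolerant = "thermophile",
             psychrotolerant = "psychrophile",
             psychrotrophic = "psychrophile")
  map <- c(stats::setNames(canon, tolower(canon)), extra)
  key <- tolower(trimws2(raw))
  out <- unname(map[key])
  out[is.na(out)] <- "unbinned"
  out
}

# normalized class labels for one axis of a census
census_niche_axis <- function(census, axis = c("o2", "temperature")) {
  axis <- match.arg(axis)
  normalize_growth_label(census[[axis]])
}

#' Per-niche-class abundance profile
#'
#' Mean gene counts per family and genome count within each oxygen or
#' temperature class, plus each family's share (percent) of the summed gene
#' counts of the class. Classes with no organisms are omitted; organisms
#' whose label does not normalize are excluded.
#'
#' @param census a `pec_census`.
#' @param axis `"o2"` or `"temperature"`.
#' @return data frame with one row per populated class, in canonical class
#'   order: `class`, `n`, `mean_fd4`, `mean_fd2`, `mean_fld`, `mean_total`,
#'   `share_fd4`, `share_fd2`, `share_fld` (shares in percent, summing to
#'   100 where the class has any genes).
#' @export
niche_profile <- function(census, axis = c("o2", "temperature")) {
  axis <- match.arg(axis)
  levels <- niche_classes()[[axis]]
  lab <- census_niche_axis(census, axis)
  rows <- lapply(levels, function(lev) {
    sub <- census[lab == lev, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sums <- c(fd4 = sum(sub$n_fd4), fd2 = sum(sub$n_fd2), fld = sum(sub$n_fld))
    tot <- sum(sums)
    shares <- if (tot > 0) 100 * sums / tot else c(fd4 = NA_real_, fd2 = NA_real_, fld = NA_real_)
    data.frame(class = lev, n = nrow(sub),
               mean_fd4 = mean(sub$n_fd4), mean_fd2 = mean(sub$n_fd2),
               mean_fld = mean(sub$n_fld), mean_total = mean(sub$total),
               share_fd4 = shares[["fd4"]], share_fd2 = shares[["fd2"]],
               share_fld = shares[["fld"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(class = character(), n = integer(),
                      mean_fd4 = numeric(), mean_fd2 = numeric(),
                      mean_fld = numeric(), mean_total = numeric(),
                      share_fd4 = numeric(), share_fd2 = numeric(),
                      share_fld = numeric())
  rownames(out) <- NULL
  out
}

#' Temperature-by-oxygen abundance grid
#'
#' Average per-genome gene counts of one family over the cross of
#' temperature and oxygen classes, with a companion genome-count grid.
#' Display values are rounded to two significant figures; cells with no
#' organisms are `"N/A"`. Full-precision values are retained in `values`.
#'
#' @param census a `pec_census`.
#' @param family family code (`"fd4"`, `"fd2"`, `"fld"`) or `"total"`.
#' @return object of class `pec_niche_grid`: list with numeric matrices
#'   `values` (full precision, `NA` when empty) and `counts` (genomes per
#'   cell), and character matrix `display`; rows are temperature classes
#'   (cold to hot), columns oxygen classes (anaerobic to aerobic).
#' @export
niche_grid <- function(census, family = c("fd4", "fd2", "fld", "total")) {
  family <- match.arg(family)
  col <- if (family == "total") "total" else paste0("n_", family)
  temp <- census_niche_axis(census, "temperature")
  o2 <- census_niche_axis(census, "o2")
  tl <- niche_classes()$temperature
  ol <- niche_classes()$o2
  values <- matrix(NA_real_, length(tl), length(ol), dimnames = list(tl, ol))
  counts <- matrix(0L, length(tl), length(ol), dimnames = list(tl, ol))
  for (ti in seq_along(tl)) for (oi in seq_along(ol)) {
    sel <- temp == tl[ti] & o2 == ol[oi]
    counts[ti, oi] <- sum(sel)
    if (any(sel)) values[ti, oi] <- mean(census[[col]][sel])
  }
  display <- matrix(format_sig2(values), nrow(values), ncol(values),
                    dimnames = dimnames(values))
  structure(list(values = values, counts = counts, display = display,
                 family = family),
            class = "pec_niche_grid")
}

# two-significant-figure display formatting; NA -> "N/A"
format_sig2 <- function(x) {
  out <- vapply(as.vector(x), function(v) {
    if (is.na(v)) "N/A" else format(signif(v, 2), scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' @export
print.pec_niche_grid <- function(x, ...) {
  cat(sprintf("Niche grid (%s): mean genes/genome over temperature x O2 classes\n",
              if (x$family == "total") "total PEC"
              else pec_families()[[x$family]]))
  print(x$display, quote = FALSE)
  invisible(x)
}

#' 7Fe fraction of [4Fe-4S] genes per oxygen class
#'
#' For each oxygen class, the fraction of [4Fe-4S] Fd genes that also carry
#' the 7Fe ferredoxin signature, pooled over the organisms of the class:
#' `sum(n_7fe) / sum(n_fd4)`. The fraction is reported as `NA` when the
#' class has no [4Fe-4S] genes. 7Fe ferredoxins bind one [3Fe-4S] cluster
#' and are a proposed oxygen-tolerance adaptation, so this fraction is
#' expected to rise with oxygen exposure.
#'
#' @param census a `pec_census`.
#' @return data frame `class`, `n_organisms`, `n_fd4_genes`, `n_7fe_genes`,
#'   `fraction`, one row per populated oxygen class in canonical order.
#' @export
seven_fe_fractions <- function(census) {
  lab <- census_niche_axis(census, "o2")
  rows <- lapply(niche_classes()$o2, function(lev) {
    sub <- census[lab == lev, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    d4 <- sum(sub$n_fd4); d7 <- sum(sub$n_7fe)
    data.frame(class = lev, n_organisms = nrow(sub),
               n_fd4_genes = d4, n_7fe_genes = d7,
               fraction = if (d4 > 0) d7 / d4 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(class = character(), n_organisms = integer(),
                      n_fd4_genes = integer(), n_7fe_genes = integer(),
                      fraction = numeric())
  rownames(out) <- NULL
  out
}

#' Per-pH normalized abundance profile
#'
#' For every distinct external pH value observed in the census, the summed
#' family gene counts divided by the number of organisms at that pH.
#' Organisms without a pH annotation are excluded from this profile only.
#'
#' @param census a `pec_census`.
#' @return data frame `ph`, `n_organisms`, `avg_fd4`, `avg_fd2`, `avg_fld`,
#'   sorted by pH.
#' @export
ph_profile <- function(census) {
  sub <- census[!is.na(census$ph), , drop = FALSE]
  phs <- sort(unique(sub$ph))
  rows <- lapply(phs, function(p) {
    s <- sub[sub$ph == p, , drop = FALSE]
    data.frame(ph = p, n_organisms = nrow(s),
               avg_fd4 = sum(s$n_fd4) / nrow(s),
               avg_fd2 = sum(s$n_fd2) / nrow(s),
               avg_fld = sum(s$n_fld) / nrow(s))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ph = numeric(), n_organisms = integer(),
                      avg_fd4 = numeric(), avg_fd2 = numeric(),
                      avg_fld = numeric())
  rownames(out) <- NULL
  out
}

#' Weighted pH statistics and paired family comparisons
#'
#' Treats each family's per-pH normalized count profile as a weight function
#' over pH: the weighted mean pH of a family tells where on the pH axis its
#' genes concentrate. The weighted standard deviation uses the
#' frequency-weight population form `sqrt(sum(w*(x-xw)^2)/sum(w))`. Family
#' pairs are compared with a paired two-tailed t-test over the pH bins
#' shared by both profiles (the per-pH normalized counts are the paired
#' values); with `weights = "raw"` the summed (un-normalized) counts per pH
#' are used instead. Degenerate pairings with zero-variance differences are
#' reported as `p = 1` when all differences are zero and `p = 0` for a
#' constant nonzero difference.
#'
#' @param profile data frame from [ph_profile()].
#' @param weights `"normalized"` (default) or `"raw"`.
#' @return object of class `pec_ph_stats`: list with `families` (data frame
#'   `family`, `weighted_mean_ph`, `weighted_sd_ph`), `pairs` (data frame
#'   `family_a`, `family_b`, `t`, `df`, `p`, `n_bins`), `n_bins`,
#'   `weights`, and `sd_convention`.
#' @export
ph_weighted_comparison <- function(profile, weights = c("normalized", "raw")) {
  weights <- match.arg(weights)
  fams <- names(pec_families())
  w <- lapply(fams, function(f) {
    v <- profile[[paste0("avg_", f)]]
    if (weights == "raw") v <- v * profile$n_organisms
    v
  })
  names(w) <- fams
  x <- profile$ph

  fam_stats <- do.call(rbind, lapply(fams, function(f) {
    wf <- w[[f]]
    if (sum(wf) <= 0) {
      data.frame(family = f, weighted_mean_ph = NA_real_,
                 weighted_sd_ph = NA_real_)
    } else {
      m <- sum(wf * x) / sum(wf)
      s <- sqrt(sum(wf * (x - m)^2) / sum(wf))
      data.frame(family = f, weighted_mean_ph = m, weighted_sd_ph = s)
    }
  }))

  combos <- utils::combn(fams, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    fa <- combos[1, i]; fb <- combos[2, i]
    d <- w[[fa]] - w[[fb]]
    n <- length(d)
    if (n < 2L) {
      return(data.frame(family_a = fa, family_b = fb, t = NA_real_,
                        df = NA_real_, p = NA_real_, n_bins = n))
    }
    if (sd(d) == 0) {
      p <- if (all(d == 0)) 1 else 0
      return(data.frame(family_a = fa, family_b = fb, t = NA_real_,
                        df = n - 1, p = p, n_bins = n))
    }
    tt <- stats::t.test(w[[fa]], w[[fb]], paired = TRUE,
                        alternative = "two.sided")
    data.frame(family_a = fa, family_b = fb,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n_bins = n)
  }))
  rownames(fam_stats) <- rownames(pairs) <- NULL
  structure(
    list(families = fam_stats, pairs = pairs, n_bins = nrow(profile),
         weights = weights,
         sd_convention = "frequency-weight population form sum(w*(x-xw)^2)/sum(w)"),
    class = "pec_ph_stats"
  )
}

#' @export
print.pec_ph_stats <- function(x, ...) {
  cat(sprintf("Weighted pH statistics over %d pH bins (%s counts)\n",
              x$n_bins, x$weights))
  print.data.frame(x$families, digits = 4)
  cat("Paired two-tailed t-tests over shared pH bins:\n")
  print.data.frame(x$pairs, digits = 4)
  invisible(x)
}
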