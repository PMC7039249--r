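#' Ternary compositional binning of PEC gene pools
#'
#' Each organism's three family counts are normalized to percentages summing
#' to 100 and assigned to a triangular grid cell of side `step` percent.
#' Cells come in two orientations: "up" cells indexed by `(i, j, k)` with
#' `i + j + k = 100/step - 1` covering the region where each coordinate `l`
#' satisfies `p_l >= index_l * step`, and "down" cells with
#' `i + j + k = 100/step - 2` covering `p_l <= (index_l + 1) * step`.
#' Cell index `i` corresponds to the [4Fe-4S] axis, `j` to [2Fe-2S], `k` to
#' Fld, each spanning `[index*step, (index+1)*step]` percent.
#'
#' Boundary handling follows the published procedure: a composition lying on
#' the closed boundary of two or more cells is placed uniformly at random in
#' one of the adjoining cells, under the supplied seed. Boundary detection
#' uses exact integer arithmetic on `count/total` (no floating-point
#' epsilons): the adjoining set is every cell whose closed region contains
#' the point. Organisms with zero total are excluded and counted in
#' `n_excluded`.
#'
#' @param census a `pec_census`.
#' @param step bin width in percent; must divide 100 (default 10).
#' @param seed integer seed for boundary resolution.
#' @return object of class `pec_ternary`: list with `bins` (data frame
#'   `i_fd4`, `i_fd2`, `i_fld`, `orientation`, `n`), `step`, `n_excluded`,
#'   `n_organisms`, `seed`.
#' @export
ternary_bins <- function(census, step = 10L, seed = 1L) {
  step <- check_count(step, "step", min = 1L)
  if (100L %% step != 0L)
    stop("'step' must divide 100 evenly", call. = FALSE)
  seed <- check_count(seed, "seed", min = 0L)
  ncell <- 100L %/% step

  counts <- cbind(census$n_fd4, census$n_fd2, census$n_fld)
  totals <- census$total
  keep <- totals > 0L
  n_excluded <- sum(!keep)

  assign_one <- function(c3, total) {
    cells <- adjoining_ternary_cells(c3, total, ncell)
    if (nrow(cells) == 1L) return(cells)
    cells[sample.int(nrow(cells), 1L), , drop = FALSE]
  }

  assigned <- with_seed(seed, {
    idx <- which(keep)
    do.call(rbind, lapply(idx, function(i) assign_one(counts[i, ], totals[i])))
  })

  if (is.null(assigned)) {
    bins <- data.frame(i_fd4 = integer(), i_fd2 = integer(), i_fld = integer(),
                       orientation = character(), n = integer())
  } else {
    key <- paste(assigned$i, assigned$j, assigned$k, sep = ",")
    t <- table(key)
    parts <- do.call(rbind, strsplit(names(t), ",", fixed = TRUE))
    bins <- data.frame(
      i_fd4 = as.integer(parts[, 1]),
      i_fd2 = as.integer(parts[, 2]),
      i_fld = as.integer(parts[, 3]),
      n = as.integer(t)
    )
    bins$orientation <- ifelse(bins$i_fd4 + bins$i_fd2 + bins$i_fld == ncell - 1L,
                               "up", "down")
    bins <- bins[order(bins$i_fd4, bins$i_fd2, bins$i_fld),
                 c("i_fd4", "i_fd2", "i_fld", "orientation", "n")]
    rownames(bins) <- NULL
  }
  structure(
    list(bins = bins, step = step, n_excluded = n_excluded,
         n_organisms = nrow(census), seed = seed),
    class = "pec_ternary"
  )
}

#' Enumerate the ternary cells whose closed region contains a composition
#'
#' Exact integer arithmetic: the point in cell units along axis `l` is
#' `ncell * c_l / total`; it lies on a cell boundary on that axis iff
#' `ncell * c_l` is divisible by `total`. Candidate index ranges per axis are
#' expanded at boundaries, and candidate triples are kept when they form a
#' valid up/down cell whose closed region contains the point.
#'
#' @param c3 integer vector of the three family counts.
#' @param total their sum (must be positive).
#' @param ncell number of cells per edge (`100/step`).
#' @return data frame of cell index triples `i`, `j`, `k` (one row per
#'   adjoining cell; a single row for interior points).
#' @keywords internal
adjoining_ternary_cells <- function(c3, total, ncell) {
  stopifnot(total > 0L, sum(c3) == total)
  num <- as.integer(ncell) * as.integer(c3)  # position * total, per axis
  lo <- num %/% total
  on_boundary <- (num %% total) == 0L
  cand <- lapply(1:3, function(l) {
    v <- if (on_boundary[l]) c(lo[l] - 1L, lo[l]) else lo[l]
    v[v >= 0L & v <= ncell - 1L]
  })
  grid <- expand.grid(i = cand[[1]], j = cand[[2]], k = cand[[3]])
  s <- grid$i + grid$j + grid$k
  ok <- logical(nrow(grid))
  up <- s == ncell - 1L
  down <- s == ncell - 2L
  # up cell: p_l >= index_l * step  <=>  num_l >= index_l * total
  if (any(up)) {
    g <- grid[up, , drop = FALSE]
    ok[up] <- g$i * total <= num[1] & g$j * total <= num[2] & g$k * total <= num[3]
  }
  # down cell: p_l <= (index_l + 1) * step  <=>  num_l <= (index_l + 1) * total
  if (any(down)) {
    g <- grid[down, , drop = FALSE]
    ok[down] <- (g$i + 1L) * total >= num[1] & (g$j + 1L) * total >= num[2] &
      (g$k + 1L) * total >= num[3]
  }
  out <- grid[ok, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    stop("internal error: no ternary cell contains the composition ",
         paste(c3, collapse = "/"), call. = FALSE)
  out
}

#' @export
print.pec_ternary <- function(x, ...) {
  cat(sprintf("Ternary PEC composition grid (step %d%%): %d organisms binned, %d excluded (total = 0)\n",
              x$step, sum(x$bins$n), x$n_excluded))
  top <- x$bins[order(-x$bins$n), , drop = FALSE]
  print.data.frame(head(top, 5L))
  invisible(x)
}
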