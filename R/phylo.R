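#' Normalize a taxon label for tree-census matching
#'
#' Species-tree label dialects differ from genome-database organism names in
#' case, surrounding quotes and the use of underscores for spaces. Matching
#' is exact after folding case, trimming, stripping single quotes, and
#' collapsing runs of spaces/underscores to a single space. Unmatched labels
#' are reported, never fuzzily guessed.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
normalize_taxon_label <- function(x) {
  x <- gsub("'", "", as.character(x), fixed = TRUE)
  x <- gsub("[ _]+", " ", x)
  tolower(trimws(x))
}

# read a Newick file or pass a phylo through; tolerates single-quoted labels
read_taxon_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L && file.exists(tree)) {
    txt <- paste(readLines(tree, warn = FALSE), collapse = "")
  } else if (is.character(tree) && length(tree) == 1L) {
    txt <- tree
  } else {
    stop("'tree' must be a phylo object, a Newick string, or a file path",
         call. = FALSE)
  }
  # protect spaces inside single-quoted labels, then drop the quotes
  m <- gregexpr("'[^']*'", txt)
  regmatches(txt, m) <- lapply(regmatches(txt, m), function(labs)
    gsub(" ", "_", gsub("'", "", labs, fixed = TRUE), fixed = TRUE))
  ape::read.tree(text = txt)
}

#' Prune a species tree to the organisms of a census
#'
#' Keeps exactly the leaves whose normalized label matches a normalized
#' census organism id; internal nodes left with a single child are
#' collapsed, summing branch lengths where present. Pruning is idempotent,
#' and pruning to a superset of the leaf set is the identity (up to
#' serialization).
#'
#' @param tree an `ape::phylo` object, a Newick string, or a path to a
#'   Newick file.
#' @param census a `pec_census`.
#' @param normalizer label-normalizing function applied to both sides
#'   (default [normalize_taxon_label()]).
#' @return the pruned `phylo` tree. Tips dropped for lack of a census match
#'   are listed in the `unmatched_tips` attribute.
#' @export
prune_to_census <- function(tree, census, normalizer = normalize_taxon_label) {
  tree <- read_taxon_tree(tree)
  tip_norm <- normalizer(tree$tip.label)
  org_norm <- normalizer(census$organism_id)
  keep <- tree$tip.label[tip_norm %in% org_norm]
  if (length(keep) == 0L)
    stop("no tree leaf matches any census organism; example tree labels: ",
         paste(head(tree$tip.label, 3), collapse = ", "),
         " | example organism ids: ",
         paste(head(census$organism_id, 3), collapse = ", "), call. = FALSE)
  pruned <- ape::keep.tip(tree, keep)
  attr(pruned, "unmatched_tips") <- setdiff(tree$tip.label, keep)
  pruned
}

#' Export per-leaf stacked-bar annotations for a pruned tree
#'
#' Builds an iTOL-compatible multi-value bar dataset carrying the three
#' family gene counts of every leaf's organism, in the fixed family order
#' [4Fe-4S] Fd, [2Fe-2S] Fd, Fld, plus the organism's domain. Every leaf
#' must match a census organism; a missing leaf is an error naming the leaf.
#'
#' @param tree a pruned `phylo` tree (or Newick string/path).
#' @param census a `pec_census`.
#' @param file optional path; when given, the iTOL dataset text is written
#'   there.
#' @param label dataset label shown in the iTOL legend.
#' @param colors three colour strings for the family bars.
#' @param normalizer label-normalizing function (default
#'   [normalize_taxon_label()]).
#' @return data frame `leaf`, `n_fd4`, `n_fd2`, `n_fld`, `domain` (one row
#'   per leaf) with the full dataset text in the `itol_text` attribute;
#'   returned invisibly when `file` is given.
#' @export
export_leaf_annotations <- function(tree, census, file = NULL,
                                    label = "PEC gene counts",
                                    colors = c("#d7191c", "#1a9641", "#2c7bb6"),
                                    normalizer = normalize_taxon_label) {
  tree <- read_taxon_tree(tree)
  idx <- match(normalizer(tree$tip.label), normalizer(census$organism_id))
  if (anyNA(idx))
    stop("tree leaf not present in census: ",
         tree$tip.label[which(is.na(idx))[1]], call. = FALSE)
  ann <- data.frame(
    leaf = tree$tip.label,
    n_fd4 = census$n_fd4[idx],
    n_fd2 = census$n_fd2[idx],
    n_fld = census$n_fld[idx],
    domain = census$domain[idx],
    stringsAsFactors = FALSE
  )
  fams <- pec_families()
  header <- c(
    "DATASET_MULTIBAR",
    "SEPARATOR COMMA",
    paste0("DATASET_LABEL,", label),
    "COLOR,#666666",
    paste0("FIELD_COLORS,", paste(colors, collapse = ",")),
    paste0("FIELD_LABELS,", paste(unname(fams), collapse = ",")),
    "DATA"
  )
  data_lines <- sprintf("%s,%d,%d,%d", ann$leaf, ann$n_fd4, ann$n_fd2, ann$n_fld)
  text <- paste(c(header, data_lines), collapse = "\n")
  attr(ann, "itol_text") <- text
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(ann))
  }
  ann
}
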