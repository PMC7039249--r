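#' PEC family labels
#'
#' Internal family codes and their display labels, in the fixed reporting
#' order used throughout the package: [4Fe-4S] Fd, [2Fe-2S] Fd, Fld.
#'
#' @return named character vector mapping family codes (`fd4`, `fd2`, `fld`)
#'   to display labels.
#' @export
#' @examples
#' pec_families()
pec_families <- function() {
  c(fd4 = "[4Fe-4S] Fd", fd2 = "[2Fe-2S] Fd", fld = "Fld")
}

#' Signature-to-family map
#'
#' The InterPro signatures used to classify genes into the three small
#' low-potential PEC families, plus the 7Fe ferredoxin signature, which marks
#' a sub-type within the [4Fe-4S] family and never creates a fourth count:
#'
#' * `IPR017896` -> `[4Fe-4S] Fd` (Fd cluster-binding domain)
#' * `IPR001041` -> `[2Fe-2S] Fd` (Fd cluster-binding domain)
#' * `IPR008254` -> `Fld` (flavodoxin/nitric oxide synthase)
#' * `IPR000813` -> 7Fe flag (one [3Fe-4S] + one [4Fe-4S] cluster)
#'
#' The length cutoff retains genes encoding proteins of at most `length_cutoff`
#' residues ("over 200" excluded, so 200 itself is kept); it bounds the census
#' to small single-domain carriers and avoids nitric-oxide-synthase false
#' positives on the flavodoxin signature.
#'
#' @param length_cutoff integer, residues; genes longer than this are dropped.
#' @return an object of class `pec_signature_map`.
#' @export
pec_signature_map <- function(length_cutoff = 200L) {
  length_cutoff <- check_count(length_cutoff, "length_cutoff", min = 1L)
  structure(
    list(
      families = c(IPR017896 = "fd4", IPR001041 = "fd2", IPR008254 = "fld"),
      seven_fe = "IPR000813",
      length_cutoff = length_cutoff
    ),
    class = "pec_signature_map"
  )
}

#' @export
print.pec_signature_map <- function(x, ...) {
  fams <- pec_families()
  cat("PEC signature map\n")
  for (acc in names(x$families))
    cat(sprintf("  %s -> %s\n", acc, fams[[x$families[[acc]]]]))
  cat(sprintf("  %s -> 7Fe flag (within %s)\n", x$seven_fe, fams[["fd4"]]))
  cat(sprintf("  length cutoff: <= %d residues\n", x$length_cutoff))
  invisible(x)
}

#' Classify one gene's signature set into PEC families
#'
#' Family membership is a pure function of the signature set: a gene belongs
#' to every primary family whose signature it carries (a gene matching both
#' Fd cluster signatures is counted in both families). The 7Fe signature
#' flags the gene but never adds a family. Accessions outside the map are
#' ignored.
#'
#' @param signatures character vector of signature accessions for one gene
#'   (a single semicolon-separated string is also accepted).
#' @param map a [pec_signature_map()].
#' @return list with `families` (character vector of family codes, possibly
#'   empty) and `seven_fe` (logical).
#' @export
#' @examples
#' classify_gene(c("IPR017896", "IPR000813"))
#' classify_gene("IPR999999")  # decoy: no family
classify_gene <- function(signatures, map = pec_signature_map()) {
  sigs <- split_accessions(signatures)
  fams <- unname(map$families[names(map$families) %in% sigs])
  list(families = fams, seven_fe = map$seven_fe %in% sigs)
}

# split ";"-joined accession strings into a unique accession vector
split_accessions <- function(x) {
  unique(trimws2(unlist(strsplit(as.character(x), ";", fixed = TRUE))))
}

# vectorised classification: one row per gene, logical membership columns
classify_signature_table <- function(sig_strings, map = pec_signature_map()) {
  sets <- lapply(sig_strings, split_accessions)
  known <- c(names(map$families), map$seven_fe)
  out <- data.frame(row.names = seq_along(sets))
  for (code in names(pec_families())) {
    accs <- names(map$families)[map$families == code]
    out[[code]] <- vapply(sets, function(s) any(accs %in% s), logical(1))
  }
  out$seven_fe <- vapply(sets, function(s) map$seven_fe %in% s, logical(1))
  unknown <- unlist(lapply(sets, function(s) s[!s %in% known & nzchar(s)]))
  attr(out, "unknown_accessions") <- table(unknown)
  out
}
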